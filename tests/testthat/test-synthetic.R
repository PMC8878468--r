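# synthetic_data module: truth tables, rendering, plate kinetics

test_that("cell_truth enforces its invariants", {
  t0 <- sample_cell_truth(30, seed = 1)
  expect_s3_class(t0, "cell_truth")

  bad <- as.data.frame(t0)
  bad$pyknosed_subclass[bad$nucleus_class == "healthy"][1] <- "mitotic"
  expect_error(cell_truth(bad), "pyknosed_subclass")

  bad2 <- as.data.frame(t0)
  i <- which(bad2$nucleus_class != "healthy")[1]
  bad2$tubulin_effect[i] <- TRUE
  expect_error(cell_truth(bad2), "tubulin_effect")

  bad3 <- as.data.frame(t0)
  bad3$fucci_state[1] <- "red"
  expect_error(cell_truth(bad3, mode = "highvia_extend"), "fucci")

  # phenotype booleans defined exactly on healthy nuclei
  t1 <- sample_cell_truth(200, viability_probs = c(
    healthy = 0.5, early_apoptotic = 0.2, late_apoptotic = 0.1,
    necrotic = 0.1, lysed = 0.1), phenotype_probs = c(
    tubulin = 0.3, mito = 0.3, membrane = 0.3), seed = 2)
  healthy <- t1$nucleus_class == "healthy"
  expect_true(all(!is.na(t1$tubulin_effect[healthy])))
  expect_true(all(is.na(t1$tubulin_effect[!healthy])))
  expect_true(all((t1$pyknosed_subclass != "n/a") ==
                    (t1$nucleus_class == "pyknosed")))
})

test_that("render_field: empty field, determinism, bounds, packing", {
  prm <- small_params()
  empty <- cell_truth(data.frame(
    cell_id = integer(0), x = numeric(0), y = numeric(0),
    nucleus_class = character(0), pyknosed_subclass = character(0),
    viability_class = character(0), fucci_state = character(0),
    tubulin_effect = logical(0), mito_mass_increased = logical(0),
    membrane_permeable = logical(0)))
  f0 <- render_field(empty, params = prm, seed = 3,
                     channels = c("hoechst", "bf"))
  expect_equal(max(f0$nuclei_mask), 0L)
  # background-only: intensities near the configured background everywhere
  proj <- project_stack(f0$channels$hoechst)
  expect_lt(quantile(proj, 0.999), prm$bg[["hoechst"]] * 1.5)

  truth <- sample_cell_truth(50, params = prm, min_spacing = 25, seed = 4)
  f1 <- render_field(truth, params = prm, seed = 5)
  f2 <- render_field(truth, params = prm, seed = 5)
  expect_identical(f1$channels, f2$channels)   # bit-exact reproducibility
  expect_identical(f1$nuclei_mask, f2$nuclei_mask)

  out <- as.data.frame(truth)
  out$x[1] <- prm$field[1] + 10
  expect_error(render_field(cell_truth(out), params = prm, seed = 6),
               "field bounds")

  dense <- sample_cell_truth(60, params = render_params(
    field = c(100L, 100L), packing_limit = 0.2), min_spacing = 2,
    margin = 5, seed = 7)
  expect_error(render_field(dense, params = render_params(
    field = c(100L, 100L)), seed = 8), "packing")
})

test_that("precipitate artifact renders as one bright component", {
  prm <- small_params()
  truth <- sample_cell_truth(10, params = prm, seed = 9)
  art <- artifact_truth("precipitate", x = 160, y = 160, size = 12,
                        intensity_scale = 8)
  fld <- render_field(truth, artifacts = list(art), params = prm,
                      seed = 10, channels = "hoechst")
  proj <- project_stack(fld$channels$hoechst)
  # recompute from the rendered array: nuclear means from the truth mask
  nuc_means <- tapply(proj[fld$nuclei_mask > 0],
                      fld$nuclei_mask[fld$nuclei_mask > 0], mean)
  ref <- median(nuc_means)
  bright <- proj > 4 * ref
  lab <- phenogate:::.label_components_cpp(bright, TRUE)
  areas <- tabulate(lab[lab > 0])
  big <- which(areas > 20)  # ignore stray bright single pixels
  expect_identical(length(big), 1L)
  expect_gt(mean(proj[lab == big]), 4 * ref)
  # and it coincides with the artifact's truth footprint
  expect_gt(mean(fld$artifact_mask[lab == big] > 0), 0.5)
  expect_error(artifact_truth("precipitate", 1, 1, intensity_scale = 0.5),
               "intensity_scale")
})

test_that("plate design validation and config round-trip", {
  expect_error(make_plate_design(letters[1:50]), "wells available")
  d <- make_plate_design(c("a", "b"), concentrations = c(1, 10),
                         timepoints = c(0, 24))
  expect_s3_class(d, "plate_design")
  # outer wells rejected
  w <- d$wells
  w$well[1] <- "A01"
  expect_error(plate_design(w, mode = d$mode), "outer wells")
  # < 2 DMSO wells rejected
  w2 <- d$wells[d$wells$role != "dmso_control", ]
  expect_error(plate_design(w2), "dmso_control")

  path <- withr::local_tempfile(fileext = ".txt")
  write_plate_design(d, path)
  d2 <- read_plate_design(path)
  expect_equal(d2$wells, d$wells)
  expect_equal(d2$timepoints, d$timepoints)
  expect_equal(d2$basal_growth_rate, d$basal_growth_rate)
})

test_that("simulate_plate: conservation, determinism, DMSO growth", {
  d <- make_plate_design("cmpd", concentrations = serial_dilution(10, 4),
                         timepoints = c(0, 12, 24, 48), n_dmso = 3)
  kin <- list(cmpd = kinetics_spec(1, kinetic_class = "intermediate"))
  expect_error(simulate_plate(d, list(), seed = 1), "missing kinetics")

  sim <- simulate_plate(d, kin, seed = 11)
  cc <- sim$counts
  # conservation at every time point
  tot <- cc$n_healthy + cc$n_early_apoptotic + cc$n_late_apoptotic +
    cc$n_necrotic + cc$n_lysed + cc$n_cleared
  expect_identical(tot, cc$n_total_created)
  expect_identical(simulate_plate(d, kin, seed = 11)$counts, cc)

  # DMSO wells: expected healthy count strictly increasing (mean over seeds)
  mean_traj <- Reduce(`+`, lapply(1:20, function(s) {
    x <- simulate_plate(d, kin, seed = 100 + s)$counts
    dm <- x[x$role == "dmso_control", ]
    tapply(dm$n_healthy, dm$timepoint, mean)
  })) / 20
  expect_true(all(diff(mean_traj) > 0))
})

test_that("expected healthy fraction is non-increasing in concentration", {
  set.seed(42)
  for (rep in 1:12) {
    kin <- kinetics_spec(
      ic50 = 10^runif(1, -2, 1), hill = runif(1, 0.5, 3),
      kinetic_class = sample(c("rapid", "intermediate", "slow"), 1),
      terminal_state_bias = setNames(runif(3) + 0.05,
                                     c("apoptotic", "necrotic", "lysed")))
    tt <- sample(c(12, 24, 48, 72), 1)
    conc <- sort(10^runif(8, -3, 2))
    h <- vapply(conc, function(cv)
      expected_trajectory(kin, cv, tt)$H, numeric(1))
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("rapid compounds cross 50% earlier than slow (sample of seeds)", {
  d <- make_plate_design(c("fast", "slow"), concentrations = 10,
                         timepoints = seq(0, 48, by = 4))
  kin <- list(fast = kinetics_spec(1, kinetic_class = "rapid"),
              slow = kinetics_spec(1, kinetic_class = "slow"))
  cross_time <- function(cc, cmpd) {
    x <- cc[!is.na(cc$compound) & cc$compound == cmpd, ]
    dm <- cc[cc$role == "dmso_control", ]
    dm_mean <- tapply(dm$n_healthy, dm$timepoint, mean)
    frac <- x$n_healthy / dm_mean[as.character(x$timepoint)]
    t_hit <- x$timepoint[frac < 0.5]
    if (length(t_hit)) min(t_hit) else Inf
  }
  wins <- vapply(1:20, function(s) {
    cc <- simulate_plate(d, kin, seed = 500 + s)$counts
    cross_time(cc, "fast") < cross_time(cc, "slow")
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("G1-arrest compound raises red fraction above DMSO at 18 h", {
  d <- make_plate_design("g1", concentrations = 1, mode = "fucci",
                         timepoints = c(0, 18), n_dmso = 4)
  kin <- list(g1 = kinetics_spec(1, cell_cycle_action = "g1_arrest"))
  up <- vapply(1:10, function(s) {
    cc <- simulate_plate(d, kin, seed = 900 + s)$counts
    tr <- cc[cc$role == "treatment" & cc$timepoint == 18, ]
    dm <- cc[cc$role == "dmso_control" & cc$timepoint == 18, ]
    tr$n_red / tr$n_healthy > mean(dm$n_red / dm$n_healthy)
  }, logical(1))
  expect_gte(mean(up), 0.9)
})

test_that("materialize_well preserves fractions and caps cells", {
  d <- make_plate_design("cmpd", concentrations = 10,
                         timepoints = c(0, 24), n0 = 500L)
  kin <- list(cmpd = kinetics_spec(1, kinetic_class = "intermediate",
                                   phenotype_probs = c(tubulin = 0.5,
                                                       mito = 0,
                                                       membrane = 0)))
  sim <- simulate_plate(d, kin, seed = 13)
  dm_well <- d$wells$well[d$wells$role == "dmso_control"][1]
  tr_well <- d$wells$well[d$wells$role == "treatment"][1]
  truth <- materialize_well(sim, dm_well, 24, max_cells = 300)
  expect_lte(nrow(truth), 300)
  row <- sim$counts[sim$counts$well == dm_well & sim$counts$timepoint == 24, ]
  expect_equal(mean(truth$viability_class == "healthy"),
               row$n_healthy / (row$n_healthy + row$n_early_apoptotic +
                                  row$n_late_apoptotic + row$n_necrotic +
                                  row$n_lysed),
               tolerance = 0.05)
  tr_truth <- materialize_well(sim, tr_well, 24, max_cells = 300)
  h <- tr_truth$nucleus_class == "healthy"
  # phenotype probabilities flow from the kinetics spec into healthy cells
  expect_gt(mean(tr_truth$tubulin_effect[h]), 0.1)
})
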