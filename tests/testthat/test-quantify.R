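# quantify module: fractions, normalization, GR, 4PL, flags, reporting

test_that("well_fractions arithmetic and FUCCI exclusion rule", {
  rec <- data.frame(
    label_hio = "normal",
    label_nuclei = rep(c("healthy", "pyknosed", "fragmented"),
                       c(80, 15, 5)))
  s <- well_fractions(rec, min_count = 50)
  expect_equal(s$frac_nuclei_healthy, 0.80)
  expect_equal(s$frac_nuclei_pyknosed, 0.15)
  expect_equal(s$frac_nuclei_fragmented, 0.05)
  expect_equal(s$frac_nuclei_healthy + s$frac_nuclei_pyknosed +
                 s$frac_nuclei_fragmented, 1, tolerance = 1e-12)
  expect_false(s$low_count_flag)

  recf <- data.frame(
    label_hio = "normal", label_nuclei = "healthy",
    label_fucci = rep(c("red", "green", "yellow", "unlabeled"),
                      c(40, 40, 10, 10)))
  sf <- well_fractions(recf, min_count = 10)
  expect_equal(sf$frac_fucci_red, 4 / 9)
  expect_equal(sf$frac_fucci_green, 4 / 9)
  expect_equal(sf$frac_fucci_yellow, 1 / 9)
  expect_identical(sf$n_fucci_labeled, 90L)

  # zero cells: null fractions + low-count flag
  s0 <- well_fractions(rec[0, ], min_count = 50)
  expect_true(s0$low_count_flag)
  expect_true(is.na(s0$frac_nuclei_healthy))

  # random label multiset vs brute-force counting loop
  withr::with_seed(9, {
    labs <- sample(c("healthy", "pyknosed", "fragmented"), 500, TRUE,
                   prob = c(0.6, 0.3, 0.1))
  })
  sr <- well_fractions(data.frame(label_hio = "normal",
                                  label_nuclei = labs))
  for (cl in c("healthy", "pyknosed", "fragmented")) {
    cnt <- 0L
    for (x in labs) if (x == cl) cnt <- cnt + 1L
    expect_identical(sr[[paste0("n_nuclei_", cl)]], cnt)
    expect_equal(sr[[paste0("frac_nuclei_", cl)]], cnt / 500)
  }
})

test_that("normalize_to_dmso uses the plate/timepoint DMSO mean", {
  d <- make_plate_design("c1", concentrations = 1, timepoints = 24,
                         n_dmso = 2, n_untreated = 0)
  wells <- d$wells$well
  s <- data.frame(well = wells, timepoint = 24,
                  n_healthy_nuclei = c(120, 100, 140))
  # wells: 1 treatment (120), 2 dmso (100, 140)
  out <- normalize_to_dmso(s, d)
  expect_equal(out$healthy_nuclei_norm, c(1.0, 100 / 120, 140 / 120))
  dm <- d$wells$role == "dmso_control"
  expect_equal(mean(out$healthy_nuclei_norm[dm]), 1, tolerance = 1e-12)
  s2 <- data.frame(well = wells[1], timepoint = 24, n_healthy_nuclei = 60)
  d1 <- d; d1$wells <- d1$wells[1, , drop = FALSE]
  expect_error(normalize_to_dmso(s2, d1), "DMSO")
})

test_that("growth rate closed forms and property vs re-implementation", {
  expect_equal(growth_rate(400, 100, 400), 1, tolerance = 1e-12)
  expect_equal(growth_rate(100, 100, 400), 0, tolerance = 1e-12)
  expect_equal(growth_rate(200, 100, 400), 2^0.5 - 1, tolerance = 1e-12)
  expect_error(growth_rate(100, 100, 90), "undefined|grow")
  expect_error(growth_rate(-1, 100, 400), "positive")

  gr_ref <- function(x_c, x_0, x_ctrl)   # independent re-implementation
    exp(log(2) * (log(x_c / x_0) / log(x_ctrl / x_0))) - 1
  withr::with_seed(10, {
    for (i in 1:10000) {
      x0 <- runif(1, 10, 1000)
      xc <- runif(1, 1, 5000)
      xctrl <- x0 * runif(1, 1.01, 8)
      expect_equal(growth_rate(xc, x0, xctrl), gr_ref(xc, x0, xctrl),
                   tolerance = 1e-12)
    }
  })
})

test_that("4PL fitting: recovery, degeneracy, equivariance", {
  conc <- serial_dilution(10, 7)
  y <- 1 / (1 + (conc / 1.0)^1)
  fit <- fit_dose_response(conc, y, timepoint = 24)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1, tolerance = 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-3)
  expect_lte(fit$bottom, fit$top)

  # all responses flat -> no finite potency
  flat <- fit_dose_response(conc, rep(1, 7))
  expect_false(flat$converged)
  expect_match(flat$reason, "no effect")

  expect_error(fit_dose_response(conc[1:3], y[1:3]), ">= 4")

  # unit relabeling shifts IC50 by exactly 1e3 (float-precision exact)
  fit_nM <- fit_dose_response(conc * 1e3, y)
  expect_equal(fit_nM$ic50 / fit$ic50, 1e3, tolerance = 1e-9)

  # quick noise check (full Monte-Carlo lives in the acceptance suite)
  errs <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      yn <- y * exp(rnorm(7, 0, 0.05))
    })
    abs(log10(fit_dose_response(conc, yn)$ic50))
  }, numeric(1))
  expect_lte(median(errs), log10(1.25))
})

test_that("flag_compound matches the stated threshold examples", {
  lines <- c("U2OS", "HEK293T", "MRC9")
  base <- expand.grid(compound = "c1", cell_line = lines,
                      concentration = 10, timepoint = 24,
                      stringsAsFactors = FALSE)
  base$low_count_flag <- FALSE
  base$hio_ratio <- 0.05
  base$frac_nuclei_healthy <- 0.9
  base$frac_nuclei_pyknosed <- 0.06
  base$frac_nuclei_fragmented <- 0.04
  base$frac_tubulin_effect <- 0.05
  base$frac_mito_increased <- 0.05
  base$frac_membrane_permeable <- 0.02

  # DMSO-like values: zero flags
  expect_false(flag_compound(base, "c1")$flagged_overall)

  # healthy 0.45 in all three lines
  s1 <- base; s1$frac_nuclei_healthy <- 0.45
  c1 <- flag_compound(s1, "c1")
  expect_true(c1$flagged_overall)
  expect_identical(c1$flags, "healthy_nuclei_lt_50")

  # tubulin 0.92 in all three lines, all else nominal
  s2 <- base; s2$frac_tubulin_effect <- 0.92
  expect_identical(flag_compound(s2, "c1")$flags, "tubulin_gt_50")

  # firing in only two of three lines does not flag
  s3 <- base; s3$frac_tubulin_effect <- c(0.92, 0.92, 0.3)
  expect_false(flag_compound(s3, "c1")$flagged_overall)

  # missing cell line: evaluated over available lines with a note
  s4 <- s1[s1$cell_line != "MRC9", ]
  c4 <- flag_compound(s4, "c1", cell_lines = lines)
  expect_true(c4$incomplete_panel)
  expect_match(c4$notes, "incomplete-panel")
  expect_true("healthy_nuclei_lt_50" %in% c4$flags)

  # low-count wells never fire rules
  s5 <- s1; s5$low_count_flag <- TRUE
  expect_false(flag_compound(s5, "c1")$flagged_overall)
})

test_that("flag engine agrees with the brute-force evaluator (sample)", {
  # 200 randomized tables here; the full 1000 run in the acceptance suite
  for (s in 1:200) {
    tab <- random_summary_table(1, seed = 3000 + s)
    got <- sort(flag_compound(tab, "c1")$flags)
    ref <- brute_force_flags(tab, "c1")
    expect_identical(got, ref)
  }
})

test_that("population_heatmap_table is tidy and round-trips", {
  s <- expand.grid(compound = c("a", "b"), timepoint = c(12, 24),
                   cell_line = "U2OS", concentration = 10,
                   stringsAsFactors = FALSE)
  s$hio_ratio <- seq(0.1, 0.8, length.out = 4)
  s$frac_nuclei_healthy <- seq(0.9, 0.3, length.out = 4)
  s$frac_tubulin_effect <- seq(0.05, 0.65, length.out = 4)
  tab <- population_heatmap_table(s)
  expect_identical(nrow(tab), 12L)  # 2 compounds x 2 timepoints x 3 metrics

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  tab2 <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(tab2$value, tab$value)
  expect_identical(tab2$metric, tab$metric)

  # biological duplicates: arithmetic mean, replicates retained
  s2 <- rbind(s[1, ], s[1, ])
  s2$hio_ratio <- c(0.2, 0.4)
  t2 <- population_heatmap_table(s2, metrics = "hio_ratio")
  expect_identical(nrow(t2), 1L)
  expect_equal(t2$value, 0.3)  # (0.2 + 0.4) / 2 by hand
  expect_identical(t2$n_replicates, 2L)
  expect_match(t2$values, "0.2;0.4")
})
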