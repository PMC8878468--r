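# features module: closed-form shapes, generator contrasts, invariances

disk_mask <- function(n, cx, cy, r, label = 1L) {
  xg <- matrix(rep(1:n, each = n), n)
  yg <- matrix(rep(1:n, times = n), n)
  m <- matrix(0L, n, n)
  m[(xg - cx)^2 + (yg - cy)^2 <= r^2] <- label
  m
}

test_that("closed-form nucleus features on a perfect disk", {
  nuc <- disk_mask(64, 32, 32, 11)
  img <- matrix(500, 64, 64)
  img[nuc > 0] <- 2000
  f <- nuclear_features(nuc, img)
  expect_equal(nrow(f), 1L)
  expect_equal(f$nuc_compactness, 1, tolerance = 0.1)
  expect_lt(f$nuc_cv_dna, 0.02)           # uniform intensity
  expect_equal(f$nuc_area, sum(nuc > 0))
  expect_equal(f$nuc_fragment_count, 1)
  expect_equal(f$nuc_fragment_area_frac, 0)
  expect_equal(f$nuc_eccentricity, 0, tolerance = 0.1)
  expect_gt(f$nuc_solidity, 0.9)
  expect_equal(f$nuc_radial_ratio, 1, tolerance = 0.05)

  expect_identical(nrow(nuclear_features(matrix(0L, 10, 10),
                                         matrix(0, 10, 10))), 0L)
})

test_that("pyknosed nuclei are smaller and brighter than healthy (n=200)", {
  prm <- train_params()
  per_field <- 115
  stats <- list()
  for (k in 1:4) {
    truth <- sample_cell_truth(
      per_field, viability_probs = c(healthy = 0.5, early_apoptotic = 0.5,
                                     late_apoptotic = 0, necrotic = 0,
                                     lysed = 0),
      mitotic_fraction = 0, params = prm, seed = 30 + k)
    fld <- render_field(truth, params = prm, seed = 40 + k,
                        channels = "hoechst")
    proj <- project_stack(fld$channels$hoechst)
    nuc <- segment_nuclei(proj)
    f <- nuclear_features(nuc, proj)
    cent <- mask_centroids(nuc)
    cls <- vapply(seq_len(nrow(cent)), function(i) {
      j <- which.min((truth$x - cent$x[i])^2 + (truth$y - cent$y[i])^2)
      truth$nucleus_class[j]
    }, character(1))
    stats[[k]] <- data.frame(cls = cls, area = f$nuc_area,
                             mean = f$nuc_mean_dna)
  }
  s <- do.call(rbind, stats)
  expect_gte(sum(s$cls == "pyknosed"), 200)
  expect_gte(sum(s$cls == "healthy"), 200)
  expect_gt(mean(s$mean[s$cls == "pyknosed"]),
            mean(s$mean[s$cls == "healthy"]))
  expect_lt(mean(s$area[s$cls == "pyknosed"]),
            mean(s$area[s$cls == "healthy"]))
})

test_that("mito-increased cells show elevated cytoplasmic mito signal", {
  prm <- train_params()
  rows <- list()
  for (k in 1:4) {
    truth <- sample_cell_truth(100, mode = "multiplex",
                               phenotype_probs = c(tubulin = 0, mito = 0.5,
                                                   membrane = 0),
                               mitotic_fraction = 0, params = prm,
                               seed = 50 + k)
    fld <- render_field(truth, params = prm, seed = 60 + k)
    ext <- extract_features(fld)
    rows[[k]] <- label_features_with_truth(ext, truth)
  }
  lf <- do.call(rbind, rows)
  inc <- lf$true_mito_mass_increased
  expect_gte(sum(inc), 150)
  expect_gte(sum(!inc), 150)
  expect_gt(mean(lf$cyto_mean_561[inc]), mean(lf$cyto_mean_561[!inc]))
})

test_that("features are translation-invariant and mask-local", {
  nuc <- disk_mask(96, 40, 36, 9)
  body <- disk_mask(96, 40, 36, 20)
  attr(body, "nucleus_group") <- data.frame(nucleus = 1L, body = 1L)
  withr::with_seed(77, {
    ch <- list(ch488 = matrix(runif(96 * 96, 100, 200), 96),
               ch561 = matrix(runif(96 * 96, 100, 200), 96),
               ch640 = matrix(runif(96 * 96, 100, 200), 96),
               bf = matrix(runif(96 * 96, 1000, 1100), 96))
  })
  hoechst <- matrix(300, 96, 96)
  hoechst[nuc > 0] <- 2500
  f1n <- nuclear_features(nuc, hoechst, body)
  f1c <- cell_features(body, nuc, ch, mode = "highvia_extend")

  # translate everything by (7, 11) with wrap-around (pure permutation, so
  # background percentiles are unchanged)
  roll <- function(m, dy, dx) {
    m2 <- m[c((nrow(m) - dy + 1):nrow(m), 1:(nrow(m) - dy)), ]
    m2[, c((ncol(m) - dx + 1):ncol(m), 1:(ncol(m) - dx))]
  }
  nuc2 <- roll(nuc, 11, 7); body2 <- roll(body, 11, 7)
  attr(body2, "nucleus_group") <- data.frame(nucleus = 1L, body = 1L)
  ch2 <- lapply(ch, roll, dy = 11, dx = 7)
  f2n <- nuclear_features(nuc2, roll(hoechst, 11, 7), body2)
  f2c <- cell_features(body2, nuc2, ch2, mode = "highvia_extend")
  for (col in setdiff(names(f1n), "cell_id"))
    expect_equal(f2n[[col]], f1n[[col]], tolerance = 1e-9, label = col)
  for (col in setdiff(names(f1c), c("cell_id", "no_cytoplasm")))
    expect_equal(f2c[[col]], f1c[[col]], tolerance = 1e-9, label = col)

  # mask-locality: editing pixels outside the body never changes the
  # cell's features (edits avoid the bottom quantile so the field-level
  # background estimate is untouched)
  ch3 <- ch
  edit <- body == 0 & ch$ch488 > quantile(ch$ch488, 0.2)
  ch3$ch488[edit] <- 1e5
  f3c <- cell_features(body, nuc, ch3, mode = "highvia_extend")
  expect_identical(f3c$cyto_sd_488, f1c$cyto_sd_488)
  expect_identical(f3c$cyto_mean_488, f1c$cyto_mean_488)
})

test_that("degenerate body equal to nucleus yields zeroed cytoplasm", {
  nuc <- disk_mask(48, 24, 24, 10)
  body <- nuc
  attr(body, "nucleus_group") <- data.frame(nucleus = 1L, body = 1L)
  ch <- list(ch488 = matrix(150, 48, 48), ch561 = matrix(150, 48, 48),
             ch640 = matrix(150, 48, 48), bf = matrix(1000, 48, 48))
  f <- cell_features(body, nuc, ch, mode = "highvia_extend")
  expect_true(f$no_cytoplasm)
  expect_identical(f$cyto_mean_488, 0)
  expect_identical(f$cyto_sd_561, 0)

  # missing channel for the mode errors naming the channel
  expect_error(cell_features(body, nuc, ch[c("ch488", "bf")],
                             mode = "multiplex"), "ch561")
})
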