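# segmentation module: projection, phase contrast, nuclei, cell bodies

test_that("project_stack: identity, zero slice, brute-force oracle", {
  m <- matrix(runif(30 * 20), 30, 20)
  expect_identical(project_stack(list(m)), m)
  expect_identical(project_stack(list(m, matrix(0, 30, 20))), m)

  withr::with_seed(5, {
    stack <- lapply(1:7, function(z) matrix(runif(30 * 20), 30, 20))
  })
  got <- project_stack(stack)
  ref <- matrix(0, 30, 20)
  for (r in 1:30) for (c in 1:20)
    ref[r, c] <- max(vapply(stack, function(s) s[r, c], numeric(1)))
  expect_identical(got, ref)

  expect_error(project_stack(list()), "non-empty")
  expect_error(project_stack(list(m, matrix(0, 10, 10))), "share dimensions")
})

test_that("digital_phase_contrast: symmetry, support, level", {
  base <- matrix(100, 60, 60)
  stack <- lapply(1:7, function(z) base)
  expect_true(all(digital_phase_contrast(stack) == 0))

  # slices differing only inside a disk -> support exactly that disk
  xg <- matrix(rep(1:60, each = 60), 60)
  yg <- matrix(rep(1:60, times = 60), 60)
  disk <- (xg - 30)^2 + (yg - 30)^2 <= 10^2
  s5 <- base
  s5[disk] <- 160
  stack[[5]] <- s5
  d <- digital_phase_contrast(stack)
  expect_identical(d > 0, disk)

  # level above the maximum normalized difference -> all zero
  d2 <- digital_phase_contrast(stack, level = 0.5)
  expect_true(all(d2 == 0))

  expect_error(digital_phase_contrast(stack, z_lo = 5, z_hi = 3), "z_lo")
  expect_error(digital_phase_contrast(stack, z_lo = 1, z_hi = 9), "z_lo")
  expect_error(digital_phase_contrast(stack, level = 0), "level")
})

test_that("segment_nuclei: blank image and generator field", {
  blank <- matrix(300, 200, 200)
  lab <- segment_nuclei(blank)
  expect_identical(attr(lab, "n_objects"), 0L)

  prm <- render_params(field = c(640L, 640L))
  truth <- sample_cell_truth(80, params = prm, seed = 21)
  fld <- render_field(truth, params = prm, seed = 22, channels = "hoechst")
  nuc <- segment_nuclei(project_stack(fld$channels$hoechst))
  expect_identical(attr(nuc, "n_objects"), 80L)
  cent <- mask_centroids(nuc)
  d <- vapply(seq_len(nrow(truth)), function(i)
    sqrt(min((cent$x - truth$x[i])^2 + (cent$y - truth$y[i])^2)),
    numeric(1))
  expect_lt(max(d), 1)
  # labels consecutive 1..K and masks form a partition by construction
  expect_identical(sort(unique(as.vector(nuc[nuc > 0]))), 1:80)
})

test_that("fragmented nuclei stay split at segmentation", {
  prm <- small_params()
  truth <- sample_cell_truth(
    5, viability_probs = c(healthy = 0, early_apoptotic = 0,
                           late_apoptotic = 1, necrotic = 0, lysed = 0),
    params = prm, min_spacing = 80, margin = 40, seed = 23)
  fld <- render_field(truth, params = prm, seed = 24, channels = "hoechst")
  nuc <- segment_nuclei(project_stack(fld$channels$hoechst))
  cent <- mask_centroids(nuc)
  per_cell <- vapply(seq_len(nrow(truth)), function(i)
    sum((cent$x - truth$x[i])^2 + (cent$y - truth$y[i])^2 <=
          prm$body_radius^2), numeric(1))
  expect_gte(mean(per_cell >= 2), 0.5)  # fragments are NOT merged
})

test_that("segment_nuclei is translation-equivariant and scale-invariant", {
  prm <- small_params()
  truth <- sample_cell_truth(20, params = prm, margin = 45, seed = 25)
  fld <- render_field(truth, params = prm, seed = 26, channels = "hoechst")
  proj <- project_stack(fld$channels$hoechst)
  lab1 <- segment_nuclei(proj)

  # translate by (7, 11) px with background padding
  h <- nrow(proj); w <- ncol(proj)
  shifted <- matrix(median(proj), h, w)
  shifted[(1 + 11):h, (1 + 7):w] <- proj[1:(h - 11), 1:(w - 7)]
  lab2 <- segment_nuclei(shifted)
  expect_identical(attr(lab2, "n_objects"), attr(lab1, "n_objects"))
  c1 <- mask_centroids(lab1)
  c2 <- mask_centroids(lab2)
  ord1 <- order(c1$x, c1$y); ord2 <- order(c2$x, c2$y)
  expect_equal(c2$x[ord2], c1$x[ord1] + 7, tolerance = 0.2)
  expect_equal(c2$y[ord2], c1$y[ord1] + 11, tolerance = 0.2)

  # multiplicative intensity rescaling: log-Otsu default
  lab3 <- segment_nuclei(proj * 3.7)
  expect_identical(lab3[, ], lab1[, ])
  # affine rescaling with the quantile method
  qp <- segment_params(threshold_method = "quantile", quantile = 0.9)
  expect_identical(segment_nuclei(2.5 * proj + 40, qp)[, ],
                   segment_nuclei(proj, qp)[, ])
})

test_that("segment_cell_bodies: partition, grouping, fallback", {
  # two nuclei inside one connected foreground blob -> two disjoint bodies
  # exhausting the blob
  h <- 120; w <- 120
  xg <- matrix(rep(1:w, each = h), h)
  yg <- matrix(rep(1:h, times = w), h)
  blob <- ((xg - 60)^2 / 45^2 + (yg - 60)^2 / 25^2) <= 1
  contrast <- matrix(0, h, w)
  contrast[blob] <- 0.5
  nuclei <- matrix(0L, h, w)
  nuclei[(xg - 40)^2 + (yg - 60)^2 <= 64] <- 1L
  nuclei[(xg - 80)^2 + (yg - 60)^2 <= 64] <- 2L
  attr(nuclei, "n_objects") <- 2L
  body <- segment_cell_bodies(contrast, nuclei, group_radius = 10,
                              fg_threshold = 0.25)
  expect_identical(attr(body, "n_objects"), 2L)
  expect_true(all(body[blob] > 0))                    # exhaustive
  expect_identical(sort(unique(as.vector(body[blob]))), 1:2) # disjoint
  expect_true(all(body[nuclei == 1] == body[nuclei == 1][1]))
  expect_identical(body[nuclei == 1][1] == body[nuclei == 2][1], FALSE)

  # nucleus with no foreground support -> fallback disk
  nuclei2 <- matrix(0L, h, w)
  nuclei2[(xg - 30)^2 + (yg - 30)^2 <= 36] <- 1L
  body2 <- segment_cell_bodies(matrix(0, h, w), nuclei2,
                               fallback_radius = 10, fg_threshold = 0.5)
  expect_identical(attr(body2, "fallback"), 1L)
  expect_gt(sum(body2 == 1), sum(nuclei2 == 1))

  # fragmented nucleus objects within group_radius share one body
  nuclei3 <- matrix(0L, h, w)
  nuclei3[(xg - 55)^2 + (yg - 55)^2 <= 16] <- 1L
  nuclei3[(xg - 68)^2 + (yg - 62)^2 <= 16] <- 2L
  body3 <- segment_cell_bodies(contrast, nuclei3, group_radius = 25,
                               fg_threshold = 0.25)
  expect_identical(attr(body3, "n_objects"), 1L)
  gm <- attr(body3, "nucleus_group")
  expect_identical(gm$body, c(1L, 1L))

  expect_error(segment_cell_bodies(matrix(0, 10, 10), nuclei), "shapes")
})
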