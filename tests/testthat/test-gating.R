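# gating module: node training, rule fallbacks, hierarchy contracts

test_that("train_node validates its inputs", {
  withr::with_seed(1, {
    feats <- data.frame(matrix(rnorm(60 * 13), 60, 13))
  })
  names(feats) <- nucleus_feature_set()
  feats$label <- rep(c("healthy", "pyknosed"), each = 30)
  # missing class listed by name
  expect_error(train_node("NUCLEI3", feats, seed = 1), "fragmented")
  feats$label[1] <- "weird"
  expect_error(train_node("NUCLEI3", feats, seed = 1), "outside node classes")
  feats$label[1] <- "healthy"
  feats$label[31:60] <- c(rep("pyknosed", 15), rep("fragmented", 15))
  expect_error(train_node("NUCLEI3", feats, seed = 1), ">= 20")
})

test_that("training is deterministic and ties give intermediate posteriors", {
  withr::with_seed(2, {
    X <- data.frame(matrix(rnorm(300 * 13), 300, 13))
  })
  names(X) <- nucleus_feature_set()
  X$label <- ifelse(X$nuc_area > 0, "healthy",
                    ifelse(X$nuc_mean_dna > 0, "pyknosed", "fragmented"))
  n1 <- train_node("NUCLEI3", X, seed = 7)
  n2 <- train_node("NUCLEI3", X, seed = 7)
  probe <- X[1:40, ]
  expect_identical(predict(n1, probe), predict(n2, probe))

  # two identical feature rows with conflicting labels: training succeeds,
  # posterior stays away from certainty on that point
  dup <- X[rep(1, 60), ]
  dup$label <- rep(c("healthy", "pyknosed"), 30)
  filler <- X[2:41, ]
  filler$label <- "fragmented"
  tied <- train_node("NUCLEI3", rbind(dup, filler), seed = 8)
  p <- predict(tied, dup[1, ])
  expect_lt(p$p_healthy, 0.8)
  expect_gt(p$p_healthy, 0.2)
})

test_that("classify_hio rule fallback follows the stated thresholds", {
  f <- data.frame(nuc_mean_dna = c(1000, 4100, 900, 2100),
                  nuc_solidity = c(0.9, 0.9, 0.4, 0.4))
  got <- classify_hio(f, ref_intensity = 1000)
  expect_identical(got$label,
                   c("normal", "high_intensity_object", "normal",
                     "high_intensity_object"))
  # default reference: median nuclear mean of the field
  f2 <- data.frame(nuc_mean_dna = c(rep(1000, 9), 9000),
                   nuc_solidity = rep(0.9, 10))
  expect_identical(classify_hio(f2)$label[10], "high_intensity_object")
})

test_that("hierarchy contracts are enforced as errors", {
  f <- data.frame(matrix(rnorm(5 * 13), 5, 13))
  names(f) <- nucleus_feature_set()
  node <- cached_nuclei3()
  f$label_hio <- c("normal", "normal", "high_intensity_object", "normal",
                   "normal")
  expect_error(classify_nuclei(f, node), "hierarchy violation")
  f$label_hio <- "normal"
  expect_silent(classify_nuclei(f, node))

  g <- data.frame(ring_mean_annexin = c(500, 10),
                  label_nuclei = c("pyknosed", "healthy"))
  expect_error(resolve_pyknosed(g, annexin_threshold = 100),
               "hierarchy violation")
  g$label_nuclei <- "pyknosed"
  got <- resolve_pyknosed(g, annexin_threshold = 100)
  expect_identical(got$label, c("apoptotic", "mitotic"))

  expect_error(classify_viability(f, NULL), "untrained")

  ph <- data.frame(cyto_sd_488 = c(1, 1), cyto_mean_561 = c(1, 1),
                   cyto_mean_488 = c(1, 1), ring_mean_annexin = c(0, 0),
                   label_nuclei = c("healthy", "pyknosed"))
  expect_error(classify_phenotypes(ph, annexin_threshold = 10,
                                   dmso_ref = list(tubulin_sd = 1,
                                                   mito_mean = 1,
                                                   membrane_mean = 1)),
               "hierarchy violation")
})

test_that("mito decision is not evaluated in Annexin-positive cells", {
  ph <- data.frame(cyto_sd_488 = c(1, 1, 1), cyto_mean_561 = c(9, 9, 1),
                   cyto_mean_488 = c(1, 1, 1),
                   ring_mean_annexin = c(0, 500, 0),
                   label_nuclei = "healthy")
  got <- classify_phenotypes(ph, annexin_threshold = 100,
                             dmso_ref = list(tubulin_sd = 5, mito_mean = 5,
                                             membrane_mean = 5),
                             mode = "multiplex")
  expect_identical(got$mito_increased,
                   c("increased", "not_evaluated", "not_increased"))
})

test_that("classify_fucci fallback matches the reporter logic", {
  f <- data.frame(nuc_mean_488 = c(900, 10, 900, 10),
                  nuc_mean_561 = c(15, 900, 900, 12))
  got <- classify_fucci(f, thresholds = c(green = 100, red = 100))
  expect_identical(got$label, c("green", "red", "yellow", "unlabeled"))
  expect_error(classify_fucci(f[, 1, drop = FALSE],
                              thresholds = c(green = 1, red = 1)),
               "FUCCI channels missing")
  f$label_nuclei <- c("healthy", "healthy", "pyknosed", "healthy")
  expect_error(classify_fucci(f, thresholds = c(green = 100, red = 100)),
               "hierarchy violation")
  # config can admit pyknosed nuclei too
  expect_silent(classify_fucci(f, thresholds = c(green = 100, red = 100),
                               allow_classes = c("healthy", "pyknosed")))
})

test_that("NUCLEI3 node beats the majority baseline by >= 20 points", {
  node <- cached_nuclei3()
  acc <- node$training_meta$heldout_accuracy
  expect_gte(acc, 0.90)
  baseline <- 1 / 3  # balanced training world
  expect_gte(acc, baseline + 0.20)
})

test_that("gating model validation and bit-stable serialization", {
  node <- cached_nuclei3()
  expect_error(gating_model("fucci", list(VIA5 = node)), "not allowed")
  expect_error(gating_model("highvia_extend", list(NUCLEI3 = "x")),
               "gating_node")
  m <- gating_model("fucci", list(NUCLEI3 = node))
  path <- withr::local_tempfile(fileext = ".json")
  save_gating_model(m, path)
  m2 <- load_gating_model(path)
  withr::with_seed(3, {
    probe <- data.frame(matrix(rnorm(25 * 13), 25, 13))
  })
  names(probe) <- nucleus_feature_set()
  expect_identical(predict(m2$nodes$NUCLEI3, probe),
                   predict(m$nodes$NUCLEI3, probe))
  expect_identical(m2$nodes$NUCLEI3$model, m$nodes$NUCLEI3$model)
})

test_that("apply_gating walks the hierarchy with audit bookkeeping", {
  prm <- train_params()
  truth <- sample_cell_truth(
    90, mode = "fucci",
    viability_probs = c(healthy = 0.7, early_apoptotic = 0.15,
                        late_apoptotic = 0.15, necrotic = 0, lysed = 0),
    params = prm, seed = 71)
  fld <- render_field(truth, params = prm, seed = 72)
  ext <- extract_features(fld)
  model <- gating_model("fucci", list(NUCLEI3 = cached_nuclei3()))
  thr <- fucci_thresholds_from_field(fld, ext$nuclei)
  g <- apply_gating(model, ext$features,
                    refs = list(fucci_thresholds = thr))
  rec <- g$records
  # every normal object gets exactly one nuclei label; HIO objects none
  expect_true(all(!is.na(rec$label_nuclei[rec$label_hio == "normal"])))
  expect_true(all(is.na(rec$label_nuclei[rec$label_hio != "normal"])))
  # FUCCI labels exist exactly on healthy nuclei
  healthy <- !is.na(rec$label_nuclei) & rec$label_nuclei == "healthy"
  expect_true(all(!is.na(rec$label_fucci[healthy])))
  expect_true(all(is.na(rec$label_fucci[!healthy])))
  # audit: counts entering each gate match the hierarchy
  a <- g$audit
  expect_identical(a$entering[a$node == "HIO"], nrow(rec))
  expect_identical(a$entering[a$node == "NUCLEI3"],
                   sum(rec$label_hio == "normal"))
  expect_identical(a$entering[a$node == "FUCCI"], sum(healthy))
  # posteriors retained for trained nodes
  expect_true(all(c("post_nuclei_healthy", "post_nuclei_pyknosed",
                    "post_nuclei_fragmented") %in% names(rec)))
  ph <- unname(rowSums(rec[rec$label_hio == "normal",
                           c("post_nuclei_healthy", "post_nuclei_pyknosed",
                             "post_nuclei_fragmented")]))
  expect_equal(ph, rep(1, length(ph)), tolerance = 1e-9)
})

test_that("autofluorescent haze drives the HIO fraction above 0.5", {
  prm <- small_params()
  truth <- sample_cell_truth(25, params = prm, seed = 81)
  art <- artifact_truth("autofluorescence", x = 160, y = 160, size = 400,
                        intensity_scale = 6)
  fld <- render_field(truth, artifacts = list(art), params = prm, seed = 82,
                      channels = c("hoechst", "bf"))
  proj <- project_stack(fld$channels$hoechst)
  nuc <- segment_nuclei(proj)
  f <- nuclear_features(nuc, proj)
  # reference intensity from a clean (DMSO-like) field, as at plate level
  clean <- render_field(sample_cell_truth(25, params = prm, seed = 83),
                        params = prm, seed = 84, channels = "hoechst")
  cproj <- project_stack(clean$channels$hoechst)
  cn <- segment_nuclei(cproj)
  ref <- median(nuclear_features(cn, cproj)$nuc_mean_dna)
  got <- classify_hio(f, ref_intensity = ref)
  expect_gt(mean(got$label == "high_intensity_object"), 0.5)
})
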