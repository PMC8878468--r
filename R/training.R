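## Generator-backed training sets: render labeled fields, extract features,
## and match segmented cells back to ground truth by centroid proximity —
## the synthetic stand-in for training gates on reference-compound wells
## annotated by a cell biologist.

#' Match segmented cells to generator ground truth
#'
#' Assigns each segmented cell (body group) the truth row whose center is
#' nearest to the cell's nucleus-group centroid, within `max_dist` px.
#' Unmatched cells are dropped.
#'
#' @param ext Output of [extract_features()].
#' @param truth The [cell_truth()] table the field was rendered from.
#' @param max_dist Maximum centroid distance (px).
#' @return The feature table with appended truth columns (`true_*`).
#' @export
label_features_with_truth <- function(ext, truth, max_dist = 15) {
  feat <- ext$features
  if (!nrow(feat) || !nrow(truth)) return(feat[0, , drop = FALSE])
  cent <- mask_centroids(ext$nuclei)
  grp_map <- attr(ext$body, "nucleus_group")
  grp <- grp_map$body[match(cent$label, grp_map$nucleus)]
  gx <- tapply(cent$x, grp, mean)
  gy <- tapply(cent$y, grp, mean)
  ids <- as.integer(names(gx))
  hit <- integer(length(ids))
  for (i in seq_along(ids)) {
    d2 <- (truth$x - gx[i])^2 + (truth$y - gy[i])^2
    j <- which.min(d2)
    hit[i] <- if (d2[j] <= max_dist^2) j else NA_integer_
  }
  keep <- ids[!is.na(hit)]
  rows <- hit[!is.na(hit)]
  out <- feat[match(keep, feat$cell_id), , drop = FALSE]
  tr <- truth[rows, , drop = FALSE]
  out$true_nucleus_class <- tr$nucleus_class
  out$true_pyknosed_subclass <- tr$pyknosed_subclass
  out$true_viability_class <- tr$viability_class
  out$true_fucci_state <- tr$fucci_state
  out$true_tubulin_effect <- tr$tubulin_effect
  out$true_mito_mass_increased <- tr$mito_mass_increased
  out$true_membrane_permeable <- tr$membrane_permeable
  out[complete.cases(out$cell_id), , drop = FALSE]
}

#' Generate a labeled training set for a gating node
#'
#' Renders synthetic fields whose truth covers the node's classes at
#' (approximately) `n_per_class` cells each, extracts features and labels
#' them with ground truth. Rendering continues until every class reaches its
#' quota (segmentation losses are compensated).
#'
#' @param node_id Gating node id.
#' @param n_per_class Target examples per class.
#' @param mode Assay mode.
#' @param seed Integer seed.
#' @param params Rendering parameters ([render_params()]); `separability`
#'   there is the difficulty knob.
#' @param cells_per_field Cells rendered per field.
#' @return data.frame of features plus a `label` column, ready for
#'   [train_node()].
#' @export
make_training_set <- function(node_id, n_per_class = 200, mode = NULL,
                              seed, params = render_params(field = c(640L, 640L)),
                              cells_per_field = 120) {
  node_id <- match.arg(node_id, node_ids())
  if (missing(seed)) stopf("seed is required")
  if (is.null(mode))
    mode <- switch(node_id, VIA5 = "highvia_extend", FUCCI = "fucci",
                   TUBULIN = , MITO = , MEMBRANE = "multiplex",
                   "highvia_extend")
  spec <- training_world(node_id)
  out <- list()
  got <- setNames(rep(0L, length(spec$classes)), spec$classes)
  fld <- 0L
  while (any(got < n_per_class) && fld < 80L) {
    fld <- fld + 1L
    truth <- sample_cell_truth(
      cells_per_field, mode = mode, viability_probs = spec$viability_probs,
      mitotic_fraction = spec$mitotic_fraction,
      fucci_probs = spec$fucci_probs,
      phenotype_probs = spec$phenotype_probs, params = params,
      seed = derive_seed(seed, fld, 1L))
    fieldimg <- render_field(truth, mode = mode, params = params,
                             seed = derive_seed(seed, fld, 2L),
                             channels = spec$channels)
    ext <- extract_features(fieldimg)
    lf <- label_features_with_truth(ext, truth)
    if (!nrow(lf)) next
    lf$label <- spec$label_fun(lf)
    lf <- lf[!is.na(lf$label) & lf$label %in% spec$classes, , drop = FALSE]
    out[[fld]] <- lf
    tb <- table(factor(lf$label, levels = spec$classes))
    got <- got + as.integer(tb)
  }
  all <- do.call(rbind, out)
  # balance down to the quota per class, preserving field order
  keep <- unlist(lapply(spec$classes, function(cl) {
    idx <- which(all$label == cl)
    if (length(idx) < n_per_class)
      stopf("could not generate %d examples of class %s (got %d)",
            n_per_class, cl, length(idx))
    idx[seq_len(n_per_class)]
  }))
  all[sort(keep), , drop = FALSE]
}

# which truth mixture exposes a node's classes, and how feature rows map to
# node labels
training_world <- function(node_id) {
  even5 <- c(healthy = 0.2, early_apoptotic = 0.2, late_apoptotic = 0.2,
             necrotic = 0.2, lysed = 0.2)
  base <- list(
    mitotic_fraction = 0.04,
    fucci_probs = c(red = 0.3, green = 0.3, yellow = 0.3, unlabeled = 0.1),
    phenotype_probs = c(tubulin = 0, mito = 0, membrane = 0),
    channels = NULL)
  w <- switch(node_id,
    NUCLEI3 = list(
      # cover the full spectrum of nuclear phenotypes: necrotic and lysed
      # cells carry condensed (pyknosed-class) nuclei of intermediate
      # appearance and must be represented, or they split arbitrarily
      # between healthy and pyknosed at test time
      classes = pg_classes$NUCLEI3,
      viability_probs = c(healthy = 0.35, early_apoptotic = 0.15,
                          late_apoptotic = 0.25, necrotic = 0.15,
                          lysed = 0.1),
      label_fun = function(lf) lf$true_nucleus_class),
    VIA5 = list(
      classes = pg_classes$VIA5,
      viability_probs = even5,
      label_fun = function(lf) lf$true_viability_class),
    PYKNOSED2 = list(
      classes = pg_classes$PYKNOSED2,
      viability_probs = c(healthy = 0.5, early_apoptotic = 0.5,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      mitotic_fraction = 0.5,
      label_fun = function(lf)
        ifelse(lf$true_pyknosed_subclass == "n/a", NA_character_,
               lf$true_pyknosed_subclass)),
    FUCCI = list(
      classes = pg_classes$FUCCI,
      viability_probs = c(healthy = 1, early_apoptotic = 0,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      label_fun = function(lf)
        ifelse(lf$true_fucci_state == "n/a", NA_character_,
               lf$true_fucci_state)),
    TUBULIN = list(
      classes = pg_classes$TUBULIN,
      viability_probs = c(healthy = 1, early_apoptotic = 0,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      phenotype_probs = c(tubulin = 0.5, mito = 0, membrane = 0),
      label_fun = function(lf)
        ifelse(is.na(lf$true_tubulin_effect), NA_character_,
               ifelse(lf$true_tubulin_effect, "tubulin_effect",
                      "no_effect"))),
    MITO = list(
      classes = pg_classes$MITO,
      viability_probs = c(healthy = 1, early_apoptotic = 0,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      phenotype_probs = c(tubulin = 0, mito = 0.5, membrane = 0),
      label_fun = function(lf)
        ifelse(is.na(lf$true_mito_mass_increased), NA_character_,
               ifelse(lf$true_mito_mass_increased, "increased",
                      "not_increased"))),
    MEMBRANE = list(
      classes = pg_classes$MEMBRANE,
      viability_probs = c(healthy = 1, early_apoptotic = 0,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      phenotype_probs = c(tubulin = 0, mito = 0, membrane = 0.5),
      label_fun = function(lf)
        ifelse(is.na(lf$true_membrane_permeable), NA_character_,
               ifelse(lf$true_membrane_permeable, "permeable", "normal"))),
    HIO = list(
      classes = pg_classes$HIO,
      viability_probs = c(healthy = 1, early_apoptotic = 0,
                          late_apoptotic = 0, necrotic = 0, lysed = 0),
      label_fun = function(lf) "normal"),
    stopf("no training world for node %s", node_id))
  modifyList(base, w)
}

#' Train a full gating model on generator data
#'
#' Trains every node the mode needs on synthetic labeled fields — the
#' package's stand-in for reference-compound training wells.
#'
#' @param mode Assay mode.
#' @param seed Integer seed.
#' @param n_per_class Training examples per class and node.
#' @param params Rendering parameters.
#' @return A trained [gating_model()].
#' @export
train_default_model <- function(mode, seed, n_per_class = 120,
                                params = render_params(field = c(640L, 640L))) {
  mode <- match.arg(mode, pg_modes())
  wanted <- switch(mode,
    highvia_extend = c("NUCLEI3", "PYKNOSED2", "VIA5"),
    multiplex = c("NUCLEI3", "PYKNOSED2", "TUBULIN", "MITO", "MEMBRANE"),
    fucci = c("NUCLEI3", "FUCCI"))
  nodes <- list()
  for (i in seq_along(wanted)) {
    nid <- wanted[i]
    ts <- make_training_set(nid, n_per_class, mode = mode,
                            seed = derive_seed(seed, i, 101L),
                            params = params)
    nodes[[nid]] <- train_node(nid, ts, seed = derive_seed(seed, i, 202L),
                               mode = mode)
  }
  gating_model(mode, nodes,
               provenance = list(training = "synthetic generator",
                                 n_per_class = n_per_class,
                                 seed = as.integer(seed),
                                 separability = params$separability))
}
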