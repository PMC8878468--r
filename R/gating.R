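## Hierarchical gating tree. Each node is a supervised classifier (seeded
## bagged-CART ensemble) over a declared feature subset; HIO, Annexin and
## FUCCI nodes also have rule-based fallbacks so a pipeline can run without
## training data. Hierarchy contracts are enforced at classification time:
## phenotype nodes only ever see healthy-nucleus cells, the mitochondrial
## decision is only evaluated in Annexin-negative cells, and the
## mitotic/apoptotic split only applies to pyknosed nuclei.

NA_SENTINEL <- -1e9  # absent-channel features are constant-imputed

node_ids <- function() names(pg_classes)

#' Feature subset used by a gating node
#'
#' @param node_id One of `HIO, NUCLEI3, PYKNOSED2, VIA5, TUBULIN, MITO,
#'   MEMBRANE, FUCCI`.
#' @param mode Assay mode (channel roles differ between modes).
#' @return Character vector of feature ids.
#' @export
node_feature_subset <- function(node_id, mode = "highvia_extend") {
  mode <- match.arg(mode, pg_modes())
  mito_ch <- mito_channel(mode)
  mito_feats <- if (!is.na(mito_ch))
    paste0(c("cyto_mean_", "cyto_sd_", "cyto_p90_"),
           sub("ch", "", mito_ch)) else character(0)
  switch(node_id,
    HIO = c("body_area", "body_solidity", "body_compactness",
            "nuc_mean_dna", "nuc_max_dna"),
    NUCLEI3 = nucleus_feature_set(),
    PYKNOSED2 = c("ring_mean_annexin", "body_area", "body_compactness",
                  "body_eccentricity", "body_solidity",
                  "border_irregularity", "body_nucleus_area_ratio",
                  "nuc_area", "nuc_mean_dna", "nuc_cv_dna",
                  "nuc_compactness", "nuc_radial_ratio"),
    VIA5 = c(nucleus_feature_set(), body_feature_set()),
    TUBULIN = c("cyto_mean_488", "cyto_sd_488", "cyto_p90_488",
                "bf_texture_sd"),
    MITO = c(mito_feats, "body_area", "body_nucleus_area_ratio"),
    MEMBRANE = if (mode == "highvia_extend")
      c("cyto_mean_561", "cyto_sd_561", "cyto_p90_561", "body_area") else
      c("cyto_mean_488", "cyto_p90_488", "body_area", "body_compactness"),
    FUCCI = c("nuc_mean_488", "nuc_mean_561", "nuc_area", "nuc_mean_dna"),
    stopf("unknown node id %s", node_id))
}

features_to_matrix <- function(features, subset) {
  miss <- setdiff(subset, names(features))
  if (length(miss))
    stopf("feature table lacks: %s", paste(miss, collapse = ", "))
  X <- as.matrix(features[, subset, drop = FALSE])
  storage.mode(X) <- "double"
  X[!is.finite(X)] <- NA_SENTINEL
  X
}

#' Train one gating node
#'
#' Fits a seeded bagged decision-tree ensemble on labeled features. A
#' stratified 75/25 held-out split measures accuracy (recorded in
#' `training_meta`); the returned model is refit on all rows. Class priors
#' are never used to drop classes: every declared class must be present with
#' at least 20 examples.
#'
#' @param node_id Node identifier (see [node_feature_subset()]).
#' @param labeled_features data.frame of features plus a `label` column.
#' @param seed Integer seed.
#' @param mode Assay mode (selects channel-dependent feature subsets).
#' @param classes Node class vocabulary (fixed order = tie-break order).
#' @param feature_subset Override the node's default feature subset.
#' @param ntree,min_leaf,max_depth Ensemble hyper-parameters.
#' @return A `gating_node` (fields: `node_id`, `classes`, `feature_subset`,
#'   `model`, `training_meta`).
#' @export
train_node <- function(node_id, labeled_features, seed,
                       mode = "highvia_extend",
                       classes = pg_classes[[node_id]],
                       feature_subset = node_feature_subset(node_id, mode),
                       ntree = 80L, min_leaf = 3L, max_depth = 14L) {
  node_id <- match.arg(node_id, node_ids())
  if (missing(seed)) stopf("seed is required")
  if (!"label" %in% names(labeled_features))
    stopf("labeled_features needs a 'label' column")
  lab <- as.character(labeled_features$label)
  bad <- setdiff(unique(lab), classes)
  if (length(bad))
    stopf("labels outside node classes {%s}: %s",
          paste(classes, collapse = ", "), paste(bad, collapse = ", "))
  cnt <- table(factor(lab, levels = classes))
  if (any(cnt == 0))
    stopf("missing class(es) in training data for %s: %s (need all of %s)",
          node_id, paste(classes[cnt == 0], collapse = ", "),
          paste(classes, collapse = ", "))
  if (any(cnt < 20))
    stopf("need >= 20 examples per class; got %s",
          paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))

  X <- features_to_matrix(labeled_features, feature_subset)
  y <- match(lab, classes) - 1L
  K <- length(classes)
  mtry <- max(1L, floor(sqrt(ncol(X))))

  # stratified 75/25 held-out accuracy
  heldout <- with_seed(derive_seed(seed, 1L), {
    test_idx <- unlist(lapply(seq_len(K) - 1L, function(k) {
      idx <- which(y == k)
      sample(idx, max(1L, floor(length(idx) * 0.25)))
    }))
    tr <- setdiff(seq_along(y), test_idx)
    f <- .forest_fit_cpp(X[tr, , drop = FALSE], y[tr], K, ntree, mtry,
                         min_leaf, max_depth, derive_seed(seed, 2L))
    p <- .forest_predict_cpp(f, X[test_idx, , drop = FALSE], K)
    mean(max.col(p, ties.method = "first") - 1L == y[test_idx])
  })

  forest <- .forest_fit_cpp(X, y, K, ntree, mtry, min_leaf, max_depth,
                            derive_seed(seed, 3L))
  structure(list(
    node_id = node_id, classes = classes, feature_subset = feature_subset,
    model = forest,
    training_meta = list(n_per_class = as.list(cnt), seed = as.integer(seed),
                         heldout_accuracy = heldout,
                         classifier = "bagged_cart",
                         ntree = ntree, min_leaf = min_leaf,
                         max_depth = max_depth,
                         feature_version = FEATURE_VERSION)),
    class = "gating_node")
}

#' Predict classes and posteriors from a gating node
#'
#' Posterior ties are resolved deterministically by the node's fixed class
#' order.
#'
#' @param object A `gating_node`.
#' @param newdata Feature data.frame.
#' @param ... Unused.
#' @return data.frame: `label` plus one posterior column per class
#'   (`p_<class>`).
#' @export
predict.gating_node <- function(object, newdata, ...) {
  X <- features_to_matrix(newdata, object$feature_subset)
  K <- length(object$classes)
  p <- .forest_predict_cpp(object$model, X, K)
  out <- data.frame(label = object$classes[max.col(p, ties.method = "first")],
                    stringsAsFactors = FALSE)
  colnames(p) <- paste0("p_", object$classes)
  cbind(out, as.data.frame(p))
}

#' @export
print.gating_node <- function(x, ...) {
  cat(sprintf("<gating_node %s> classes: %s | held-out acc %.3f (n=%s)\n",
              x$node_id, paste(x$classes, collapse = "/"),
              x$training_meta$heldout_accuracy,
              paste(unlist(x$training_meta$n_per_class), collapse = "/")))
  invisible(x)
}

#' Assemble a gating model
#'
#' @param mode Assay mode; the node set must match it (FUCCI node only in
#'   fucci mode, viability node only in highvia_extend, phenotype nodes only
#'   in multiplex).
#' @param nodes Named list of `gating_node`s.
#' @param provenance Free-form provenance list (recorded, not interpreted).
#' @return A `gating_model`.
#' @export
gating_model <- function(mode, nodes = list(), provenance = list()) {
  mode <- match.arg(mode, pg_modes())
  allowed <- switch(mode,
    highvia_extend = c("HIO", "NUCLEI3", "PYKNOSED2", "VIA5"),
    multiplex = c("HIO", "NUCLEI3", "PYKNOSED2", "TUBULIN", "MITO",
                  "MEMBRANE"),
    fucci = c("HIO", "NUCLEI3", "FUCCI"))
  bad <- setdiff(names(nodes), allowed)
  if (length(bad))
    stopf("node(s) %s not allowed in mode %s", paste(bad, collapse = ", "),
          mode)
  for (nm in names(nodes))
    if (!inherits(nodes[[nm]], "gating_node") || nodes[[nm]]$node_id != nm)
      stopf("nodes must be named gating_node objects matching their id")
  structure(list(mode = mode, nodes = nodes,
                 provenance = c(list(package_version = "0.1.0",
                                     feature_version = FEATURE_VERSION),
                                provenance)),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf("<gating_model mode=%s> nodes: %s\n", x$mode,
              if (length(x$nodes)) paste(names(x$nodes), collapse = ", ")
              else "(none; rule fallbacks only)"))
  invisible(x)
}

#' Serialize / reload a gating model
#'
#' JSON at 17 significant digits, so doubles (tree thresholds, leaf
#' posteriors) round-trip bit-stably.
#'
#' @param model A `gating_model`.
#' @param path File path.
#' @return `load_gating_model` returns the model; `save_gating_model` the
#'   path, invisibly.
#' @export
save_gating_model <- function(model, path) {
  stopifnot(inherits(model, "gating_model"))
  writeLines(jsonlite::serializeJSON(model, digits = 17), path)
  invisible(path)
}

#' @rdname save_gating_model
#' @export
load_gating_model <- function(path) {
  m <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  stopifnot(inherits(m, "gating_model"))
  m
}

check_hierarchy <- function(features, column, allowed, node) {
  if (column %in% names(features)) {
    bad <- !(features[[column]] %in% allowed)
    if (any(bad))
      stopf("hierarchy violation: %s received %d cell(s) with %s not in {%s}",
            node, sum(bad), column, paste(allowed, collapse = ", "))
  }
  invisible(TRUE)
}

#' Classify objects as nuclei vs high-intensity objects
#'
#' Trained node when available; otherwise the rule fallback: an object is a
#' high-intensity object when its mean DNA intensity exceeds `k` times the
#' reference nuclear mean, or when it has non-nuclear shape (solidity < 0.5)
#' at more than twice the reference. The reference defaults to the field's
#' median nuclear mean but should come from DMSO wells at plate level, where
#' compound fluorescence cannot inflate it.
#'
#' @param features Feature table.
#' @param node Optional trained `HIO` `gating_node`.
#' @param ref_intensity Reference nuclear mean intensity.
#' @param k High-intensity multiplier (default 4).
#' @return data.frame `label` (+ posteriors when a node is used).
#' @export
classify_hio <- function(features, node = NULL, ref_intensity = NULL,
                         k = 4) {
  if (!is.null(node)) return(predict(node, features))
  if (is.null(ref_intensity))
    ref_intensity <- median(features$nuc_mean_dna, na.rm = TRUE)
  hi <- features$nuc_mean_dna > k * ref_intensity |
    (features$nuc_solidity < 0.5 & features$nuc_mean_dna >
       2 * ref_intensity)
  hi[is.na(hi)] <- FALSE
  data.frame(label = ifelse(hi, "high_intensity_object", "normal"),
             stringsAsFactors = FALSE)
}

#' Classify nuclear phenotype (healthy / pyknosed / fragmented)
#'
#' Requires a trained `NUCLEI3` node. Refuses objects labeled
#' high-intensity upstream (hierarchy contract).
#'
#' @param features Feature table; may carry a `label_hio` column, which must
#'   be `"normal"` throughout.
#' @param node Trained `NUCLEI3` node.
#' @return data.frame `label` + posteriors.
#' @export
classify_nuclei <- function(features, node) {
  if (is.null(node)) stopf("NUCLEI3 node is untrained")
  check_hierarchy(features, "label_hio", "normal", "NUCLEI3")
  predict(node, features)
}

#' Resolve pyknosed nuclei into mitotic vs apoptotic
#'
#' Trained node when available; rule fallback: Annexin membrane-ring
#' intensity above `annexin_threshold` (typically the DMSO-well 95th
#' percentile) means apoptotic, else mitotic.
#'
#' @param features Feature table of pyknosed-nucleus cells only (enforced
#'   via `label_nuclei` when present).
#' @param node Optional trained `PYKNOSED2` node.
#' @param annexin_threshold Ring-intensity cutoff for the fallback.
#' @return data.frame `label` (+ posteriors when a node is used).
#' @export
resolve_pyknosed <- function(features, node = NULL,
                             annexin_threshold = NULL) {
  check_hierarchy(features, "label_nuclei", "pyknosed", "PYKNOSED2")
  if (!is.null(node)) return(predict(node, features))
  if (is.null(annexin_threshold))
    stopf("rule fallback needs annexin_threshold (DMSO 95th percentile)")
  if (!"ring_mean_annexin" %in% names(features) ||
      all(is.na(features$ring_mean_annexin)))
    stopf("Annexin channel features missing")
  pos <- features$ring_mean_annexin > annexin_threshold
  pos[is.na(pos)] <- FALSE
  data.frame(label = ifelse(pos, "apoptotic", "mitotic"),
             stringsAsFactors = FALSE)
}

#' Classify five-state viability
#'
#' @param features Feature table (normal-intensity objects).
#' @param node Trained `VIA5` node (required; the five states are defined by
#'   reference-compound training, e.g. staurosporine-like apoptosis and
#'   digitonin-like lysis controls).
#' @return data.frame `label` + posteriors.
#' @export
classify_viability <- function(features, node) {
  if (is.null(node)) stopf("VIA5 node is untrained")
  check_hierarchy(features, "label_hio", "normal", "VIA5")
  predict(node, features)
}

#' Classify healthy-nucleus phenotypes (tubulin / mito / membrane)
#'
#' Three independent binary decisions on healthy-nucleus cells only. The
#' mitochondrial decision is evaluated only in Annexin-negative cells
#' (spectral overlap with the Annexin conjugate); Annexin-positive cells get
#' `"not_evaluated"`.
#'
#' @param features Feature table of healthy-nucleus cells (enforced via
#'   `label_nuclei` when present).
#' @param nodes Named list with optional trained `TUBULIN`, `MITO`,
#'   `MEMBRANE` nodes.
#' @param annexin_threshold Ring-intensity cutoff defining Annexin-positive.
#' @param dmso_ref Named list of DMSO reference quantiles for the rule
#'   fallbacks: `tubulin_sd`, `mito_mean`, `membrane_mean` (95th
#'   percentiles among DMSO healthy cells).
#' @param mode Assay mode.
#' @return data.frame with `tubulin_effect`, `mito_increased` (character:
#'   increased / not_increased / not_evaluated), `membrane_permeable`.
#' @export
classify_phenotypes <- function(features, nodes = list(),
                                annexin_threshold = NULL, dmso_ref = NULL,
                                mode = "multiplex") {
  check_hierarchy(features, "label_nuclei", "healthy", "phenotype nodes")
  n <- nrow(features)
  get2 <- function(node_id, ref_feature, ref_value) {
    if (!is.null(nodes[[node_id]]))
      return(predict(nodes[[node_id]], features)$label)
    if (is.null(ref_value))
      stopf("%s node untrained and no DMSO reference for rule fallback",
            node_id)
    v <- features[[ref_feature]] > ref_value
    v[is.na(v)] <- FALSE
    pg_classes[[node_id]][1 + v]
  }
  tub <- get2("TUBULIN", "cyto_sd_488", dmso_ref$tubulin_sd)
  mito_feat <- paste0("cyto_mean_", sub("ch", "", mito_channel(mode)))
  mito <- get2("MITO", mito_feat, dmso_ref$mito_mean)
  memb_feat <- if (mode == "highvia_extend") "cyto_mean_561" else
    "cyto_mean_488"
  memb <- get2("MEMBRANE", memb_feat, dmso_ref$membrane_mean)

  if (is.null(annexin_threshold))
    stopf("annexin_threshold required (mito is Annexin-gated)")
  ann_pos <- features$ring_mean_annexin > annexin_threshold
  ann_pos[is.na(ann_pos)] <- FALSE
  mito[ann_pos] <- "not_evaluated"
  data.frame(tubulin_effect = tub == "tubulin_effect",
             mito_increased = mito,
             membrane_permeable = memb == "permeable",
             stringsAsFactors = FALSE)
}

#' Classify FUCCI cell-cycle state
#'
#' red = G1 (RFP-Cdt1), green = S/G2/M (GFP-Geminin), yellow = G1/S
#' transition (both), unlabeled = neither (excluded from fraction
#' denominators downstream). Trained node when available; rule fallback
#' thresholds each nuclear reporter intensity against per-plate background
#' (95th percentile of non-nuclear signal in DMSO wells).
#'
#' @param features Feature table of healthy-nucleus cells (configurable
#'   relaxation via `allow_classes`).
#' @param node Optional trained `FUCCI` node.
#' @param thresholds Named vector `c(green=, red=)` background cutoffs for
#'   the fallback.
#' @param allow_classes Upstream nuclear labels admitted (default healthy
#'   only; pyknosed/fragmented can be opted in).
#' @return data.frame `label` (+ posteriors when a node is used).
#' @export
classify_fucci <- function(features, node = NULL, thresholds = NULL,
                           allow_classes = "healthy") {
  check_hierarchy(features, "label_nuclei", allow_classes, "FUCCI")
  need <- c("nuc_mean_488", "nuc_mean_561")
  if (!all(need %in% names(features)))
    stopf("FUCCI channels missing: need %s", paste(need, collapse = ", "))
  if (!is.null(node)) return(predict(node, features))
  if (is.null(thresholds))
    stopf("rule fallback needs thresholds = c(green=, red=)")
  g <- features$nuc_mean_488 > thresholds[["green"]]
  r <- features$nuc_mean_561 > thresholds[["red"]]
  g[is.na(g)] <- FALSE
  r[is.na(r)] <- FALSE
  lab <- ifelse(g & r, "yellow",
                ifelse(r, "red", ifelse(g, "green", "unlabeled")))
  data.frame(label = lab, stringsAsFactors = FALSE)
}

#' Per-plate FUCCI background thresholds from a reference field
#'
#' 95th percentile of non-nuclear (background-subtracted) reporter signal,
#' intended to be computed on DMSO wells.
#'
#' @param field An `image_field` in fucci mode.
#' @param nuclei Optional nuclei mask (segmented if missing).
#' @return Named vector `c(green=, red=)`.
#' @export
fucci_thresholds_from_field <- function(field, nuclei = NULL) {
  proj488 <- project_stack(field$channels$ch488)
  proj561 <- project_stack(field$channels$ch561)
  if (is.null(nuclei))
    nuclei <- segment_nuclei(project_stack(field$channels$hoechst))
  out <- nuclei == 0
  c(green = unname(quantile(background_subtract(proj488)[out], 0.95)),
    red = unname(quantile(background_subtract(proj561)[out], 0.95)))
}

#' Run the full gating hierarchy over a feature table
#'
#' Applies, in order and with hierarchy filtering: HIO; NUCLEI3 on normal
#' objects; PYKNOSED2 on pyknosed nuclei (when Annexin is available); VIA5
#' (highvia_extend), phenotype nodes (multiplex) or FUCCI (fucci) on their
#' admissible populations. Returns one row per cell with every node label
#' plus an audit of counts entering/leaving each gate.
#'
#' @param model A `gating_model` (possibly with missing nodes where rule
#'   fallbacks exist).
#' @param features Feature table from [extract_features()].
#' @param refs List of rule-fallback references: `ref_intensity`,
#'   `annexin_threshold`, `fucci_thresholds`, `dmso_ref`.
#' @return List: `records` (cell table with labels) and `audit`
#'   (per-node entering/classified counts).
#' @export
apply_gating <- function(model, features, refs = list()) {
  stopifnot(inherits(model, "gating_model"))
  mode <- model$mode
  n <- nrow(features)
  rec <- features
  audit <- list()
  note <- function(node, entering, classified)
    audit[[node]] <<- data.frame(node = node, entering = entering,
                                 classified = classified)

  put_post <- function(rec, idx, pred, prefix) {
    for (pc in grep("^p_", names(pred), value = TRUE)) {
      col <- paste0("post_", prefix, "_", sub("^p_", "", pc))
      if (is.null(rec[[col]])) rec[[col]] <- NA_real_
      rec[[col]][idx] <- pred[[pc]]
    }
    rec
  }

  hio <- classify_hio(features, model$nodes$HIO, refs$ref_intensity)
  rec$label_hio <- hio$label
  rec <- put_post(rec, seq_len(n), hio, "hio")
  note("HIO", n, n)

  normal <- which(rec$label_hio == "normal")
  rec$label_nuclei <- NA_character_
  if (length(normal)) {
    nuc <- classify_nuclei(cbind(features[normal, , drop = FALSE],
                                 label_hio = rec$label_hio[normal]),
                           model$nodes$NUCLEI3)
    rec$label_nuclei[normal] <- nuc$label
    rec <- put_post(rec, normal, nuc, "nuclei")
  }
  note("NUCLEI3", length(normal), length(normal))

  rec$label_pyknosed <- NA_character_
  pyk <- which(!is.na(rec$label_nuclei) & rec$label_nuclei == "pyknosed")
  ann_available <- !is.na(annexin_channel(mode)) &&
    (!is.null(model$nodes$PYKNOSED2) || !is.null(refs$annexin_threshold))
  if (length(pyk) && ann_available) {
    sub <- cbind(features[pyk, , drop = FALSE],
                 label_nuclei = rec$label_nuclei[pyk])
    rec$label_pyknosed[pyk] <- resolve_pyknosed(
      sub, model$nodes$PYKNOSED2, refs$annexin_threshold)$label
    note("PYKNOSED2", length(pyk), length(pyk))
  }

  healthy <- which(!is.na(rec$label_nuclei) & rec$label_nuclei == "healthy")
  if (mode == "highvia_extend") {
    rec$label_via <- NA_character_
    if (length(normal)) {
      via <- classify_viability(cbind(features[normal, , drop = FALSE],
                                      label_hio = rec$label_hio[normal]),
                                model$nodes$VIA5)
      rec$label_via[normal] <- via$label
      rec <- put_post(rec, normal, via, "via")
    }
    note("VIA5", length(normal), length(normal))
  } else if (mode == "multiplex") {
    rec$tubulin_effect <- NA
    rec$mito_increased <- NA_character_
    rec$membrane_permeable <- NA
    if (length(healthy)) {
      ph <- classify_phenotypes(
        cbind(features[healthy, , drop = FALSE],
              label_nuclei = rec$label_nuclei[healthy]),
        model$nodes[c("TUBULIN", "MITO", "MEMBRANE")],
        annexin_threshold = refs$annexin_threshold,
        dmso_ref = refs$dmso_ref, mode = mode)
      rec$tubulin_effect[healthy] <- ph$tubulin_effect
      rec$mito_increased[healthy] <- ph$mito_increased
      rec$membrane_permeable[healthy] <- ph$membrane_permeable
    }
    note("PHENO", length(healthy), length(healthy))
  } else if (mode == "fucci") {
    rec$label_fucci <- NA_character_
    if (length(healthy)) {
      fu <- classify_fucci(cbind(features[healthy, , drop = FALSE],
                                 label_nuclei = rec$label_nuclei[healthy]),
                           model$nodes$FUCCI, refs$fucci_thresholds)
      rec$label_fucci[healthy] <- fu$label
      rec <- put_post(rec, healthy, fu, "fucci")
    }
    note("FUCCI", length(healthy), length(healthy))
  }
  list(records = rec, audit = do.call(rbind, audit))
}
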