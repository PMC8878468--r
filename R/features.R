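## Per-object feature extraction. Two fixed, versioned feature sets feed the
## gating nodes: NUCLEUS_SET (13 features of the DNA-channel objects,
## aggregated per cell body so fragmented nuclei stay one cell) and BODY_SET
## (19 features of the cell body and its cytoplasmic/membrane compartments).
## Intensities are measured on maximum projections after subtracting the
## field's 5th percentile per channel (robust, parameter-light background).

FEATURE_VERSION <- "1"

#' Nucleus feature set (13 features)
#' @return Character vector of feature ids.
#' @export
nucleus_feature_set <- function() c(
  "nuc_area", "nuc_equiv_diameter", "nuc_perimeter", "nuc_compactness",
  "nuc_eccentricity", "nuc_solidity", "nuc_mean_dna", "nuc_sd_dna",
  "nuc_max_dna", "nuc_cv_dna", "nuc_fragment_count", "nuc_fragment_area_frac",
  "nuc_radial_ratio")

#' Cell-body feature set (19 features)
#' @return Character vector of feature ids.
#' @export
body_feature_set <- function() c(
  "body_area", "body_equiv_diameter", "body_compactness",
  "body_eccentricity", "body_solidity", "body_nucleus_area_ratio",
  "cyto_mean_488", "cyto_sd_488", "cyto_p90_488",
  "cyto_mean_561", "cyto_sd_561", "cyto_p90_561",
  "cyto_mean_640", "cyto_sd_640", "cyto_p90_640",
  "ring_mean_annexin", "bf_texture_sd", "contrast_mean",
  "border_irregularity")

# shape statistics for every label in a mask
region_shapes <- function(lab) {
  K <- max(lab)
  if (K == 0)
    return(data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), ecc = numeric(0),
                      solidity = numeric(0), cx = numeric(0),
                      cy = numeric(0), border_irr = numeric(0)))
  pos <- which(lab > 0)
  l <- lab[pos]
  r <- (pos - 1) %% nrow(lab)
  c <- (pos - 1) %/% nrow(lab)
  area <- tabulate(l, K)
  cx <- as.numeric(tapply(c, factor(l, levels = 1:K), mean))
  cy <- as.numeric(tapply(r, factor(l, levels = 1:K), mean))
  per <- as.numeric(.perimeter_cpp(lab, K))
  ecc <- sol <- birr <- numeric(K)
  sp <- split(seq_along(l), factor(l, levels = 1:K))
  for (k in seq_len(K)) {
    idx <- sp[[k]]
    if (!length(idx)) { ecc[k] <- NA; sol[k] <- NA; birr[k] <- NA; next }
    xs <- c[idx]; ys <- r[idx]
    # eccentricity from central second moments
    mxx <- mean((xs - cx[k])^2) + 1 / 12
    myy <- mean((ys - cy[k])^2) + 1 / 12
    mxy <- mean((xs - cx[k]) * (ys - cy[k]))
    tr <- mxx + myy
    dt <- sqrt(max((mxx - myy)^2 / 4 + mxy^2, 0))
    l1 <- tr / 2 + dt; l2 <- max(tr / 2 - dt, 1e-9)
    ecc[k] <- sqrt(max(1 - l2 / l1, 0))
    # solidity: area / convex hull area
    if (length(idx) >= 3) {
      pts <- unique(cbind(xs, ys))
      if (nrow(pts) >= 3) {
        hull <- chull(pts)
        hp <- pts[hull, , drop = FALSE]
        ha <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                        c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
        # hull of pixel centers underestimates; pad by a half-pixel band
        sol[k] <- min(area[k] / max(ha + 0.5 * per[k], 1), 1)
      } else sol[k] <- 1
    } else sol[k] <- 1
    # border irregularity: cv of boundary-pixel distance to centroid
    dd <- sqrt((xs - cx[k])^2 + (ys - cy[k])^2)
    qb <- dd >= quantile(dd, 0.75)
    birr[k] <- if (mean(dd[qb]) > 0) sd(dd[qb]) / mean(dd[qb]) else 0
  }
  data.frame(label = 1:K, area = area, perimeter = per, ecc = ecc,
             solidity = sol, cx = cx, cy = cy, border_irr = birr)
}

# per-label intensity stats of img over mask
region_intensity <- function(lab, img, K = max(lab)) {
  if (K == 0)
    return(data.frame(label = integer(0), mean = numeric(0),
                      sd = numeric(0), max = numeric(0), p90 = numeric(0)))
  pos <- which(lab > 0)
  l <- factor(lab[pos], levels = 1:K)
  v <- img[pos]
  data.frame(label = 1:K,
             mean = as.numeric(tapply(v, l, mean)),
             sd = as.numeric(tapply(v, l, function(x)
               if (length(x) > 1) sd(x) else 0)),
             max = as.numeric(tapply(v, l, max)),
             p90 = as.numeric(tapply(v, l, quantile, probs = 0.9)))
}

background_subtract <- function(img) {
  pmax(img - quantile(img, 0.05), 0)
}

#' Nuclear features per cell
#'
#' One row per cell body with at least one nucleus fragment; fragment
#' statistics (count, per-fragment areas/intensities) are aggregated per
#' body, so a fragmented nucleus is described by its fragment ensemble.
#' Units: px and px^2 for geometry, background-subtracted counts for
#' intensities, ratios dimensionless.
#'
#' @param nuclei Nuclei label mask.
#' @param hoechst 2-D DNA-channel projection.
#' @param body Cell-body label mask carrying the `nucleus_group` attribute
#'   from [segment_cell_bodies()]; may be `NULL` (each nucleus treated as
#'   its own cell).
#' @return data.frame `(cell_id, <13 nucleus features>)`.
#' @export
nuclear_features <- function(nuclei, hoechst, body = NULL) {
  K <- max(nuclei)
  cols <- nucleus_feature_set()
  if (K == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols) + 1),
                                  c("cell_id", cols)))
    return(out)
  }
  if (!all(dim(nuclei) == dim(hoechst))) stopf("mask/image shapes differ")
  img <- background_subtract(hoechst)
  sh <- region_shapes(nuclei)
  it <- region_intensity(nuclei, img, K)
  grp_map <- if (!is.null(body)) attr(body, "nucleus_group") else NULL
  grp <- if (!is.null(grp_map)) grp_map$body[match(1:K, grp_map$nucleus)]
    else 1:K
  grp[is.na(grp)] <- max(grp, 0, na.rm = TRUE) + seq_len(sum(is.na(grp)))

  # radial intensity ratio per fragment, then area-weighted per group
  rad <- radial_ratio(nuclei, img, sh)

  g <- factor(grp)
  agg <- function(x, w = sh$area)
    as.numeric(tapply(x * w, g, sum) / tapply(w, g, sum))
  tot_area <- as.numeric(tapply(sh$area, g, sum))
  nfrag <- as.numeric(tapply(sh$area, g, length))
  big_frac <- as.numeric(tapply(sh$area, g, max)) / tot_area
  per_sum <- as.numeric(tapply(sh$perimeter, g, sum))
  out <- data.frame(
    cell_id = as.integer(levels(g)),
    nuc_area = tot_area,
    nuc_equiv_diameter = 2 * sqrt(tot_area / pi),
    nuc_perimeter = per_sum,
    nuc_compactness = pmin(4 * pi * tot_area / per_sum^2, 1.25),
    nuc_eccentricity = agg(sh$ecc),
    nuc_solidity = agg(sh$solidity),
    nuc_mean_dna = agg(it$mean),
    nuc_sd_dna = agg(it$sd),
    nuc_max_dna = as.numeric(tapply(it$max, g, max)),
    nuc_cv_dna = NA_real_,
    nuc_fragment_count = nfrag,
    nuc_fragment_area_frac = 1 - big_frac,
    nuc_radial_ratio = agg(rad))
  out$nuc_cv_dna <- out$nuc_sd_dna / pmax(out$nuc_mean_dna, 1e-9)
  out
}

# mean intensity in the inner half-radius region over the outer region,
# a nuclear-condensation indicator
radial_ratio <- function(lab, img, sh) {
  K <- max(lab)
  pos <- which(lab > 0)
  l <- lab[pos]
  r <- (pos - 1) %% nrow(lab)
  c <- (pos - 1) %/% nrow(lab)
  v <- img[pos]
  out <- numeric(K)
  sp <- split(seq_along(l), factor(l, levels = 1:K))
  for (k in seq_len(K)) {
    idx <- sp[[k]]
    if (!length(idx)) { out[k] <- 1; next }
    d <- sqrt((c[idx] - sh$cx[k])^2 + (r[idx] - sh$cy[k])^2)
    inner <- d <= quantile(d, 0.5)
    mo <- mean(v[idx][!inner])
    out[k] <- if (is.finite(mo) && mo > 0) mean(v[idx][inner]) / mo else 1
  }
  out
}

#' Cell-body features per cell
#'
#' Cytoplasm is the body minus nucleus pixels; the membrane ring is the body
#' boundary band (default 3 px). Channels not acquired in the declared mode
#' yield `NA` features; a channel required by the mode but missing from
#' `channels` is an error naming the channel. Degenerate cells whose body
#' equals their nucleus get zero cytoplasmic intensities and a
#' `no_cytoplasm` note.
#'
#' @param body Cell-body label mask (see [segment_cell_bodies()]).
#' @param nuclei Nuclei label mask.
#' @param channels Named list of 2-D projections (`ch488`, `ch561`, `ch640`,
#'   `bf`) as available for the mode.
#' @param mode Assay mode.
#' @param contrast Optional contrast image for `contrast_mean`.
#' @param ring_width Membrane ring width (px).
#' @return data.frame `(cell_id, <19 body features>, no_cytoplasm)`.
#' @export
cell_features <- function(body, nuclei, channels, mode = "highvia_extend",
                          contrast = NULL, ring_width = 3) {
  mode <- match.arg(mode, pg_modes())
  need <- setdiff(names(channel_roles(mode)), "hoechst")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stopf("mode %s requires channel(s) %s", mode,
          paste(miss, collapse = ", "))
  K <- max(body)
  cols <- body_feature_set()
  if (K == 0)
    return(cbind(data.frame(cell_id = integer(0)),
                 as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                        cols)),
                 data.frame(no_cytoplasm = logical(0))))

  sh <- region_shapes(body)
  nuc_in_body <- matrix(0L, nrow(body), ncol(body))
  pos <- nuclei > 0 & body > 0
  nuc_in_body[pos] <- body[pos]
  nuc_area_in <- tabulate(nuc_in_body[nuc_in_body > 0], K)

  cyto <- body
  cyto[nuclei > 0] <- 0L
  cyto_area <- tabulate(cyto[cyto > 0], K)

  # membrane ring: body pixels within ring_width of the body's outside
  d <- .distance_transform_cpp(body > 0)
  ring <- body
  ring[d > ring_width] <- 0L

  bgsub <- lapply(channels, background_subtract)

  cyto_stats <- function(ch) {
    if (!ch %in% names(bgsub)) {
      return(data.frame(mean = rep(NA_real_, K), sd = NA_real_,
                        p90 = NA_real_))
    }
    s <- region_intensity(cyto, bgsub[[ch]], K)
    s$mean[cyto_area == 0] <- 0
    s$sd[cyto_area == 0] <- 0
    s$p90[cyto_area == 0] <- 0
    s[, c("mean", "sd", "p90")]
  }
  s488 <- cyto_stats("ch488")
  s561 <- cyto_stats("ch561")
  s640 <- cyto_stats("ch640")

  ann_ch <- annexin_channel(mode)
  ring_ann <- if (!is.na(ann_ch) && ann_ch %in% names(bgsub))
    region_intensity(ring, bgsub[[ann_ch]], K)$mean else rep(NA_real_, K)

  bf_sd <- if ("bf" %in% names(channels))
    region_intensity(body, channels$bf, K)$sd else rep(NA_real_, K)
  ctr_mean <- if (!is.null(contrast))
    region_intensity(body, contrast, K)$mean else rep(NA_real_, K)

  data.frame(
    cell_id = 1:K,
    body_area = sh$area,
    body_equiv_diameter = 2 * sqrt(sh$area / pi),
    body_compactness = pmin(4 * pi * sh$area / sh$perimeter^2, 1.25),
    body_eccentricity = sh$ecc,
    body_solidity = sh$solidity,
    body_nucleus_area_ratio = nuc_area_in / pmax(sh$area, 1),
    cyto_mean_488 = s488$mean, cyto_sd_488 = s488$sd,
    cyto_p90_488 = s488$p90,
    cyto_mean_561 = s561$mean, cyto_sd_561 = s561$sd,
    cyto_p90_561 = s561$p90,
    cyto_mean_640 = s640$mean, cyto_sd_640 = s640$sd,
    cyto_p90_640 = s640$p90,
    ring_mean_annexin = ring_ann,
    bf_texture_sd = bf_sd,
    contrast_mean = ctr_mean,
    border_irregularity = sh$border_irr,
    no_cytoplasm = cyto_area == 0)
}

# mean (background-subtracted) channel intensity over each cell's nucleus
# pixels, aggregated per body group; named by cell_id
nuclear_channel_mean <- function(nuclei, body, img) {
  K <- max(nuclei)
  if (K == 0) return(setNames(numeric(0), character(0)))
  it <- region_intensity(nuclei, background_subtract(img), K)
  areas <- tabulate(nuclei[nuclei > 0], K)
  grp_map <- attr(body, "nucleus_group")
  grp <- if (!is.null(grp_map)) grp_map$body[match(1:K, grp_map$nucleus)]
    else 1:K
  g <- factor(grp)
  v <- as.numeric(tapply(it$mean * areas, g, sum) / tapply(areas, g, sum))
  setNames(v, levels(g))
}

#' Full feature table for one field
#'
#' Convenience wrapper: projections, phase contrast, nuclei + body
#' segmentation and the joined nucleus/body feature table.
#'
#' @param field An `image_field` (see [render_field()] / [read_field()]).
#' @param seg_params See [segment_params()].
#' @param gating_extras Compute contrast image from bright field when
#'   available.
#' @return List: `features` (joined table keyed by `cell_id`), `nuclei`,
#'   `body` masks, `projections` (named list), `contrast`.
#' @export
extract_features <- function(field, seg_params = segment_params(),
                             gating_extras = TRUE) {
  mode <- field$metadata$mode
  proj <- lapply(field$channels, project_stack)
  hoechst <- proj$hoechst
  if (is.null(hoechst)) stopf("field lacks the hoechst channel")
  nuclei <- segment_nuclei(hoechst, seg_params)
  contrast <- if ("bf" %in% names(field$channels))
    digital_phase_contrast(field$channels$bf) else NULL
  shape_src <- if (!is.null(contrast)) contrast else
    background_subtract(hoechst)
  body <- segment_cell_bodies(shape_src, nuclei)
  nf <- nuclear_features(nuclei, hoechst, body)
  cf <- cell_features(body, nuclei, proj[setdiff(names(proj), "hoechst")],
                      mode = mode, contrast = contrast)
  feat <- merge(nf, cf, by = "cell_id", all = TRUE)
  # nuclear reporter intensities (FUCCI gating and related nodes)
  for (ch in intersect(c("ch488", "ch561"), names(proj))) {
    nm <- nuclear_channel_mean(nuclei, body, proj[[ch]])
    feat[[paste0("nuc_mean_", sub("ch", "", ch))]] <-
      nm[match(feat$cell_id, names(nm))]
  }
  list(features = feat, nuclei = nuclei, body = body, projections = proj,
       contrast = contrast)
}
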