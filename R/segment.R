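## Nuclei detection from the Hoechst channel and cell-body assignment from
## bright field: smoothing -> global threshold -> connected components ->
## optional watershed split -> size filter, then seeded watershed of the
## bright-field/phase-contrast foreground around nuclei.

#' Maximum-intensity projection of a z-stack
#'
#' @param stack List of 2-D matrices (common shape) or a 3-D array with z as
#'   the third dimension.
#' @return A single matrix, the per-pixel maximum over slices.
#' @export
project_stack <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  if (!is.list(stack) || length(stack) == 0)
    stopf("stack must be a non-empty list of matrices")
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all slices must share dimensions")
  Reduce(pmax, stack)
}

#' Digital phase contrast from a bright-field z-stack
#'
#' Contrast image computed as the normalized absolute difference between an
#' above-focus and a below-focus slice, `|z_hi - z_lo| / (z_hi + z_lo)`, with
#' values below `level` set to 0 (soft threshold). Defaults follow the
#' acquisition convention of slices 3 and 5 (1-based) at level 0.003.
#'
#' @param stack Bright-field z-stack (list of matrices).
#' @param z_lo,z_hi 1-based slice indices, `z_lo < z_hi`.
#' @param level Soft threshold on the normalized difference; > 0.
#' @return Contrast matrix in `[0, 1]`.
#' @export
digital_phase_contrast <- function(stack, z_lo = 3L, z_hi = 5L,
                                   level = 0.003) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  nz <- length(stack)
  if (z_lo < 1 || z_hi > nz || z_lo >= z_hi)
    stopf("need 1 <= z_lo < z_hi <= %d", nz)
  if (level <= 0) stopf("level must be > 0")
  lo <- stack[[z_lo]]
  hi <- stack[[z_hi]]
  d <- abs(hi - lo) / pmax(hi + lo, .Machine$double.eps)
  d[d < level] <- 0
  d
}

#' Otsu threshold
#'
#' Classical between-class-variance maximizer on a 256-bin histogram.
#'
#' @param img Numeric matrix.
#' @param nbins Histogram bins.
#' @return Threshold value on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

#' Default nuclei segmentation parameters
#'
#' Size bounds derive from the generator's nucleus geometry (healthy radius
#' ~9 px: area ~254 px^2; pyknosed fragments go well below, artifacts above)
#' and are configurable for other magnifications.
#'
#' @param smooth_sigma Gaussian pre-smoothing (px).
#' @param threshold_method `"otsu"` (log-domain, default), `"otsu_linear"`
#'   or `"quantile"`.
#' @param quantile Used when `threshold_method = "quantile"`.
#' @param min_area,max_area Object area bounds (px^2).
#' @param split_touching Apply a conservative distance-transform watershed
#'   to split merged nuclei.
#' @param exclude_border Drop objects touching the field border (kept by
#'   default: fields are single and centered, discarding would bias counts).
#' @return Named list.
#' @export
segment_params <- function(smooth_sigma = 1.5, threshold_method = "otsu",
                           quantile = 0.995, min_area = 30,
                           max_area = 2500, split_touching = FALSE,
                           exclude_border = FALSE) {
  list(smooth_sigma = smooth_sigma, threshold_method = threshold_method,
       quantile = quantile, min_area = min_area, max_area = max_area,
       split_touching = split_touching, exclude_border = exclude_border)
}

#' Segment nuclei from a Hoechst projection
#'
#' Smoothing, global thresholding (Otsu by default), connected components,
#' optional conservative watershed splitting of merged objects, then an
#' area filter. Labels are relabeled consecutively `1..K`. A blank image
#' yields an empty mask (0 objects), not an error.
#'
#' @param img 2-D Hoechst (DNA channel) projection.
#' @param params See [segment_params()].
#' @return Integer label matrix with attributes `n_objects` and
#'   `provenance = "nuclei"`.
#' @export
segment_nuclei <- function(img, params = segment_params()) {
  if (!is.matrix(img)) stopf("img must be a 2-D matrix")
  sm <- if (params$smooth_sigma > 0)
    .gaussian_blur_cpp(img, params$smooth_sigma) else img
  thr <- switch(params$threshold_method,
    # log-domain Otsu: robust when the foreground is multimodal (dim lysed
    # remnants next to bright condensed nuclei would push a linear Otsu cut
    # above the dim class)
    otsu = exp(otsu_threshold(log(pmax(sm, 1)))),
    otsu_linear = otsu_threshold(sm),
    quantile = quantile(sm, params$quantile),
    stopf("unknown threshold_method"))
  bin <- sm > thr
  if (!any(bin)) {
    lab <- matrix(0L, nrow(img), ncol(img))
    attr(lab, "n_objects") <- 0L
    attr(lab, "provenance") <- "nuclei"
    return(lab)
  }
  lab <- .label_components_cpp(bin, TRUE)
  if (params$split_touching) lab <- split_touching_objects(lab, sm)
  lab <- filter_by_area(lab, params$min_area, params$max_area)
  if (params$exclude_border) lab <- drop_border_objects(lab)
  attr(lab, "provenance") <- "nuclei"
  lab
}

# conservative distance-transform watershed split: only components with >= 2
# well-separated distance maxima are re-partitioned
split_touching_objects <- function(lab, intensity) {
  areas <- tabulate(lab[lab > 0])
  if (!length(areas)) return(lab)
  med_area <- median(areas)
  bin <- lab > 0
  d <- .distance_transform_cpp(bin)
  typical_r <- sqrt(med_area / pi)
  peaks <- .local_maxima_cpp(d, bin, max(3L, as.integer(round(typical_r))),
                             typical_r * 0.5)
  if (nrow(peaks) == 0) return(lab)
  seeds <- matrix(0L, nrow(lab), ncol(lab))
  seeds[cbind(peaks[, 1], peaks[, 2])] <- seq_len(nrow(peaks))
  # count peaks per component; leave single-peak components untouched
  comp_of_peak <- lab[cbind(peaks[, 1], peaks[, 2])]
  multi <- as.integer(names(which(table(comp_of_peak) >= 2)))
  big <- which(areas > 1.5 * med_area)
  target <- intersect(multi, big)
  if (!length(target)) return(lab)
  sel <- lab %in% target
  seeds[!sel] <- 0L
  ws <- .watershed_cpp(-d, seeds, sel & bin)
  out <- lab
  out[sel] <- ws[sel] + max(lab)
  relabel_consecutive(out)
}

filter_by_area <- function(lab, min_area, max_area) {
  K <- max(lab)
  if (K == 0) {
    attr(lab, "n_objects") <- 0L
    return(lab)
  }
  areas <- tabulate(lab[lab > 0], K)
  keep <- areas >= min_area & areas <= max_area
  relabel_keep(lab, keep)
}

drop_border_objects <- function(lab) {
  K <- max(lab)
  if (K == 0) return(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- !(seq_len(K) %in% border[border > 0])
  relabel_keep(lab, keep)
}

relabel_keep <- function(lab, keep) {
  map <- integer(length(keep))
  map[keep] <- seq_len(sum(keep))
  out <- lab
  pos <- lab > 0
  out[pos] <- map[lab[pos]]
  attr(out, "n_objects") <- sum(keep)
  attr(out, "provenance") <- attr(lab, "provenance")
  out
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  relabel_keep(replace(lab, lab > 0, match(lab[lab > 0], u)),
               rep(TRUE, length(u)))
}

#' Object centroids of a label mask
#'
#' @param lab Integer label matrix.
#' @return data.frame `label, x, y` (0-based pixel coordinates, x = column).
#' @export
mask_centroids <- function(lab) {
  K <- max(lab)
  if (K == 0)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  pos <- which(lab > 0)
  l <- lab[pos]
  r <- (pos - 1) %% nrow(lab)
  c <- (pos - 1) %/% nrow(lab)
  data.frame(label = seq_len(K),
             x = as.numeric(tapply(c, l, mean)),
             y = as.numeric(tapply(r, l, mean)))
}

#' Assign cell bodies around nuclei
#'
#' Foreground is obtained by thresholding the phase-contrast (or bright
#' field projection) image; nucleus pixels are always foreground (bodies are
#' defined interdependent of nuclei). The foreground is partitioned among
#' nuclei by seeded watershed. Nucleus objects whose centroids fall within
#' `group_radius` of each other are grouped into a single seed first, so a
#' fragmented nucleus yields one body. Nuclei with (almost) no foreground
#' support receive a disk fallback body.
#'
#' @param contrast 2-D contrast image (see [digital_phase_contrast()]) or a
#'   bright-field projection.
#' @param nuclei Nuclei label mask from the same field.
#' @param group_radius Fragment-grouping radius (px).
#' @param fallback_radius Disk radius (px) for unsupported nuclei.
#' @param fg_threshold Foreground threshold; `NULL` = Otsu on nonzero values.
#' @return Integer label matrix (`provenance = "cell_body"`), one label per
#'   nucleus group, with attributes `nucleus_group` (data.frame mapping
#'   nucleus label -> body label) and `fallback` (body labels that used the
#'   disk fallback).
#' @export
segment_cell_bodies <- function(contrast, nuclei, group_radius = 25,
                                fallback_radius = 12, fg_threshold = NULL) {
  if (!all(dim(contrast) == dim(nuclei)))
    stopf("contrast image and nuclei mask shapes differ")
  K <- max(nuclei)
  empty <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (K == 0) {
    attr(empty, "n_objects") <- 0L
    attr(empty, "provenance") <- "cell_body"
    attr(empty, "nucleus_group") <- data.frame(nucleus = integer(0),
                                               body = integer(0))
    attr(empty, "fallback") <- integer(0)
    return(empty)
  }
  cent <- mask_centroids(nuclei)
  grp <- group_by_proximity(cent, group_radius)

  nz <- contrast[contrast > 0]
  thr <- if (!is.null(fg_threshold)) fg_threshold else
    if (length(nz)) otsu_threshold(matrix(nz)) else Inf
  fg <- contrast > thr
  fg[nuclei > 0] <- TRUE

  seeds <- empty
  pos <- nuclei > 0
  seeds[pos] <- grp[nuclei[pos]]
  ws <- .watershed_cpp(-contrast, seeds, fg)

  # fallback disks for groups with no body beyond their nucleus pixels
  G <- max(grp)
  body_area <- tabulate(ws[ws > 0], G)
  nuc_area <- tabulate(grp[nuclei[pos]], G)
  fallback <- which(body_area <= nuc_area + 2)
  if (length(fallback)) {
    h <- nrow(ws); w <- ncol(ws)
    gx <- tapply(cent$x, grp, mean)
    gy <- tapply(cent$y, grp, mean)
    for (g in fallback) {
      cx <- gx[[as.character(g)]]; cy <- gy[[as.character(g)]]
      c0 <- max(1, floor(cx - fallback_radius) + 1)
      c1 <- min(w, ceiling(cx + fallback_radius) + 1)
      r0 <- max(1, floor(cy - fallback_radius) + 1)
      r1 <- min(h, ceiling(cy + fallback_radius) + 1)
      xg <- matrix(rep((c0:c1) - 1, each = r1 - r0 + 1), r1 - r0 + 1)
      yg <- matrix(rep((r0:r1) - 1, times = c1 - c0 + 1), r1 - r0 + 1)
      disk <- (xg - cx)^2 + (yg - cy)^2 <= fallback_radius^2
      sub <- ws[r0:r1, c0:c1]
      sub[disk & sub == 0] <- g
      ws[r0:r1, c0:c1] <- sub
    }
  }
  attr(ws, "n_objects") <- G
  attr(ws, "provenance") <- "cell_body"
  attr(ws, "nucleus_group") <- data.frame(nucleus = cent$label,
                                          body = grp)
  attr(ws, "fallback") <- fallback
  ws
}

# single-linkage grouping of nucleus centroids within radius
group_by_proximity <- function(cent, radius) {
  n <- nrow(cent)
  grp <- seq_len(n)
  if (n > 1 && radius > 0) {
    find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
    for (i in seq_len(n - 1))
      for (j in seq(i + 1, n)) {
        if ((cent$x[i] - cent$x[j])^2 + (cent$y[i] - cent$y[j])^2 <=
            radius^2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
        }
      }
    for (i in seq_len(n)) grp[i] <- find(i)
  }
  match(grp, sort(unique(grp)))
}
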