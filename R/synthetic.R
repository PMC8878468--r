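## Synthetic field / plate simulator with exact ground truth.
##
## The generator is the package's stated world: rendered fields emulate a
## confocal high-content acquisition (one centered field per well, seven
## z-slices, 16-bit), and plate simulation is a discrete-time (1 h) Markov
## chain over viability compartments with exact bookkeeping, so that every
## analysis stage can be verified against known truth.

#' Default rendering parameters
#'
#' Geometry and intensity model for [render_field()]. Intensities are
#' expected photon counts on a 16-bit scale; nucleus/body sizes are in
#' pixels. `separability` scales every phenotype effect size away from (1 =
#' default) so classifier tests can sweep difficulty.
#'
#' @param field Field size in pixels, `c(width, height)`.
#' @param nz Number of z-slices per channel.
#' @param focus_z In-focus slice (1-based).
#' @param z_blur Gaussian blur (px) added per z-step away from focus.
#' @param nucleus_radius,body_radius Mean radii (px) of a healthy nucleus /
#'   cell body.
#' @param read_sd Gaussian read-noise standard deviation (counts).
#' @param separability Phenotype effect-size multiplier.
#' @param packing_limit Maximum allowed nuclear area fraction of the field;
#'   denser truth tables are rejected by [render_field()].
#' @return Named list of parameters.
#' @export
render_params <- function(field = c(1000L, 1000L), nz = 7L, focus_z = 4L,
                          z_blur = 1.4, nucleus_radius = 9, body_radius = 20,
                          read_sd = 8, separability = 1,
                          packing_limit = 0.2) {
  list(field = as.integer(field), nz = as.integer(nz),
       focus_z = as.integer(focus_z), z_blur = z_blur,
       nucleus_radius = nucleus_radius, body_radius = body_radius,
       read_sd = read_sd, separability = separability,
       packing_limit = packing_limit,
       # channel backgrounds (counts)
       bg = c(hoechst = 300, ch488 = 200, ch561 = 200, ch640 = 180,
              bf = 20000),
       nucleus_amp = 3000, body_bf_amp = 2500, annexin_amp = 1800,
       perm_amp = 2200, mito_amp = 900, tubulin_amp = 1100,
       fucci_amp = 2200, z_decay = 0.7)
}

# Per-viability-class rendering effects, relative to a healthy cell.
# EA/LA/necrotic/lysed differ in nuclear condensation, Annexin V exposure,
# permeability-dye uptake, mitochondrial signal and body size; mitotic cells
# share the condensed nucleus of early apoptosis but are Annexin-negative.
viability_render_table <- function() {
  data.frame(
    viability_class = c("healthy", "early_apoptotic", "late_apoptotic",
                        "necrotic", "lysed", "mitotic"),
    nuc_size = c(1, 0.62, 0.40, 0.78, 0.50, 0.62),
    nuc_amp = c(1, 2.2, 1.3, 1.45, 0.55, 2.2),
    fragmented = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    annexin = c(0, 1, 1, 0.15, 0.4, 0),
    perm = c(0, 0.05, 0.5, 1.0, 1.6, 0),
    mito = c(1, 1.5, 1.2, 0.6, 0.2, 1),
    body_size = c(1, 0.85, 0.85, 1.25, 0.35, 0.9),
    stringsAsFactors = FALSE)
}

#' Construct / validate a cell ground-truth table
#'
#' One row per simulated cell. Invariants enforced: `pyknosed_subclass` is
#' `"n/a"` exactly when the nucleus is not pyknosed; the three phenotype
#' booleans are defined (non-`NA`) only for cells with a healthy nucleus;
#' `fucci_state` is `"n/a"` outside FUCCI-mode simulations.
#'
#' @param df data.frame with columns `cell_id, x, y, nucleus_class,
#'   pyknosed_subclass, viability_class, fucci_state, tubulin_effect,
#'   mito_mass_increased, membrane_permeable`.
#' @param mode Assay mode, see [pg_modes()].
#' @return The validated data.frame with class `"cell_truth"`.
#' @export
cell_truth <- function(df, mode = "highvia_extend") {
  mode <- match.arg(mode, pg_modes())
  need <- c("cell_id", "x", "y", "nucleus_class", "pyknosed_subclass",
            "viability_class", "fucci_state", "tubulin_effect",
            "mito_mass_increased", "membrane_permeable")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("cell truth lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$nucleus_class %in% pg_classes$NUCLEI3))
      stopf("invalid nucleus_class")
    if (!all(df$viability_class %in% pg_classes$VIA5))
      stopf("invalid viability_class")
    pyk <- df$nucleus_class == "pyknosed"
    if (any(df$pyknosed_subclass[pyk] == "n/a") ||
        any(df$pyknosed_subclass[!pyk] != "n/a"))
      stopf("pyknosed_subclass must be set exactly for pyknosed nuclei")
    healthy <- df$nucleus_class == "healthy"
    for (b in c("tubulin_effect", "mito_mass_increased",
                "membrane_permeable"))
      if (any(!is.na(df[[b]][!healthy])))
        stopf("%s must be NA for non-healthy nuclei", b)
    if (mode != "fucci" && any(df$fucci_state != "n/a"))
      stopf("fucci_state must be 'n/a' outside fucci mode")
  }
  structure(df, class = c("cell_truth", "data.frame"), mode = mode)
}

#' Sample a random cell ground-truth table
#'
#' Places `n` cells with a minimum pairwise spacing (dart throwing) and
#' assigns viability, nuclear and phenotype states. Healthy-viability cells
#' are mitotic (condensed, Annexin-negative nucleus) with probability
#' `mitotic_fraction`.
#'
#' @param n Number of cells.
#' @param mode Assay mode.
#' @param viability_probs Named probabilities over the five viability states.
#' @param mitotic_fraction Fraction of healthy-viability cells in mitosis.
#' @param fucci_probs Occupancy over red/green/yellow/unlabeled (fucci mode).
#' @param phenotype_probs Named probabilities `c(tubulin=, mito=, membrane=)`
#'   that a healthy-nucleus cell carries each phenotype.
#' @param params Rendering parameters, see [render_params()].
#' @param min_spacing Minimum center-to-center distance (px); `NULL` =
#'   adaptive: 34 px (comfortably non-touching at default geometry) shrunk
#'   as needed for dense populations or small fields.
#' @param margin Border margin for centers (px).
#' @param seed Integer seed (required; the generator is deterministic).
#' @return A [cell_truth()] table.
#' @export
sample_cell_truth <- function(n, mode = "highvia_extend",
                              viability_probs = c(healthy = 1,
                                early_apoptotic = 0, late_apoptotic = 0,
                                necrotic = 0, lysed = 0),
                              mitotic_fraction = 0.04,
                              fucci_probs = c(red = 0.40, green = 0.45,
                                yellow = 0.12, unlabeled = 0.03),
                              phenotype_probs = c(tubulin = 0, mito = 0,
                                membrane = 0),
                              params = render_params(),
                              min_spacing = NULL, margin = 20, seed) {
  mode <- match.arg(mode, pg_modes())
  if (missing(seed)) stopf("seed is required")
  if (is.null(min_spacing))
    min_spacing <- min(34, sqrt(0.35 * prod(params$field) / max(n, 1)))
  with_seed(seed, {
    pts <- place_centers(n, params$field, min_spacing, margin)
    via <- pg_classes$VIA5[
      sample.int(5, n, replace = TRUE,
                 prob = viability_probs[pg_classes$VIA5])]
    mitotic <- via == "healthy" & runif(n) < mitotic_fraction
    nuc <- c(healthy = "healthy", early_apoptotic = "pyknosed",
             late_apoptotic = "fragmented", necrotic = "pyknosed",
             lysed = "pyknosed")[via]
    nuc[mitotic] <- "pyknosed"
    sub <- ifelse(nuc == "pyknosed",
                  ifelse(mitotic, "mitotic", "apoptotic"), "n/a")
    healthy_nuc <- nuc == "healthy"
    fucci <- rep("n/a", n)
    if (mode == "fucci") {
      fucci <- pg_classes$FUCCI[
        sample.int(4, n, replace = TRUE, prob = fucci_probs)]
    }
    tub <- mito <- memb <- rep(NA, n)
    tub[healthy_nuc] <- runif(sum(healthy_nuc)) < phenotype_probs[["tubulin"]]
    mito[healthy_nuc] <- runif(sum(healthy_nuc)) < phenotype_probs[["mito"]]
    memb[healthy_nuc] <- runif(sum(healthy_nuc)) <
      phenotype_probs[["membrane"]]
    cell_truth(data.frame(
      cell_id = seq_len(n), x = pts[, 1], y = pts[, 2],
      nucleus_class = unname(nuc), pyknosed_subclass = unname(sub),
      viability_class = via, fucci_state = fucci,
      tubulin_effect = tub, mito_mass_increased = mito,
      membrane_permeable = memb, stringsAsFactors = FALSE), mode)
  })
}

# Dart-throwing placement with minimum spacing; errors if the field cannot
# accommodate the requested density.
place_centers <- function(n, field, min_spacing, margin) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  xs <- ys <- numeric(n)
  k <- 0L
  tries <- 0L
  max_tries <- 400L * n
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, margin, field[1] - 1 - margin)
    y <- runif(1, margin, field[2] - 1 - margin)
    if (k == 0L ||
        min((xs[1:k] - x)^2 + (ys[1:k] - y)^2) >= min_spacing^2) {
      k <- k + 1L
      xs[k] <- x
      ys[k] <- y
    }
  }
  if (k < n)
    stopf("could not place %d cells with spacing %.1f px in a %dx%d field",
          n, min_spacing, field[1], field[2])
  cbind(x = xs, y = ys)
}

#' Construct an artifact ground-truth entry
#'
#' @param kind `"precipitate"` (irregular bright blob, emulating poorly
#'   soluble compounds) or `"autofluorescence"` (broad haze from
#'   intrinsically fluorescent compounds).
#' @param x,y Center (px).
#' @param size Characteristic radius (px).
#' @param intensity_scale Brightness multiplier relative to the median
#'   nuclear mean intensity; must exceed 1.
#' @return List of class `"artifact_truth"`.
#' @export
artifact_truth <- function(kind = c("precipitate", "autofluorescence"),
                           x, y, size = 15, intensity_scale = 8) {
  kind <- match.arg(kind)
  if (intensity_scale <= 1) stopf("intensity_scale must be > 1")
  structure(list(kind = kind, x = x, y = y, size = size,
                 intensity_scale = intensity_scale),
            class = "artifact_truth")
}

# super-Gaussian disk: ~1 inside radius r, soft edge
sdisk <- function(dx2, r) exp(-(dx2 / r^2)^4)

# elliptical nucleus profile on a squared-distance grid
nucleus_profile <- function(xg, yg, cx, cy, ra, rb, theta) {
  u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  v <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  q <- (u / ra)^2 + (v / rb)^2
  exp(-q^3)
}

#' Render a multi-channel field from ground truth
#'
#' Renders each cell with 2-D ellipse/disk primitives into per-channel
#' z-stacks (default 7 slices on a 16-bit scale; the in-focus slice is
#' progressively blurred away from focus), then applies Poisson-Gaussian
#' noise. Each phenotype is rendered distinguishably: pyknosed nuclei are
#' smaller and brighter, fragmented nuclei split into 3-6 fragments, FUCCI
#' states set nuclear red/green intensities, tubulin effects change
#' cytoplasmic 488 texture, mitochondrial mass scales the MitoTracker
#' channel, permeable cells take up the permeability dye and
#' Annexin-positive cells carry a membrane-ring signal. Ground-truth
#' instance masks are returned alongside.
#'
#' @param truth A [cell_truth()] table.
#' @param artifacts List of [artifact_truth()] entries.
#' @param mode Assay mode.
#' @param params See [render_params()].
#' @param seed Integer seed (required; rendering is bit-reproducible).
#' @param channels Optional subset of channel ids to render (speed).
#' @return An `image_field` list: `channels` (named list of z-stacks, each a
#'   list of matrices), `pixel_depth`, `metadata`, plus ground-truth
#'   `nuclei_mask`, `body_mask`, `artifact_mask` and the input `truth`.
#' @export
render_field <- function(truth, artifacts = list(), mode = attr(truth, "mode"),
                         params = render_params(), seed, channels = NULL) {
  mode <- match.arg(mode, pg_modes())
  if (missing(seed)) stopf("seed is required")
  if (inherits(artifacts, "artifact_truth")) artifacts <- list(artifacts)
  w <- params$field[1]; h <- params$field[2]
  n <- nrow(truth)
  if (n && (any(truth$x < 0 | truth$x > w - 1) ||
            any(truth$y < 0 | truth$y > h - 1)))
    stopf("cell centers must lie inside field bounds")
  chs <- names(channel_roles(mode))
  if (!is.null(channels)) {
    bad <- setdiff(channels, chs)
    if (length(bad)) stopf("unknown channels for mode %s: %s", mode,
                           paste(bad, collapse = ", "))
    chs <- intersect(chs, channels)
  }

  with_seed(seed, {
    vt <- viability_render_table()
    s <- params$separability
    # per-cell render specs
    eff_key <- truth$viability_class
    eff_key[truth$pyknosed_subclass == "mitotic"] <- "mitotic"
    ri <- match(eff_key, vt$viability_class)
    blend <- function(v) 1 + s * (v - 1)
    nuc_r <- pmax(2, rnorm(n, params$nucleus_radius, 1.0)) *
      blend(vt$nuc_size[ri])
    nuc_amp <- params$nucleus_amp * exp(rnorm(n, 0, 0.15)) *
      blend(vt$nuc_amp[ri])
    body_r <- pmax(4, rnorm(n, params$body_radius, 2.5)) *
      blend(vt$body_size[ri])
    annexin_lv <- s * vt$annexin[ri]
    perm_lv <- s * vt$perm[ri]
    mito_lv <- blend(vt$mito[ri]) *
      ifelse(!is.na(truth$mito_mass_increased) & truth$mito_mass_increased,
             1 + 0.8 * s, 1)
    memb_perm <- !is.na(truth$membrane_permeable) & truth$membrane_permeable
    tub_eff <- !is.na(truth$tubulin_effect) & truth$tubulin_effect

    # packing check on nuclear area
    if (n && sum(pi * nuc_r^2) / (w * h) > params$packing_limit)
      stopf("nuclear packing %.2f exceeds limit %.2f; too many cells",
            sum(pi * nuc_r^2) / (w * h), params$packing_limit)

    # expectation images (in-focus) per channel
    E <- lapply(chs, function(ch) matrix(0, h, w))
    names(E) <- chs
    bf_cell <- if ("bf" %in% chs) matrix(0, h, w) else NULL # phase factor
    nuclei_mask <- matrix(0L, h, w)
    body_mask <- matrix(0L, h, w)
    nuc_str <- matrix(0, h, w)
    body_str <- matrix(0, h, w)

    roles <- channel_roles(mode)
    ann_ch <- annexin_channel(mode)
    mito_ch <- mito_channel(mode)

    for (i in seq_len(n)) {
      cx <- truth$x[i]; cy <- truth$y[i]
      br <- body_r[i]
      pad <- ceiling(br * 1.8 + 6)
      c0 <- max(1, floor(cx) - pad + 1); c1 <- min(w, floor(cx) + pad + 1)
      r0 <- max(1, floor(cy) - pad + 1); r1 <- min(h, floor(cy) + pad + 1)
      xg <- matrix(rep((c0:c1) - 1, each = r1 - r0 + 1), r1 - r0 + 1)
      yg <- matrix(rep((r0:r1) - 1, times = c1 - c0 + 1), r1 - r0 + 1)
      d2 <- (xg - cx)^2 + (yg - cy)^2

      # nucleus profile (possibly fragmented)
      if (vt$fragmented[ri[i]]) {
        # karyorrhexis: fragments dispersed on a jittered ring inside the
        # cell radius, ring radius scaled with fragment count so adjacent
        # fragments stay individually resolvable
        nf <- sample(3:5, 1)
        ang <- 2 * pi * seq_len(nf) / nf + runif(nf, -0.15, 0.15)
        ring_r <- min((2.4 * nuc_r[i] + 5) / (2 * sin(pi / nf)), br)
        rad <- ring_r * runif(nf, 0.92, 1.08)
        prof <- 0
        for (f in seq_len(nf)) {
          fr <- nuc_r[i] * runif(1, 0.8, 1.2)
          prof <- prof + nucleus_profile(xg, yg, cx + rad[f] * cos(ang[f]),
                                         cy + rad[f] * sin(ang[f]),
                                         fr, fr * runif(1, 0.8, 1),
                                         runif(1, 0, pi))
        }
        prof <- pmin(prof, 1.2)
      } else {
        ecc <- runif(1, 0.75, 1)
        prof <- nucleus_profile(xg, yg, cx, cy, nuc_r[i], nuc_r[i] * ecc,
                                runif(1, 0, pi))
      }
      bodyp <- sdisk(d2, br)
      cyto <- pmax(bodyp - prof, 0)
      ringp <- exp(-((sqrt(d2) - br)^2) / (2 * 2^2))

      if ("hoechst" %in% chs)
        E$hoechst[r0:r1, c0:c1] <- E$hoechst[r0:r1, c0:c1] +
          nuc_amp[i] * prof
      if (!is.na(ann_ch) && ann_ch %in% chs && annexin_lv[i] > 0)
        E[[ann_ch]][r0:r1, c0:c1] <- E[[ann_ch]][r0:r1, c0:c1] +
          params$annexin_amp * annexin_lv[i] * ringp
      if (!is.na(mito_ch) && mito_ch %in% chs) {
        gran <- 1 + 0.25 * rnorm(length(d2))
        E[[mito_ch]][r0:r1, c0:c1] <- E[[mito_ch]][r0:r1, c0:c1] +
          params$mito_amp * mito_lv[i] * cyto * pmax(gran, 0)
      }
      if (mode == "highvia_extend" && "ch561" %in% chs && perm_lv[i] > 0)
        E$ch561[r0:r1, c0:c1] <- E$ch561[r0:r1, c0:c1] +
          params$perm_amp * perm_lv[i] * bodyp
      if (mode == "multiplex" && "ch488" %in% chs) {
        tex_amp <- if (tub_eff[i]) 0.12 + 0.38 * s else 0.12
        tex <- 1 + tex_amp * rnorm(length(d2))
        base <- params$tubulin_amp * cyto * pmax(tex, 0)
        if (memb_perm[i]) base <- base + 0.6 * s * params$tubulin_amp * bodyp
        E$ch488[r0:r1, c0:c1] <- E$ch488[r0:r1, c0:c1] + base
      }
      if (mode == "fucci") {
        if (truth$fucci_state[i] %in% c("green", "yellow") &&
            "ch488" %in% chs)
          E$ch488[r0:r1, c0:c1] <- E$ch488[r0:r1, c0:c1] +
            params$fucci_amp * prof
        if (truth$fucci_state[i] %in% c("red", "yellow") && "ch561" %in% chs)
          E$ch561[r0:r1, c0:c1] <- E$ch561[r0:r1, c0:c1] +
            params$fucci_amp * prof
      }
      if (!is.null(bf_cell)) {
        tex <- 1 + 0.12 * rnorm(length(d2))
        bf_cell[r0:r1, c0:c1] <- bf_cell[r0:r1, c0:c1] +
          bodyp * pmax(tex, 0)
      }

      # ground-truth masks (strongest contributor wins on overlap)
      nm <- prof > 0.35
      upd <- nm & (nuc_amp[i] * prof > nuc_str[r0:r1, c0:c1])
      sub_n <- nuclei_mask[r0:r1, c0:c1]
      sub_n[upd] <- truth$cell_id[i]
      nuclei_mask[r0:r1, c0:c1] <- sub_n
      str_n <- nuc_str[r0:r1, c0:c1]
      str_n[upd] <- (nuc_amp[i] * prof)[upd]
      nuc_str[r0:r1, c0:c1] <- str_n
      bm <- bodyp > 0.35
      updb <- bm & (bodyp > body_str[r0:r1, c0:c1])
      sub_b <- body_mask[r0:r1, c0:c1]
      sub_b[updb] <- truth$cell_id[i]
      body_mask[r0:r1, c0:c1] <- sub_b
      str_b <- body_str[r0:r1, c0:c1]
      str_b[updb] <- bodyp[updb]
      body_str[r0:r1, c0:c1] <- str_b
    }

    # reference nuclear brightness for artifact scaling: median over cells of
    # (mean rendered nuclear intensity); approximated as 0.62 * amp, the mean
    # of the super-Gaussian profile over its >0.35 support.
    med_nuc_mean <- if (n) median(nuc_amp) * 0.62 else
      params$nucleus_amp * 0.62

    artifact_mask <- matrix(0L, h, w)
    for (a in seq_along(artifacts)) {
      art <- artifacts[[a]]
      stopifnot(inherits(art, "artifact_truth"))
      amp <- art$intensity_scale * med_nuc_mean
      if (art$kind == "precipitate") {
        # irregular blob: union of small disks along a random walk
        steps <- 14
        px <- art$x; py <- art$y
        fp <- matrix(FALSE, h, w)
        for (k in seq_len(steps)) {
          rr <- art$size * runif(1, 0.25, 0.5)
          c0 <- max(1, floor(px - rr)); c1 <- min(w, ceiling(px + rr))
          r0 <- max(1, floor(py - rr)); r1 <- min(h, ceiling(py + rr))
          if (c1 >= c0 && r1 >= r0) {
            xg <- matrix(rep((c0:c1) - 1, each = r1 - r0 + 1), r1 - r0 + 1)
            yg <- matrix(rep((r0:r1) - 1, times = c1 - c0 + 1), r1 - r0 + 1)
            fp[r0:r1, c0:c1] <- fp[r0:r1, c0:c1] |
              ((xg - px)^2 + (yg - py)^2 <= rr^2)
          }
          stp <- art$size * 0.45
          px <- min(max(px + rnorm(1, 0, stp), 2), w - 3)
          py <- min(max(py + rnorm(1, 0, stp), 2), h - 3)
        }
        if ("hoechst" %in% chs) E$hoechst[fp] <- E$hoechst[fp] + amp
        artifact_mask[fp] <- a
      } else {
        # fluorescent-compound haze: the compound accumulates in and
        # around cells, so the glow is cell-weighted with a diffuse floor
        # (a perfectly uniform offset would just be background)
        xg <- matrix(rep(seq_len(w) - 1, each = h), h)
        yg <- matrix(rep(seq_len(h) - 1, times = w), h)
        haze <- exp(-(((xg - art$x)^2 + (yg - art$y)^2) /
                        (2 * art$size^2)))
        weight <- 0.2 + pmin(body_str, 1)
        for (ch in intersect(c("hoechst", "ch488"), chs))
          E[[ch]] <- E[[ch]] + amp * haze * weight
        artifact_mask[haze > 0.5 & body_str > 0.35] <- a
      }
    }

    # assemble z-stacks with defocus blur + Poisson-Gaussian noise
    maxv <- 2^16 - 1
    out <- list()
    for (ch in chs) {
      base <- E[[ch]]
      stack <- vector("list", params$nz)
      blur_cache <- list() # keyed by |z - focus|; slices share defocus blur
      for (z in seq_len(params$nz)) {
        dz <- abs(z - params$focus_z)
        if (ch == "bf") {
          # phase effect: cells darker below focus, brighter above
          phase <- params$body_bf_amp * (z - params$focus_z) / 2
          Ez <- params$bg[["bf"]] + phase * bf_cell
        } else {
          key <- as.character(dz)
          if (is.null(blur_cache[[key]]))
            blur_cache[[key]] <- if (dz > 0)
              .gaussian_blur_cpp(base, params$z_blur * dz) else base
          Ez <- params$bg[[ch]] + blur_cache[[key]] * params$z_decay^dz
        }
        noisy <- Ez + sqrt(pmax(Ez, 0) + params$read_sd^2) *
          rnorm(length(Ez))
        stack[[z]] <- matrix(pmin(pmax(round(noisy), 0), maxv), h, w)
      }
      out[[ch]] <- stack
    }

    structure(list(
      channels = out, pixel_depth = 16L,
      metadata = list(mode = mode, field = params$field, nz = params$nz,
                      well = NA_character_, timepoint = NA_real_,
                      cell_line = NA_character_),
      nuclei_mask = nuclei_mask, body_mask = body_mask,
      artifact_mask = artifact_mask, truth = truth),
      class = "image_field")
  })
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %dx%d px, %d z, channels: %s (mode %s)\n",
              x$metadata$field[1], x$metadata$field[2], x$metadata$nz,
              paste(names(x$channels), collapse = ", "),
              x$metadata$mode))
  invisible(x)
}

#' Compound kinetics specification
#'
#' Parameters of the compartmental death model for one compound. Cytotoxic
#' exit from the healthy pool follows a Hill function of concentration whose
#' midpoint halves every `potency_halving_time` hours (potency increases
#' with exposure time), referenced to `ic50` at 24 h. `kinetic_class` sets
#' the maximal exit rate and the default halving time (rapid <
#' intermediate < slow).
#'
#' @param ic50 IC50 (µM) at the 24 h reference time; > 0.
#' @param hill Hill slope; > 0.
#' @param kinetic_class `"rapid"`, `"intermediate"` or `"slow"`.
#' @param potency_halving_time Hours for the midpoint to halve; defaults to
#'   8/16/32 h for rapid/intermediate/slow.
#' @param terminal_state_bias Route weights over apoptotic (early -> late
#'   apoptotic -> necrotic -> lysed), necrotic (direct) and lysed (direct).
#' @param cell_cycle_action `"none"`, `"g1_arrest"`, `"s_arrest"` or
#'   `"g2m_arrest"` (FUCCI-mode occupancy shift).
#' @param phenotype_probs Maximal probabilities that a surviving
#'   healthy-nucleus cell shows tubulin / mito / membrane phenotypes
#'   (scaled by the Hill occupancy).
#' @return List of class `"kinetics_spec"`.
#' @export
kinetics_spec <- function(ic50, hill = 1.2,
                          kinetic_class = c("intermediate", "rapid", "slow"),
                          potency_halving_time = NULL,
                          terminal_state_bias = c(apoptotic = 0.6,
                            necrotic = 0.3, lysed = 0.1),
                          cell_cycle_action = c("none", "g1_arrest",
                            "s_arrest", "g2m_arrest"),
                          phenotype_probs = c(tubulin = 0, mito = 0,
                            membrane = 0)) {
  kinetic_class <- match.arg(kinetic_class)
  cell_cycle_action <- match.arg(cell_cycle_action)
  if (ic50 <= 0) stopf("ic50 must be > 0")
  if (hill <= 0) stopf("hill must be > 0")
  defaults <- c(rapid = 8, intermediate = 16, slow = 32)
  kmax <- c(rapid = 0.30, intermediate = 0.12, slow = 0.05)
  if (is.null(potency_halving_time))
    potency_halving_time <- defaults[[kinetic_class]]
  tsb <- terminal_state_bias / sum(terminal_state_bias)
  structure(list(ic50 = ic50, hill = hill, kinetic_class = kinetic_class,
                 potency_halving_time = potency_halving_time,
                 k_max = kmax[[kinetic_class]],
                 terminal_state_bias = tsb,
                 cell_cycle_action = cell_cycle_action,
                 phenotype_probs = phenotype_probs),
            class = "kinetics_spec")
}

# time-dependent midpoint and per-hour exit probability
ic50_at <- function(kin, t, t_ref = 24) {
  kin$ic50 * 2^(-(t - t_ref) / kin$potency_halving_time)
}

exit_prob <- function(kin, conc, t) {
  if (conc <= 0) return(0)
  m <- ic50_at(kin, t)
  min(kin$k_max * conc^kin$hill / (conc^kin$hill + m^kin$hill), 0.95)
}

# FUCCI occupancy at time t under a cell-cycle action
fucci_occupancy <- function(kin = NULL, conc = 0, t = 0) {
  p0 <- c(red = 0.40, green = 0.45, yellow = 0.12, unlabeled = 0.03)
  if (is.null(kin) || conc <= 0 || kin$cell_cycle_action == "none")
    return(p0)
  target <- switch(kin$cell_cycle_action,
    g1_arrest = c(red = 0.80, green = 0.10, yellow = 0.07,
                  unlabeled = 0.03),
    s_arrest = c(red = 0.10, green = 0.35, yellow = 0.52, unlabeled = 0.03),
    g2m_arrest = c(red = 0.07, green = 0.85, yellow = 0.05,
                   unlabeled = 0.03))
  m <- ic50_at(kin, t)
  eff <- conc^kin$hill / (conc^kin$hill + m^kin$hill)
  w <- eff * (1 - exp(-t / 12))
  (1 - w) * p0 + w * target
}

#' Construct / validate a plate design
#'
#' @param wells data.frame with columns `well` (e.g. "B02"), `compound`
#'   (`NA` for controls), `concentration` (µM; 0 for controls), `role`
#'   (`treatment`, `dmso_control`, `untreated`, `reference_compound`) and
#'   `cell_line`.
#' @param timepoints Observation times (hours after treatment).
#' @param mode Assay mode.
#' @param basal_growth_rate Per-hour division probability of healthy cells
#'   (default log(2)/24: 24 h doubling).
#' @param n0 Cells per well field at treatment time.
#' @return List of class `"plate_design"`.
#' @export
plate_design <- function(wells, timepoints = c(0, 12, 24, 36, 48, 60, 72),
                         mode = "highvia_extend",
                         basal_growth_rate = log(2) / 24, n0 = 200L) {
  mode <- match.arg(mode, pg_modes())
  need <- c("well", "compound", "concentration", "role", "cell_line")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("plate design lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (sum(wells$role == "dmso_control") < 2)
    stopf("plate design needs at least 2 dmso_control wells")
  rc <- well_to_rowcol(wells$well)
  outer <- rc$row < 1 | rc$row > 14 | rc$col < 1 | rc$col > 22
  if (any(outer))
    stopf("outer wells are buffer-filled and cannot be assigned: %s",
          paste(wells$well[outer], collapse = ", "))
  tr <- wells$role %in% c("treatment", "reference_compound")
  if (any(is.na(wells$compound[tr])) ||
      any(wells$concentration[tr] <= 0))
    stopf("treatment wells need a compound and a positive concentration")
  structure(list(wells = wells, timepoints = sort(unique(timepoints)),
                 mode = mode, basal_growth_rate = basal_growth_rate,
                 n0 = as.integer(n0)),
            class = "plate_design")
}

# "B02" -> 0-based row/col on a 16x24 (384-well) grid
well_to_rowcol <- function(well) {
  row <- match(substr(well, 1, 1), LETTERS[1:16]) - 1L
  col <- as.integer(substr(well, 2, 3)) - 1L
  if (any(is.na(row)) || any(is.na(col))) stopf("malformed well id")
  list(row = row, col = col)
}

rowcol_to_well <- function(row, col) {
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

#' Build a standard plate design
#'
#' Lays out a dilution series for each compound plus DMSO-control and
#' untreated wells in the inner wells of a 384-well grid (outer wells are
#' buffer, mirroring standard screening practice).
#'
#' @param compounds Character vector of compound ids.
#' @param concentrations Concentrations (µM) tested per compound; default a
#'   7-point half-log serial dilution from 10 µM.
#' @param n_dmso Number of DMSO (0.1%) control wells.
#' @param n_untreated Number of untreated wells.
#' @param cell_line Cell line tag.
#' @inheritParams plate_design
#' @return A [plate_design()].
#' @export
make_plate_design <- function(compounds,
                              concentrations = serial_dilution(10, 7),
                              n_dmso = 4L, n_untreated = 2L,
                              cell_line = "U2OS", mode = "highvia_extend",
                              timepoints = c(0, 12, 24, 36, 48, 60, 72),
                              basal_growth_rate = log(2) / 24, n0 = 200L) {
  rows <- 1:14  # 0-based rows 1..14 = B..O
  cols <- 1:22  # 0-based cols 1..22 = 02..23
  slots <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  n_need <- length(compounds) * length(concentrations) + n_dmso + n_untreated
  if (n_need > nrow(slots))
    stopf("design needs %d wells; only %d inner wells available", n_need,
          nrow(slots))
  wells <- data.frame(
    well = rowcol_to_well(slots$row[seq_len(n_need)],
                          slots$col[seq_len(n_need)]),
    compound = NA_character_, concentration = 0, role = "dmso_control",
    cell_line = cell_line, stringsAsFactors = FALSE)
  k <- 1L
  for (cp in compounds)
    for (cc in concentrations) {
      wells$compound[k] <- cp
      wells$concentration[k] <- cc
      wells$role[k] <- "treatment"
      k <- k + 1L
    }
  if (n_dmso) k <- k + n_dmso
  if (n_untreated)
    wells$role[seq(k, length.out = n_untreated)] <- "untreated"
  plate_design(wells, timepoints, mode, basal_growth_rate, n0)
}

#' Serial dilution series
#'
#' @param top Highest concentration (µM).
#' @param n Number of points.
#' @param factor Dilution factor between consecutive points (default
#'   half-log, ~3.16).
#' @return Decreasing numeric vector of length `n`.
#' @export
serial_dilution <- function(top = 10, n = 7, factor = sqrt(10)) {
  top / factor^(seq_len(n) - 1)
}

#' Simulate population kinetics for a whole plate
#'
#' Runs the compartment model for every well: healthy cells divide at the
#' basal rate; in treatment wells they exit at a Hill-of-concentration rate
#' whose midpoint decreases over time; exited cells follow their terminal
#' route through early apoptotic -> late apoptotic -> necrotic -> lysed
#' (apoptotic route) or enter necrotic/lysed directly; lysed cells are
#' eventually cleared (detached/disintegrated) but stay in the books.
#' FUCCI-mode wells additionally receive cell-cycle occupancies shifted per
#' the compound's `cell_cycle_action`. DMSO and untreated wells follow basal
#' growth only.
#'
#' @param design A [plate_design()].
#' @param kinetics Named list: compound id -> [kinetics_spec()]. Every
#'   treatment compound must be present.
#' @param seed Integer seed.
#' @return List of class `"plate_sim"` with the design, kinetics and a
#'   `counts` data.frame (one row per well x timepoint) holding per-state
#'   counts, cumulative cleared count, total cells ever created and (fucci
#'   mode) FUCCI occupancy counts among healthy cells.
#' @export
simulate_plate <- function(design, kinetics = list(), seed) {
  stopifnot(inherits(design, "plate_design"))
  if (missing(seed)) stopf("seed is required")
  wl <- design$wells
  tr <- wl$role %in% c("treatment", "reference_compound")
  missing_kin <- setdiff(unique(wl$compound[tr]), names(kinetics))
  if (length(missing_kin))
    stopf("missing kinetics spec for compound(s): %s",
          paste(missing_kin, collapse = ", "))
  if (!any(wl$role == "dmso_control"))
    stopf("no DMSO wells: downstream normalization would be impossible")

  rows <- list()
  for (i in seq_len(nrow(wl))) {
    kin <- if (tr[i]) kinetics[[wl$compound[i]]] else NULL
    ws <- derive_seed(seed, i)
    rows[[i]] <- simulate_well(kin, wl$concentration[i], design, ws,
                               fucci = design$mode == "fucci")
    rows[[i]]$well <- wl$well[i]
  }
  counts <- do.call(rbind, lapply(rows, function(r) r))
  counts <- merge(counts, wl, by = "well", sort = FALSE)
  counts <- counts[order(match(counts$well, wl$well), counts$timepoint), ]
  rownames(counts) <- NULL
  structure(list(design = design, kinetics = kinetics, counts = counts,
                 seed = as.integer(seed)),
            class = "plate_sim")
}

# one well's trajectory; returns data.frame over design$timepoints
simulate_well <- function(kin, conc, design, seed, fucci = FALSE) {
  tps <- design$timepoints
  pd <- design$basal_growth_rate
  prog <- c(ea2la = 0.20, la2n = 0.10, n2l = 0.08, l2clear = 0.05)
  with_seed(seed, {
    st <- c(H = design$n0, EA = 0L, LA = 0L, N = 0L, L = 0L)
    cleared <- 0L
    created <- design$n0
    out <- list()
    rec <- function(t) {
      r <- data.frame(timepoint = t, n_healthy = st[["H"]],
                      n_early_apoptotic = st[["EA"]],
                      n_late_apoptotic = st[["LA"]],
                      n_necrotic = st[["N"]], n_lysed = st[["L"]],
                      n_cleared = cleared, n_total_created = created)
      if (fucci) {
        occ <- fucci_occupancy(kin, conc, t)
        fc <- if (st[["H"]] > 0)
          as.integer(rmultinom(1, st[["H"]], occ)) else integer(4)
        r$n_red <- fc[1]; r$n_green <- fc[2]
        r$n_yellow <- fc[3]; r$n_unlabeled <- fc[4]
      }
      r
    }
    if (0 %in% tps) out[["0"]] <- rec(0)
    for (t in seq_len(max(tps))) {
      pe <- if (is.null(kin)) 0 else exit_prob(kin, conc, t)
      ex <- if (pe > 0 && st[["H"]] > 0) rbinom(1, st[["H"]], pe) else 0L
      route <- if (ex > 0)
        as.integer(rmultinom(1, ex, kin$terminal_state_bias)) else
          integer(3)
      st[["H"]] <- st[["H"]] - ex
      dv <- if (st[["H"]] > 0) rbinom(1, st[["H"]], pd) else 0L
      st[["H"]] <- st[["H"]] + dv
      created <- created + dv
      m_ea <- if (st[["EA"]] > 0) rbinom(1, st[["EA"]], prog["ea2la"]) else 0L
      m_la <- if (st[["LA"]] > 0) rbinom(1, st[["LA"]], prog["la2n"]) else 0L
      m_n <- if (st[["N"]] > 0) rbinom(1, st[["N"]], prog["n2l"]) else 0L
      m_l <- if (st[["L"]] > 0) rbinom(1, st[["L"]], prog["l2clear"]) else 0L
      st[["EA"]] <- st[["EA"]] - m_ea + route[1]
      st[["LA"]] <- st[["LA"]] - m_la + m_ea
      st[["N"]] <- st[["N"]] - m_n + m_la + route[2]
      st[["L"]] <- st[["L"]] - m_l + m_n + route[3]
      cleared <- cleared + m_l
      if (t %in% tps) out[[as.character(t)]] <- rec(t)
    }
    do.call(rbind, out)
  })
}

#' Expected healthy-cell trajectory (deterministic mean of the simulator)
#'
#' Closed-form expectation of the compartment model, used as the independent
#' reference for Monte-Carlo properties (e.g. monotonicity of the expected
#' healthy fraction in concentration).
#'
#' @inheritParams simulate_plate
#' @param kin A [kinetics_spec()] or `NULL` (control well).
#' @param conc Concentration (µM).
#' @param times Hours at which to report.
#' @param n0 Initial healthy count.
#' @param basal_growth_rate Per-hour division probability.
#' @return data.frame with expected per-state counts at `times`.
#' @export
expected_trajectory <- function(kin, conc, times, n0 = 200,
                                basal_growth_rate = log(2) / 24) {
  prog <- c(ea2la = 0.20, la2n = 0.10, n2l = 0.08, l2clear = 0.05)
  st <- c(H = n0, EA = 0, LA = 0, N = 0, L = 0)
  cleared <- 0
  out <- list()
  if (0 %in% times)
    out[["0"]] <- c(timepoint = 0, st, cleared = cleared)
  for (t in seq_len(max(times))) {
    pe <- if (is.null(kin)) 0 else exit_prob(kin, conc, t)
    ex <- st[["H"]] * pe
    st[["H"]] <- (st[["H"]] - ex) * (1 + basal_growth_rate)
    route <- ex * kin_route(kin)
    m <- c(st[["EA"]], st[["LA"]], st[["N"]], st[["L"]]) * prog
    st[["EA"]] <- st[["EA"]] - m[1] + route[1]
    st[["LA"]] <- st[["LA"]] - m[2] + m[1]
    st[["N"]] <- st[["N"]] - m[3] + m[2] + route[2]
    st[["L"]] <- st[["L"]] - m[4] + m[3] + route[3]
    cleared <- cleared + m[4]
    if (t %in% times)
      out[[as.character(t)]] <- c(timepoint = t, st, cleared = cleared)
  }
  as.data.frame(do.call(rbind, out))
}

kin_route <- function(kin) {
  if (is.null(kin)) return(c(0, 0, 0))
  unname(kin$terminal_state_bias[c("apoptotic", "necrotic", "lysed")])
}

#' Materialize per-cell ground truth for one simulated well/timepoint
#'
#' Converts the compartment counts of a [simulate_plate()] run into a
#' [cell_truth()] table that [render_field()] can draw, sub-sampling
#' proportionally when the population exceeds `max_cells` (a rendered field
#' cannot hold an unbounded population; fractions are preserved).
#'
#' @param sim A `plate_sim`.
#' @param well Well id.
#' @param timepoint Hour (must be one of the design's timepoints).
#' @param max_cells Rendering cap.
#' @param params Rendering parameters (for placement geometry).
#' @return A [cell_truth()] table.
#' @export
materialize_well <- function(sim, well, timepoint, max_cells = 400,
                             params = render_params()) {
  stopifnot(inherits(sim, "plate_sim"))
  cts <- sim$counts
  r <- cts[cts$well == well & cts$timepoint == timepoint, ]
  if (nrow(r) != 1) stopf("no simulated record for %s at %s h", well,
                          timepoint)
  n_state <- c(healthy = r$n_healthy, early_apoptotic = r$n_early_apoptotic,
               late_apoptotic = r$n_late_apoptotic, necrotic = r$n_necrotic,
               lysed = r$n_lysed)
  tot <- sum(n_state)
  ws <- derive_seed(sim$seed, match(well, sim$design$wells$well),
                    timepoint, 7L)
  if (tot > max_cells) {
    sc <- max_cells / tot
    n_state <- with_seed(ws, {
      # largest-remainder rounding with stochastic residual keeps fractions
      base <- floor(n_state * sc)
      resid <- n_state * sc - base
      extra <- max_cells - sum(base)
      if (extra > 0) {
        add <- sample(seq_along(n_state), size = extra, replace = TRUE,
                      prob = resid + 1e-9)
        for (i in add) base[i] <- base[i] + 1L
      }
      base
    })
    tot <- sum(n_state)
  }
  mode <- sim$design$mode
  kin <- NULL
  if (r$role %in% c("treatment", "reference_compound"))
    kin <- sim$kinetics[[r$compound]]
  vp <- if (tot > 0) n_state / tot else n_state
  ph <- c(tubulin = 0, mito = 0, membrane = 0)
  if (!is.null(kin)) {
    m <- ic50_at(kin, timepoint)
    eff <- r$concentration^kin$hill /
      (r$concentration^kin$hill + m^kin$hill)
    ph <- kin$phenotype_probs * eff
  }
  truth <- sample_cell_truth(tot, mode = mode, viability_probs = vp,
                             phenotype_probs = ph, params = params,
                             seed = derive_seed(ws, 11L))
  if (mode == "fucci" && tot > 0) {
    occ <- fucci_occupancy(kin, r$concentration, timepoint)
    healthy <- truth$nucleus_class == "healthy"
    truth$fucci_state <- "n/a"
    truth$fucci_state[healthy] <- with_seed(derive_seed(ws, 13L),
      pg_classes$FUCCI[sample.int(4, sum(healthy), replace = TRUE,
                                  prob = occ)])
    # non-healthy nuclei keep reporter color too (config-dependent gating)
    nh <- !healthy
    truth$fucci_state[nh] <- with_seed(derive_seed(ws, 17L),
      pg_classes$FUCCI[sample.int(4, sum(nh), replace = TRUE, prob = occ)])
    truth <- cell_truth(as.data.frame(truth), mode)
  }
  truth
}
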