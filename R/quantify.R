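## Per-well aggregation, DMSO normalization, normalized growth rate,
## time-resolved four-parameter-logistic dose-response and the per-compound
## flagging certificate.

#' Flagging thresholds
#'
#' The default per-property flagging rules: a compound is flagged on a
#' property when the fraction crosses the threshold in the stated direction
#' (healthy nuclei is a "less than" rule; everything else "greater than"),
#' in every cell line of the configured panel.
#'
#' @return data.frame `rule, metric, direction, threshold`.
#' @export
default_flag_rules <- function() {
  data.frame(
    rule = c("hio_gt_50", "healthy_nuclei_lt_50", "pyknosed_gt_50",
             "fragmented_gt_50", "tubulin_gt_50", "mito_gt_50",
             "membrane_gt_50"),
    metric = c("hio_ratio", "frac_nuclei_healthy", "frac_nuclei_pyknosed",
               "frac_nuclei_fragmented", "frac_tubulin_effect",
               "frac_mito_increased", "frac_membrane_permeable"),
    direction = c(">", "<", ">", ">", ">", ">", ">"),
    threshold = rep(0.5, 7),
    stringsAsFactors = FALSE)
}

fraction_block <- function(labels, classes, prefix) {
  n <- sum(!is.na(labels))
  counts <- as.integer(table(factor(labels, levels = classes)))
  fr <- if (n > 0) counts / n else rep(NA_real_, length(classes))
  out <- c(as.list(counts), as.list(fr))
  names(out) <- c(paste0("n_", prefix, "_", classes),
                  paste0("frac_", prefix, "_", classes))
  out
}

#' Summarize one well/timepoint of gated cell records
#'
#' Computes counts and fractions per gating partition. Fraction denominators
#' follow the hierarchy: nuclear fractions are over normal-intensity
#' objects, viability fractions over normal objects, phenotype fractions
#' over healthy-nucleus cells, and FUCCI fractions over labeled
#' (non-"unlabeled") healthy-nucleus cells only. Zero cells yields null
#' fractions and `low_count_flag`.
#'
#' @param records Gated cell records (from [apply_gating()]) of a single
#'   well/timepoint.
#' @param min_count Minimum normal-object count below which
#'   `low_count_flag` is set (fraction-based rules should then be ignored).
#' @param well,timepoint Identifiers carried into the summary.
#' @return One-row data.frame (`well_summary`).
#' @export
well_fractions <- function(records, min_count = 50L, well = NA_character_,
                           timepoint = NA_real_) {
  n_obj <- nrow(records)
  hio <- if ("label_hio" %in% names(records)) records$label_hio else
    rep("normal", n_obj)
  n_hio <- sum(hio == "high_intensity_object", na.rm = TRUE)
  normal <- records[hio == "normal", , drop = FALSE]
  n_normal <- nrow(normal)

  out <- data.frame(well = well, timepoint = timepoint, n_objects = n_obj,
                    n_hio = n_hio,
                    hio_ratio = if (n_obj > 0) n_hio / n_obj else NA_real_,
                    n_normal = n_normal)
  out <- cbind(out, fraction_block(normal$label_nuclei,
                                   pg_classes$NUCLEI3, "nuclei"))
  if ("label_via" %in% names(records))
    out <- cbind(out, fraction_block(normal$label_via, pg_classes$VIA5,
                                     "via"))
  healthy <- normal[!is.na(normal$label_nuclei) &
                      normal$label_nuclei == "healthy", , drop = FALSE]
  out$n_healthy_nuclei <- nrow(healthy)
  if ("tubulin_effect" %in% names(records)) {
    nh <- nrow(healthy)
    evaluated <- healthy$mito_increased != "not_evaluated"
    out$frac_tubulin_effect <- if (nh) mean(healthy$tubulin_effect) else
      NA_real_
    out$frac_mito_increased <- if (any(evaluated))
      mean(healthy$mito_increased[evaluated] == "increased") else NA_real_
    out$frac_membrane_permeable <- if (nh)
      mean(healthy$membrane_permeable) else NA_real_
  }
  if ("label_fucci" %in% names(records)) {
    lab <- healthy$label_fucci[!is.na(healthy$label_fucci) &
                                 healthy$label_fucci != "unlabeled"]
    n_lab <- length(lab)
    out$n_fucci_labeled <- n_lab
    for (cl in c("red", "green", "yellow"))
      out[[paste0("frac_fucci_", cl)]] <-
        if (n_lab) sum(lab == cl) / n_lab else NA_real_
  }
  out$low_count_flag <- n_normal < min_count
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Normalize healthy counts to same-plate, same-timepoint DMSO wells
#'
#' Adds `healthy_nuclei_norm` (and `healthy_via_norm` when five-state
#' viability labels are present): healthy count divided by the arithmetic
#' mean healthy count of the DMSO-control wells at the same timepoint. The
#' DMSO wells normalize against themselves, so their mean is 1 by
#' construction.
#'
#' @param summaries data.frame of [well_fractions()] rows for one plate.
#' @param design The [plate_design()] providing well roles.
#' @return `summaries` with normalization columns appended.
#' @export
normalize_to_dmso <- function(summaries, design) {
  roles <- design$wells$role[match(summaries$well, design$wells$well)]
  if (!any(roles == "dmso_control", na.rm = TRUE))
    stopf("no DMSO wells present; cannot normalize")
  summaries$healthy_nuclei_norm <- NA_real_
  has_via <- "n_via_healthy" %in% names(summaries)
  if (has_via) summaries$healthy_via_norm <- NA_real_
  for (tp in unique(summaries$timepoint)) {
    sel <- summaries$timepoint == tp
    dm <- sel & roles == "dmso_control"
    if (!any(dm)) stopf("no DMSO wells at timepoint %s", tp)
    denom <- mean(summaries$n_healthy_nuclei[dm])
    summaries$healthy_nuclei_norm[sel] <-
      summaries$n_healthy_nuclei[sel] / denom
    if (has_via) {
      denom_v <- mean(summaries$n_via_healthy[dm])
      summaries$healthy_via_norm[sel] <- summaries$n_via_healthy[sel] /
        denom_v
    }
  }
  summaries
}

#' Normalized growth rate
#'
#' `GR = 2^(log2(x_c/x_0) / log2(x_ctrl/x_0)) - 1`: 1 means control-like
#' growth, 0 stasis, negative net cell loss.
#'
#' @param x_c Treated cell count at time t.
#' @param x_0 Count at treatment time.
#' @param x_ctrl Control (DMSO/untreated) count at time t; must exceed
#'   `x_0` (growing control), else the metric is undefined.
#' @return GR value (dimensionless).
#' @export
growth_rate <- function(x_c, x_0, x_ctrl) {
  if (any(c(x_c, x_0, x_ctrl) <= 0))
    stopf("growth_rate needs positive counts")
  if (x_ctrl <= x_0)
    stopf("control did not grow (x_ctrl <= x_0); GR undefined")
  2^(log2(x_c / x_0) / log2(x_ctrl / x_0)) - 1
}

#' Fit a four-parameter logistic dose-response
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 +
#' (c/ic50)^hill)` against log10 concentration, with multi-start bounded
#' optimization (top in `[0.5, 1.5]`, bottom in `[0, top]`, log10(ic50)
#' within the tested range +/- 2 decades). Initialization and bounds depend
#' on concentrations only through log10(c), so rescaling units shifts the
#' IC50 estimate exactly. A series whose response never drops materially
#' (range < `min_span`) is reported `converged = FALSE` with reason
#' "no effect within tested range".
#'
#' @param concentrations Concentrations (µM or any consistent unit); >= 4
#'   distinct values required.
#' @param responses Normalized responses (typically normalized healthy
#'   count; control ~ 1).
#' @param timepoint Hour tag carried into the result.
#' @param min_span Minimal response range treated as a real effect.
#' @return List of class `"dose_response_fit"`: `ic50, hill, top, bottom,
#'   converged, reason, rss, timepoint`.
#' @export
fit_dose_response <- function(concentrations, responses,
                              timepoint = NA_real_, min_span = 0.2) {
  ok <- is.finite(concentrations) & is.finite(responses) & concentrations > 0
  x <- log10(concentrations[ok])
  y <- responses[ok]
  if (length(unique(x)) < 4)
    stopf("need >= 4 distinct positive concentrations")
  res <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_, converged = FALSE, reason = "",
              rss = NA_real_, timepoint = timepoint)
  class(res) <- "dose_response_fit"
  if (diff(range(y)) < min_span) {
    res$reason <- "no effect within tested range"
    res$top <- mean(y)
    return(res)
  }
  f <- function(p) {
    yy <- p[4] + (p[3] - p[4]) / (1 + 10^((x - p[1]) * p[2]))
    sum((yy - y)^2)
  }
  lo <- c(min(x) - 2, 0.1, 0.5, 0)
  hi <- c(max(x) + 2, 8, 1.5, 1.5)
  starts <- expand.grid(l = unname(quantile(x, c(0.25, 0.5, 0.75))),
                        h = c(0.8, 1.5, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- unname(c(starts$l[i], starts$h[i], max(min(max(y), 1.5), 0.5),
                   min(max(min(y), 0), 1.4)))
    p0 <- pmin(pmax(p0, lo), hi)
    fit <- tryCatch(
      optim(p0, f, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    res$reason <- "optimization failed"
    return(res)
  }
  p <- best$par
  if (p[4] > p[3]) { # enforce bottom <= top at the reported scale
    p[c(3, 4)] <- p[c(4, 3)]
    p[2] <- -p[2]
  }
  res$ic50 <- 10^p[1]
  res$hill <- p[2]
  res$top <- p[3]
  res$bottom <- p[4]
  res$rss <- best$value
  # midpoint far outside the tested range = no measurable potency
  if (p[1] > max(x) + 1) {
    res$reason <- "no effect within tested range"
  } else {
    res$converged <- TRUE
  }
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<4PL fit> IC50 = %.4g, hill = %.2f, top = %.2f, bottom = %.2f (rss %.3g)\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss))
  else cat(sprintf("<4PL fit> not converged: %s\n", x$reason))
  invisible(x)
}

#' Evaluate flagging rules and build a compound certificate
#'
#' Each rule fires for a (cell line, concentration, timepoint) cell when its
#' metric crosses the threshold in the rule's direction (and the well is not
#' low-count). A property flags the compound overall when the same rule
#' fires in every cell line of the panel at some shared (concentration,
#' timepoint). Missing cell lines are evaluated over the available ones with
#' an `incomplete_panel` note.
#'
#' @param summaries data.frame with columns `compound, cell_line,
#'   concentration, timepoint, low_count_flag` and the metric columns of
#'   [default_flag_rules()] (absent metrics are skipped).
#' @param compound Compound id (single).
#' @param rules Threshold rules (defaults per [default_flag_rules()]).
#' @param cell_lines Panel definition; default: the cell lines present.
#' @return List of class `"compound_certificate"`: `compound`, `table`
#'   (per-line rule evaluations), `flags` (rules firing panel-wide),
#'   `flagged_overall`, `incomplete_panel`, `notes`.
#' @export
flag_compound <- function(summaries, compound,
                          rules = default_flag_rules(),
                          cell_lines = NULL) {
  s <- summaries[summaries$compound == compound, , drop = FALSE]
  if (!nrow(s)) stopf("no summaries for compound %s", compound)
  panel <- cell_lines %||% sort(unique(s$cell_line))
  incomplete <- !all(panel %in% s$cell_line)
  avail <- intersect(panel, unique(s$cell_line))

  evals <- list()
  for (i in seq_len(nrow(rules))) {
    m <- rules$metric[i]
    if (!m %in% names(s)) next
    v <- s[[m]]
    fire <- if (rules$direction[i] == ">") v > rules$threshold[i] else
      v < rules$threshold[i]
    fire[is.na(fire)] <- FALSE
    fire[s$low_count_flag] <- FALSE
    evals[[rules$rule[i]]] <- data.frame(
      rule = rules$rule[i], cell_line = s$cell_line,
      concentration = s$concentration, timepoint = s$timepoint,
      value = v, fires = fire, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, evals)
  rownames(tab) <- NULL

  flags <- character(0)
  if (!is.null(tab)) {
    for (r in unique(tab$rule)) {
      tr <- tab[tab$rule == r & tab$fires, , drop = FALSE]
      if (!nrow(tr)) next
      combos <- unique(tr[, c("concentration", "timepoint")])
      for (j in seq_len(nrow(combos))) {
        lines_firing <- unique(tr$cell_line[
          tr$concentration == combos$concentration[j] &
            tr$timepoint == combos$timepoint[j]])
        if (all(avail %in% lines_firing)) {
          flags <- c(flags, r)
          break
        }
      }
    }
  }
  structure(list(compound = compound, table = tab, flags = unique(flags),
                 flagged_overall = length(flags) > 0,
                 incomplete_panel = incomplete,
                 notes = if (incomplete)
                   sprintf("incomplete-panel: evaluated over %s of {%s}",
                           paste(avail, collapse = ","),
                           paste(panel, collapse = ",")) else character(0)),
            class = "compound_certificate")
}

#' @export
print.compound_certificate <- function(x, ...) {
  cat(sprintf("<certificate %s> %s%s\n", x$compound,
              if (x$flagged_overall)
                paste("FLAGGED:", paste(x$flags, collapse = ", ")) else
                "no flags",
              if (x$incomplete_panel) " [incomplete panel]" else ""))
  invisible(x)
}

#' Long-format reporting table
#'
#' Tidies per-well summaries into (compound x timepoint x metric) rows for
#' heat-map style reporting; biological replicates (same compound,
#' concentration, cell line, timepoint, metric) are averaged arithmetically,
#' and the replicate values retained in `values`.
#'
#' @param summaries Per-well summary data.frame (must carry `compound`,
#'   `concentration`, `cell_line`, `timepoint`).
#' @param metrics Metric columns to report.
#' @return Long data.frame: `compound, concentration, cell_line, timepoint,
#'   metric, value, n_replicates, values`.
#' @export
population_heatmap_table <- function(summaries,
                                     metrics = intersect(
                                       c("healthy_nuclei_norm", "hio_ratio",
                                         "frac_nuclei_healthy",
                                         "frac_nuclei_pyknosed",
                                         "frac_nuclei_fragmented",
                                         "frac_tubulin_effect",
                                         "frac_mito_increased",
                                         "frac_membrane_permeable",
                                         "frac_fucci_red",
                                         "frac_fucci_green",
                                         "frac_fucci_yellow"),
                                       names(summaries))) {
  if (!nrow(summaries)) stopf("need at least one summary row")
  rows <- list()
  key <- c("compound", "concentration", "cell_line", "timepoint")
  for (m in metrics) {
    agg <- aggregate(summaries[[m]],
                     by = summaries[key], FUN = function(v) mean(v),
                     drop = TRUE)
    nrep <- aggregate(summaries[[m]], by = summaries[key],
                      FUN = length)$x
    vals <- aggregate(summaries[[m]], by = summaries[key],
                      FUN = function(v) paste(signif(v, 10),
                                              collapse = ";"))$x
    agg$metric <- m
    agg$value <- agg$x
    agg$x <- NULL
    agg$n_replicates <- nrep
    agg$values <- vals
    rows[[m]] <- agg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c(key, "metric", "value", "n_replicates", "values")]
}
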