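# Shared fixtures. Everything is generated in code; trained nodes and
# rendered fields are cached per test run because several files reuse them.

.pg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pg_cache[[key]])) .pg_cache[[key]] <- force(expr)
  .pg_cache[[key]]
}

# small-field parameters used by most unit tests (full-size fields are
# exercised in test-acceptance.R)
small_params <- function(...) render_params(field = c(320L, 320L), ...)

train_params <- function(...) render_params(field = c(640L, 640L), ...)

# a modest NUCLEI3 node shared across gating tests (60/class)
cached_nuclei3 <- function() cached("nuclei3", {
  ts <- make_training_set("NUCLEI3", n_per_class = 60, seed = 421,
                          params = train_params())
  train_node("NUCLEI3", ts, seed = 422)
})

# synthetic separable FUCCI feature rows with ground truth
fucci_feature_rows <- function(n, seed, bg = 20, amp = 1200) {
  withr::with_seed(seed, {
    state <- sample(c("red", "green", "yellow", "unlabeled"), n, TRUE,
                    prob = c(0.35, 0.35, 0.2, 0.1))
    g <- bg * runif(n) + ifelse(state %in% c("green", "yellow"),
                                amp * exp(rnorm(n, 0, 0.2)), 0)
    r <- bg * runif(n) + ifelse(state %in% c("red", "yellow"),
                                amp * exp(rnorm(n, 0, 0.2)), 0)
    data.frame(nuc_mean_488 = g, nuc_mean_561 = r,
               nuc_area = rnorm(n, 250, 20), nuc_mean_dna = rnorm(n, 2000, 100),
               truth = state, stringsAsFactors = FALSE)
  })
}

# random well-summary tables for the flagging engine property test
random_summary_table <- function(n_compounds, seed,
                                 lines = c("U2OS", "HEK293T", "MRC9")) {
  withr::with_seed(seed, {
    grid <- expand.grid(compound = paste0("c", seq_len(n_compounds)),
                        cell_line = lines, concentration = c(1, 10),
                        timepoint = c(12, 24), stringsAsFactors = FALSE)
    n <- nrow(grid)
    nuc <- matrix(stats::runif(3 * n), ncol = 3)
    nuc <- nuc / rowSums(nuc)
    cbind(grid, data.frame(
      low_count_flag = stats::runif(n) < 0.05,
      hio_ratio = stats::runif(n),
      frac_nuclei_healthy = nuc[, 1], frac_nuclei_pyknosed = nuc[, 2],
      frac_nuclei_fragmented = nuc[, 3],
      frac_tubulin_effect = stats::runif(n),
      frac_mito_increased = stats::runif(n),
      frac_membrane_permeable = stats::runif(n)))
  })
}

# independent brute-force evaluator of the flagging rules (kept deliberately
# dumb: nested loops, no shared code with flag_compound)
brute_force_flags <- function(tab, compound,
                              lines = c("U2OS", "HEK293T", "MRC9")) {
  rules <- list(
    hio_gt_50 = function(r) r$hio_ratio > 0.5,
    healthy_nuclei_lt_50 = function(r) r$frac_nuclei_healthy < 0.5,
    pyknosed_gt_50 = function(r) r$frac_nuclei_pyknosed > 0.5,
    fragmented_gt_50 = function(r) r$frac_nuclei_fragmented > 0.5,
    tubulin_gt_50 = function(r) r$frac_tubulin_effect > 0.5,
    mito_gt_50 = function(r) r$frac_mito_increased > 0.5,
    membrane_gt_50 = function(r) r$frac_membrane_permeable > 0.5)
  s <- tab[tab$compound == compound, ]
  flags <- character(0)
  for (rn in names(rules)) {
    fired <- FALSE
    for (cc in unique(s$concentration)) for (tp in unique(s$timepoint)) {
      all_lines <- TRUE
      for (ln in lines) {
        r <- s[s$cell_line == ln & s$concentration == cc &
                 s$timepoint == tp, ]
        ok <- nrow(r) == 1 && !r$low_count_flag && rules[[rn]](r)
        if (!ok) { all_lines <- FALSE; break }
      }
      if (all_lines) { fired <- TRUE; break }
    }
    if (fired) flags <- c(flags, rn)
  }
  sort(flags)
}
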