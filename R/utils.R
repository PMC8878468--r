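#' Assay modes
#'
#' The three supported staining/readout modes: `"highvia_extend"` (five-state
#' viability kinetics), `"multiplex"` (tubulin / mitochondrial mass /
#' membrane permeability phenotyping) and `"fucci"` (cell-cycle reporter).
#'
#' @return Character vector of mode identifiers.
#' @export
pg_modes <- function() c("highvia_extend", "multiplex", "fucci")

#' Channel layout for an assay mode
#'
#' Maps physical acquisition channels to their biological role in each mode.
#' `hoechst` (405 nm) always carries the DNA stain; the 488/561/640 channels
#' are repurposed per mode; `bf` is bright field.
#'
#' @param mode One of [pg_modes()].
#' @return Named character vector: channel id -> role.
#' @export
channel_roles <- function(mode) {
  mode <- match.arg(mode, pg_modes())
  switch(mode,
    highvia_extend = c(hoechst = "dna", ch488 = "annexin",
                       ch561 = "permeability", ch640 = "mito", bf = "bf"),
    multiplex = c(hoechst = "dna", ch488 = "tubulin",
                  ch561 = "mito", ch640 = "annexin", bf = "bf"),
    fucci = c(hoechst = "dna", ch488 = "fucci_green",
              ch561 = "fucci_red", bf = "bf"))
}

# channel carrying the Annexin V signal, NA if mode has none
annexin_channel <- function(mode) {
  roles <- channel_roles(mode)
  ch <- names(roles)[roles == "annexin"]
  if (length(ch)) ch else NA_character_
}

mito_channel <- function(mode) {
  roles <- channel_roles(mode)
  ch <- names(roles)[roles == "mito"]
  if (length(ch)) ch else NA_character_
}

# Gating class vocabularies (fixed orders double as deterministic
# tie-break order for posterior ties).
pg_classes <- list(
  HIO = c("normal", "high_intensity_object"),
  NUCLEI3 = c("healthy", "pyknosed", "fragmented"),
  PYKNOSED2 = c("mitotic", "apoptotic"),
  VIA5 = c("healthy", "early_apoptotic", "late_apoptotic", "necrotic",
           "lysed"),
  TUBULIN = c("no_effect", "tubulin_effect"),
  MITO = c("not_increased", "increased"),
  MEMBRANE = c("normal", "permeable"),
  FUCCI = c("red", "green", "yellow", "unlabeled"))

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483587
  for (k in seq_along(ix)) {
    s <- (s * 48271 + as.double(ix[k]) * 16807 + k) %% 2147483587
  }
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
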