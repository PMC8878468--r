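## Field and plate I/O plus the end-to-end pipeline. Filename convention for
## image stacks (self-defined; archived screens use instrument-specific
## layouts): {well}_{t}h_{channel}_z{k}.tif, one grayscale TIFF per slice.

field_file <- function(well, timepoint, channel, z) {
  sprintf("%s_%gh_%s_z%d.tif", well, timepoint, channel, z)
}

#' Write an image field as per-slice TIFF files
#'
#' @param field An `image_field`.
#' @param dir Output directory (created if needed).
#' @param well,timepoint Identifiers for the filename convention
#'   `{well}_{t}h_{channel}_z{k}.tif`.
#' @return Character vector of written paths, invisibly.
#' @export
write_field <- function(field, dir, well = field$metadata$well,
                        timepoint = field$metadata$timepoint) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bits <- field$pixel_depth %||% 16L
  paths <- character(0)
  for (ch in names(field$channels))
    for (z in seq_along(field$channels[[ch]])) {
      p <- file.path(dir, field_file(well, timepoint, ch, z))
      write_tiff(field$channels[[ch]][[z]], p, bits = bits)
      paths <- c(paths, p)
    }
  invisible(paths)
}

#' Read an image field from per-slice TIFF files
#'
#' Assembles all channels/z-slices matching the filename convention for one
#' well/timepoint. Errors name missing slices (gaps in the z sequence) and
#' shape mismatches.
#'
#' @param dir Directory holding the TIFFs.
#' @param well Well id.
#' @param timepoint Hours.
#' @param mode Assay mode recorded in metadata.
#' @param metadata Extra metadata entries (cell_line etc.).
#' @return An `image_field`.
#' @export
read_field <- function(dir, well, timepoint, mode = "highvia_extend",
                       metadata = list()) {
  pat <- sprintf("^%s_%gh_([A-Za-z0-9]+)_z([0-9]+)\\.tif$", well, timepoint)
  files <- list.files(dir, pattern = pat)
  if (!length(files))
    stopf("no files for %s at %g h under %s", well, timepoint, dir)
  m <- regmatches(files, regexec(pat, files))
  ch <- vapply(m, `[`, "", 2)
  z <- as.integer(vapply(m, `[`, "", 3))
  channels <- list()
  dims <- NULL
  nz_all <- unique(vapply(split(z, ch), max, integer(1)))
  if (length(nz_all) != 1)
    stopf("channels disagree on z-count: %s",
          paste(sprintf("%s=%d", names(split(z, ch)),
                        vapply(split(z, ch), max, integer(1))),
                collapse = ", "))
  nz <- nz_all
  bits <- NA_integer_
  for (c1 in unique(ch)) {
    zs <- sort(z[ch == c1])
    missing_z <- setdiff(seq_len(nz), zs)
    if (length(missing_z))
      stopf("missing z-slice file(s): %s",
            paste(field_file(well, timepoint, c1, missing_z),
                  collapse = ", "))
    stack <- vector("list", nz)
    for (k in seq_len(nz)) {
      img <- read_tiff(file.path(dir, field_file(well, timepoint, c1, k)))
      bits <- attr(img, "bits")
      if (is.null(dims)) dims <- dim(img)
      if (!all(dim(img) == dims))
        stopf("shape mismatch in %s (expected %dx%d)",
              field_file(well, timepoint, c1, k), dims[1], dims[2])
      attr(img, "bits") <- NULL
      stack[[k]] <- img
    }
    channels[[c1]] <- stack
  }
  structure(list(
    channels = channels, pixel_depth = bits,
    metadata = modifyList(list(mode = mode, field = rev(dims), nz = nz,
                               well = well, timepoint = timepoint,
                               cell_line = NA_character_), metadata)),
    class = "image_field")
}

#' Write / read a plate design as a plain-text config file
#'
#' Format: `key: value` header lines (`mode`, `timepoints` comma-separated,
#'  `basal_growth_rate`, `n0`), a `[wells]` marker, then a CSV block with
#' columns `well, compound, concentration, role, cell_line`.
#'
#' @param design A [plate_design()].
#' @param path File path.
#' @return `read_plate_design` returns the design; `write_plate_design` the
#'   path, invisibly.
#' @export
write_plate_design <- function(design, path) {
  stopifnot(inherits(design, "plate_design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# phenogate plate design v1",
    paste0("mode: ", design$mode),
    paste0("timepoints: ", paste(design$timepoints, collapse = ",")),
    paste0("basal_growth_rate: ",
           format(design$basal_growth_rate, digits = 17)),
    paste0("n0: ", design$n0),
    "[wells]"), con)
  write.csv(design$wells, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_design
#' @export
read_plate_design <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "[wells]")
  if (!length(sep)) stopf("%s: missing [wells] section", path)
  hdr <- grep("^[a-z0-9_]+: ", lines[seq_len(sep - 1)], value = TRUE)
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  wells <- read.csv(textConnection(lines[(sep + 1):length(lines)]),
                    stringsAsFactors = FALSE,
                    colClasses = c(well = "character",
                                   compound = "character",
                                   concentration = "numeric",
                                   role = "character",
                                   cell_line = "character"))
  wells$compound[wells$compound %in% c("", "NA")] <- NA_character_
  plate_design(
    wells,
    timepoints = as.numeric(strsplit(vals[keys == "timepoints"], ",")[[1]]),
    mode = vals[keys == "mode"],
    basal_growth_rate = as.numeric(vals[keys == "basal_growth_rate"]),
    n0 = as.integer(vals[keys == "n0"]))
}

#' Write / read compound kinetics specs (JSON)
#'
#' @param kinetics Named list of [kinetics_spec()].
#' @param path File path.
#' @return `read_kinetics` the named list; `write_kinetics` the path,
#'   invisibly.
#' @export
write_kinetics <- function(kinetics, path) {
  writeLines(jsonlite::serializeJSON(kinetics, digits = 17), path)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param mode Assay mode.
#' @param design A [plate_design()] or path to one.
#' @param images_dir Directory of TIFF stacks (see [write_field()]); may be
#'   `NULL` when `fields` supplies in-memory data.
#' @param fields Optional in-memory fields: nested list
#'   `fields[[well]][[as.character(timepoint)]]`.
#' @param model_file Optional serialized [gating_model()]; when absent a
#'   default model is trained on generator data.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param seg_params,thresholds,min_count,cell_lines Stage parameters.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(mode, design, images_dir = NULL, fields = NULL,
                       model_file = NULL, out_dir, seed = 1L,
                       seg_params = segment_params(),
                       thresholds = default_flag_rules(), min_count = 50L,
                       cell_lines = NULL) {
  mode <- match.arg(mode, pg_modes())
  if (is.character(design)) design <- read_plate_design(design)
  stopifnot(inherits(design, "plate_design"))
  if (is.null(images_dir) && is.null(fields))
    stopf("need images_dir or in-memory fields")
  if (!is.null(images_dir) && !dir.exists(images_dir))
    stopf("images_dir does not exist: %s", images_dir)
  if (!is.null(model_file) && !file.exists(model_file))
    stopf("model_file does not exist: %s", model_file)
  structure(list(mode = mode, design = design, images_dir = images_dir,
                 fields = fields, model_file = model_file,
                 out_dir = out_dir, seed = as.integer(seed),
                 seg_params = seg_params, thresholds = thresholds,
                 min_count = min_count, cell_lines = cell_lines),
            class = "run_config")
}

pg_log <- function(stage, fmt, ...) {
  message(sprintf("[phenogate %s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Segments every well/timepoint field, extracts features, computes DMSO
#' reference statistics, applies the gating hierarchy, aggregates per-well
#' summaries with DMSO normalization and growth rates, and writes per-cell
#' and per-well CSVs, certificates JSON, a gate audit log and the resolved
#' configuration. Deterministic given (inputs, config, seed); timestamps are
#' isolated in the log file only.
#'
#' @param config A [run_config()].
#' @return List: `cells`, `summaries`, `certificates`, `audit`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  mode <- config$mode
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  get_field <- function(well, tp) {
    if (!is.null(config$fields))
      return(config$fields[[well]][[as.character(tp)]])
    read_field(config$images_dir, well, tp, mode = mode)
  }
  slots <- expand.grid(well = design$wells$well,
                       timepoint = design$timepoints,
                       stringsAsFactors = FALSE)
  if (!is.null(config$fields)) {
    keep <- mapply(function(w, tp)
      !is.null(config$fields[[w]][[as.character(tp)]]),
      slots$well, slots$timepoint)
    slots <- slots[keep, , drop = FALSE]
  }

  # stage 1: segmentation + features everywhere
  exts <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    f <- tryCatch(get_field(slots$well[i], slots$timepoint[i]),
                  error = function(e)
                    stopf("stage segmentation, well %s: %s", slots$well[i],
                          conditionMessage(e)))
    f$metadata$mode <- mode
    exts[[i]] <- extract_features(f, config$seg_params)
    exts[[i]]$field <- f
  }
  pg_log("segment", "%d well/timepoint fields, %s cells total",
         nrow(slots), sum(vapply(exts, function(e) nrow(e$features), 0)))

  # stage 2: DMSO references for rule fallbacks
  dmso_wells <- design$wells$well[design$wells$role == "dmso_control"]
  dmso_idx <- which(slots$well %in% dmso_wells)
  if (!length(dmso_idx)) stopf("stage references: no DMSO wells imaged")
  dmso_feat <- do.call(rbind, lapply(dmso_idx,
                                     function(i) exts[[i]]$features))
  refs <- list(
    ref_intensity = median(dmso_feat$nuc_mean_dna, na.rm = TRUE))
  if (!is.na(annexin_channel(mode)))
    refs$annexin_threshold <- quantile(dmso_feat$ring_mean_annexin, 0.95,
                                       na.rm = TRUE)
  if (mode == "multiplex")
    refs$dmso_ref <- list(
      tubulin_sd = quantile(dmso_feat$cyto_sd_488, 0.95, na.rm = TRUE),
      mito_mean = quantile(dmso_feat[[paste0("cyto_mean_",
        sub("ch", "", mito_channel(mode)))]], 0.95, na.rm = TRUE),
      membrane_mean = quantile(dmso_feat$cyto_mean_488, 0.95,
                               na.rm = TRUE))
  if (mode == "fucci")
    refs$fucci_thresholds <- fucci_thresholds_from_field(
      exts[[dmso_idx[1]]]$field, exts[[dmso_idx[1]]]$nuclei)

  # stage 3: gating model
  model <- if (!is.null(config$model_file))
    load_gating_model(config$model_file) else {
      pg_log("train", "no model file; training default model (seed %d)",
             config$seed)
      train_default_model(mode, seed = config$seed)
    }
  if (model$mode != mode) stopf("model mode %s != run mode %s", model$mode,
                                mode)

  # stage 4: gate everything
  cells <- list()
  audits <- list()
  summaries <- list()
  for (i in seq_len(nrow(slots))) {
    g <- tryCatch(apply_gating(model, exts[[i]]$features, refs),
                  error = function(e)
                    stopf("stage gating, well %s: %s", slots$well[i],
                          conditionMessage(e)))
    rec <- g$records
    if (nrow(rec)) {
      rec <- cbind(well = slots$well[i], timepoint = slots$timepoint[i],
                   rec)
      cells[[i]] <- rec
    }
    a <- g$audit
    a$well <- slots$well[i]
    a$timepoint <- slots$timepoint[i]
    audits[[i]] <- a
    summaries[[i]] <- well_fractions(g$records, config$min_count,
                                     well = slots$well[i],
                                     timepoint = slots$timepoint[i])
  }
  cells <- do.call(rbind, cells)
  audit <- do.call(rbind, audits)
  summ <- do.call(rbind, summaries)
  summ <- merge(summ, design$wells, by = "well", sort = FALSE)
  summ <- normalize_to_dmso(summ, design)

  # growth rate vs t=0 and same-timepoint DMSO mean
  summ$growth_rate <- NA_real_
  if (0 %in% summ$timepoint) {
    for (i in seq_len(nrow(summ))) {
      tp <- summ$timepoint[i]
      if (tp == 0) next
      x0 <- summ$n_healthy_nuclei[summ$well == summ$well[i] &
                                    summ$timepoint == 0]
      ctrl <- mean(summ$n_healthy_nuclei[summ$role == "dmso_control" &
                                           summ$timepoint == tp])
      if (length(x0) == 1 && x0 > 0 && summ$n_healthy_nuclei[i] > 0 &&
          ctrl > x0)
        summ$growth_rate[i] <- growth_rate(summ$n_healthy_nuclei[i], x0,
                                           ctrl)
    }
  }

  # certificates per compound
  cmp <- unique(summ$compound[summ$role %in% c("treatment",
                                               "reference_compound")])
  certs <- lapply(cmp, function(cc)
    flag_compound(summ, cc, rules = config$thresholds,
                  cell_lines = config$cell_lines))
  names(certs) <- cmp

  paths <- list(
    cells = file.path(config$out_dir, "cells.csv"),
    summaries = file.path(config$out_dir, "well_summaries.csv"),
    certificates = file.path(config$out_dir, "certificates.json"),
    audit = file.path(config$out_dir, "gate_audit.csv"),
    config = file.path(config$out_dir, "resolved_config.json"))
  write.csv(cells, paths$cells, row.names = FALSE)
  write.csv(summ, paths$summaries, row.names = FALSE)
  write.csv(audit, paths$audit, row.names = FALSE)
  writeLines(jsonlite::toJSON(lapply(certs, unclass), auto_unbox = TRUE,
                              digits = NA, na = "null", pretty = TRUE),
             paths$certificates)
  cfg_out <- config[c("mode", "seed", "min_count")]
  cfg_out$design_wells <- nrow(design$wells)
  cfg_out$timepoints <- design$timepoints
  cfg_out$seg_params <- config$seg_params
  cfg_out$thresholds <- config$thresholds
  writeLines(jsonlite::toJSON(cfg_out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$config)
  pg_log("done", "%d cells, %d summaries, %d certificates",
         if (is.null(cells)) 0L else nrow(cells), nrow(summ), length(certs))
  list(cells = cells, summaries = summ, certificates = certs,
       audit = audit, paths = paths)
}
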