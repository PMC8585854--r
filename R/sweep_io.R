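# Plain-text storage for sweep archives and cohort tables.
#
# No standard interchange format exists for PERG sweep data (vendor
# formats are proprietary), so blocks are stored as TSV voltage matrices
# (rows = sweeps, columns = samples, uV) with a JSON sidecar per block
# carrying all metadata. Times are implicit: sample index over sampling
# rate, first sample at t = 0.

#' Construct and validate a sweep block
#'
#' @param subject_id,group,eye metadata labels.
#' @param condition a [stimulus_condition()].
#' @param sampling_rate_hz,sweep_length_s sampling metadata; the matrix
#'   must have exactly `round(sampling_rate_hz * sweep_length_s)` columns.
#' @param sweeps numeric matrix, one row per sweep, uV.
#' @return A list of class `"perg_sweep_block"`.
#' @export
new_sweep_block <- function(subject_id, group, eye, condition,
                            sampling_rate_hz, sweep_length_s, sweeps) {
  stopifnot(inherits(condition, "perg_condition"), is.matrix(sweeps))
  n_expect <- round(sampling_rate_hz * sweep_length_s)
  if (ncol(sweeps) != n_expect) {
    stop(sprintf("sweep matrix has %d columns but metadata implies %d samples",
                 ncol(sweeps), n_expect))
  }
  if (!all(is.finite(sweeps))) stop("sweep matrix contains non-finite voltages")
  structure(list(subject_id = subject_id, group = group, eye = eye,
                 condition = condition,
                 sampling_rate_hz = sampling_rate_hz,
                 sweep_length_s = sweep_length_s, sweeps = sweeps),
            class = "perg_sweep_block")
}

.block_key <- function(b) {
  paste(b$subject_id, b$eye, b$condition$check_size_deg,
        b$condition$reversal_rate_rps, sep = "/")
}

#' Construct a sweep archive
#'
#' A validated collection of sweep blocks with unique
#' (subject, eye, condition) keys, plus free-form provenance metadata
#' (stimulus luminance, contrast, field size, software tag, ...).
#'
#' @param blocks list of [new_sweep_block()] objects.
#' @param provenance named list of free-form metadata.
#' @return A list of class `"perg_sweep_archive"`.
#' @export
sweep_archive <- function(blocks, provenance = list()) {
  stopifnot(is.list(blocks),
            all(vapply(blocks, inherits, TRUE, "perg_sweep_block")))
  keys <- vapply(blocks, .block_key, "")
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, eye, condition) blocks: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  structure(list(blocks = blocks, provenance = provenance),
            class = "perg_sweep_archive")
}

.block_paths <- function(root, b) {
  dir <- file.path(root, b$subject_id, b$eye)
  stem <- sprintf("%s_%s", format(b$condition$check_size_deg),
                  format(b$condition$reversal_rate_rps))
  list(dir = dir, tsv = file.path(dir, paste0(stem, ".tsv")),
       json = file.path(dir, paste0(stem, ".json")))
}

#' Write a sweep archive to disk
#'
#' Layout: `<root>/<subject>/<eye>/<checksize>_<rate>.tsv` (voltage
#' matrix, 10 significant digits) plus a `.json` sidecar per block, and
#' `provenance.json` at the root. Round-trips through [read_archive()]
#' to within 1e-9 uV.
#'
#' @param archive a [sweep_archive()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "perg_sweep_archive"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create archive directory: ", path)
  jsonlite::write_json(archive$provenance,
                       file.path(path, "provenance.json"), auto_unbox = TRUE)
  for (b in archive$blocks) {
    p <- .block_paths(path, b)
    dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
    lines <- apply(b$sweeps, 1, function(r)
      paste(sprintf("%.10e", r), collapse = "\t"))
    writeLines(lines, p$tsv)
    meta <- list(subject_id = b$subject_id, group = b$group, eye = b$eye,
                 check_size_deg = b$condition$check_size_deg,
                 reversal_rate_rps = b$condition$reversal_rate_rps,
                 sampling_rate_hz = b$sampling_rate_hz,
                 sweep_length_s = b$sweep_length_s,
                 n_sweeps = nrow(b$sweeps), n_samples = ncol(b$sweeps))
    jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a sweep archive from disk
#'
#' Reads the layout produced by [write_archive()], validating every
#' block: the TSV sample count must match the sidecar and the implied
#' `sampling_rate_hz * sweep_length_s`, voltages must be finite, and
#' (subject, eye, condition) keys must be unique.
#'
#' @param path archive directory.
#' @return A `perg_sweep_archive`.
#' @export
read_archive <- function(path) {
  if (!dir.exists(path)) stop("no such archive directory: ", path)
  tsvs <- list.files(path, pattern = "\\.tsv$", recursive = TRUE,
                     full.names = TRUE)
  if (!length(tsvs)) stop("archive contains no sweep blocks: ", path)
  blocks <- lapply(tsvs, function(tsv) {
    sidecar <- sub("\\.tsv$", ".json", tsv)
    if (!file.exists(sidecar)) stop("missing sidecar for block: ", tsv)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mat <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
    dimnames(mat) <- NULL
    if (ncol(mat) != meta$n_samples || nrow(mat) != meta$n_sweeps) {
      stop(sprintf("block %s: sidecar says %d x %d, TSV is %d x %d",
                   tsv, meta$n_sweeps, meta$n_samples, nrow(mat), ncol(mat)))
    }
    if (!all(is.finite(mat))) stop("block ", tsv, ": non-finite voltages")
    cond <- stimulus_condition(meta$check_size_deg, meta$reversal_rate_rps,
                               meta$sweep_length_s)
    new_sweep_block(meta$subject_id, meta$group, meta$eye, cond,
                    meta$sampling_rate_hz, meta$sweep_length_s, mat)
  })
  prov_file <- file.path(path, "provenance.json")
  prov <- if (file.exists(prov_file))
    jsonlite::read_json(prov_file, simplifyVector = TRUE) else list()
  sweep_archive(blocks, prov)
}

.cohort_columns <- c("subject", "group", "eye", "check_size_deg",
                     "reversal_rate_rps", "amplitude_uV", "noise_uV",
                     "snr", "response_time_ms")
.cohort_required <- setdiff(.cohort_columns, c("noise_uV", "snr"))

#' Write / read a cohort table as CSV
#'
#' One row per subject x eye x condition. Fixed leading column order:
#' subject, group, eye, check_size_deg, reversal_rate_rps, amplitude_uV,
#' noise_uV, snr, response_time_ms; extra columns are preserved after
#' these. `noise_uV` and `snr` are written as NA when the table does not
#' carry them (e.g. ground-truth tables). Reading requires all columns
#' except `noise_uV`/`snr` and tolerates unknown extras.
#'
#' @param records cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: the
#'   validated data frame.
#' @export
write_cohort_csv <- function(records, path) {
  miss <- setdiff(.cohort_required, names(records))
  if (length(miss)) {
    stop("cohort table is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  for (col in c("noise_uV", "snr")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  extra <- setdiff(names(records), .cohort_columns)
  records <- records[, c(.cohort_columns, extra)]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such cohort CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_required, names(df))
  if (length(miss)) {
    stop("cohort CSV lacks required columns: ", paste(miss, collapse = ", "))
  }
  df
}
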