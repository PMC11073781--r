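#' Read and write abdominal records and peak annotations
#'
#' Records are plain CSV with a `time_s` column followed by `ch01..chNN`
#' channel columns (microvolts). Annotations are plain text, one 1-based fetal
#' R-peak sample index per line.
#'
#' @param record an abdominal record tibble.
#' @param path file path.
#' @return `read_record_csv()` returns a record tibble with an `fs` attribute
#'   inferred from the time column; `read_peak_annotations()` an integer
#'   vector; writers return their input invisibly.
#' @name record_io
NULL

#' @rdname record_io
#' @export
write_record_csv <- function(record, path) {
  readr::write_csv(as_tibble(record), path)
  invisible(record)
}

#' @rdname record_io
#' @export
read_record_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  fs <- 1 / median(diff(rec$time_s))
  attr(rec, "fs") <- round(fs, 6)
  class(rec) <- c("abdominal_record", class(rec))
  rec
}

#' @rdname record_io
#' @param peaks integer vector of 1-based peak sample indices.
#' @export
write_peak_annotations <- function(peaks, path) {
  writeLines(as.character(as.integer(peaks)), path)
  invisible(peaks)
}

#' @rdname record_io
#' @export
read_peak_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "fetalpeaks_io_error")
  }
  as.integer(readLines(path))
}

#' Write a simulated cohort to disk
#'
#' One record CSV and one fetal-peak annotation file per subject, plus a JSON
#' manifest carrying the generating configuration, the seed and per-file MD5
#' checksums.
#'
#' @param cohort a tibble from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param cfg,seed the configuration and seed the cohort was generated with
#'   (recorded in the manifest).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, cfg = sim_config(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::pmap(cohort, function(subject, record, truth, ...) {
    rec_path <- file.path(dir, paste0(subject, ".csv"))
    ann_path <- file.path(dir, paste0(subject, "_fetal_peaks.txt"))
    write_record_csv(record, rec_path)
    write_peak_annotations(truth$fetal_peaks, ann_path)
    list(subject = subject, record = basename(rec_path), annotations = basename(ann_path))
  })
  cfg_out <- cfg
  cfg_out$seed <- NULL
  manifest <- list(
    n_subjects = nrow(cohort), seed = seed,
    config = unclass(cfg_out),
    files = files,
    md5 = as.list(tools::md5sum(list.files(dir, pattern = "\\.(csv|txt)$", full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
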