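#' Root-mean-square of a numeric vector
#'
#' @param x numeric vector.
#' @return scalar RMS value.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Internal: stop unless a scalar condition holds, with a classed error.
assert_that <- function(ok, msg, class = "fetalpeaks_config_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Round half to even at `digits` decimal places (IEC 60559 behaviour of
# base::round, wrapped for explicitness where printed-table reproduction
# depends on the rounding mode).
round_half_even <- function(x, digits = 0) round(x, digits)

# Channel column names for an n-channel record tibble: ch01, ch02, ...
channel_names <- function(n_channels) sprintf("ch%02d", seq_len(n_channels))

# Extract the samples-by-channels numeric matrix from a record tibble.
record_matrix <- function(record) {
  chans <- grep("^ch[0-9]+$", names(record), value = TRUE)
  assert_that(length(chans) > 0, "record has no channel columns (ch01, ch02, ...)")
  as.matrix(record[chans])
}

#' Construct an abdominal record from a samples-by-channels matrix
#'
#' @param mat numeric matrix, one row per sample, one column per lead
#'   (microvolts).
#' @param fs sampling rate in Hz.
#' @param subject optional subject id.
#' @return a record tibble (`time_s`, `ch01..chNN`) with an `fs` attribute.
#' @export
abdominal_record <- function(mat, fs, subject = NA_character_) {
  assert_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  assert_that(is_scalar_number(fs) && fs > 0, "fs must be > 0")
  record_from_matrix(mat, fs, subject)
}

# Rebuild a record tibble from a matrix, preserving fs/subject attributes.
record_from_matrix <- function(mat, fs, subject = NA_character_) {
  colnames(mat) <- channel_names(ncol(mat))
  rec <- as_tibble(mat)
  rec <- tibble(time_s = (seq_len(nrow(mat)) - 1) / fs) |> dplyr::bind_cols(rec)
  attr(rec, "fs") <- fs
  attr(rec, "subject") <- subject
  class(rec) <- c("abdominal_record", class(rec))
  rec
}

#' Sampling rate of a record
#' @param record an abdominal record tibble.
#' @return sampling rate in Hz.
#' @export
record_fs <- function(record) {
  fs <- attr(record, "fs", exact = TRUE)
  if (is.null(fs)) {
    # fall back to the time column spacing
    assert_that("time_s" %in% names(record), "record carries neither an fs attribute nor a time_s column")
    fs <- 1 / median(diff(record$time_s))
  }
  fs
}
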