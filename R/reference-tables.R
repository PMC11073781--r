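#' Reference validation summaries from a 26-subject abdominal-ECG study
#'
#' Two small tables bundled for validating the package's summary arithmetic
#' against published per-subject and per-fold results of a noninvasive fetal
#' R-peak detection study on clinical (confidential, not redistributable)
#' abdominal recordings:
#'
#' * `reference_cohort()` — demographics and the leave-one-subject-out
#'   detection accuracy of each of 26 monitored pregnancies: maternal health
#'   status (`Normal`, `Exists` = has a condition, `None` = not reported),
#'   gestational age (weeks), estimated fetal weight (g), maternal age
#'   (years), BMI (kg/m^2) and accuracy (%).
#' * `reference_folds()` — accuracy (%) and F1 of each fold of a 5-fold
#'   subject-dependent cross-validation.
#'
#' Only the printed tables are bundled; the underlying signals are not
#' available.
#'
#' @return a tibble.
#' @export
#' @examples
#' mean(reference_cohort()$accuracy_pct)
reference_cohort <- function() {
  readr::read_csv(system.file("extdata", "loso_cohort_reference.csv",
                              package = "fetalpeaks"),
                  show_col_types = FALSE)
}

#' @rdname reference_cohort
#' @export
reference_folds <- function() {
  readr::read_csv(system.file("extdata", "kfold_reference.csv",
                              package = "fetalpeaks"),
                  show_col_types = FALSE)
}
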