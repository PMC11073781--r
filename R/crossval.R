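#' k-fold cross-validation over labeled frames
#'
#' Folds are built from subject-contiguous blocks: each subject's frames are
#' cut into `k` contiguous chunks which are assigned to folds by a seeded
#' permutation, so every fold sees material from every subject while frames
#' within a chunk stay contiguous. `pipeline` is called once per fold with the
#' training and test `frame_set`s and must return a 0/1 prediction vector for
#' the test frames.
#'
#' @param frames a labeled `frame_set`.
#' @param k number of folds (>= 2, <= number of frames).
#' @param pipeline `function(train_frames, test_frames) -> predicted labels`.
#' @param seed integer seed fixing the fold assignment.
#' @return a list: `folds` (per-fold [confusion_metrics()] rows with a `fold`
#'   column), `summary` (column means of the derived metrics), `assignment`
#'   (fold id per frame).
#' @export
kfold_cv <- function(frames, k = 5, pipeline, seed = 1) {
  n <- dim(frames$x)[1]
  assert_that(k >= 2 && k <= n, "k must lie in [2, number of frames]")
  set.seed(seed)
  subj <- frames$info$subject
  subj[is.na(subj)] <- "all"
  assignment <- integer(n)
  for (s in unique(subj)) {
    idx <- which(subj == s)
    chunk <- ceiling(seq_along(idx) / (length(idx) / k))
    chunk <- pmin(chunk, k)
    perm <- sample.int(k)
    assignment[idx] <- perm[chunk]
  }
  fold_rows <- purrr::map(seq_len(k), function(f) {
    test_idx <- which(assignment == f)
    train_idx <- which(assignment != f)
    pred <- pipeline(subset_frames(frames, train_idx), subset_frames(frames, test_idx))
    confusion_metrics(frames$info$label[test_idx], pred) |>
      mutate(fold = f, .before = 1)
  })
  folds <- bind_rows(fold_rows)
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")
  list(folds = folds,
       summary = folds |> summarise(across(all_of(metrics), mean)),
       assignment = assignment)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, `pipeline` trains on every other subject's frames and
#' predicts the held-out subject's frames; no information from the test
#' subject enters training.
#'
#' @param frames a labeled `frame_set` whose `info$subject` marks subjects
#'   (>= 2 distinct).
#' @param pipeline `function(train_frames, test_frames) -> predicted labels`.
#' @param seed integer seed passed to `set.seed` before the first run (for
#'   stochastic pipelines).
#' @return a list: `subjects` (per-subject [confusion_metrics()] rows),
#'   `mean_accuracy`, `sd_accuracy` (sample SD).
#' @export
loso_cv <- function(frames, pipeline, seed = 1) {
  subj <- frames$info$subject
  ids <- unique(subj)
  assert_that(length(ids) >= 2, "leave-one-subject-out needs at least 2 subjects")
  set.seed(seed)
  rows <- purrr::map(ids, function(s) {
    test_idx <- which(subj == s)
    train_idx <- which(subj != s)
    pred <- pipeline(subset_frames(frames, train_idx), subset_frames(frames, test_idx))
    confusion_metrics(frames$info$label[test_idx], pred) |>
      mutate(subject = s, .before = 1)
  })
  subjects <- bind_rows(rows)
  list(subjects = subjects,
       mean_accuracy = mean(subjects$accuracy),
       sd_accuracy = sd(subjects$accuracy))
}

#' Stratified cohort summaries
#'
#' Arithmetic mean (and sample SD) of a value column over rows matching each
#' stratum predicate. Empty strata are flagged and excluded. Rounding for
#' printed-table reproduction is half-even at the requested precision.
#'
#' @param table a cohort tibble.
#' @param strata named list of one-sided formulas over the table's columns,
#'   e.g. `list(preterm = ~ ga_weeks < 30)`.
#' @param value the value column (bare name or string).
#' @param digits decimal places for `mean_rounded` (half-even).
#' @return a tibble: `stratum`, `n`, `mean`, `sd`, `mean_rounded`.
#' @export
#' @examples
#' tbl <- tibble::tibble(ga_weeks = c(25, 31, 36), accuracy_pct = c(88, 86, 93))
#' stratified_summary(tbl, list(late = ~ ga_weeks > 30), accuracy_pct)
stratified_summary <- function(table, strata, value, digits = 1) {
  value_col <- rlang::as_name(rlang::enquo(value))
  assert_that(value_col %in% names(table), paste0("no column named ", value_col))
  rows <- purrr::imap(strata, function(f, nm) {
    keep <- rlang::eval_tidy(rlang::f_rhs(f), data = table)
    assert_that(is.logical(keep) && length(keep) == nrow(table),
                paste0("stratum predicate '", nm, "' is not a row predicate"))
    keep <- keep & !is.na(keep)
    v <- table[[value_col]][keep]
    if (length(v) == 0) {
      warn(paste0("stratum '", nm, "' matched no rows; excluded"))
      return(NULL)
    }
    tibble(stratum = nm, n = length(v), mean = mean(v),
           sd = if (length(v) > 1) sd(v) else NA_real_,
           mean_rounded = round_half_even(mean(v), digits))
  })
  bind_rows(purrr::compact(rows))
}
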