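#' Frame-level confusion counts and derived metrics
#'
#' Class 1 is the positive class (frame contains a fetal R-peak). When a
#' derived ratio is undefined (empty denominator) it is reported as 0 and
#' flagged.
#'
#' @param truth,pred equal-length binary (0/1) vectors.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1`, `degenerate` (TRUE when
#'   any ratio had an empty denominator).
#' @export
confusion_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("truth and prediction vectors differ in length",
          class = "fetalpeaks_shape_error")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp)
  npv <- safe(tn, tn + fn)
  f1 <- safe(2 * tp, 2 * tp + fp + fn)
  degenerate <- anyNA(c(sens, spec, ppv, npv, f1))
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = (tp + tn) / length(truth),
         sensitivity = ifelse(is.na(sens), 0, sens),
         specificity = ifelse(is.na(spec), 0, spec),
         ppv = ifelse(is.na(ppv), 0, ppv),
         npv = ifelse(is.na(npv), 0, npv),
         f1 = ifelse(is.na(f1), 0, f1),
         degenerate = degenerate)
}

#' ROC curve and area under it
#'
#' Operating points over all posterior thresholds with trapezoidal AUC. The
#' orientation is fixed (higher posterior means Class 1), so anti-separating
#' posteriors genuinely score below 0.5.
#'
#' @param truth binary labels with both classes present.
#' @param posterior Class-1 posterior probabilities.
#' @return a list: `auc` (scalar) and `curve` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(truth, posterior) {
  if (length(unique(truth)) < 2) {
    abort("AUC is undefined when the truth holds a single class",
          class = "fetalpeaks_degenerate_class_error")
  }
  r <- pROC::roc(response = factor(truth, levels = c(0, 1)),
                 predictor = posterior, direction = "<", quiet = TRUE)
  curve <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
    arrange(.data$fpr, .data$tpr)
  list(auc = as.numeric(r$auc), curve = curve)
}

#' Plot a ROC curve with the chance diagonal
#'
#' @param roc a list from [roc_auc()].
#' @return a ggplot.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", roc$auc))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, `n >= 3`, each with nonzero variance.
#' @return a one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3, "need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a zero-variance input",
          class = "fetalpeaks_degenerate_variance_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement summary
#'
#' Differences `d = a - b`; bias is `mean(d)` and the limits of agreement are
#' `bias +/- 1.96 * sd(d)` (sample SD).
#'
#' @param a,b equal-length paired measurements, `n >= 2`.
#' @return a `bland_altman` tibble: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    abort("paired measurements differ in length", class = "fetalpeaks_shape_error")
  }
  if (length(a) < 2) {
    abort("at least 2 pairs are needed", class = "fetalpeaks_insufficient_data_error")
  }
  d <- a - b
  bias <- mean(d); s <- sd(d)
  out <- tibble(bias = bias, sd_diff = s,
                loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                n = length(d))
  attr(out, "means") <- (a + b) / 2
  attr(out, "diffs") <- d
  class(out) <- c("bland_altman", class(out))
  out
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = attr(object, "means"), diff = attr(object, "diffs"))
  ggplot2::ggplot(df, ggplot2::aes(mean, diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high)) +
    ggplot2::labs(x = "mean of pair", y = "difference",
                  title = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high))
}

#' Beat-level peak matching (secondary metric)
#'
#' Greedy one-to-one matching of detected peaks to reference peaks within a
#' temporal tolerance; a convenience for validating heart-rate estimates, not
#' the primary frame-level metric.
#'
#' @param detected,truth 1-based sample indices.
#' @param fs sampling rate in Hz.
#' @param tol_ms match tolerance in milliseconds.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `f1`.
#' @export
match_peaks <- function(detected, truth, fs, tol_ms = 50) {
  tol <- tol_ms / 1000 * fs
  used <- logical(length(truth))
  tp <- 0L
  for (p in detected) {
    cand <- which(!used & abs(truth - p) <= tol)
    if (length(cand) > 0) {
      used[cand[which.min(abs(truth[cand] - p))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  tibble(tp = tp, fp = fp, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
         ppv = if (tp + fp > 0) tp / (tp + fp) else 0,
         f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}
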