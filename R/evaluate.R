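#' Score predictions against ground truth
#'
#' Builds the 3 x 3 confusion matrix (rows = true, columns = predicted)
#' and derives per-class and overall accuracy in percent, the way droplet
#' classification results are reported: accuracy of class k is
#' `100 * confusion[k, k] / n_k`.
#'
#' @param preds Predicted labels: an integer vector, or a data.frame with
#'   a `label` column (and optionally `file` for alignment).
#' @param truth True labels: an integer vector, or a data.frame with
#'   `label` and optionally `file`.
#' @return An object of class `"evaluation_report"`: list with
#'   `confusion`, `per_class_accuracy`, `overall_accuracy`, `n_per_class`.
#' @export
#' @examples
#' score_predictions(c(0, 1, 2, 2), c(0, 1, 1, 2))
score_predictions <- function(preds, truth) {
  al <- align_labels(preds, truth)
  p <- al$pred; t <- al$truth
  stopifnot(length(p) == length(t), length(p) > 0)
  classes <- 0:2
  confusion <- matrix(0L, 3, 3,
                      dimnames = list(true = classes, predicted = classes))
  for (k in seq_along(p))
    confusion[t[k] + 1L, p[k] + 1L] <- confusion[t[k] + 1L, p[k] + 1L] + 1L
  n_per_class <- rowSums(confusion)
  per_class <- ifelse(n_per_class > 0,
                      100 * diag(confusion) / n_per_class, NA_real_)
  structure(list(confusion = confusion,
                 per_class_accuracy = unname(per_class),
                 overall_accuracy = 100 * sum(diag(confusion)) / length(p),
                 n_per_class = unname(n_per_class)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  overall accuracy: %.1f%% (n = %d)\n",
              x$overall_accuracy, sum(x$n_per_class)))
  cls <- c("Empty/0", "Single/1", "Multiple/2")
  for (k in 1:3)
    cat(sprintf("  %-10s %6.1f%%  (n = %d)\n", cls[k],
                x$per_class_accuracy[k], x$n_per_class[k]))
  cat("  confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

# align predictions and truth, by file when both carry file columns
align_labels <- function(preds, truth) {
  pl <- if (is.data.frame(preds)) preds$label else preds
  tl <- if (is.data.frame(truth)) truth$label else truth
  if (is.data.frame(preds) && is.data.frame(truth) &&
      !is.null(preds$file) && !is.null(truth$file)) {
    extra_p <- setdiff(preds$file, truth$file)
    extra_t <- setdiff(truth$file, preds$file)
    if (length(extra_p) || length(extra_t))
      stop("score_predictions(): file sets differ; only in predictions: [",
           paste(utils::head(extra_p, 5), collapse = ", "),
           "]; only in truth: [",
           paste(utils::head(extra_t, 5), collapse = ", "), "]")
    tl <- tl[match(preds$file, truth$file)]
  } else if (length(pl) != length(tl)) {
    stop("score_predictions(): ", length(pl), " predictions vs ",
         length(tl), " truth labels")
  }
  list(pred = as.integer(pl), truth = as.integer(tl))
}

#' Accuracy under confidence-threshold retention
#'
#' For each threshold, keeps the predictions whose confidence reaches it
#' and reports the retained fraction and the accuracy on the retained
#' subset. Retention is non-increasing across ascending thresholds
#' (retained sets are superlevel sets of the confidence). An empty
#' retained subset has undefined accuracy, reported as `NA` -- never
#' imputed as 0.
#'
#' @param preds Data.frame with `label` and `confidence` columns.
#' @param truth Integer vector of true labels (or data.frame with
#'   `label`).
#' @param thresholds Ascending numeric thresholds in `[0, 100]`.
#' @return Data.frame `threshold, retained_fraction, accuracy` (accuracy
#'   in percent).
#' @export
retention_accuracy <- function(preds, truth, thresholds = c(0, 75, 90)) {
  stopifnot(is.data.frame(preds), all(c("label", "confidence") %in%
                                        names(preds)))
  stopifnot(!is.unsorted(thresholds))
  tl <- if (is.data.frame(truth)) truth$label else truth
  tl <- as.integer(tl)
  stopifnot(length(tl) == nrow(preds))
  out <- lapply(thresholds, function(th) {
    keep <- preds$confidence >= th
    acc <- if (any(keep)) 100 * mean(preds$label[keep] == tl[keep])
           else NA_real_
    data.frame(threshold = th, retained_fraction = mean(keep),
               accuracy = acc)
  })
  do.call(rbind, out)
}

#' Welch's unequal-variances t-test
#'
#' Compares two sets of accuracy scores (e.g. replicate models trained on
#' raw vs preprocessed images) with the Welch statistic
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)`, the
#' Welch-Satterthwaite degrees of freedom, and a two-sided p-value from
#' the t distribution. Two identical constant samples give `t = 0`,
#' `p = 1`.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(11, 12, 13))
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Paired t-test on index-paired scores
#'
#' Paired companion of [welch_t_test()] for repeated measurements of the
#' same experiments (pairing is by index).
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
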