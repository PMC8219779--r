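#' ROC points over pooled box scores
#'
#' A prediction is positive when its score strictly exceeds the threshold.
#' One point is produced per distinct score, plus `-Inf` and `+Inf`
#' sentinels (everything positive / everything negative). Sensitivity is
#' non-increasing and specificity non-decreasing in the threshold.
#'
#' @param scores numeric vector of box scores.
#' @param labels binary vector (0/1) of the same length.
#' @return data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_points <- function(scores, labels) {
  check_scored_boxes(scores, labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & labels == 0) / n_neg,
                 numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

check_scored_boxes <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  if (!any(labels == 1) || !any(labels == 0))
    stop("ROC analysis needs both classes present in the labels")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Trapezoidal area, computed as the Mann-Whitney concordance statistic:
#' the probability that a random positive box outscores a random negative
#' one, with ties counting one half.
#'
#' @inheritParams roc_points
#' @return scalar in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  check_scored_boxes(scores, labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-index cutoff
#'
#' Returns the threshold maximizing J = sensitivity + specificity - 1 over
#' the distinct observed scores, with ties broken toward the smallest
#' (most sensitive) cutoff. Predictions at the cutoff use the strict rule
#' score > cutoff.
#'
#' @inheritParams roc_points
#' @return scalar cutoff. If the maximal J is 0 the cutoff is degenerate
#'   (scores carry no signal at any threshold); attribute `"J"` holds the
#'   attained index either way.
#' @export
youden_cutoff <- function(scores, labels) {
  check_scored_boxes(scores, labels)
  cand <- sort(unique(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  J <- vapply(cand, function(t)
    sum(scores > t & labels == 1) / n_pos +
      sum(scores <= t & labels == 0) / n_neg - 1, numeric(1))
  best <- which(J >= max(J) - 0)[1]  # smallest qualifying cutoff
  structure(cand[best], J = J[best])
}

#' Confusion-matrix metrics at a cutoff
#'
#' Tabulates predictions (positive iff score > cutoff) against labels and
#' reports sensitivity, specificity, PPV, NPV and accuracy as percentages.
#' A ratio with a zero denominator is reported as `NaN` with a warning,
#' never silently as zero.
#'
#' @inheritParams roc_points
#' @param cutoff finite threshold.
#' @return named list: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percentages).
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  if (!is.finite(cutoff)) stop("'cutoff' must be finite")
  pred <- scores > cutoff
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    100 * num / den
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       ppv = ratio(tp, tp + fp, "PPV"),
       npv = ratio(tn, tn + fn, "NPV"),
       accuracy = ratio(tp + tn, tp + fp + tn + fn, "accuracy"))
}

#' Evaluate a localization model on a test set
#'
#' Pools all (image, box) score/target pairs of the evaluation set into one
#' ROC population (200 images give 9800 pairs), computes the AUC, selects
#' the Youden cutoff on the evaluated set, and tabulates the
#' confusion-matrix metrics at that cutoff — one report row in the shape
#' `AUC, Cut-off, Sensitivity%, Specificity%, PPV%, NPV%, Accuracy%`.
#'
#' @param object a `kmc_fit` or `kmc_network`.
#' @param data a `labeled_dataset`, or a [prep_dataset()] list with `x`
#'   and `y`.
#' @param model_id identifier for the report row; defaults to a name
#'   derived from the network architecture.
#' @return one-row data frame of class `eval_report` with columns `model`,
#'   `auc`, `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (percentages at full precision; the print method rounds).
#'   A degenerate cutoff (maximal Youden index 0) is flagged with a warning
#'   and recorded in attribute `"degenerate"`.
#' @export
evaluate_model <- function(object, data, model_id = NULL) {
  net <- if (inherits(object, "kmc_fit")) object$network else object
  stopifnot(inherits(net, "kmc_network"))
  pp <- if (inherits(data, "labeled_dataset"))
    prep_dataset(data, net$resolution) else data
  scores <- as.vector(forward_net(net, pp$x))
  labels <- as.vector(pp$y)
  auc <- auc_score(scores, labels)
  cutoff <- youden_cutoff(scores, labels)
  degenerate <- attr(cutoff, "J") <= 0
  if (degenerate)
    warning("degenerate cutoff: maximal Youden index is 0", call. = FALSE)
  m <- confusion_metrics(scores, labels, as.numeric(cutoff))
  if (is.null(model_id))
    model_id <- if (!is.null(net$spec)) format(net$spec) else
      sprintf("net-%dx%d", net$resolution, net$resolution)
  out <- data.frame(model = model_id, auc = auc,
                    cutoff = as.numeric(cutoff),
                    sensitivity = m$sensitivity, specificity = m$specificity,
                    ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  show <- data.frame(
    Model = df$model,
    AUC = round(df$auc, digits),
    `Cut-off` = round(df$cutoff, digits),
    `Sensitivity%` = round_half_up(df$sensitivity, 1),
    `Specificity%` = round_half_up(df$specificity, 1),
    `PPV%` = round_half_up(df$ppv, 1),
    `NPV%` = round_half_up(df$npv, 1),
    `Accuracy%` = round_half_up(df$accuracy, 1),
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

# Display rounding: half away from zero at `digits` decimals.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write evaluation reports as CSV
#'
#' Column heads follow the standard report layout:
#' `Model,AUC,Cut-off,Sensitivity%,Specificity%,PPV%,NPV%,Accuracy%`.
#'
#' @param reports an `eval_report` (possibly multi-row, see [run_sweep()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  df <- as.data.frame(reports)
  names(df) <- c("Model", "AUC", "Cut-off", "Sensitivity%", "Specificity%",
                 "PPV%", "NPV%", "Accuracy%")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
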