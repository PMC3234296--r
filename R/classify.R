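# Predicted efficiency as a binary classifier of PCR success.
#
# A reaction succeeds when its measured efficiency reaches the chosen
# experimental threshold (success at exactly the threshold counts as
# success; strictly below it is a fail). ROC and precision-recall curves
# sweep the predicted efficiency as the decision score.

#' Label PCR success by measured efficiency
#'
#' @param measured Measured efficiencies in \[1, 2\].
#' @param threshold Experimental success threshold; reactions strictly
#'   below it are fails. Default 1.65 (65% efficiency).
#' @return Logical vector.
#' @export
#' @examples
#' label_success(c(1.64, 1.65, 2.0))  # FALSE TRUE TRUE
label_success <- function(measured, threshold = 1.65) {
  if (any(measured < 1 | measured > 2, na.rm = TRUE))
    qe_stop("measured efficiencies must lie in [1, 2]", "qe_invalid_input")
  if (threshold <= 1 || threshold >= 2)
    qe_warn(sprintf("success threshold %.3g lies outside (1, 2)", threshold),
            "qe_threshold_warning")
  measured >= threshold
}

roc_input_check <- function(scores, labels) {
  if (length(scores) != length(labels))
    qe_stop("scores and labels must have equal length", "qe_invalid_input")
  labels <- as.logical(labels)
  if (all(labels) || all(!labels))
    qe_stop("curve undefined: both classes must be present", "qe_single_class")
  labels
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a decision threshold (predict positive
#' when `score >= threshold`, ties grouped), with endpoints (0,0) and
#' (1,1); AUC by the trapezoid rule.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Logical (or 0/1) true class labels; both classes required.
#' @return List of class `roc_curve`: `points` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- roc_input_check(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr, -Inf),
                        fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[!duplicated(pts[c("fpr", "tpr")]), ]
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Precision-recall curve
#'
#' Same threshold sweep as [roc_curve()]; precision at zero predicted
#' positives is defined as 1 by convention (a curve anchor at recall 0).
#'
#' @inheritParams roc_curve
#' @return List of class `pr_curve`: `points` (tibble `threshold`,
#'   `recall`, `precision`).
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) == length(labels) && all(as.logical(labels))) {
    # degenerate all-positive case: precision is identically 1
    thr <- sort(unique(scores), decreasing = TRUE)
    rec <- vapply(thr, function(t) mean(scores >= t), numeric(1))
    return(structure(list(points = tibble::tibble(
      threshold = c(Inf, thr), recall = c(0, rec),
      precision = rep(1, length(thr) + 1L))), class = "pr_curve"))
  }
  labels <- roc_input_check(scores, labels)
  n_pos <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  pp <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr),
                        recall = c(0, tp / n_pos),
                        precision = c(1, tp / pp))
  structure(list(points = pts), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve: %d points\n", nrow(x$points)))
  invisible(x)
}

#' ROC/PR evaluation across experimental success thresholds
#'
#' Labels success at each experimental threshold, then evaluates the
#' predicted efficiency as the decision score. Thresholds yielding a
#' single class are skipped with a warning.
#'
#' @param predicted Predicted efficiencies (decision scores).
#' @param measured Measured efficiencies in \[1, 2\].
#' @param thresholds Experimental thresholds to sweep
#'   (default `c(1.60, 1.65, 1.80)`).
#' @return List of class `threshold_sweep`: `summary` (tibble `threshold`,
#'   `n_pos`, `n_neg`, `auc`) and `curves`, a per-threshold list with the
#'   `roc` and `pr` objects.
#' @export
threshold_sweep <- function(predicted, measured,
                            thresholds = c(1.60, 1.65, 1.80)) {
  if (length(predicted) != length(measured))
    qe_stop("predicted and measured must be aligned", "qe_invalid_input")
  curves <- list()
  rows <- list()
  for (th in thresholds) {
    labels <- suppressWarnings(label_success(measured, th))
    if (all(labels) || all(!labels)) {
      qe_warn(sprintf("threshold %.3g yields a single class; skipped", th),
              "qe_threshold_warning")
      next
    }
    roc <- roc_curve(predicted, labels)
    pr <- pr_curve(predicted, labels)
    curves[[sprintf("%.2f", th)]] <- list(roc = roc, pr = pr)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      threshold = th, n_pos = sum(labels), n_neg = sum(!labels),
      auc = roc$auc)
  }
  summary <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(threshold = numeric(), n_pos = integer(),
                   n_neg = integer(), auc = numeric())
  structure(list(summary = summary[order(-summary$auc), ], curves = curves),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("threshold sweep (sorted by AUC)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
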