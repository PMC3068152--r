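#' Empirical ROC curve over all observed cut-offs
#'
#' Sweeps every distinct observed score as a candidate cut-off and records the
#' confusion counts and rates at each operating point. A sample is called
#' positive iff its score is *strictly* beyond the cut-off in the positive
#' direction: `score > cutoff` for `direction = "greater_is_positive"` (the RQ
#' convention: over-expression calls disease) or `score < cutoff` for
#' `"less_is_positive"` (the delta-Ct convention, where lower cycle thresholds
#' mean higher expression). Ties at the cut-off are therefore negative calls.
#'
#' The curve runs from the all-negative operating point (cut-off = the extreme
#' observed score, fpr = tpr = 0) to the all-positive point (an infinite
#' sentinel cut-off beyond the other extreme, fpr = tpr = 1), so TPR and FPR
#' are non-decreasing along it. All finite cut-offs are observed score values,
#' making every operating point exactly reproducible from the data.
#'
#' Samples with missing (`NA`) scores are excluded before the sweep.
#'
#' @param scores numeric score per sample; `NA` allowed.
#' @param labels `"case"` / `"control"` per sample.
#' @param direction which tail calls positive; see Details.
#' @return An object of class `roc_curve`: a data frame with one row per
#'   operating point and columns `cutoff`, `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `fpr`, `sensitivity`, `specificity`, plus attributes `direction`,
#'   `n_case`, `n_control`.
#' @seealso [auc()], [cutoff_at_fpr()]
#' @export
roc_curve <- function(scores, labels,
                      direction = c("greater_is_positive", "less_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have the same length")
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) stop("labels must be 'case' or 'control', got: ",
                        paste(bad, collapse = ", "))
  n_case <- sum(labels == "case")
  n_control <- sum(labels == "control")
  if (n_case == 0 || n_control == 0)
    stop("degenerate labels: need at least one case and one control with non-missing scores")

  if (direction == "greater_is_positive") {
    cutoffs <- c(sort(unique(scores), decreasing = TRUE), -Inf)
    pos <- function(cut) scores > cut
  } else {
    cutoffs <- c(sort(unique(scores)), Inf)
    pos <- function(cut) scores < cut
  }
  is_case <- labels == "case"
  tp <- vapply(cutoffs, function(cut) sum(pos(cut) & is_case), integer(1))
  fp <- vapply(cutoffs, function(cut) sum(pos(cut) & !is_case), integer(1))
  curve <- data.frame(
    cutoff = cutoffs, tp = tp, fp = fp,
    tn = n_control - fp, fn = n_case - tp,
    tpr = tp / n_case, fpr = fp / n_control)
  curve$sensitivity <- curve$tpr
  curve$specificity <- 1 - curve$fpr
  structure(curve, direction = direction, n_case = n_case,
            n_control = n_control, class = c("roc_curve", "data.frame"))
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area over the (FPR, TPR) operating points of a [roc_curve()].
#' On the empirical curve built over all observed cut-offs this equals the
#' tie-corrected Mann-Whitney probability
#' \eqn{P(S_{case} > S_{control}) + \tfrac{1}{2} P(S_{case} = S_{control})}
#' over all case-control pairs, so an uninformative constant score gives
#' exactly 0.5 and perfect separation gives 1.
#'
#' @param curve a [roc_curve()].
#' @return Area in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Pick the cut-off attaining a target false-positive rate
#'
#' Among operating points with `fpr <= target_fpr`, returns the one maximising
#' TPR; ties on TPR resolve to the most conservative admissible cut-off (the
#' one calling fewest positives, i.e. the largest cut-off under
#' `greater_is_positive`). The all-negative point (fpr = 0, tpr = 0) is always
#' on the curve, so an admissible point always exists.
#'
#' @param curve a [roc_curve()].
#' @param target_fpr target false-positive rate in \[0, 1).
#' @return List with `cutoff`, `achieved_fpr`, `achieved_tpr`.
#' @export
cutoff_at_fpr <- function(curve, target_fpr) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.numeric(target_fpr) || length(target_fpr) != 1 ||
      target_fpr < 0 || target_fpr >= 1)
    stop("`target_fpr` must be a single value in [0, 1)")
  ok <- which(curve$fpr <= target_fpr + 1e-12)
  # curve rows run from fewest to most positive calls: the first row attaining
  # the maximal admissible TPR is the most conservative cut-off
  best <- ok[which.max(curve$tpr[ok])]
  list(cutoff = curve$cutoff[best],
       achieved_fpr = curve$fpr[best],
       achieved_tpr = curve$tpr[best])
}

#' @rdname roc_curve
#' @param path file to write the operating points to (TSV).
#' @param curve a [roc_curve()].
#' @export
write_roc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.table(as.data.frame(curve)[, c("cutoff", "tp", "fp", "tn", "fn", "tpr", "fpr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
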