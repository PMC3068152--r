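#' Confusion matrix of predicted against true labels
#'
#' @param predicted character vector of `"case"` / `"control"` calls.
#' @param truth character vector of true labels; `"unknown"` is not allowed
#'   here (a blinded set cannot be scored).
#' @return A `confusion_matrix`: list of counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("evaluation error: `predicted` and `truth` differ in length")
  if (any(!truth %in% c("case", "control")))
    stop("evaluation error: `truth` must contain only 'case'/'control'")
  if (any(!predicted %in% c("case", "control")))
    stop("evaluation error: `predicted` must contain only 'case'/'control'")
  structure(list(tp = sum(predicted == "case" & truth == "case"),
                 fp = sum(predicted == "case" & truth == "control"),
                 tn = sum(predicted == "control" & truth == "control"),
                 fn = sum(predicted == "control" & truth == "case")),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative counts, for building a matrix directly
#'   (e.g. from a published table).
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Percentage summaries of a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive value
#' and accuracy, each as a percentage. Raw (full-precision) values are kept
#' alongside integer percents rounded half-up, the convention used when such
#' tables are reported. A metric whose denominator is zero is returned as
#' `NA` (undefined), not an error.
#'
#' @param cm a `confusion_matrix`.
#' @return List with elements `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` -- each a list of `pct` (raw percent) and `pct_rounded` -- plus
#'   the `counts`.
#' @export
summary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- list(
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv         = pct(cm$tp, cm$tp + cm$fp),
    npv         = pct(cm$tn, cm$tn + cm$fn),
    accuracy    = pct(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn))
  out <- lapply(raw, function(x) list(pct = x, pct_rounded = round_half_up(x)))
  out$counts <- unclass(cm)
  out
}

# round-half-up to the nearest integer (R's round() is round-half-even)
round_half_up <- function(x) ifelse(is.na(x), NA_real_, floor(x + 0.5))

#' Per-gene prediction accuracy under calibrated cut-offs
#'
#' Predicts every sample from each gene alone -- positive iff the value is
#' measured and strictly beyond that gene's cut-off, consistent with the
#' missing-gets-0 profile rule (an unmeasured gene calls "control") -- and
#' counts agreements with the true labels.
#'
#' @param ds an [expression_dataset()] with known labels.
#' @param cutoffs a `gene_cutoff_table` for the same gene panel.
#' @return Data frame with `gene`, `n_correct`, `n_total`, `pct_correct`.
#' @export
per_gene_accuracy <- function(ds, cutoffs) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (any(ds$labels == "unknown"))
    stop("evaluation error: dataset labels must be known")
  fired <- binarize(ds, cutoffs)   # also validates the gene sets match
  truth_case <- matrix(ds$labels == "case", nrow = nrow(fired),
                       ncol = ncol(fired), byrow = TRUE)
  correct <- rowSums((fired == 1L) == truth_case)
  data.frame(gene = cutoffs$gene,
             n_correct = correct,
             n_total = ncol(fired),
             pct_correct = 100 * correct / ncol(fired),
             row.names = NULL)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) two-sided t-test,
#' \eqn{t = (\bar{x} - \bar{y}) / \sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom, as used to compare mean expression
#' between cases and controls gene by gene.
#'
#' @param x,y numeric vectors, each with at least two values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: both groups need at least 2 values")
  if (stats::var(x) + stats::var(y) == 0)
    stop("insufficient data: zero variance in both groups")
  fit <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return Correlation in \[-1, 1\]; `NA` (undefined) when either input has
#'   zero variance.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("`x` and `y` must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}
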