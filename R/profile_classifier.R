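#' Calibrate per-gene cut-offs at a fixed false-positive rate
#'
#' For every gene in the panel, runs [roc_curve()] on that gene's non-missing
#' values in a labelled training set and selects, via [cutoff_at_fpr()], the
#' cut-off maximising sensitivity subject to the per-gene training FPR not
#' exceeding `target_fpr`. On the RQ scale higher expression calls disease
#' (`greater_is_positive`); on the delta-Ct scale the direction flips
#' (`less_is_positive`), since lower cycle thresholds mean more transcript.
#'
#' @param training an [expression_dataset()] with case/control labels.
#' @param target_fpr per-gene false-positive rate ceiling, e.g. 0.05 or 0.10.
#' @return A `gene_cutoff_table`: data frame with one row per gene and columns
#'   `gene`, `cutoff`, `direction`, `target_fpr`, `achieved_fpr`,
#'   `achieved_tpr`, `n_cases_used`, `n_controls_used`.
#' @export
calibrate_gene_cutoffs <- function(training, target_fpr = 0.05) {
  stopifnot(inherits(training, "expression_dataset"))
  direction <- scale_direction(training$scale)
  rows <- lapply(gene_ids(training), function(g) {
    scores <- training$values[g, ]
    measured <- !is.na(scores)
    lab <- training$labels[measured]
    if (sum(lab == "case") == 0 || sum(lab == "control") == 0)
      stop("calibration error: gene '", g,
           "' has no measured cases or no measured controls")
    curve <- roc_curve(scores, training$labels, direction = direction)
    pick <- cutoff_at_fpr(curve, target_fpr)
    data.frame(gene = g, cutoff = pick$cutoff, direction = direction,
               target_fpr = target_fpr,
               achieved_fpr = pick$achieved_fpr,
               achieved_tpr = pick$achieved_tpr,
               n_cases_used = attr(curve, "n_case"),
               n_controls_used = attr(curve, "n_control"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("gene_cutoff_table", "data.frame"))
}

scale_direction <- function(scale) {
  switch(scale,
         RQ = "greater_is_positive",
         DELTA_CT = "less_is_positive",
         stop("unknown scale: ", scale))
}

#' Binarize a panel dataset into gene profiles
#'
#' Applies a calibrated [calibrate_gene_cutoffs()] table to a dataset: digit
#' \eqn{g} of a sample's profile is 1 iff gene \eqn{g} was measured and its
#' value lies strictly beyond the gene's cut-off in the positive direction;
#' lower/equal values *and missing values* give 0. Summing the digits gives
#' the gene profile score, an integer between 0 and the panel size.
#'
#' The dataset must contain exactly the calibrated genes -- a gene column
#' missing outright would otherwise contribute silent zeros and bias every
#' score downward.
#'
#' @param ds an [expression_dataset()] on the scale the cut-offs were
#'   calibrated for.
#' @param cutoffs a `gene_cutoff_table` from [calibrate_gene_cutoffs()].
#' @return `binarize()`: integer 0/1 matrix, genes x samples, in cut-off
#'   table gene order.
#' @export
binarize <- function(ds, cutoffs) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(cutoffs, "gene_cutoff_table"))
  if (!setequal(gene_ids(ds), cutoffs$gene))
    stop("configuration error: dataset gene set does not match cut-off table",
         " (missing: ", paste(setdiff(cutoffs$gene, gene_ids(ds)), collapse = ", "),
         ")")
  vals <- ds$values[cutoffs$gene, , drop = FALSE]
  fired <- vals > cutoffs$cutoff
  flip <- cutoffs$direction == "less_is_positive"
  fired[flip, ] <- vals[flip, , drop = FALSE] < cutoffs$cutoff[flip]
  fired[is.na(fired)] <- FALSE
  storage.mode(fired) <- "integer"
  fired
}

#' @rdname binarize
#' @param profiles 0/1 profile matrix from `binarize()` (genes x samples).
#' @return `profile_score()`: named integer vector of per-sample digit sums.
#' @export
profile_score <- function(profiles) {
  if (!is.matrix(profiles) || !all(profiles %in% c(0L, 1L)))
    stop("`profiles` must be a 0/1 matrix, genes x samples")
  colSums(profiles)
}

#' Calibrate and apply the profile-score classifier
#'
#' `calibrate_score_cutoff()` treats the integer profile scores like any other
#' score: it builds the empirical ROC curve over the observed distinct scores
#' (direction `greater_is_positive`) and picks the score cut-off maximising
#' training sensitivity at a training FPR of at most `target_fpr`.
#' `classify()` then calls a sample `"case"` iff its score is strictly greater
#' than the cut-off; scores equal to or below it are `"control"`.
#'
#' @param training_scores integer profile scores of the labelled training set.
#' @param labels `"case"` / `"control"` per training sample.
#' @param target_fpr training false-positive rate ceiling.
#' @return A `score_classifier`: list with `score_cutoff`, `target_fpr`,
#'   `achieved_fpr`, `achieved_tpr`.
#' @export
calibrate_score_cutoff <- function(training_scores, labels, target_fpr = 0.05) {
  curve <- roc_curve(training_scores, labels, direction = "greater_is_positive")
  pick <- cutoff_at_fpr(curve, target_fpr)
  structure(list(score_cutoff = pick$cutoff, target_fpr = target_fpr,
                 achieved_fpr = pick$achieved_fpr,
                 achieved_tpr = pick$achieved_tpr),
            class = "score_classifier")
}

#' @rdname calibrate_score_cutoff
#' @param scores integer profile scores to classify.
#' @param clf a `score_classifier`.
#' @return `classify()`: character vector of `"case"` / `"control"` calls.
#' @export
classify <- function(scores, clf) {
  stopifnot(inherits(clf, "score_classifier"))
  out <- ifelse(scores > clf$score_cutoff, "case", "control")
  if (!is.null(names(scores))) names(out) <- names(scores)
  out
}

#' @export
print.score_classifier <- function(x, ...) {
  cat(sprintf("score_classifier: case iff profile score > %s (target FPR %.2f; training FPR %.3f, TPR %.3f)\n",
              format(x$score_cutoff), x$target_fpr, x$achieved_fpr, x$achieved_tpr))
  invisible(x)
}

#' Serialize classifier artifacts
#'
#' The gene cut-off table and score classifier are frozen to JSON so a
#' calibrated classifier can be applied later to a blinded dataset without
#' sharing any state with training. Profiles, scores and predictions are
#' written as TSV (`sample_id`, the 0/1 digit string, `score`, and the
#' predicted label when given).
#'
#' @param cutoffs a `gene_cutoff_table`.
#' @param path output file.
#' @export
write_gene_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "gene_cutoff_table"))
  jsonlite::write_json(as.data.frame(cutoffs), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_cutoffs
#' @export
read_gene_cutoffs <- function(path) {
  df <- jsonlite::fromJSON(path)
  structure(df, class = c("gene_cutoff_table", "data.frame"))
}

#' @rdname write_gene_cutoffs
#' @param clf a `score_classifier`.
#' @export
write_score_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "score_classifier"))
  jsonlite::write_json(unclass(clf), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_cutoffs
#' @export
read_score_classifier <- function(path) {
  structure(jsonlite::fromJSON(path), class = "score_classifier")
}

#' @rdname write_gene_cutoffs
#' @param profiles 0/1 matrix from [binarize()].
#' @param predictions optional per-sample predicted labels from [classify()].
#' @export
write_profiles <- function(profiles, path, predictions = NULL) {
  df <- data.frame(sample_id = colnames(profiles),
                   profile = apply(profiles, 2, paste, collapse = ""),
                   score = unname(profile_score(profiles)))
  if (!is.null(predictions)) df$predicted_label <- unname(predictions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
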