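#' Expression dataset for a qPCR gene panel
#'
#' Container for a genes x samples matrix of qPCR-derived expression values
#' together with per-sample class labels. Values live on one of two scales:
#' `"RQ"` (relative quantity, \eqn{2^{-\Delta\Delta C_T}}, strictly positive)
#' or `"DELTA_CT"` (normalised cycle thresholds, where *lower* values mean
#' *higher* expression). Missing measurements are stored as `NA` in the
#' matrix; [missing_mask()] exposes them as a logical mask.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique: they are the gene and
#'   sample identifiers.
#' @param scale `"RQ"` or `"DELTA_CT"`.
#' @param labels character vector of per-sample classes, one of `"case"`,
#'   `"control"`, `"unknown"`; recycled from `"unknown"` when `NULL`
#'   (a blinded dataset).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `scale` and `labels` (named by sample).
#' @export
expression_dataset <- function(values, scale = c("RQ", "DELTA_CT"), labels = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier: ",
         colnames(values)[duplicated(colnames(values))][1])
  if (is.null(labels)) labels <- rep("unknown", ncol(values))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("`labels` must have one entry per sample")
  bad <- setdiff(unique(labels), c("case", "control", "unknown"))
  if (length(bad))
    stop("invalid label(s): ", paste(bad, collapse = ", "))
  names(labels) <- colnames(values)
  if (scale == "RQ") {
    offending <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
    if (nrow(offending) > 0)
      stop(sprintf("RQ values must be strictly positive: gene '%s', sample '%s' has %g",
                   rownames(values)[offending[1, 1]],
                   colnames(values)[offending[1, 2]],
                   values[offending[1, , drop = FALSE]]))
  }
  structure(list(values = values, scale = scale, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples on the %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(factor(x$labels, levels = c("case", "control", "unknown")))
  cat(sprintf("labels: %d case, %d control, %d unknown; %d missing cells (%.1f%%)\n",
              tab[["case"]], tab[["control"]], tab[["unknown"]],
              sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname expression_dataset
#' @param ds an `expression_dataset`.
#' @return `missing_mask()`: logical matrix, `TRUE` where a measurement is absent.
#' @export
missing_mask <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  is.na(ds$values)
}

#' @rdname expression_dataset
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @rdname expression_dataset
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' Drop samples with too few measured genes
#'
#' Retains only samples with at least `min_present` non-missing gene values.
#' The reference study required measurements for at least half the panel
#' (22 of 44 reporter genes) before a sample entered clustering. The gene set
#' is never changed and the filter is idempotent.
#'
#' @param ds an [expression_dataset()].
#' @param min_present minimum number of measured genes a sample must have;
#'   between 0 and the number of genes.
#' @return The filtered `expression_dataset` (possibly with zero samples).
#' @export
filter_min_present <- function(ds, min_present) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(min_present) || length(min_present) != 1 ||
      min_present < 0 || min_present > nrow(ds$values))
    stop("`min_present` must be a single count between 0 and the number of genes")
  keep <- colSums(!is.na(ds$values)) >= min_present
  expression_dataset(ds$values[, keep, drop = FALSE], scale = ds$scale,
                     labels = ds$labels[keep])
}
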