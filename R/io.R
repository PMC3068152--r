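#' Read and write wide-format expression tables
#'
#' Reads a delimited (TSV by default, CSV for `.csv` paths) wide-format
#' expression table into an [expression_dataset()]. The first column holds
#' identifiers; the remaining columns hold values. `orientation` says which
#' dimension is in rows: `"genes_in_rows"` (the on-disk default written by
#' [write_expression_table()]) or `"samples_in_rows"`. Empty cells and the
#' literal `NA` both denote missing measurements; [write_expression_table()]
#' writes empty cells.
#'
#' @param path expression table file.
#' @param scale value scale of the table, `"RQ"` or `"DELTA_CT"`.
#' @param labels_path optional two-column sample label file (TSV:
#'   `sample_id`, `label` in case/control/unknown). When absent all samples
#'   are labelled `"unknown"` -- a blinded dataset.
#' @param orientation `"genes_in_rows"` or `"samples_in_rows"`.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, scale = c("RQ", "DELTA_CT"),
                                  labels_path = NULL,
                                  orientation = c("genes_in_rows", "samples_in_rows")) {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  sep <- table_sep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("format error: expression table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("format error: non-numeric entries in expression table")
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read_labels(labels_path)
    missing_samples <- setdiff(colnames(mat), names(lab))
    if (length(missing_samples))
      stop("label file lacks sample(s): ", paste(missing_samples, collapse = ", "))
    labels <- unname(lab[colnames(mat)])
  }
  expression_dataset(mat, scale = scale, labels = labels)
}

#' @rdname read_expression_table
#' @param ds an [expression_dataset()] to serialise.
#' @export
write_expression_table <- function(ds, path,
                                   orientation = c("genes_in_rows", "samples_in_rows")) {
  stopifnot(inherits(ds, "expression_dataset"))
  orientation <- match.arg(orientation)
  mat <- if (orientation == "genes_in_rows") ds$values else t(ds$values)
  id_col <- if (orientation == "genes_in_rows") "gene_id" else "sample_id"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_expression_table
#' @return `read_labels()`: named character vector of labels keyed by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = table_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("format error: label file needs sample_id and label columns")
  lab <- as.character(df[[2]])
  bad <- setdiff(unique(lab), c("case", "control", "unknown"))
  if (length(bad)) stop("invalid label(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[[1]])) stop("format error: duplicate sample id in label file")
  stats::setNames(lab, as.character(df[[1]]))
}

#' @rdname read_expression_table
#' @export
write_labels <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  utils::write.table(
    data.frame(sample_id = sample_ids(ds), label = unname(ds$labels)),
    path, sep = table_sep(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

table_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
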