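#' Construct a validated expression matrix
#'
#' Bundles a normalized log2 intensity matrix (genes x samples) with the
#' case/control assignment of each sample. This is the container every
#' downstream differential-expression operation consumes; construction fails
#' fast on the conditions the statistics assume: unique gene identifiers, no
#' missing or non-finite intensities, and at least two samples per group.
#'
#' @param values Numeric matrix of log2 intensities; rownames are gene
#'   identifiers, colnames are sample identifiers.
#' @param labels Character vector, one entry per column of `values`, each
#'   `"case"` or `"control"`. May be named by sample id; names, when present,
#'   must match `colnames(values)`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `labels` (character vector aligned to columns).
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
#' em <- expression_matrix(m, rep(c("case", "control"), each = 5))
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_lncnet("lncnet_invalid_input", "`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_lncnet("lncnet_invalid_input", "`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_lncnet("lncnet_invalid_input", "gene identifiers must be unique")
  if (anyDuplicated(colnames(values)))
    stop_lncnet("lncnet_invalid_input", "sample identifiers must be unique")
  if (any(!is.finite(values)))
    stop_lncnet("lncnet_invalid_input", "expression values must be finite with no missing entries")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop_lncnet("lncnet_invalid_input", "`labels` must have one entry per sample column")
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(values)))
      stop_lncnet("lncnet_invalid_input", "label names do not match sample identifiers")
    labels <- labels[colnames(values)]
  }
  if (!all(labels %in% c("case", "control")))
    stop_lncnet("lncnet_invalid_input", "labels must be 'case' or 'control'")
  if (sum(labels == "case") < 2L || sum(labels == "control") < 2L)
    stop_lncnet("lncnet_insufficient_replicates", "need >= 2 samples per group")
  structure(list(values = values, labels = unname(labels)), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Write / read an expression matrix and its sample labels as TSV
#'
#' The expression file has a `gene_id` first column and one column per sample;
#' the label file has columns `sample_id` and `group`.
#'
#' @param em An `expr_matrix`.
#' @param expr_path,labels_path Output (or input) file paths.
#' @return `write_expression` returns the paths invisibly; `read_expression`
#'   returns an `expr_matrix`.
#' @export
write_expression <- function(em, expr_path, labels_path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values, check.names = FALSE)
  write_tsv(df, expr_path)
  write_tsv(data.frame(sample_id = colnames(em$values), group = em$labels), labels_path)
  invisible(c(expr_path, labels_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, labels_path) {
  df <- read_tsv(expr_path)
  lab <- read_tsv(labels_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  expression_matrix(values, setNames(lab$group, lab$sample_id))
}
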