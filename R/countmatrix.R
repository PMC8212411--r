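#' Build a validated gene x cell count matrix
#'
#' The basic container for raw single-cell expression data: a sparse
#' gene x cell matrix of non-negative integer counts, a condition label per
#' cell (typically \code{"low"} / \code{"high"} for the two tumour groups),
#' and, for simulated data only, the true cell type each cell was drawn from.
#'
#' @param counts Matrix-like (dense or \pkg{Matrix} sparse) of non-negative
#'   integer counts, genes in rows, cells in columns.
#' @param condition Character vector, one label per cell.
#' @param gene_ids,cell_ids Unique identifiers; default to the dimnames of
#'   \code{counts}.
#' @param true_type Optional character vector of ground-truth cell types
#'   (present only for synthetic data).
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts} (a \code{dgCMatrix} with dimnames), \code{condition} and
#'   \code{true_type}.
#' @export
count_matrix <- function(counts, condition,
                         gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         true_type = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    .stopf("count_matrix() needs gene and cell identifiers")
  }
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(gene_ids)) .stopf("duplicate gene_ids in count matrix")
  if (anyDuplicated(cell_ids)) .stopf("duplicate cell_ids in count matrix")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    .stopf("dimnames (%d genes, %d cells) do not match matrix (%d x %d)",
           length(gene_ids), length(cell_ids), nrow(counts), ncol(counts))
  }
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    bad <- which(counts@x < 0 | counts@x != round(counts@x))[1L]
    .stopf("counts must be non-negative integers (offending value %g)",
           counts@x[bad])
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts) || anyNA(condition)) {
    .stopf("a condition label is required for every cell")
  }
  if (!is.null(true_type)) {
    true_type <- as.character(true_type)
    if (length(true_type) != ncol(counts)) {
      .stopf("true_type must have one entry per cell")
    }
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, condition = condition, true_type = true_type),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$condition)),
                            as.integer(table(x$condition))), collapse = ", ")))
  invisible(x)
}

# Fast internal constructor for matrices already known to be valid.
.new_count_matrix <- function(counts, condition, true_type = NULL) {
  structure(list(counts = counts, condition = condition, true_type = true_type),
            class = "CountMatrix")
}

# Subset a CountMatrix keeping metadata aligned (no re-validation).
.subset_cm <- function(m, genes = NULL, cells = NULL) {
  gi <- genes %||% rownames(m$counts)
  ci <- cells %||% colnames(m$counts)
  keep <- match(ci, colnames(m$counts))
  .new_count_matrix(m$counts[gi, ci, drop = FALSE],
                    condition = m$condition[keep],
                    true_type = if (is.null(m$true_type)) NULL else m$true_type[keep])
}

#' Construct a normalized expression matrix
#'
#' Log-scale normalized values with per-cell condition labels and an optional
#' ordered list of variable genes used downstream for annotation.
#'
#' @param values Gene x cell matrix of finite, non-negative log-normalized
#'   values (sparse or dense).
#' @param condition Character vector, one label per cell.
#' @param variable_genes Optional ordered character vector, a subset of the
#'   row names of \code{values}.
#' @return An object of class \code{NormalizedMatrix}.
#' @export
normalized_matrix <- function(values, condition, variable_genes = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .stopf("normalized values need gene and cell dimnames")
  }
  vx <- if (inherits(values, "sparseMatrix")) values@x else values
  if (length(vx) && (any(!is.finite(vx)) || any(vx < 0))) {
    .stopf("normalized values must be finite and >= 0")
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) .stopf("one condition label per cell required")
  if (!is.null(variable_genes) && !all(variable_genes %in% rownames(values))) {
    .stopf("variable_genes must be a subset of the gene ids")
  }
  structure(list(values = values, condition = condition,
                 variable_genes = variable_genes),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells, %d variable genes\n",
              nrow(x$values), ncol(x$values), length(x$variable_genes)))
  invisible(x)
}
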