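#' Quality-control and normalization parameters
#'
#' Defaults follow the standard single-cell toolchain conventions for sorted
#' plate-based HSPC data: cells with fewer than 1000 detected genes are
#' dropped, genes must be seen in at least 3 cells, cells with more than 5\%
#' of their counts from mitochondrial genes are removed, normalization is
#' log1p of counts-per-10,000, and 2000 variable genes are selected.
#'
#' @param min_nonzero_genes_per_cell Minimum detected (non-zero) genes a cell
#'   must have; cells with fewer are filtered.
#' @param min_cells_per_gene Minimum number of (surviving) cells a gene must
#'   be detected in.
#' @param max_mito_fraction Maximum allowed mitochondrial count fraction per
#'   cell, in [0, 1].
#' @param noncoding_gene_list Optional character vector of gene ids to drop
#'   before any other filter. \code{NULL} (unspecified) skips the step with a
#'   warning; supply \code{character(0)} to state explicitly that there is
#'   nothing to drop.
#' @param mito_gene_list Optional explicit set of mitochondrial gene ids;
#'   by default genes whose id starts with \code{"mt-"} (case-insensitive).
#' @param scale_factor Per-cell library-size target for normalization.
#' @param n_variable_genes Number of variable genes to select.
#' @return An object of class \code{QCParams}.
#' @export
qc_params <- function(min_nonzero_genes_per_cell = 1000,
                      min_cells_per_gene = 3,
                      max_mito_fraction = 0.05,
                      noncoding_gene_list = NULL,
                      mito_gene_list = NULL,
                      scale_factor = 10000,
                      n_variable_genes = 2000) {
  if (min_nonzero_genes_per_cell < 0 || min_cells_per_gene < 0 ||
      scale_factor <= 0 || n_variable_genes < 1) {
    .stopf("QC thresholds must be non-negative (and scale_factor positive)")
  }
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    .stopf("max_mito_fraction must lie in [0, 1]")
  }
  structure(list(min_nonzero_genes_per_cell = min_nonzero_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_fraction = max_mito_fraction,
                 noncoding_gene_list = noncoding_gene_list,
                 mito_gene_list = mito_gene_list,
                 scale_factor = scale_factor,
                 n_variable_genes = n_variable_genes),
            class = "QCParams")
}

.mito_genes_of <- function(gene_ids, p) {
  if (!is.null(p$mito_gene_list)) {
    intersect(gene_ids, p$mito_gene_list)
  } else {
    gene_ids[grepl("^mt-", gene_ids, ignore.case = TRUE)]
  }
}

#' Filter a count matrix
#'
#' Applies the four filters in one fixed pass, in this order: (1) drop
#' non-coding genes (when a list is supplied); (2) drop cells with fewer than
#' \code{min_nonzero_genes_per_cell} detected genes; (3) drop genes detected
#' in fewer than \code{min_cells_per_gene} of the surviving cells; (4) drop
#' cells whose mitochondrial count fraction exceeds
#' \code{max_mito_fraction}. There is no iteration to a fixpoint; the counts
#' removed by each step are attached as \code{attr(, "qc_summary")}.
#'
#' @param m A \code{CountMatrix}.
#' @param p A \code{QCParams}.
#' @return The filtered \code{CountMatrix}.
#' @export
filter_matrix <- function(m, p = qc_params()) {
  stopifnot(inherits(m, "CountMatrix"))
  summary <- list(input = c(genes = nrow(m$counts), cells = ncol(m$counts)))

  # (1) non-coding genes
  if (is.null(p$noncoding_gene_list)) {
    .warnf("no non-coding gene list supplied; skipping the non-coding filter")
    summary$noncoding_genes_removed <- NA_integer_
  } else {
    drop <- intersect(rownames(m$counts), p$noncoding_gene_list)
    summary$noncoding_genes_removed <- length(drop)
    if (length(drop)) m <- .subset_cm(m, genes = setdiff(rownames(m$counts), drop))
  }

  .check_cells <- function(m, step) {
    if (ncol(m$counts) == 0) {
      .stopf("all cells removed; the '%s' filter eliminated the majority", step)
    }
    m
  }

  # (2) cells by detected-gene count (cells with fewer than the minimum go)
  nz <- Matrix::colSums(m$counts > 0)
  keep_cells <- colnames(m$counts)[nz >= p$min_nonzero_genes_per_cell]
  summary$low_complexity_cells_removed <- ncol(m$counts) - length(keep_cells)
  if (length(keep_cells) < ncol(m$counts)) m <- .subset_cm(m, cells = keep_cells)
  m <- .check_cells(m, "min_nonzero_genes_per_cell")

  # (3) genes by prevalence among surviving cells
  ncell <- Matrix::rowSums(m$counts > 0)
  keep_genes <- rownames(m$counts)[ncell >= p$min_cells_per_gene]
  summary$low_prevalence_genes_removed <- nrow(m$counts) - length(keep_genes)
  if (length(keep_genes) < nrow(m$counts)) m <- .subset_cm(m, genes = keep_genes)
  if (nrow(m$counts) == 0) {
    .stopf("all genes removed by the 'min_cells_per_gene' filter")
  }

  # (4) cells by mitochondrial count fraction
  mito <- .mito_genes_of(rownames(m$counts), p)
  if (length(mito)) {
    tot <- Matrix::colSums(m$counts)
    mfrac <- Matrix::colSums(m$counts[mito, , drop = FALSE]) / pmax(tot, 1)
    keep_cells <- colnames(m$counts)[mfrac <= p$max_mito_fraction]
    summary$high_mito_cells_removed <- ncol(m$counts) - length(keep_cells)
    if (length(keep_cells) < ncol(m$counts)) m <- .subset_cm(m, cells = keep_cells)
    m <- .check_cells(m, "max_mito_fraction")
  } else {
    summary$high_mito_cells_removed <- 0L
  }

  summary$output <- c(genes = nrow(m$counts), cells = ncol(m$counts))
  attr(m, "qc_summary") <- summary
  m
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' \code{value(g, c) = log(1 + count(g, c) / total(c) * scale_factor)}. Zeros
#' stay zero, so sparsity is preserved.
#'
#' @param m A \code{CountMatrix} (every cell must have total count > 0).
#' @param scale_factor Library-size target (default 10,000).
#' @return A \code{NormalizedMatrix}.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "CountMatrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    .stopf("cell(s) with zero total count (e.g. '%s') must be filtered first",
           colnames(m$counts)[which(tot == 0)[1L]])
  }
  v <- m$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  normalized_matrix(v, condition = m$condition)
}

#' Select highly variable genes
#'
#' Ranks genes by a standardized dispersion: per gene, the mean and the
#' dispersion (variance/mean) of the de-logged normalized expression are
#' computed; genes are placed into 20 equal-count bins of mean expression and
#' the log-dispersion is z-scored within each bin (falling back to the global
#' mean/sd for degenerate bins). Ties are broken by gene id so the selection
#' is deterministic.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param n Number of genes to return; if larger than the gene universe, all
#'   genes are returned with a warning.
#' @param n_bins Number of mean-expression bins.
#' @return Character vector of gene ids, most variable first.
#' @export
select_variable_genes <- function(nm, n = 2000, n_bins = 20) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  genes <- rownames(nm$values)
  if (n >= length(genes)) {
    if (n > length(genes)) {
      .warnf("requested %d variable genes of %d available; returning all",
             n, length(genes))
    }
    return(genes)
  }
  x <- .expm1_sparse(nm$values)
  mu <- Matrix::rowMeans(x)
  # E[x^2] - E[x]^2, computed sparsely
  ex2 <- Matrix::rowMeans(x^2)
  v <- pmax(0, (ex2 - mu^2) * ncol(x) / max(1, ncol(x) - 1))
  disp <- ifelse(mu > 0, v / mu, 0)
  d <- log(disp + 1e-12)

  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) {
    cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(mu))
  }
  g_mean <- mean(d)
  g_sd <- stats::sd(d)
  z <- numeric(length(d))
  for (b in unique(bin)) {
    i <- which(bin == b)
    m_b <- mean(d[i])
    s_b <- stats::sd(d[i])
    if (length(i) < 2 || !is.finite(s_b) || s_b == 0) {
      m_b <- g_mean
      s_b <- if (is.finite(g_sd) && g_sd > 0) g_sd else 1
    }
    z[i] <- (d[i] - m_b) / s_b
  }
  ord <- order(-z, genes)
  genes[ord][seq_len(min(n, length(genes)))]
}
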