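#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration (via the exact null distribution of the Mann-Whitney U
#' statistic) when the pooled sample has at most 12 observations and no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction. When every value is identical across both samples
#' the p-value is 1.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param mode \code{"auto"} (default), \code{"exact"} or \code{"normal"}.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) .stopf("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  if (mode == "auto") mode <- if (n <= 12 && !ties) "exact" else "normal"
  r <- data.table::frank(pooled, ties.method = "average")
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  if (mode == "exact") {
    if (ties) .stopf("exact mode requires tie-free samples")
    p <- 2 * min(stats::pwilcox(u, n_a, n_b),
                 stats::pwilcox(u - 1, n_a, n_b, lower.tail = FALSE))
    return(min(1, p))
  }

  mu <- n_a * n_b / 2
  tab <- rle(sort(pooled))$lengths
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  v <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Linear fold change of de-logged normalized expression
#'
#' \code{FC = (mean(expm1(high)) + 1) / (mean(expm1(low)) + 1)}: the groups'
#' normalized values are de-logged, averaged, and compared with a pseudocount
#' of 1 guarding empty denominators.
#'
#' @param a_norm Log-normalized values of the high-condition cells.
#' @param b_norm Log-normalized values of the low-condition cells.
#' @return Positive fold change (high over low).
#' @export
fold_change <- function(a_norm, b_norm) {
  if (!length(a_norm) || !length(b_norm)) .stopf("both groups must be non-empty")
  (mean(expm1(a_norm)) + 1) / (mean(expm1(b_norm)) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values, monotone, capped at 1, in the input order.
#'
#' @param pvals Probabilities in [0, 1].
#' @return Adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    .stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cell-type differential expression between conditions
#'
#' For the unpruned cells of one annotated type, genes are first restricted
#' to those detected in at least \code{min_detect} of the cells in either
#' condition and showing at least \code{fold_threshold}-fold difference in
#' either direction; only the surviving genes are Wilcoxon-tested and BH
#' adjustment runs across that surviving set.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param ann A \code{CellAnnotation} for the same cells.
#' @param cell_type Type to test (>= 3 unpruned cells needed per condition).
#' @param fold_threshold Two-sided linear fold-change prefilter (default 1.2).
#' @param min_detect Detection-fraction prefilter (default 0.10).
#' @param condition_levels Length-2 vector: (low, high) condition labels.
#' @return A \code{data.frame} of class \code{DEGRecord} with one row per
#'   tested gene: \code{cell_type}, \code{gene}, \code{fold_change}
#'   (high/low, linear), \code{pct_low}, \code{pct_high}, \code{p_raw},
#'   \code{p_adj}; sorted by \code{p_adj}, then by decreasing |log FC|.
#' @export
differential_expression <- function(nm, ann, cell_type,
                                    fold_threshold = 1.2, min_detect = 0.10,
                                    condition_levels = c("low", "high")) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(ann, "CellAnnotation"))
  if (fold_threshold < 1) .stopf("fold_threshold must be >= 1")
  sel <- !ann$pruned & !is.na(ann$best_type) & ann$best_type == cell_type
  cells_low <- ann$cell_id[sel & ann$condition == condition_levels[1]]
  cells_high <- ann$cell_id[sel & ann$condition == condition_levels[2]]
  if (length(cells_low) < 3 || length(cells_high) < 3) {
    .stopf("insufficient cells for type '%s': %d low / %d high unpruned cells (>= 3 needed each)",
           cell_type, length(cells_low), length(cells_high))
  }
  Xl <- as.matrix(nm$values[, cells_low, drop = FALSE])
  Xh <- as.matrix(nm$values[, cells_high, drop = FALSE])
  pct_low <- rowMeans(Xl > 0)
  pct_high <- rowMeans(Xh > 0)
  fc <- (rowMeans(expm1(Xh)) + 1) / (rowMeans(expm1(Xl)) + 1)
  keep <- pmax(pct_low, pct_high) >= min_detect &
    (fc >= fold_threshold | fc <= 1 / fold_threshold)
  genes <- rownames(Xl)[keep]
  p_raw <- vapply(genes, function(g) wilcoxon_rank_sum(Xh[g, ], Xl[g, ]),
                  numeric(1))
  out <- data.frame(cell_type = rep(cell_type, length(genes)),
                    gene = genes,
                    fold_change = unname(fc[keep]),
                    pct_low = unname(pct_low[keep]),
                    pct_high = unname(pct_high[keep]),
                    p_raw = unname(p_raw),
                    p_adj = if (length(genes)) bh_adjust(p_raw) else numeric(0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, -abs(log(out$fold_change)), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("DEGRecord", "data.frame"))
}

#' Densitometry ratios of a secreted-factor table
#'
#' @param raw A \code{data.frame} with columns \code{factor},
#'   \code{dens_low}, \code{dens_high} (positive densitometry units).
#' @return The table with a recomputed \code{ratio = dens_high / dens_low}
#'   column, sorted by descending ratio.
#' @export
array_ratios <- function(raw) {
  need <- c("factor", "dens_low", "dens_high")
  if (!all(need %in% names(raw))) {
    .stopf("secretome table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(raw$dens_low)) || any(!is.finite(raw$dens_high)) ||
      any(raw$dens_low <= 0) || any(raw$dens_high <= 0)) {
    .stopf("densitometry values must be positive")
  }
  out <- raw[, need]
  out$ratio <- out$dens_high / out$dens_low
  out <- out[order(-out$ratio, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair secreted factors with differentially expressed receptors and rank
#'
#' Emits one record per (ligand, receptor, cell type) combination where the
#' ligand's high/low densitometry ratio exceeds \code{ratio_min}, the pair is
#' listed in the ligand-receptor table, and the receptor appears among that
#' cell type's differential-expression records with fold change > 1 (up in
#' the high condition) and adjusted p below \code{padj_max}. Receptor symbols
#' are matched case-insensitively. Records are sorted by descending ligand
#' ratio, then descending receptor fold change, then ascending adjusted p;
#' ranks are assigned after sorting. Per-gate failure counts are attached as
#' \code{attr(, "diagnostics")}.
#'
#' @param sec Secretome table (see \code{\link{array_ratios}}; a \code{ratio}
#'   column is computed if absent).
#' @param degs Combined \code{DEGRecord} rows (possibly several cell types).
#' @param lr Ligand-receptor pair table.
#' @param ratio_min Ligand ratio gate (strict, default 1.0).
#' @param padj_max Receptor significance gate (default 0.05).
#' @return A \code{data.frame} of class \code{CrosstalkRanking} with columns
#'   \code{ligand}, \code{receptor}, \code{cell_type}, \code{ligand_ratio},
#'   \code{receptor_fold}, \code{p_adj}, \code{rank}.
#' @export
pair_and_rank <- function(sec, degs, lr, ratio_min = 1.0, padj_max = 0.05) {
  if (!"ratio" %in% names(sec)) sec <- array_ratios(sec)
  empty <- data.frame(ligand = character(0), receptor = character(0),
                      cell_type = character(0), ligand_ratio = numeric(0),
                      receptor_fold = numeric(0), p_adj = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  diag <- c(candidate_pairs = 0L, ligand_not_measured = 0L,
            failed_ratio_gate = 0L, receptor_not_tested = 0L,
            failed_fold_gate = 0L, failed_padj_gate = 0L, emitted = 0L)
  rows <- list()
  for (i in seq_len(NROW(lr))) {
    lig <- lr$ligand[i]; rec <- lr$receptor[i]
    diag["candidate_pairs"] <- diag["candidate_pairs"] + 1L
    si <- match(lig, sec$factor)
    if (is.na(si)) {
      diag["ligand_not_measured"] <- diag["ligand_not_measured"] + 1L
      next
    }
    if (!(sec$ratio[si] > ratio_min)) {
      diag["failed_ratio_gate"] <- diag["failed_ratio_gate"] + 1L
      next
    }
    hits <- which(tolower(degs$gene) == tolower(rec))
    if (!length(hits)) {
      diag["receptor_not_tested"] <- diag["receptor_not_tested"] + 1L
      next
    }
    for (h in hits) {
      if (!(degs$fold_change[h] > 1)) {
        diag["failed_fold_gate"] <- diag["failed_fold_gate"] + 1L
      } else if (!(degs$p_adj[h] < padj_max)) {
        diag["failed_padj_gate"] <- diag["failed_padj_gate"] + 1L
      } else {
        diag["emitted"] <- diag["emitted"] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          ligand = lig, receptor = rec, cell_type = degs$cell_type[h],
          ligand_ratio = sec$ratio[si], receptor_fold = degs$fold_change[h],
          p_adj = degs$p_adj[h], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty[, -7]
  out <- unique(out)
  out <- out[order(-out$ligand_ratio, -out$receptor_fold, out$p_adj,
                   out$ligand, out$receptor, out$cell_type), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  structure(out, class = c("CrosstalkRanking", "data.frame"))
}
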