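#' Spearman-correlation scores of cells against a reference compendium
#'
#' Each cell's expression vector is rank-correlated (Spearman, midranks for
#' ties) with every reference type profile over a common gene set. The score
#' is invariant to any strictly monotone transform of the cell's expression.
#'
#' @param expr A gene x cell matrix of normalized expression (a single cell
#'   may be given as a named vector).
#' @param ref A \code{ReferenceCompendium}.
#' @param genes Genes to score on; default, the genes shared by \code{expr}
#'   and the reference.
#' @return A cell x type matrix of correlations in [-1, 1]; a cell that is
#'   constant over the scoring genes gets \code{NA} scores (its correlation
#'   is undefined and the cell is pruned downstream).
#' @export
score_cells <- function(expr, ref, genes = NULL) {
  stopifnot(inherits(ref, "ReferenceCompendium"))
  if (is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "cell"))
  }
  genes <- genes %||% intersect(rownames(expr), ref$gene_ids)
  if (length(genes) < 2) .stopf("need at least 2 shared genes to score")
  if (!all(genes %in% rownames(expr)) || !all(genes %in% ref$gene_ids)) {
    .stopf("scoring genes must be present in both the cells and the reference")
  }
  X <- as.matrix(expr[genes, , drop = FALSE])
  P <- t(as.matrix(ref$profiles[, genes, drop = FALSE]))  # genes x types
  RX <- .col_midranks(X)
  RP <- .col_midranks(P)
  s <- suppressWarnings(stats::cor(RX, RP))
  dimnames(s) <- list(colnames(expr), ref$type_names)
  s
}

#' Chi-squared outlier test for a top-matching annotation score
#'
#' Measures how far the best per-type correlation stands out from the rest:
#' \code{T = ((max - median(others)) / (1.4826 * MAD(others)))^2} is referred
#' to the upper tail of a chi-squared distribution with 1 df. When the MAD of
#' the non-top scores is 0, their standard deviation is used instead; if that
#' is 0 too the test degenerates (p = 0 when the top score strictly exceeds
#' the rest, p = 1 when all scores are equal).
#'
#' @param scores Numeric vector of per-type correlation scores (>= 3 values).
#' @return Upper-tail probability in [0, 1]; small values mean the top match
#'   clearly stands out.
#' @export
outlier_test <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 3) .stopf("outlier test needs at least 3 finite scores")
  top_i <- which.max(scores)
  others <- scores[-top_i]
  med <- stats::median(others)
  disp <- 1.4826 * stats::mad(others, constant = 1)
  if (disp == 0) disp <- stats::sd(others)
  if (!is.finite(disp) || disp == 0) {
    return(if (scores[top_i] > med) 0 else 1)
  }
  stat <- ((scores[top_i] - med) / disp)^2
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Annotate cells by correlation to a reference compendium
#'
#' Assigns every cell the reference type with the highest Spearman score,
#' computes the outlier-test probability of that top match, and prunes cells
#' whose best match does not stand out (\code{outlier_p >= prune_alpha}),
#' whose best and second scores tie (broken lexicographically by type name),
#' or whose score is undefined. Annotation is fully deterministic.
#'
#' @param nm A \code{NormalizedMatrix}; scoring uses its
#'   \code{variable_genes} (intersected with the reference genes) when set.
#' @param ref A \code{ReferenceCompendium} with >= 2 types.
#' @param prune_alpha Pruning threshold on the outlier probability.
#' @param genes Optional explicit scoring gene set.
#' @return A \code{data.frame} of class \code{CellAnnotation} with columns
#'   \code{cell_id}, \code{condition}, \code{best_type}, \code{best_score},
#'   \code{second_score}, \code{outlier_p}, \code{pruned}.
#' @export
annotate <- function(nm, ref, prune_alpha = 0.05, genes = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(ref, "ReferenceCompendium"))
  if (length(ref$type_names) < 2) .stopf("the reference needs at least 2 types")
  genes <- genes %||% nm$variable_genes %||% rownames(nm$values)
  genes <- intersect(intersect(genes, rownames(nm$values)), ref$gene_ids)
  if (length(genes) < 20) {
    .stopf("configuration error: only %d genes shared between data and reference (>= 20 required)",
           length(genes))
  }
  s <- score_cells(nm$values, ref, genes)
  # lexicographic column order makes the first-maximum rule a deterministic
  # tie-break by type name
  s <- s[, order(colnames(s)), drop = FALSE]
  n <- nrow(s)
  fin_cnt <- rowSums(is.finite(s))
  s2 <- s
  s2[!is.finite(s2)] <- -Inf
  bi <- max.col(s2, ties.method = "first")
  best <- s2[cbind(seq_len(n), bi)]
  best_type <- colnames(s)[bi]
  s3 <- s2
  s3[cbind(seq_len(n), bi)] <- -Inf
  second <- s3[cbind(seq_len(n), max.col(s3, ties.method = "first"))]
  best_type[fin_cnt == 0] <- NA_character_
  best[fin_cnt == 0] <- NA_real_
  second[!is.finite(second)] <- NA_real_
  outlier_p <- rep(NA_real_, n)
  for (i in which(fin_cnt >= 3)) outlier_p[i] <- outlier_test(s[i, ])
  tie <- !is.na(best) & !is.na(second) & (best - second) < 1e-12
  pruned <- is.na(best_type) | tie |
    (!is.na(outlier_p) & outlier_p >= prune_alpha)
  structure(data.frame(cell_id = rownames(s),
                       condition = nm$condition,
                       best_type = best_type,
                       best_score = best,
                       second_score = second,
                       outlier_p = outlier_p,
                       pruned = pruned,
                       stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("CellAnnotation", "data.frame"))
}

#' Annotation accuracy against simulated ground truth
#'
#' @param ann A \code{CellAnnotation}.
#' @param truth_labels Either the \code{CountMatrix} the cells came from (with
#'   \code{true_type} recorded) or a named character vector of true types.
#' @param unpruned_only Restrict to unpruned cells (default).
#' @return Fraction of cells whose assigned type equals the true type.
#' @export
annotation_accuracy <- function(ann, truth_labels, unpruned_only = TRUE) {
  if (inherits(truth_labels, "CountMatrix")) {
    truth_labels <- stats::setNames(truth_labels$true_type,
                                    colnames(truth_labels$counts))
  }
  keep <- if (unpruned_only) !ann$pruned else rep(TRUE, nrow(ann))
  if (!any(keep)) return(NA_real_)
  mean(ann$best_type[keep] == truth_labels[ann$cell_id[keep]], na.rm = TRUE)
}
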