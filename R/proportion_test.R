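#' Per-condition cell-type proportions
#'
#' Proportions are computed over unpruned annotated cells only.
#'
#' @param ann A \code{CellAnnotation}.
#' @return A type x condition matrix of proportions; each condition's column
#'   sums to 1.
#' @export
celltype_proportions <- function(ann) {
  stopifnot(inherits(ann, "CellAnnotation"))
  keep <- !ann$pruned & !is.na(ann$best_type)
  conds <- sort(unique(ann$condition))
  if (any(!conds %in% unique(ann$condition[keep]))) {
    missing <- setdiff(conds, unique(ann$condition[keep]))
    .stopf("condition '%s' has no unpruned annotated cells", missing[1L])
  }
  tab <- table(ann$best_type[keep], ann$condition[keep])
  prop <- sweep(unclass(tab), 2, colSums(tab), "/")
  prop[, conds, drop = FALSE]
}

# BCa-adjusted quantile of the sorted bootstrap replicates: the adjusted
# percentile alpha1 = Phi(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha))).
.bca_level <- function(alpha, z0, a) {
  z <- z0 + stats::qnorm(alpha)
  stats::pnorm(z0 + z / (1 - a * z))
}

.boot_quantile <- function(sorted, p) {
  # the 1e-9 guard keeps ceiling() exact when p*B lands on an integer
  sorted[min(length(sorted), max(1L, ceiling(p * length(sorted) - 1e-9)))]
}

#' BCa bootstrap test for a difference of two independent proportions
#'
#' Tests the difference \code{mean(x_high) - mean(x_low)} of two independent
#' binary membership samples (cells resampled with replacement within each
#' condition) with the bias-corrected and accelerated bootstrap, one-sided.
#' The bias correction z0 counts bootstrap replicates below the observed
#' difference (ties counted half); the acceleration is the standard jackknife
#' skewness over delete-one replicates of both samples. The one-sided p-value
#' is the smallest level at which the one-sided BCa confidence bound excludes
#' zero, found by bisection (tolerance 1e-4, search range [1/B, 0.5]; when
#' the bound does not exclude zero even at 0.5 the p-value is reported as 1).
#'
#' @param x_low,x_high Binary (0/1) membership vectors for the two
#'   conditions.
#' @param B Number of bootstrap replicates (>= 1000; default 10,000).
#' @param alpha Level for the reported two-sided BCa interval.
#' @param direction \code{"greater"} tests enrichment in the high condition,
#'   \code{"less"} depletion.
#' @param seed Required seed for the bootstrap stream.
#' @param bias_correct,accelerate Set to \code{FALSE} to force z0 = 0 or
#'   a = 0 (the interval then reduces to the percentile bootstrap).
#' @param keep_draws Keep the sorted bootstrap replicates in the result.
#' @return An object of class \code{bca_test}: a list with the sample sizes,
#'   proportions, difference, z0, acceleration, two-sided BCa interval,
#'   one-sided p-value, direction and a degeneracy flag.
#' @export
bca_test <- function(x_low, x_high, B = 10000, alpha = 0.05,
                     direction = c("greater", "less"), seed,
                     bias_correct = TRUE, accelerate = TRUE,
                     keep_draws = FALSE) {
  direction <- match.arg(direction)
  if (missing(seed)) .stopf("a bootstrap seed is required")
  if (B < 1000) .stopf("B must be at least 1000 (got %d)", B)
  x_low <- as.numeric(x_low); x_high <- as.numeric(x_high)
  if (length(x_low) < 2 || length(x_high) < 2) {
    .stopf("both membership vectors need at least 2 cells")
  }
  if (!all(x_low %in% c(0, 1)) || !all(x_high %in% c(0, 1))) {
    .stopf("membership vectors must be binary (0/1)")
  }
  n_l <- length(x_low); n_h <- length(x_high)
  s_l <- sum(x_low); s_h <- sum(x_high)
  p_l <- s_l / n_l; p_h <- s_h / n_h
  theta <- p_h - p_l

  # resampling a binary vector with replacement == a Binomial(n, phat) draw
  th <- .with_seed(seed, {
    stats::rbinom(B, n_h, p_h) / n_h - stats::rbinom(B, n_l, p_l) / n_l
  })
  sorted <- sort(th)
  degenerate <- sorted[1L] == sorted[B]

  # bias correction with half-count tie convention
  z0 <- if (bias_correct && !degenerate) {
    frac <- (sum(th < theta) + 0.5 * sum(th == theta)) / B
    stats::qnorm(min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B)))
  } else 0

  # jackknife acceleration: delete-one over both samples; for binary data the
  # leave-one-out statistic takes at most four distinct values
  a <- 0
  if (accelerate) {
    vals <- c((s_h - 1) / (n_h - 1) - p_l,  # drop a 1 from high
              s_h / (n_h - 1) - p_l,        # drop a 0 from high
              p_h - (s_l - 1) / (n_l - 1),  # drop a 1 from low
              p_h - s_l / (n_l - 1))        # drop a 0 from low
    w <- c(s_h, n_h - s_h, s_l, n_l - s_l)
    mbar <- sum(w * vals) / sum(w)
    d <- mbar - vals
    den <- sum(w * d^2)
    if (den > 0) a <- sum(w * d^3) / (6 * den^1.5)
  }

  ci <- c(.boot_quantile(sorted, .bca_level(alpha / 2, z0, a)),
          .boot_quantile(sorted, .bca_level(1 - alpha / 2, z0, a)))

  excludes <- function(ap) {
    if (direction == "greater") {
      .boot_quantile(sorted, .bca_level(ap, z0, a)) > 0
    } else {
      .boot_quantile(sorted, .bca_level(1 - ap, z0, a)) < 0
    }
  }

  if (degenerate) {
    right_sign <- if (direction == "greater") theta > 0 else theta < 0
    p_value <- if (right_sign) 1 / B else 1
  } else {
    lo <- 1 / B; hi <- 0.5
    if (!excludes(hi)) {
      p_value <- 1
    } else if (excludes(lo)) {
      p_value <- lo
    } else {
      while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        if (excludes(mid)) hi <- mid else lo <- mid
      }
      p_value <- hi
    }
  }

  structure(list(n_low = n_l, n_high = n_h, p_low = p_l, p_high = p_h,
                 diff = theta, B = B, z0 = z0, a = a,
                 ci_low = ci[1], ci_high = ci[2], alpha = alpha,
                 p_value = p_value, direction = direction,
                 degenerate = degenerate,
                 theta_star = if (keep_draws) sorted else NULL),
            class = "bca_test")
}

#' @export
print.bca_test <- function(x, ...) {
  cat(sprintf(paste0(
    "BCa bootstrap two-sample proportion test (one-sided, %s)\n",
    "  p_low = %.4f (n=%d), p_high = %.4f (n=%d), diff = %+.4f\n",
    "  B = %d, z0 = %.4f, a = %.4f, %.0f%% CI [%.4f, %.4f]\n",
    "  p = %.4g%s\n"),
    x$direction, x$p_low, x$n_low, x$p_high, x$n_high, x$diff,
    x$B, x$z0, x$a, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$p_value,
    if (x$degenerate) " (degenerate bootstrap)" else ""))
  invisible(x)
}

#' BCa proportion tests for every annotated cell type
#'
#' Runs \code{\link{bca_test}} marginally for each cell type (no cross-type
#' multiplicity correction, mirroring per-population reporting; a BH column
#' can be requested). With \code{direction = "auto"}, types with
#' \code{p_high > p_low} are tested for enrichment and the rest for
#' depletion; the chosen direction is recorded per type.
#'
#' @param ann A \code{CellAnnotation}.
#' @param B,alpha Passed to \code{\link{bca_test}}.
#' @param direction \code{"auto"}, \code{"greater"} or \code{"less"}.
#' @param seed Master seed; each type gets a derived sub-stream.
#' @param condition_levels Length-2 vector naming the reference (low) and
#'   contrast (high) condition labels.
#' @param bh Add a BH-adjusted p-value column (off by default).
#' @return A \code{data.frame}, one row per cell type, with all
#'   \code{bca_test} fields.
#' @export
test_all_proportions <- function(ann, B = 10000, alpha = 0.05,
                                 direction = "auto", seed,
                                 condition_levels = c("low", "high"),
                                 bh = FALSE) {
  stopifnot(inherits(ann, "CellAnnotation"))
  if (missing(seed)) .stopf("a bootstrap seed is required")
  keep <- !ann$pruned & !is.na(ann$best_type)
  lab <- ann$best_type[keep]
  cond <- ann$condition[keep]
  if (!all(condition_levels %in% cond)) {
    .stopf("both conditions ('%s', '%s') need unpruned cells",
           condition_levels[1], condition_levels[2])
  }
  types <- sort(unique(lab))
  rows <- lapply(seq_along(types), function(i) {
    ty <- types[i]
    x_low <- as.integer(lab[cond == condition_levels[1]] == ty)
    x_high <- as.integer(lab[cond == condition_levels[2]] == ty)
    dir_i <- if (direction == "auto") {
      if (mean(x_high) > mean(x_low)) "greater" else "less"
    } else direction
    r <- bca_test(x_low, x_high, B = B, alpha = alpha, direction = dir_i,
                  seed = .substream(seed, 100 + i))
    data.frame(cell_type = ty, n_low = r$n_low, n_high = r$n_high,
               p_low = r$p_low, p_high = r$p_high, diff = r$diff,
               B = r$B, z0 = r$z0, a = r$a,
               ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, direction = r$direction,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- bh_adjust(out$p_value)
  out[order(out$p_value, out$cell_type), , drop = FALSE]
}
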