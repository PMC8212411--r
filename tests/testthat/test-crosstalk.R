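test_that("exact Wilcoxon matches hand enumeration and base R on landmarks", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(2, 4, 6)), 1)
  set.seed(201)
  for (i in 1:100) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    a <- round(runif(n_a), 6)
    b <- round(runif(n_b), 6)
    if (anyDuplicated(c(a, b))) next
    p_pkg <- wilcoxon_rank_sum(a, b, mode = "exact")
    expect_equal(p_pkg, oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
    expect_equal(p_pkg, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the tie-corrected normal approximation is calibrated", {
  set.seed(99)
  rej <- mean(vapply(seq_len(1000), function(i) {
    a <- runif(40)
    b <- runif(40)
    wilcoxon_rank_sum(a, b) < 0.05
  }, logical(1)))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("fold change uses de-logged means with a unit pseudocount", {
  expect_equal(fold_change(log1p(c(2, 2)), log1p(c(2, 2))), 1)
  expect_equal(fold_change(log1p(c(3, 3, 3)), c(0, 0)), 4)
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
})

# Hand-built normalized matrix with one clean DE gene, one under-detected
# gene and one below the fold threshold; 20 cells per condition, one type.
de_fixture <- function() {
  n <- 40
  cells <- sprintf("c%04d", seq_len(n))
  cond <- rep(c("low", "high"), each = 20)
  vals <- matrix(0, 3, n, dimnames = list(c("Up", "SmallFC", "LowDet"), cells))
  vals["Up", ] <- ifelse(cond == "high", log1p(3), log1p(1))
  vals["SmallFC", ] <- ifelse(cond == "high", log1p(1.2), log1p(1))
  vals["LowDet", c(1, 21)] <- log1p(50)  # detected in 5% of each group
  nm <- normalized_matrix(vals, condition = cond)
  ann <- make_annotation(rep("T", n), cond)
  list(nm = nm, ann = ann)
}

test_that("detection and fold filters are applied before testing", {
  fx <- de_fixture()
  degs <- differential_expression(fx$nm, fx$ann, "T")
  expect_equal(degs$gene, "Up")
  expect_equal(degs$fold_change, 2)   # (3+1)/(1+1)
  expect_lt(degs$p_adj, 0.05)
  expect_true(all(degs$p_adj >= degs$p_raw))
})

test_that("swapping condition labels inverts fold changes, not p-values", {
  tr <- small_truth(seed = 13, planted_axis = list(ligand = "IL6",
                                                   receptor = "Il6ra",
                                                   target_type = "LT-HSC",
                                                   receptor_fold = 1.6,
                                                   ligand_ratio = 2))
  m <- simulate_counts(tr)
  nm <- log_normalize(filter_matrix(m, small_qc()))
  ann <- annotate(nm, generate_reference(tr))
  fwd <- differential_expression(nm, ann, "LT-HSC",
                                 condition_levels = c("low", "high"))
  rev <- differential_expression(nm, ann, "LT-HSC",
                                 condition_levels = c("high", "low"))
  fwd <- fwd[order(fwd$gene), ]
  rev <- rev[order(rev$gene), ]
  expect_equal(fwd$gene, rev$gene)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
  expect_equal(fwd$p_raw, rev$p_raw, tolerance = 1e-12)
})

test_that("too few cells of a type is an explicit error", {
  fx <- de_fixture()
  expect_error(differential_expression(fx$nm, fx$ann, "Missing"),
               "Missing")
})

test_that("array ratios are recomputed and sorted", {
  raw <- data.frame(factor = c("IL6", "CXCL1", "IL13"),
                    dens_low = c(100, 50, 80),
                    dens_high = c(250, 50, 60))
  out <- array_ratios(raw)
  expect_equal(out$factor[1], "IL6")
  expect_equal(out$ratio, c(2.5, 1, 0.75))
  raw$dens_low[2] <- 0
  expect_error(array_ratios(raw), "positive")
})

test_that("pairing gates and ranks candidate axes as documented", {
  sec <- data.frame(factor = c("IL6", "IL13"), dens_low = c(100, 100),
                    dens_high = c(250, 250))
  degs <- data.frame(cell_type = "MDP", gene = "Il6ra", fold_change = 1.21,
                     pct_low = 1, pct_high = 1, p_raw = 0.01, p_adj = 0.02,
                     stringsAsFactors = FALSE)
  lr <- data.frame(ligand = "IL6", receptor = "Il6ra")
  r <- pair_and_rank(sec, degs, lr)
  expect_equal(nrow(r), 1)
  expect_equal(r$rank, 1L)
  expect_equal(r$ligand_ratio, 2.5)

  # receptor matching is case-insensitive
  degs_uc <- transform(degs, gene = "IL6RA")
  expect_equal(nrow(pair_and_rank(sec, degs_uc, lr)), 1)

  # empty pair table gives a valid empty ranking
  empty <- pair_and_rank(sec, degs, lr[0, ])
  expect_equal(nrow(empty), 0)

  # equal ligand ratios break ties on receptor fold change
  degs2 <- rbind(degs,
                 data.frame(cell_type = "GMP", gene = "Il13ra1",
                            fold_change = 1.5, pct_low = 1, pct_high = 1,
                            p_raw = 0.01, p_adj = 0.02))
  lr2 <- rbind(lr, data.frame(ligand = "IL13", receptor = "Il13ra1"))
  r2 <- pair_and_rank(sec, degs2, lr2)
  expect_equal(r2$receptor[1], "Il13ra1")
  expect_equal(r2$rank, c(1L, 2L))

  # failed gates are reported in the diagnostics
  degs3 <- transform(degs, p_adj = 0.2)
  r3 <- pair_and_rank(sec, degs3, lr)
  expect_equal(nrow(r3), 0)
  expect_equal(unname(attr(r3, "diagnostics")["failed_padj_gate"]), 1L)
})
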