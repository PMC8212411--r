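test_that("tiny gene universes are built with disjoint marker programs", {
  tr <- simulation_truth(n_types = 2, type_names = c("A", "B"),
                         n_genes = 10, markers_per_type = 3,
                         lr_pairs = data.frame(ligand = "IL6", receptor = "Il6ra"),
                         n_cells = c(low = 5, high = 5))
  expect_length(tr$gene_ids, 10)
  expect_length(tr$markers$A, 3)
  expect_length(tr$markers$B, 3)
  expect_length(intersect(tr$markers$A, tr$markers$B), 0)
  expect_length(setdiff(tr$gene_ids, unlist(tr$markers)), 4)
  expect_true(tr$planted_axis$receptor %in% tr$gene_ids)

  ref <- generate_reference(tr)
  expect_equal(dim(ref$profiles), c(2, 10))

  # marker programs that do not fit in the universe are rejected
  expect_error(simulation_truth(n_types = 2, type_names = c("A", "B"),
                                n_genes = 10, markers_per_type = 6,
                                n_cells = c(low = 5, high = 5)),
               "invalid configuration")
})

test_that("proportion vectors are validated", {
  bad <- list(low = c(A = 0.6, B = 0.3), high = c(A = 0.5, B = 0.5))
  expect_error(small_truth(n_types = 2, type_names = c("A", "B"),
                           markers_per_type = 5,
                           proportions_by_condition = bad,
                           n_cells = c(low = 5, high = 5)),
               "sum to 1")
  expect_error(small_truth(planted_axis = list(ligand = "IL6", receptor = "Il6ra",
                                               target_type = "MDP",
                                               receptor_fold = 0.8,
                                               ligand_ratio = 2)),
               ">= 1")
})

test_that("identical truth yields bit-identical counts and secretome", {
  tr <- small_truth(seed = 11)
  m1 <- simulate_counts(tr)
  m2 <- simulate_counts(tr)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_identical(m1$condition, m2$condition)
  expect_identical(m1$true_type, m2$true_type)
  expect_identical(simulate_secretome(tr), simulate_secretome(tr))
})

test_that("marker_fold = 1 collapses all reference profiles to one", {
  tr <- small_truth(marker_fold = 1)
  ref <- generate_reference(tr)
  for (i in 2:nrow(ref$profiles)) {
    expect_equal(unname(ref$profiles[i, ]), unname(ref$profiles[1, ]))
  }
})

test_that("distinct type profiles correlate below a profile's self-correlation", {
  tr <- simulation_truth(seed = 5)  # 10 types, 2000 genes, marker_fold 8
  ref <- generate_reference(tr)
  sp <- cor(t(ref$profiles), method = "spearman")
  off <- sp[upper.tri(sp)]
  expect_true(all(off < 1))
  expect_equal(unname(diag(sp)), rep(1, nrow(sp)))
})

test_that("cell-type draws follow the planted composition (binomial check)", {
  # 400 high-condition cells at target proportion 0.25: the number of true
  # target cells is Binomial(400, 0.25); over 200 seeds the mean must sit
  # within 3 standard errors of 100.
  pr <- list(low = c(A = 0.25, B = 0.75), high = c(A = 0.25, B = 0.75))
  counts <- vapply(seq_len(200), function(s) {
    tr <- simulation_truth(n_types = 2, type_names = c("A", "B"),
                           n_genes = 60, markers_per_type = 5,
                           proportions_by_condition = pr,
                           n_cells = c(low = 2, high = 400),
                           planted_axis = list(ligand = "IL6", receptor = "Il6ra",
                                               target_type = "A",
                                               receptor_fold = 1, ligand_ratio = 1),
                           seed = 1000 + s)
    m <- simulate_counts(tr)
    sum(m$true_type[m$condition == "high"] == "A")
  }, numeric(1))
  se <- sqrt(400 * 0.25 * 0.75) / sqrt(200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  expect_error(simulate_counts(small_truth(n_cells = c(low = 0, high = 10))),
               "empty matrix")
})

test_that("without planted effects the two conditions are exchangeable", {
  tr <- small_truth(n_types = 2, type_names = c("A", "B"), markers_per_type = 5,
                    n_genes = 60, marker_fold = 1, dropout_dispersion = 0,
                    planted_axis = list(ligand = "IL6", receptor = "Il6ra",
                                        target_type = "A",
                                        receptor_fold = 1, ligand_ratio = 1),
                    mito_fraction_mean = 0, seed = 21)
  m <- simulate_counts(tr)
  x <- as.matrix(m$counts)
  x <- x[rowSums(x) > 0, ]  # mito genes are switched off in this truth
  pvals <- apply(x, 1, function(g) {
    stats::t.test(g[m$condition == "high"], g[m$condition == "low"])$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("the planted receptor fold is recovered on the normalized scale", {
  pr <- list(low = c(A = 0.35, B = 0.65), high = c(A = 0.35, B = 0.65))
  tr <- simulation_truth(n_types = 2, type_names = c("A", "B"),
                         n_genes = 600, markers_per_type = 20,
                         proportions_by_condition = pr,
                         n_cells = c(low = 600, high = 600),
                         planted_axis = list(ligand = "IL6", receptor = "Il6ra",
                                             target_type = "A",
                                             receptor_fold = 1.21,
                                             ligand_ratio = 2.5),
                         seed = 8)
  m <- simulate_counts(tr)
  nm <- log_normalize(m)
  x <- expm1(as.numeric(nm$values["Il6ra", ]))
  hi <- m$condition == "high" & m$true_type == "A"
  lo <- m$condition == "low" & m$true_type == "A"
  expect_gte(min(sum(hi), sum(lo)), 150)
  ratio <- mean(x[hi]) / mean(x[lo])
  expect_gte(ratio, 1.10)
  expect_lte(ratio, 1.32)
})

test_that("secretome ratios are exact without noise and stable under noise", {
  tr <- small_truth()
  sec0 <- simulate_secretome(tr, noise_sd = 0)
  expect_equal(sec0$ratio[sec0$factor == "IL6"], 2.5)
  expect_equal(sec0$ratio[sec0$factor != "IL6"],
               rep(1, sum(sec0$factor != "IL6")))

  flat <- small_truth(planted_axis = list(ligand = "IL6", receptor = "Il6ra",
                                          target_type = "MDP",
                                          receptor_fold = 1, ligand_ratio = 1))
  sec1 <- simulate_secretome(flat, noise_sd = 0)
  expect_equal(sec1$ratio, rep(1, nrow(sec1)))

  ratios <- vapply(seq_len(100), function(s) {
    sec <- simulate_secretome(small_truth(seed = 5000 + s), noise_sd = 0.1)
    sec$ratio[sec$factor == "IL6"]
  }, numeric(1))
  expect_gte(median(ratios), 2.2)
  expect_lte(median(ratios), 2.8)
})

test_that("ligand-receptor tables deduplicate and keep the planted pair", {
  tb <- make_lr_table(list(c("IL6", "Il6ra"), c("IL6", "Il6st"),
                           c("IL6", "Il6ra")))
  expect_equal(nrow(tb), 2)
  expect_equal(nrow(make_lr_table(data.frame(ligand = "IL6",
                                             receptor = "Il6ra"))), 1)
  expect_warning(empty <- make_lr_table(list()), "empty")
  expect_equal(nrow(empty), 0)
  def <- default_lr_pairs()
  expect_true(any(def$ligand == "IL6" & def$receptor == "Il6ra"))
})
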