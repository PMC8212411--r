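# Toy matrix helper: `nz` detected genes per cell out of `n_genes`.
toy_cells <- function(nz, n_genes) {
  m <- matrix(0, n_genes, length(nz),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("cell%d", seq_along(nz))))
  for (j in seq_along(nz)) m[seq_len(nz[j]), j] <- 1
  count_matrix(m, condition = rep("low", length(nz)))
}

test_that("the detected-gene cell filter uses a strict 'less than' boundary", {
  m <- toy_cells(c(1200, 999, 1000), 1250)
  f <- suppressWarnings(filter_matrix(m, qc_params(min_cells_per_gene = 0,
                                                   max_mito_fraction = 1,
                                                   noncoding_gene_list = character(0))))
  expect_equal(colnames(f$counts), c("cell1", "cell3"))
  expect_equal(attr(f, "qc_summary")$low_complexity_cells_removed, 1)
})

test_that("genes must be detected in min_cells_per_gene surviving cells", {
  m <- count_matrix(matrix(c(1, 1, 0, 0,
                             5, 5, 5, 5), nrow = 2, byrow = TRUE,
                           dimnames = list(c("rare", "common"),
                                           paste0("c", 1:4))),
                    condition = rep("low", 4))
  f <- filter_matrix(m, qc_params(min_nonzero_genes_per_cell = 0,
                                  min_cells_per_gene = 3,
                                  noncoding_gene_list = character(0)))
  expect_equal(rownames(f$counts), "common")
})

test_that("cells above the mitochondrial fraction threshold are removed", {
  m <- count_matrix(matrix(c(90, 96, 10, 4), nrow = 2, byrow = TRUE,
                           dimnames = list(c("g1", "mt-Nd1"),
                                           c("hiMito", "ok"))),
                    condition = rep("low", 2))
  f <- filter_matrix(m, qc_params(min_nonzero_genes_per_cell = 0,
                                  min_cells_per_gene = 0,
                                  max_mito_fraction = 0.05,
                                  noncoding_gene_list = character(0)))
  expect_equal(colnames(f$counts), "ok")
  expect_equal(attr(f, "qc_summary")$high_mito_cells_removed, 1)
})

test_that("removing every cell is an error naming the responsible filter", {
  m <- toy_cells(c(10, 12), 100)
  expect_error(filter_matrix(m, qc_params(min_nonzero_genes_per_cell = 50,
                                          noncoding_gene_list = character(0))),
               "min_nonzero_genes_per_cell")
  expect_warning(filter_matrix(m, qc_params(min_nonzero_genes_per_cell = 0,
                                            min_cells_per_gene = 0)),
                 "non-coding")
})

test_that("noncoding genes are dropped first when a list is supplied", {
  m <- toy_cells(c(10, 12), 100)
  f <- filter_matrix(m, qc_params(min_nonzero_genes_per_cell = 0,
                                  min_cells_per_gene = 0,
                                  noncoding_gene_list = c("g0001", "g0002",
                                                          "not-present")))
  expect_equal(nrow(f$counts), 98)
  expect_equal(attr(f, "qc_summary")$noncoding_genes_removed, 2)
})

test_that("filtering is idempotent and monotone in the cell threshold", {
  m <- simulate_counts(small_truth(seed = 9))
  f1 <- filter_matrix(m, small_qc())
  f2 <- filter_matrix(f1, small_qc())
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  expect_identical(f1$condition, f2$condition)

  retained <- vapply(c(0, 50, 100, 200, 280), function(th) {
    ok <- tryCatch(ncol(filter_matrix(m, small_qc(min_nonzero_genes_per_cell = th))$counts),
                   error = function(e) 0L)
    as.integer(ok)
  }, integer(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("log-normalization follows log1p(count / total * scale)", {
  counts <- matrix(c(10, 0,
                     9990, 500), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), c("c1", "c2")))
  m <- count_matrix(counts, condition = c("low", "high"))
  nm <- log_normalize(m, scale_factor = 10000)
  expect_equal(nm$values["gA", "c1"], log(11))
  expect_equal(nm$values["gA", "c2"], 0)

  # scale invariance: doubling every count of a cell changes nothing
  m2 <- count_matrix(counts * 2, condition = c("low", "high"))
  expect_equal(as.matrix(log_normalize(m2)$values),
               as.matrix(nm$values))

  zero <- count_matrix(matrix(c(1, 0), 2, 1,
                              dimnames = list(c("gA", "gB"), "c1")),
                       condition = "low")
  zero$counts[1, 1] <- 0
  expect_error(log_normalize(zero), "zero total")
})

test_that("variable-gene selection ranks dispersed genes first", {
  n_cells <- 20
  vals <- matrix(1, 30, n_cells,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("c%02d", 1:n_cells)))
  vals["g15", ] <- rep(c(0, 2), length.out = n_cells)  # bimodal gene
  nm <- normalized_matrix(vals, condition = rep("low", n_cells))
  expect_equal(select_variable_genes(nm, 1), "g15")
  expect_setequal(select_variable_genes(nm, 30), rownames(vals))
  expect_warning(all_genes <- select_variable_genes(nm, 40), "returning all")
  expect_setequal(all_genes, rownames(vals))
})

test_that("marker genes dominate the variable-gene set on synthetic data", {
  # few markers relative to the universe, and bins wide enough that marker
  # and background genes share a mean bin (the simulator's two-level rates
  # otherwise separate them into pure bins where z-scoring is uninformative)
  tr <- small_truth(markers_per_type = 3, seed = 4)
  nm <- log_normalize(filter_matrix(simulate_counts(tr), small_qc()))
  hvg <- select_variable_genes(nm, 30, n_bins = 5)
  markers <- intersect(unlist(tr$markers), rownames(nm$values))
  expect_gte(mean(markers %in% hvg), 0.90)
})
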