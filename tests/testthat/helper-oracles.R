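# Independent oracles and small fixture builders used across the suite.

# Brute-force exact two-sided Wilcoxon rank-sum p-value: enumerate every
# assignment of the pooled ranks to group A and count splits at least as
# extreme on either side.
oracle_wilcoxon_exact <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  splits <- utils::combn(length(pooled), n_a)
  us <- apply(splits, 2, function(idx) sum(r[idx])) - n_a * (n_a + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Hand-rolled Benjamini-Hochberg step-up: p_(i) * m / i with monotone
# enforcement from the largest p downwards, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# A small, fast simulation configuration for unit tests.
small_truth <- function(...) {
  args <- list(n_types = 4, n_genes = 300, markers_per_type = 12,
               n_cells = c(low = 150, high = 150), seed = 42)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulation_truth, args)
}

small_qc <- function(...) {
  args <- list(min_nonzero_genes_per_cell = 50,
               noncoding_gene_list = character(0),
               n_variable_genes = 300)
  user <- list(...)
  args[names(user)] <- user
  do.call(qc_params, args)
}

# Manually assembled annotation table (all cells unpruned unless stated).
make_annotation <- function(best_type, condition, pruned = FALSE) {
  n <- length(best_type)
  structure(data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                       condition = condition,
                       best_type = best_type,
                       best_score = rep(0.9, n),
                       second_score = rep(0.1, n),
                       outlier_p = rep(0.001, n),
                       pruned = rep(pruned, length.out = n),
                       stringsAsFactors = FALSE),
            class = c("CellAnnotation", "data.frame"))
}
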