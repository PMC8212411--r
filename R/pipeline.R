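#' Validated configuration for the cross-talk discovery pipeline
#'
#' @param out_dir Directory for all written artifacts.
#' @param truth A \code{SimulationTruth} defining the synthetic inputs.
#' @param qc A \code{QCParams}.
#' @param B Bootstrap replicates for the proportion tests (>= 1000).
#' @param alpha Level of the reported BCa intervals.
#' @param direction Proportion-test direction (\code{"auto"},
#'   \code{"greater"} or \code{"less"}).
#' @param prune_alpha Annotation pruning threshold.
#' @param fold_threshold,min_detect Differential-expression prefilters.
#' @param padj_max,ratio_min Gates used by \code{\link{pair_and_rank}}.
#' @param secretome_noise_sd Densitometry noise of the simulated array.
#' @param seed Master seed for every random stage.
#' @return An object of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(out_dir = NULL,
                            truth = simulation_truth(),
                            qc = qc_params(noncoding_gene_list = character(0)),
                            B = 10000, alpha = 0.05, direction = "auto",
                            prune_alpha = 0.05,
                            fold_threshold = 1.2, min_detect = 0.10,
                            padj_max = 0.05, ratio_min = 1.0,
                            secretome_noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "SimulationTruth"), inherits(qc, "QCParams"))
  if (B < 1000) .stopf("B must be >= 1000 (got %d)", B)
  if (alpha <= 0 || alpha > 0.5) .stopf("alpha must lie in (0, 0.5]")
  if (!direction %in% c("auto", "greater", "less")) {
    .stopf("direction must be 'auto', 'greater' or 'less'")
  }
  if (min_detect < 0 || min_detect > 1 || padj_max <= 0 || padj_max > 1) {
    .stopf("min_detect and padj_max must be valid probabilities")
  }
  if (fold_threshold < 1) .stopf("fold_threshold must be >= 1")
  structure(list(out_dir = out_dir, truth = truth, qc = qc, B = B,
                 alpha = alpha, direction = direction,
                 prune_alpha = prune_alpha,
                 fold_threshold = fold_threshold, min_detect = min_detect,
                 padj_max = padj_max, ratio_min = ratio_min,
                 secretome_noise_sd = secretome_noise_sd,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the cross-talk discovery pipeline in memory
#'
#' Chains all stages on synthetic inputs: simulate counts, reference and
#' secretome; QC-filter and log-normalize; select variable genes; annotate
#' cells against the reference; test per-type proportion shifts (BCa
#' bootstrap); run per-type differential expression; and pair/rank
#' ligand-receptor axes. Identical configurations give identical results.
#'
#' @param cfg A \code{PipelineConfig} (its \code{out_dir} is ignored here).
#' @return A list with every intermediate artifact: \code{truth},
#'   \code{counts}, \code{reference}, \code{secretome}, \code{lr},
#'   \code{filtered}, \code{normalized}, \code{annotation},
#'   \code{proportions}, \code{proportion_tests}, \code{degs} (combined
#'   records for every type with enough cells), \code{skipped_types},
#'   \code{ranking}.
#' @export
discover_axes <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  truth <- cfg$truth
  counts <- simulate_counts(truth)
  ref <- generate_reference(truth, scale_factor = cfg$qc$scale_factor)
  sec <- array_ratios(simulate_secretome(truth, noise_sd = cfg$secretome_noise_sd))
  lr <- make_lr_table(truth$lr_pairs)

  filt <- filter_matrix(counts, cfg$qc)
  nm <- log_normalize(filt, cfg$qc$scale_factor)
  nm$variable_genes <- select_variable_genes(nm, cfg$qc$n_variable_genes)
  ann <- annotate(nm, ref, prune_alpha = cfg$prune_alpha)
  props <- celltype_proportions(ann)
  prop_tests <- test_all_proportions(ann, B = cfg$B, alpha = cfg$alpha,
                                     direction = cfg$direction,
                                     seed = .substream(cfg$seed, 57))

  keep <- !ann$pruned & !is.na(ann$best_type)
  types <- sort(unique(ann$best_type[keep]))
  degs <- list(); skipped <- character(0)
  for (ty in types) {
    n_low <- sum(keep & ann$best_type == ty & ann$condition == "low")
    n_high <- sum(keep & ann$best_type == ty & ann$condition == "high")
    if (n_low < 3 || n_high < 3) {
      skipped <- c(skipped, ty)
      next
    }
    degs[[ty]] <- differential_expression(nm, ann, ty,
                                          fold_threshold = cfg$fold_threshold,
                                          min_detect = cfg$min_detect)
  }
  degs <- if (length(degs)) do.call(rbind, degs) else
    structure(data.frame(cell_type = character(0), gene = character(0),
                         fold_change = numeric(0), pct_low = numeric(0),
                         pct_high = numeric(0), p_raw = numeric(0),
                         p_adj = numeric(0), stringsAsFactors = FALSE),
              class = c("DEGRecord", "data.frame"))
  rownames(degs) <- NULL
  ranking <- pair_and_rank(sec, degs, lr, ratio_min = cfg$ratio_min,
                           padj_max = cfg$padj_max)
  list(truth = truth, counts = counts, reference = ref, secretome = sec,
       lr = lr, filtered = filt, normalized = nm, annotation = ann,
       proportions = props, proportion_tests = prop_tests,
       degs = degs, skipped_types = skipped, ranking = ranking)
}

#' Rank of the planted ligand-receptor axis in a cross-talk ranking
#'
#' @param ranking A \code{CrosstalkRanking}.
#' @param truth The \code{SimulationTruth} that planted the axis.
#' @return The rank (1 = top) or \code{NA} if the axis was not recovered.
#' @export
planted_axis_rank <- function(ranking, truth) {
  stopifnot(inherits(truth, "SimulationTruth"))
  hit <- ranking$ligand == truth$planted_axis$ligand &
    tolower(ranking$receptor) == tolower(truth$planted_axis$receptor) &
    ranking$cell_type == truth$planted_axis$target_type
  if (any(hit)) ranking$rank[which(hit)[1L]] else NA_integer_
}

#' Run the pipeline and write all artifacts to disk
#'
#' Executes the six stages (simulate, qc, annotate, proportions, de,
#' crosstalk), writing each artifact under \code{cfg$out_dir} together with a
#' JSON manifest recording the package version, all parameters, the seed and
#' per-stage row counts. Rerunning with the same configuration reproduces
#' identical result files. If a stage fails, the partial artifacts are kept
#' and the manifest records the failure point before the error propagates.
#'
#' @param cfg A \code{PipelineConfig} with a non-\code{NULL} \code{out_dir}.
#' @return Invisibly, the list returned by \code{\link{discover_axes}} with
#'   the manifest added.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(cfg$out_dir)) .stopf("cfg$out_dir is required to run the pipeline")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "cytocrosstalk",
    version = as.character(utils::packageVersion("cytocrosstalk")),
    seed = cfg$seed,
    parameters = list(B = cfg$B, alpha = cfg$alpha, direction = cfg$direction,
                      prune_alpha = cfg$prune_alpha,
                      fold_threshold = cfg$fold_threshold,
                      min_detect = cfg$min_detect, padj_max = cfg$padj_max,
                      ratio_min = cfg$ratio_min,
                      secretome_noise_sd = cfg$secretome_noise_sd,
                      qc = unclass(cfg$qc)[c("min_nonzero_genes_per_cell",
                                             "min_cells_per_gene",
                                             "max_mito_fraction",
                                             "scale_factor",
                                             "n_variable_genes")]),
    stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- c(list(status = "completed"), res$info)
    res$value
  }

  sim <- stage("simulate", {
    write_truth(cfg$truth, file.path(cfg$out_dir, "truth.yaml"))
    counts <- simulate_counts(cfg$truth)
    write_count_matrix(counts, file.path(cfg$out_dir, "counts"))
    ref <- generate_reference(cfg$truth, scale_factor = cfg$qc$scale_factor)
    write_reference(ref, file.path(cfg$out_dir, "reference.csv"))
    sec <- array_ratios(simulate_secretome(cfg$truth,
                                           noise_sd = cfg$secretome_noise_sd))
    write_secretome(sec, file.path(cfg$out_dir, "secretome.csv"))
    lr <- make_lr_table(cfg$truth$lr_pairs)
    write_result_table(lr, file.path(cfg$out_dir, "lr_pairs.tsv"))
    list(value = list(counts = counts, ref = ref, sec = sec, lr = lr),
         info = list(cells = ncol(counts$counts), genes = nrow(counts$counts)))
  })

  qcres <- stage("qc", {
    filt <- filter_matrix(sim$counts, cfg$qc)
    jsonlite::write_json(attr(filt, "qc_summary"),
                         file.path(cfg$out_dir, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    nm <- log_normalize(filt, cfg$qc$scale_factor)
    nm$variable_genes <- select_variable_genes(nm, cfg$qc$n_variable_genes)
    list(value = list(filt = filt, nm = nm),
         info = list(cells = ncol(filt$counts), genes = nrow(filt$counts)))
  })

  ann <- stage("annotate", {
    a <- annotate(qcres$nm, sim$ref, prune_alpha = cfg$prune_alpha)
    write_result_table(a, file.path(cfg$out_dir, "annotations.tsv"))
    list(value = a, info = list(cells = nrow(a), pruned = sum(a$pruned)))
  })

  prop <- stage("proportions", {
    pt <- test_all_proportions(ann, B = cfg$B, alpha = cfg$alpha,
                               direction = cfg$direction,
                               seed = .substream(cfg$seed, 57))
    write_result_table(pt, file.path(cfg$out_dir, "proportion_tests.tsv"))
    list(value = pt, info = list(types = nrow(pt)))
  })

  degs <- stage("de", {
    keep <- !ann$pruned & !is.na(ann$best_type)
    types <- sort(unique(ann$best_type[keep]))
    out <- list()
    for (ty in types) {
      n_low <- sum(keep & ann$best_type == ty & ann$condition == "low")
      n_high <- sum(keep & ann$best_type == ty & ann$condition == "high")
      if (n_low >= 3 && n_high >= 3) {
        out[[ty]] <- differential_expression(nm = qcres$nm, ann = ann,
                                             cell_type = ty,
                                             fold_threshold = cfg$fold_threshold,
                                             min_detect = cfg$min_detect)
      }
    }
    d <- if (length(out)) do.call(rbind, out) else
      data.frame(cell_type = character(0), gene = character(0),
                 fold_change = numeric(0), pct_low = numeric(0),
                 pct_high = numeric(0), p_raw = numeric(0),
                 p_adj = numeric(0), stringsAsFactors = FALSE)
    rownames(d) <- NULL
    write_result_table(d, file.path(cfg$out_dir, "degs.tsv"))
    list(value = d, info = list(records = nrow(d),
                                types_tested = length(out)))
  })

  stage("crosstalk", {
    r <- pair_and_rank(sim$sec, degs, sim$lr, ratio_min = cfg$ratio_min,
                       padj_max = cfg$padj_max)
    write_result_table(r, file.path(cfg$out_dir, "crosstalk_ranking.tsv"))
    list(value = r,
         info = c(list(axes = nrow(r)), as.list(attr(r, "diagnostics"))))
  })
  write_manifest()

  out <- list(manifest = manifest, out_dir = cfg$out_dir)
  invisible(out)
}
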