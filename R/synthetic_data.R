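#' Default cytokine-receptor pair fixture
#'
#' A small curated mapping of secreted factors to mouse receptor gene symbols,
#' standing in for a cytokine-cytokine receptor interaction table. It contains
#' the IL6 -> Il6ra pair that the default simulation plants, plus a spread of
#' one-to-many (IL6 signals through both Il6ra and Il6st) and unrelated pairs.
#'
#' @return A two-column \code{data.frame} with columns \code{ligand} and
#'   \code{receptor}.
#' @export
default_lr_pairs <- function() {
  data.frame(
    ligand   = c("IL6", "IL6", "IL2", "IL3", "IL13", "CXCL1",
                 "CXCL10", "CSF1", "TNF", "CXCL12", "IL10", "VEGFA"),
    receptor = c("Il6ra", "Il6st", "Il2ra", "Il3ra", "Il13ra1", "Cxcr2",
                 "Cxcr3", "Csf1r", "Tnfrsf1a", "Cxcr4", "Il10ra", "Flt1"),
    stringsAsFactors = FALSE
  )
}

# The 13 protein-coding genes of the mouse mitochondrial genome; their "mt-"
# prefix is what the QC mito filter keys on.
.mito_gene_names <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                      "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                      "mt-Nd5", "mt-Nd6", "mt-Cytb")

# Canonical LSK progenitor compartment labels.
.default_type_names <- c("LT-HSC", "ST-HSC", "MPP", "MLP", "CLP",
                         "CMP", "GMP", "MDP", "CDP", "MEP")

.default_secretome_factors <- function(lr_pairs) {
  sort(unique(c(lr_pairs$ligand, "CCL2", "CCL5", "CXCL2", "TGFB1")))
}

# Default composition: the planted target type is enriched in the high
# condition (0.10 -> 0.25) while GMP shows the opposite shift, mirroring the
# MDP/GMP contrast of the study; remaining types share the rest evenly.
.default_proportions <- function(type_names, target) {
  low <- high <- stats::setNames(numeric(length(type_names)), type_names)
  if ("GMP" %in% type_names && target != "GMP") {
    others <- setdiff(type_names, c(target, "GMP"))
    low[target] <- 0.10; low["GMP"] <- 0.25
    high[target] <- 0.25; high["GMP"] <- 0.10
    low[others] <- 0.65 / length(others)
    high[others] <- 0.65 / length(others)
  } else {
    others <- setdiff(type_names, target)
    low[target] <- 0.10
    high[target] <- 0.25
    low[others] <- 0.90 / length(others)
    high[others] <- 0.75 / length(others)
  }
  list(low = low, high = high)
}

#' Define the ground truth of a synthetic cross-talk experiment
#'
#' Encodes everything the generator needs: the progenitor types and their
#' marker programs, the per-condition composition, the planted
#' ligand/receptor/cell-type axis, and the count-model parameters. Two
#' conditions are simulated by default (\code{low}, \code{high}, for tumours of
#' low and high metastatic potential); a third label can be added through
#' \code{n_cells} and \code{proportions_by_condition}.
#'
#' The gene universe is assembled deterministically from generic genes (from
#' which the disjoint marker programs are drawn), the receptor genes of
#' \code{lr_pairs}, and up to 13 mitochondrial genes (named \code{mt-*}) that
#' exist so the mito QC filter has something to act on. The planted receptor
#' must fit in the universe and the planted ligand must be a secretome factor.
#'
#' @param n_types Number of progenitor types (>= 2).
#' @param type_names Labels for the types.
#' @param n_genes Size of the gene universe.
#' @param markers_per_type Genes in each type's marker program (disjoint
#'   across types).
#' @param baseline_mean Expected rate of a non-marker gene (arbitrary rate
#'   units; rates are renormalized to the library size per cell).
#' @param marker_fold Multiplier (> =1) applied to a type's markers.
#' @param proportions_by_condition Named list \code{condition -> } named
#'   probability vector over types; each vector must sum to 1.
#' @param n_cells Named integer vector, cells to draw per condition.
#' @param planted_axis List with \code{ligand}, \code{receptor},
#'   \code{target_type}, \code{receptor_fold} (>= 1) and \code{ligand_ratio}
#'   (>= 1). The receptor's rate is multiplied by \code{receptor_fold} only in
#'   cells of \code{target_type} in the \code{high} condition.
#' @param library_size_mean Mean total counts per cell.
#' @param dropout_dispersion Negative-binomial dispersion (0 gives Poisson
#'   counts).
#' @param mito_fraction_mean Mean per-cell mitochondrial count fraction.
#' @param secretome_factors Factor labels measured on the simulated array.
#' @param lr_pairs Ligand-receptor pair table used to seed the gene universe.
#' @param seed Master seed; all generator randomness derives from it.
#' @return An object of class \code{SimulationTruth}. Besides the arguments it
#'   stores the derived gene universe (\code{gene_ids}), the marker ledger
#'   (\code{markers}, a list per type), and the mito/receptor gene sets.
#' @export
simulation_truth <- function(n_types = 10,
                             type_names = NULL,
                             n_genes = 2000,
                             markers_per_type = 30,
                             baseline_mean = 1,
                             marker_fold = 8,
                             proportions_by_condition = NULL,
                             n_cells = c(low = 400, high = 400),
                             planted_axis = list(ligand = "IL6",
                                                 receptor = "Il6ra",
                                                 target_type = "MDP",
                                                 receptor_fold = 1.21,
                                                 ligand_ratio = 2.5),
                             library_size_mean = 10000,
                             dropout_dispersion = 0.15,
                             mito_fraction_mean = 0.02,
                             secretome_factors = NULL,
                             lr_pairs = default_lr_pairs(),
                             seed = 1) {
  if (n_types < 2) .stopf("at least 2 cell types are required")
  if (is.null(type_names)) {
    type_names <- if (n_types <= length(.default_type_names)) {
      .default_type_names[seq_len(n_types)]
    } else {
      c(.default_type_names,
        sprintf("TYPE%02d", seq_len(n_types - length(.default_type_names))))
    }
  }
  if (length(type_names) != n_types || anyDuplicated(type_names)) {
    .stopf("type_names must be %d unique labels", n_types)
  }
  if (!all(c("ligand", "receptor", "target_type", "receptor_fold",
             "ligand_ratio") %in% names(planted_axis))) {
    .stopf("planted_axis is missing fields")
  }
  if (!planted_axis$target_type %in% type_names) {
    # fall back to the first type for small bespoke configurations
    planted_axis$target_type <- type_names[[1L]]
  }
  if (planted_axis$receptor_fold < 1 || planted_axis$ligand_ratio < 1) {
    .stopf("planted receptor_fold and ligand_ratio must be >= 1")
  }
  if (marker_fold < 1) .stopf("marker_fold must be >= 1")
  if (baseline_mean <= 0) .stopf("baseline_mean must be positive")
  if (dropout_dispersion < 0) .stopf("dropout_dispersion must be >= 0")
  if (mito_fraction_mean < 0 || mito_fraction_mean >= 1) {
    .stopf("mito_fraction_mean must lie in [0, 1)")
  }
  secretome_factors <- secretome_factors %||% .default_secretome_factors(lr_pairs)
  if (!planted_axis$ligand %in% secretome_factors) {
    .stopf("planted ligand '%s' is not in the secretome factor list",
           planted_axis$ligand)
  }

  # --- deterministic gene universe ------------------------------------------
  n_markers <- n_types * markers_per_type
  receptors <- unique(c(planted_axis$receptor, lr_pairs$receptor))
  room <- n_genes - n_markers
  if (room < 1) {
    .stopf("invalid configuration: %d marker genes exceed the %d-gene universe",
           n_markers, n_genes)
  }
  receptors <- receptors[seq_len(min(length(receptors), room))]
  if (!planted_axis$receptor %in% receptors) {
    .stopf("invalid configuration: no room for the planted receptor gene")
  }
  n_mito <- min(length(.mito_gene_names), room - length(receptors))
  mito <- .mito_gene_names[seq_len(n_mito)]
  n_generic <- n_genes - length(receptors) - n_mito
  if (n_generic < n_markers) {
    .stopf("invalid configuration: marker assignment exceeds the gene universe")
  }
  generic <- sprintf("G%05d", seq_len(n_generic))
  gene_ids <- c(generic, receptors, mito)
  markers <- if (markers_per_type > 0) {
    stats::setNames(split(generic[seq_len(n_markers)],
                          rep(seq_len(n_types), each = markers_per_type)),
                    type_names)
  } else {
    stats::setNames(rep(list(character(0)), n_types), type_names)
  }

  props <- proportions_by_condition %||%
    .default_proportions(type_names, planted_axis$target_type)
  for (cond in names(props)) {
    p <- props[[cond]]
    if (is.null(names(p)) || !setequal(names(p), type_names)) {
      .stopf("proportions for condition '%s' must be named by type", cond)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      .stopf("proportions for condition '%s' must sum to 1 (got %.15f)",
             cond, sum(p))
    }
    props[[cond]] <- p[type_names]
  }
  n_cells <- n_cells[names(props)]
  if (anyNA(n_cells)) .stopf("n_cells must name every simulated condition")

  structure(list(
    n_types = n_types, type_names = type_names,
    n_genes = n_genes, markers_per_type = markers_per_type,
    baseline_mean = baseline_mean, marker_fold = marker_fold,
    proportions_by_condition = props, n_cells = n_cells,
    planted_axis = planted_axis,
    library_size_mean = library_size_mean,
    dropout_dispersion = dropout_dispersion,
    mito_fraction_mean = mito_fraction_mean,
    secretome_factors = secretome_factors,
    lr_pairs = lr_pairs, seed = as.integer(seed),
    gene_ids = gene_ids, markers = markers,
    mito_genes = mito, receptor_genes = receptors
  ), class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf(paste0(
    "SimulationTruth: %d types, %d genes (%d markers/type, fold %.3g)\n",
    "  planted axis: %s -> %s on %s (receptor fold %.3g, ligand ratio %.3g)\n",
    "  cells: %s; seed %d\n"),
    x$n_types, x$n_genes, x$markers_per_type, x$marker_fold,
    x$planted_axis$ligand, x$planted_axis$receptor,
    x$planted_axis$target_type, x$planted_axis$receptor_fold,
    x$planted_axis$ligand_ratio,
    paste(sprintf("%s=%d", names(x$n_cells), x$n_cells), collapse = ", "),
    x$seed))
  invisible(x)
}

# Expected expression rate of every gene in every type (rate units; marker
# genes are boosted, everything else sits at baseline).
.base_rates <- function(truth) {
  r <- matrix(truth$baseline_mean, length(truth$gene_ids), truth$n_types,
              dimnames = list(truth$gene_ids, truth$type_names))
  for (ty in truth$type_names) {
    mk <- truth$markers[[ty]]
    if (length(mk)) r[mk, ty] <- truth$baseline_mean * truth$marker_fold
  }
  r
}

#' Build the reference compendium matching a simulation truth
#'
#' One expression profile per cell type on the same normalized log scale the
#' annotation step scores on: each type's marker genes sit at
#' \code{baseline_mean * marker_fold}, all other genes at \code{baseline_mean},
#' and the rate vector is converted to log1p(CP10K-style) units.
#'
#' @param truth A \code{SimulationTruth}.
#' @param scale_factor Library-size scale used for the normalized profiles.
#' @return An object of class \code{ReferenceCompendium}: list with
#'   \code{profiles} (type x gene matrix), \code{type_names}, \code{gene_ids}.
#' @export
generate_reference <- function(truth, scale_factor = 10000) {
  stopifnot(inherits(truth, "SimulationTruth"))
  r <- .base_rates(truth)
  prof <- t(log1p(sweep(r, 2, colSums(r), "/") * scale_factor))
  structure(list(profiles = prof, type_names = truth$type_names,
                 gene_ids = truth$gene_ids),
            class = "ReferenceCompendium")
}

#' @export
print.ReferenceCompendium <- function(x, ...) {
  cat(sprintf("ReferenceCompendium: %d types x %d genes\n",
              length(x$type_names), length(x$gene_ids)))
  invisible(x)
}

#' Simulate a single-cell count matrix with planted structure
#'
#' For each condition, cell types are drawn from the condition's composition,
#' per-cell library sizes from a log-normal around \code{library_size_mean},
#' and counts from a negative binomial (Poisson when
#' \code{dropout_dispersion = 0}) around the type's rate profile. Cells of the
#' planted target type in the \code{high} condition have the planted receptor
#' gene's rate multiplied by \code{receptor_fold}. Each cell's mitochondrial
#' count fraction is Beta-distributed around \code{mito_fraction_mean} so the
#' mito QC filter is exercisable. The generator is a pure function of
#' \code{truth}: identical truth (including seed) gives identical counts.
#'
#' @param truth A \code{SimulationTruth}.
#' @return A \code{CountMatrix} with \code{true_type} recorded.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "SimulationTruth"))
  if (any(truth$n_cells < 1)) {
    .stopf("empty matrix requested: every condition needs at least one cell")
  }
  rates <- .base_rates(truth)
  mito <- truth$mito_genes
  nonmito <- setdiff(truth$gene_ids, mito)
  disp <- truth$dropout_dispersion
  blocks <- vector("list", length(truth$n_cells))
  names(blocks) <- names(truth$n_cells)

  for (ci in seq_along(truth$n_cells)) {
    cond <- names(truth$n_cells)[ci]
    n <- truth$n_cells[[ci]]
    blocks[[cond]] <- .with_seed(.substream(truth$seed, 11 + ci), {
      types <- sample(truth$type_names, n, replace = TRUE,
                      prob = truth$proportions_by_condition[[cond]])
      lib <- pmax(200, round(stats::rlnorm(n, log(truth$library_size_mean) - 0.02, 0.2)))
      mfrac <- if (length(mito) && truth$mito_fraction_mean > 0) {
        stats::rbeta(n, truth$mito_fraction_mean * 100,
                     (1 - truth$mito_fraction_mean) * 100)
      } else {
        numeric(n)
      }
      cr <- rates
      if (cond == "high") {
        cr[truth$planted_axis$receptor, truth$planted_axis$target_type] <-
          cr[truth$planted_axis$receptor, truth$planted_axis$target_type] *
          truth$planted_axis$receptor_fold
      }
      mu <- cr[, types, drop = FALSE]
      sc <- (1 - mfrac) * lib / colSums(mu[nonmito, , drop = FALSE])
      mu[nonmito, ] <- sweep(mu[nonmito, , drop = FALSE], 2, sc, "*")
      if (length(mito)) {
        mu[mito, ] <- matrix(rep(mfrac * lib / length(mito), each = length(mito)),
                             nrow = length(mito))
      }
      cnt <- if (disp == 0) {
        stats::rpois(length(mu), lambda = mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
      }
      dim(cnt) <- dim(mu)
      dimnames(cnt) <- dimnames(mu)
      colnames(cnt) <- sprintf("%s_cell%05d", cond, seq_len(n))
      list(counts = cnt, types = types)
    })
  }
  counts <- do.call(cbind, lapply(blocks, `[[`, "counts"))
  .new_count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                    condition = rep(names(truth$n_cells), truth$n_cells),
                    true_type = unlist(lapply(blocks, `[[`, "types"),
                                      use.names = FALSE))
}

#' Simulate a two-condition secreted-factor densitometry table
#'
#' Densitometry readings for both conditions with multiplicative log-normal
#' noise; the planted ligand's high/low ratio is centred on the truth's
#' \code{ligand_ratio}, every other factor on 1.
#'
#' @param truth A \code{SimulationTruth}.
#' @param noise_sd Log-scale standard deviation of the densitometry noise
#'   (0 gives exact ratios).
#' @return A \code{data.frame} with columns \code{factor}, \code{dens_low},
#'   \code{dens_high}, \code{ratio}.
#' @export
simulate_secretome <- function(truth, noise_sd = 0.1) {
  stopifnot(inherits(truth, "SimulationTruth"))
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  fac <- truth$secretome_factors
  ratio_par <- ifelse(fac == truth$planted_axis$ligand,
                      truth$planted_axis$ligand_ratio, 1)
  .with_seed(.substream(truth$seed, 31), {
    dens_low <- 1000 * exp(stats::rnorm(length(fac), 0, noise_sd))
    dens_high <- 1000 * ratio_par * exp(stats::rnorm(length(fac), 0, noise_sd))
    data.frame(factor = fac, dens_low = dens_low, dens_high = dens_high,
               ratio = dens_high / dens_low, stringsAsFactors = FALSE)
  })
}

#' Build a deduplicated ligand-receptor pair table
#'
#' @param pairs A two-column \code{data.frame}/matrix (ligand, receptor) or a
#'   list of length-2 vectors.
#' @return A deduplicated \code{data.frame} with columns \code{ligand} and
#'   \code{receptor}. Ligand-to-receptor is one-to-many and
#'   receptor-to-ligand many-to-one; both are allowed.
#' @export
make_lr_table <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      if (length(p) != 2) .stopf("each ligand-receptor pair needs 2 entries")
      data.frame(ligand = p[[1]], receptor = p[[2]], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairs) || NROW(pairs) == 0) {
    .warnf("empty ligand-receptor input: returning an empty table")
    return(data.frame(ligand = character(0), receptor = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) .stopf("ligand-receptor table needs two columns")
  names(pairs)[1:2] <- c("ligand", "receptor")
  pairs$ligand <- as.character(pairs$ligand)
  pairs$receptor <- as.character(pairs$receptor)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    .stopf("ligand and receptor labels must be non-empty")
  }
  out <- unique(pairs[, c("ligand", "receptor")])
  rownames(out) <- NULL
  out
}
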