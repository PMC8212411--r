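# Readers and writers. Fixed dialect: TSV with header rows, "." for missing
# values, UTF-8, LF line endings; gene symbol case is preserved on output.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a count matrix as Matrix Market plus TSV sidecars
#'
#' Writes \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv}
#' (one id per line, no header) and \code{cells.tsv} (header:
#' \code{barcode}, \code{condition}, \code{true_type}; missing true types
#' written as \code{.}).
#'
#' @param m A \code{CountMatrix}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  .write_tsv(data.frame(barcode = colnames(m$counts),
                        condition = m$condition,
                        true_type = m$true_type %||%
                          rep(NA_character_, ncol(m$counts)),
                        stringsAsFactors = FALSE),
             file.path(dir, "cells.tsv"))
  invisible(dir)
}

.check_integer_counts <- function(x, what) {
  xs <- if (inherits(x, "sparseMatrix")) methods::as(x, "CsparseMatrix")@x else x
  bad <- which(xs != round(xs))
  if (length(bad)) {
    .stopf("%s contains a non-integer entry (value %g); counts must be whole numbers",
           what, xs[bad[1L]])
  }
}

#' Read a count matrix
#'
#' Accepts either a Matrix Market triplet directory (as written by
#' \code{\link{write_count_matrix}}) or a dense CSV (first column gene ids,
#' remaining columns one cell each) with a \code{cells.tsv} metadata file.
#' Whole-valued entries stored as reals (e.g. \code{2.0}) are accepted as
#' integers; fractional entries are an error.
#'
#' @param path Directory (MTX) or CSV file.
#' @param cells_path Cell metadata file for the CSV form; defaults to
#'   \code{cells.tsv} next to the CSV.
#' @return A validated \code{CountMatrix}.
#' @export
read_count_matrix <- function(path, cells_path = NULL) {
  if (dir.exists(path)) {
    mm <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(mm) != length(genes) || ncol(mm) != length(barcodes)) {
      .stopf("matrix is %d x %d but sidecars list %d genes and %d barcodes",
             nrow(mm), ncol(mm), length(genes), length(barcodes))
    }
    if (anyDuplicated(barcodes)) {
      .stopf("duplicate barcode '%s' in barcodes.tsv",
             barcodes[duplicated(barcodes)][1L])
    }
    .check_integer_counts(mm, "matrix.mtx")
    cells <- .read_tsv(file.path(path, "cells.tsv"))
    if (!all(c("barcode", "condition") %in% names(cells))) {
      .stopf("cells.tsv needs 'barcode' and 'condition' columns")
    }
    if (anyDuplicated(cells$barcode)) {
      .stopf("duplicate barcode '%s' in cells.tsv",
             cells$barcode[duplicated(cells$barcode)][1L])
    }
    idx <- match(barcodes, cells$barcode)
    if (anyNA(idx)) .stopf("cells.tsv is missing barcode '%s'",
                           barcodes[which(is.na(idx))[1L]])
    tt <- cells$true_type[idx]
    count_matrix(mm, condition = cells$condition[idx],
                 gene_ids = genes, cell_ids = barcodes,
                 true_type = if (all(is.na(tt))) NULL else tt)
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) .stopf("dense CSV contains non-numeric entries")
    .check_integer_counts(mat, basename(path))
    rownames(mat) <- genes
    cells_path <- cells_path %||% file.path(dirname(path), "cells.tsv")
    if (!file.exists(cells_path)) {
      .stopf("cell metadata file '%s' not found", cells_path)
    }
    cells <- .read_tsv(cells_path)
    idx <- match(colnames(mat), cells$barcode)
    if (anyNA(idx)) .stopf("cells metadata is missing barcode '%s'",
                           colnames(mat)[which(is.na(idx))[1L]])
    tt <- cells$true_type[idx]
    count_matrix(mat, condition = cells$condition[idx],
                 true_type = if (is.null(tt) || all(is.na(tt))) NULL else tt)
  } else {
    .stopf("count matrix path '%s' does not exist", path)
  }
}

#' Write / read a reference compendium as CSV
#'
#' The CSV has one row per type: a \code{type} column followed by one column
#' per gene.
#'
#' @param ref A \code{ReferenceCompendium}.
#' @param path CSV file path.
#' @return \code{path} (write) or a \code{ReferenceCompendium} (read).
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ReferenceCompendium"))
  df <- data.frame(type = ref$type_names, as.data.frame(ref$profiles),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  prof <- as.matrix(df[, -1, drop = FALSE])
  rownames(prof) <- df$type
  structure(list(profiles = prof, type_names = df$type,
                 gene_ids = colnames(prof)),
            class = "ReferenceCompendium")
}

#' Write / read a secretome densitometry table as CSV
#' @param sec Secretome \code{data.frame}.
#' @param path CSV file path.
#' @export
write_secretome <- function(sec, path) {
  utils::write.csv(sec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_secretome
#' @export
read_secretome <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Serialize a simulation truth to YAML or JSON
#'
#' Only the defining parameters are written; reading reconstructs the full
#' object (gene universe, marker ledger) through
#' \code{\link{simulation_truth}}, so a round trip is exact.
#'
#' @param truth A \code{SimulationTruth}.
#' @param path File ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SimulationTruth"))
  spec <- list(
    n_types = truth$n_types, type_names = truth$type_names,
    n_genes = truth$n_genes, markers_per_type = truth$markers_per_type,
    baseline_mean = truth$baseline_mean, marker_fold = truth$marker_fold,
    proportions_by_condition = lapply(truth$proportions_by_condition, as.list),
    n_cells = as.list(truth$n_cells),
    planted_axis = truth$planted_axis,
    library_size_mean = truth$library_size_mean,
    dropout_dispersion = truth$dropout_dispersion,
    mito_fraction_mean = truth$mito_fraction_mean,
    secretome_factors = truth$secretome_factors,
    lr_pairs = list(ligand = truth$lr_pairs$ligand,
                    receptor = truth$lr_pairs$receptor),
    seed = truth$seed)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(spec, path)
  } else {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  simulation_truth(
    n_types = spec$n_types,
    type_names = unlist(spec$type_names),
    n_genes = spec$n_genes,
    markers_per_type = spec$markers_per_type,
    baseline_mean = spec$baseline_mean,
    marker_fold = spec$marker_fold,
    proportions_by_condition = lapply(spec$proportions_by_condition, unlist),
    n_cells = unlist(spec$n_cells),
    planted_axis = as.list(spec$planted_axis),
    library_size_mean = spec$library_size_mean,
    dropout_dispersion = spec$dropout_dispersion,
    mito_fraction_mean = spec$mito_fraction_mean,
    secretome_factors = unlist(spec$secretome_factors),
    lr_pairs = data.frame(ligand = unlist(spec$lr_pairs$ligand),
                          receptor = unlist(spec$lr_pairs$receptor),
                          stringsAsFactors = FALSE),
    seed = spec$seed)
}

#' Write / read result tables (annotations, DE records, rankings) as TSV
#' @param df A result \code{data.frame}.
#' @param path TSV file path.
#' @export
write_result_table <- function(df, path) {
  .write_tsv(as.data.frame(df), path)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  .read_tsv(path)
}
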