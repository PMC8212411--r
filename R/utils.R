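# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive a reproducible sub-stream seed from a master seed. Fixed offsets give
# each stage (reference, counts per condition, secretome, bootstraps, ...) an
# independent stream while keeping everything a function of one master seed.
# Result stays strictly inside the 32-bit signed range set.seed() requires.
.substream <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * abs(offset)) %% 2147483629)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Column-wise midranks (ties.method = "average") through data.table's
# C-level ranking; returns a matrix shaped like the input.
.col_midranks <- function(x) {
  r <- vapply(seq_len(ncol(x)),
              function(j) data.table::frank(x[, j], ties.method = "average"),
              numeric(nrow(x)))
  dimnames(r) <- dimnames(x)
  r
}

# expm1 on a sparse matrix without densifying (expm1(0) == 0).
.expm1_sparse <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    x@x <- expm1(x@x)
    x
  } else {
    expm1(x)
  }
}
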