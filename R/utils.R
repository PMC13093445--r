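# Helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so package randomness never perturbs (or is
#' perturbed by) surrounding code. A `NULL` seed evaluates `expr` with
#' the ambient RNG.
#'
#' @param seed integer seed, or `NULL` for no seeding.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a deterministic sub-seed
#'
#' Maps a master seed and an offset to a sub-seed inside the 32-bit
#' integer range, so that independent stochastic stages of a workflow
#' can each get their own reproducible stream from one master seed.
#'
#' @param seed integer master seed.
#' @param offset integer stage offset.
#' @return An integer sub-seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# Squared Euclidean distances between rows of X (n x d) and C (k x d).
pairDist2 <- function(X, C) {
  X <- as.matrix(X); C <- as.matrix(C)
  if (ncol(X) != ncol(C)) {
    stop("dimension mismatch: inputs have ", ncol(X),
         " columns, centers have ", ncol(C))
  }
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

# Numeric predictor matrix for the named columns of a TraitTable.
# Categorical columns must already be integer-encoded.
predictorMatrix <- function(table, columns) {
  v <- traitValues(table)
  missingCols <- setdiff(columns, colnames(v))
  if (length(missingCols)) {
    stop("columns not present in table: ", paste(missingCols, collapse = ", "))
  }
  bad <- columns[!vapply(v[columns], is.numeric, logical(1))]
  if (length(bad)) {
    stop("columns must be numeric (encode categoricals first): ",
         paste(bad, collapse = ", "))
  }
  as.matrix(v[, columns, drop = FALSE])
}

# Row indices where every named column is observed.
completeRows <- function(table, columns) {
  m <- observedMask(table)
  which(rowSums(!m[, columns, drop = FALSE]) == 0L)
}

# Subset a TraitTable by row index, preserving kinds/tags.
subsetRows <- function(table, idx) {
  TraitTable(
    values = traitValues(table)[idx, , drop = FALSE],
    columnKinds = columnKinds(table),
    observed = observedMask(table)[idx, , drop = FALSE],
    scaleTags = scaleTags(table)
  )
}
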