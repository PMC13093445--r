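#' K-means clustering of training inputs for RBF center initialization
#'
#' Lloyd's algorithm from k-means++ seeding, restarted `nInit` times with
#' the best restart (lowest within-cluster sum of squares) returned.
#' Within each restart the inertia trace is non-increasing. Clusters are
#' never left empty: when an update empties a cluster, the point farthest
#' from its current centroid is promoted to a new centroid. Deterministic
#' given the seed.
#'
#' @param X n x d numeric matrix.
#' @param k number of clusters (1..n); values above n are clamped with a
#'   warning.
#' @param seed integer seed for the restart protocol.
#' @param maxIter iteration cap per restart.
#' @param nInit number of seeded restarts.
#' @param tol convergence tolerance on total centroid movement.
#' @return A [KMeansResult-class].
#' @examples
#' res <- kmeansFit(matrix(c(0, 1, 10, 11)), k = 2, seed = 1)
#' sort(as.numeric(centroids(res)))  # 0.5 10.5
#' inertia(res)                      # 1
#' @export
kmeansFit <- function(X, k, seed = 1L, maxIter = 300L, nInit = 10L,
                      tol = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) {
    warning("k = ", k, " exceeds the number of points; clamped to ", n)
    k <- n
  }
  k <- as.integer(k)
  best <- NULL
  for (r in seq_len(nInit)) {
    fit <- withSeed(deriveSeed(seed, r), lloydOnce(X, k, maxIter, tol))
    if (is.null(best) || fit$inertia < best$inertia) {
      best <- fit
      best$restart <- r
    }
  }
  new("KMeansResult",
      centroids = best$centroids,
      assignments = as.integer(best$assignments),
      inertia = best$inertia,
      nIter = as.integer(best$nIter),
      inertiaTrace = best$trace,
      seed = as.integer(seed))
}

# One Lloyd run from a k-means++ initialization (uses the active RNG for
# seeding only; the iteration kernel is compiled and deterministic).
lloydOnce <- function(X, k, maxIter, tol) {
  init <- kmeansPlusPlus(X, k)
  fit <- .lloyd_cpp(X, init, as.integer(maxIter), tol)
  list(centroids = fit$centroids, assignments = fit$assignments,
       inertia = fit$inertia, nIter = fit$nIter, trace = fit$trace)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to the squared distance to the nearest chosen center. The
# uniform variates come from R's RNG; selection runs in compiled code.
kmeansPlusPlus <- function(X, k) {
  u <- stats::runif(k)
  .kmeanspp_cpp(X, as.integer(k), u)
}

#' @rdname accessors
#' @aliases centroids,KMeansResult-method
setMethod("centroids", "KMeansResult", function(x) x@centroids)

#' @rdname accessors
#' @aliases assignments,KMeansResult-method
setMethod("assignments", "KMeansResult", function(x) x@assignments)

#' @rdname accessors
#' @aliases inertia,KMeansResult-method
setMethod("inertia", "KMeansResult", function(x) x@inertia)

setMethod("show", "KMeansResult", function(object) {
  cat(sprintf(
    "KMeansResult: k = %d, n = %d points, inertia = %g (%d iterations)\n",
    nrow(object@centroids), length(object@assignments), object@inertia,
    object@nIter))
})

#' Canonically ordered RBF centers from a K-means fit
#'
#' The basis functions are centered at the data-driven centroids. Rows
#' are returned sorted by first coordinate, ties broken lexicographically
#' by the remaining coordinates, so that equivalent clusterings yield
#' identical center matrices regardless of label order.
#'
#' @param result a [KMeansResult-class].
#' @return k x d numeric matrix of centers.
#' @export
centersFromKmeans <- function(result) {
  C <- centroids(result)
  ord <- do.call(order, as.data.frame(C))
  C[ord, , drop = FALSE]
}
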