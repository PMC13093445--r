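#' Hyperparameter search space for the RBF network
#'
#' The network has two tuned hyperparameters: the number of basis
#' functions k (which equals the number of K-means clusters) and the
#' kernel width gamma. Defaults are k in [10, 25] (integer), gamma in
#' [0.05, 0.5] (continuous) and a budget of 10 objective evaluations per
#' feature combination, of which the first `nInitial` form a seeded
#' space-filling initial design.
#'
#' @param kBounds integer interval `c(lo, hi)`.
#' @param gammaBounds continuous interval `c(lo, hi)`.
#' @param nCalls total objective evaluations (initial design included).
#' @param nInitial size of the initial design (< nCalls, or equal for
#'   pure random search).
#' @param seed integer seed.
#' @return A `SearchSpace` list.
#' @export
searchSpace <- function(kBounds = c(10L, 25L), gammaBounds = c(0.05, 0.5),
                        nCalls = 10L, nInitial = 5L, seed = 1L) {
  stopifnot(length(kBounds) == 2L, kBounds[1] <= kBounds[2],
            length(gammaBounds) == 2L, gammaBounds[1] < gammaBounds[2],
            gammaBounds[1] > 0, nCalls >= 1L, nInitial >= 1L,
            nInitial <= nCalls)
  structure(list(kBounds = as.integer(round(kBounds)),
                 gammaBounds = as.numeric(gammaBounds),
                 nCalls = as.integer(nCalls),
                 nInitial = as.integer(nInitial),
                 seed = as.integer(seed)),
            class = "SearchSpace")
}

#' Tuning objective: negative validation R-squared
#'
#' One evaluation of the inner loop for a proposed (k, gamma): run
#' K-means with k clusters on the training inputs, center the basis
#' functions at the (canonically ordered) centroids, train the output
#' weights, predict the validation targets, and return the negative
#' coefficient of determination so that lower is better. A training
#' divergence is caught and reported as an infinite objective so the
#' surrounding search can continue.
#'
#' @param k number of basis functions / clusters.
#' @param gamma kernel width.
#' @param train,val lists with elements `x` (matrix) and `y` (vector);
#'   see [preparedData()].
#' @param config a [trainConfig()].
#' @param cache optional environment memoizing the K-means centers per k
#'   across the calls of one search (the clustering depends only on the
#'   training inputs, k and the seed).
#' @return `list(objective = -R2_val, model = trained RBFModel)`.
#' @export
rbfObjective <- function(k, gamma, train, val, config = trainConfig(),
                         cache = NULL) {
  k <- as.integer(round(k))
  if (k < 1L) stop("k must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  out <- tryCatch({
    key <- as.character(k)
    centers <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      km <- kmeansFit(train$x, k, seed = deriveSeed(config$seed, 104729L))
      cs <- centersFromKmeans(km)
      if (!is.null(cache)) cache[[key]] <- cs
      cs
    }
    model <- RBFModel(centers = centers, gamma = gamma,
                      featureNames = colnames(train$x) %||% character())
    fit <- trainRBF(model, train$x, train$y, config)
    pred <- rbfForward(fit$model, val$x)
    list(objective = -rSquared(val$y, pred), model = fit$model)
  }, error = function(e) {
    message("objective evaluation failed for k = ", k, ", gamma = ", gamma,
            ": ", conditionMessage(e))
    list(objective = Inf, model = NULL)
  })
  out
}

#' Bundle a predictor matrix and target vector
#'
#' @param table a [TraitTable-class] (log-transformed, encoded).
#' @param target continuous target column.
#' @param features predictor columns.
#' @param rows optional row subset; defaults to rows where target and all
#'   features are observed.
#' @return `list(x = matrix, y = numeric, rows = integer)`.
#' @export
preparedData <- function(table, target, features, rows = NULL) {
  if (is.null(rows)) rows <- completeRows(table, c(target, features))
  x <- predictorMatrix(table, features)[rows, , drop = FALSE]
  y <- traitValues(table)[[target]][rows]
  list(x = x, y = as.numeric(y), rows = rows)
}

#' Bayesian optimization of (k, gamma) with a GP surrogate
#'
#' Evaluates `nInitial` seeded Latin-hypercube points, then proposes the
#' remaining `nCalls - nInitial` points sequentially by maximizing
#' expected improvement under a Gaussian-process surrogate (Matern-5/2
#' kernel with per-dimension length scales, fitted by marginal
#' likelihood, on inputs rescaled to the unit box). The integer dimension
#' k is handled by continuous relaxation with rounding; a proposal that
#' duplicates an evaluated point is perturbed to the nearest unevaluated
#' k. Infinite objective values (failed evaluations) are excluded from
#' the surrogate.
#'
#' @param space a [searchSpace()].
#' @param objective function `(k, gamma) ->` either a numeric scalar or a
#'   list with elements `objective` and (optionally) `model`.
#' @return A [BOResult-class]; the incumbent is the trace minimum and its
#'   model (when the objective supplies one) is retained from that
#'   evaluation, with no retraining.
#' @export
bayesOptimize <- function(space, objective) {
  stopifnot(inherits(space, "SearchSpace"))
  kb <- space$kBounds
  gb <- space$gammaBounds
  evalPoint <- function(k, gamma) {
    res <- objective(k, gamma)
    if (is.numeric(res)) res <- list(objective = as.numeric(res), model = NULL)
    res
  }
  toK <- function(u) pmin(kb[2], pmax(kb[1], as.integer(round(
    kb[1] + u * (kb[2] - kb[1])))))
  toGamma <- function(u) gb[1] + u * (gb[2] - gb[1])
  design <- withSeed(space$seed, lhs::randomLHS(space$nInitial, 2L))
  ks <- toK(design[, 1])
  gammas <- toGamma(design[, 2])
  trace <- data.frame(k = integer(0), gamma = numeric(0),
                      objective = numeric(0))
  models <- list()
  for (i in seq_len(space$nInitial)) {
    res <- evalPoint(ks[i], gammas[i])
    trace <- rbind(trace, data.frame(k = ks[i], gamma = gammas[i],
                                     objective = res$objective))
    models[[i]] <- res$model
  }
  nRemain <- space$nCalls - space$nInitial
  for (it in seq_len(max(0L, nRemain))) {
    fin <- is.finite(trace$objective)
    prop <- if (sum(fin) >= 2L) {
      proposeEI(trace[fin, , drop = FALSE], kb, gb,
                seed = deriveSeed(space$seed, 300L + it))
    } else {
      u <- withSeed(deriveSeed(space$seed, 600L + it), stats::runif(2))
      c(k = toK(u[1]), gamma = toGamma(u[2]))
    }
    kProp <- as.integer(prop["k"])
    gProp <- as.numeric(prop["gamma"])
    # avoid re-evaluating an already-seen configuration
    dup <- function(k, g) any(trace$k == k & abs(trace$gamma - g) < 1e-9)
    if (dup(kProp, gProp)) {
      allK <- kb[1]:kb[2]
      unseen <- allK[!vapply(allK, function(kk) dup(kk, gProp), logical(1))]
      if (length(unseen)) {
        kProp <- unseen[which.min(abs(unseen - kProp))]
      } else {
        gProp <- min(gb[2], max(gb[1], gProp + (gb[2] - gb[1]) * 1e-3))
      }
    }
    res <- evalPoint(kProp, gProp)
    trace <- rbind(trace, data.frame(k = kProp, gamma = gProp,
                                     objective = res$objective))
    models[[nrow(trace)]] <- res$model
  }
  fin <- which(is.finite(trace$objective))
  if (!length(fin)) stop("all objective evaluations failed")
  bestIdx <- fin[which.min(trace$objective[fin])]
  new("BOResult",
      trace = trace,
      incumbent = c(k = trace$k[bestIdx], gamma = trace$gamma[bestIdx]),
      incumbentObjective = trace$objective[bestIdx],
      incumbentModel = if (bestIdx <= length(models)) models[[bestIdx]] else NULL)
}

#' @rdname accessors
#' @aliases incumbent,BOResult-method
setMethod("incumbent", "BOResult", function(x) x@incumbent)

#' @rdname accessors
#' @aliases searchTrace,BOResult-method
setMethod("searchTrace", "BOResult", function(x) x@trace)

setMethod("show", "BOResult", function(object) {
  cat(sprintf(
    "BOResult: %d evaluations; incumbent k = %d, gamma = %.4g, objective = %.6g\n",
    nrow(object@trace), object@incumbent["k"], object@incumbent["gamma"],
    object@incumbentObjective))
})

# ---- Gaussian-process internals (Matern-5/2 ARD) ----------------------

maternKernel <- function(X1, X2, ls, sf2) {
  # X in unit box; ls per-dimension length scales
  X1s <- sweep(as.matrix(X1), 2, ls, "/")
  X2s <- sweep(as.matrix(X2), 2, ls, "/")
  r <- sqrt(pairDist2(X1s, X2s))
  s5 <- sqrt(5) * r
  sf2 * (1 + s5 + (5 / 3) * r^2) * exp(-s5)
}

gpFit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  nll <- function(theta) {
    ls <- exp(theta[seq_len(d)])
    sf2 <- exp(theta[d + 1])
    sn2 <- exp(theta[d + 2])
    K <- maternKernel(X, X, ls, sf2) + diag(sn2, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))) +
                 0.5 * n * log(2 * pi))
  }
  start <- c(rep(log(0.3), d), log(1), log(1e-4))
  opt <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B",
                 lower = c(rep(log(0.03), d), log(1e-3), log(1e-8)),
                 upper = c(rep(log(10), d), log(100), log(1)),
                 control = list(maxit = 60)),
    error = function(e) NULL)
  theta <- if (is.null(opt)) start else opt$par
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1])
  sn2 <- exp(theta[d + 2])
  K <- maternKernel(X, X, ls, sf2) + diag(sn2, n)
  ch <- chol(K + diag(1e-10, n))
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, chol = ch, alpha = alpha, ls = ls, sf2 = sf2, sn2 = sn2,
       mu = mu, sdy = sdy)
}

gpPredict <- function(fit, Xs) {
  Ks <- maternKernel(Xs, fit$X, fit$ls, fit$sf2)
  mean <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(fit$sf2 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * mean, sd = fit$sdy * sqrt(var))
}

# Propose the next (k, gamma) by maximizing expected improvement over a
# seeded LHS candidate grid; xi is the exploration offset.
proposeEI <- function(trace, kb, gb, seed, nCand = 500L, xi = 0.01) {
  U <- cbind((trace$k - kb[1]) / max(1L, kb[2] - kb[1]),
             (trace$gamma - gb[1]) / (gb[2] - gb[1]))
  fit <- gpFit(U, trace$objective)
  cand <- withSeed(seed, lhs::randomLHS(nCand, 2L))
  pr <- gpPredict(fit, cand)
  fmin <- min(trace$objective)
  imp <- fmin - pr$mean - xi
  z <- imp / pr$sd
  ei <- imp * stats::pnorm(z) + pr$sd * stats::dnorm(z)
  bestU <- cand[which.max(ei), ]
  c(k = pmin(kb[2], pmax(kb[1],
        as.integer(round(kb[1] + bestU[1] * (kb[2] - kb[1]))))),
    gamma = gb[1] + bestU[2] * (gb[2] - gb[1]))
}
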