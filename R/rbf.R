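#' Gaussian radial-basis interpolation matrix
#'
#' Entry (i, j) is `exp(-gamma * ||x_i - c_j||^2)`: the activation of the
#' j-th basis function at the i-th input. All entries lie in (0, 1].
#'
#' @param X n x d numeric matrix of inputs.
#' @param centers k x d numeric matrix of basis centers.
#' @param gamma positive kernel width.
#' @return n x k numeric matrix.
#' @examples
#' interpolationMatrix(matrix(c(0, 0), 1), matrix(c(1, 0), 1), gamma = 1)
#' # exp(-1)
#' @export
interpolationMatrix <- function(X, centers, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar")
  }
  exp(-gamma * pairDist2(X, centers))
}

#' Forward pass of an RBF network
#'
#' Computes predictions `G %*% w` where G is the interpolation matrix of
#' `X` against the model's centers. There is no bias term. When `X`
#' carries column names and the model carries feature names, their order
#' must agree.
#'
#' @param model an [RBFModel-class].
#' @param X n x d numeric matrix (column order = `model@featureNames`).
#' @return length-n numeric vector of predictions.
#' @export
rbfForward <- function(model, X) {
  X <- as.matrix(X)
  if (length(model@featureNames) && !is.null(colnames(X)) &&
      !identical(colnames(X), model@featureNames)) {
    stop("feature columns [", paste(colnames(X), collapse = ", "),
         "] do not match model features [",
         paste(model@featureNames, collapse = ", "), "]")
  }
  G <- interpolationMatrix(X, model@centers, model@gamma)
  as.numeric(G %*% model@weights)
}

#' @describeIn rbfForward `predict` method for fitted models.
#' @param object an [RBFModel-class].
#' @param ... ignored.
#' @export
setMethod("predict", "RBFModel", function(object, X, ...) {
  rbfForward(object, X)
})

setMethod("show", "RBFModel", function(object) {
  cat(sprintf("RBFModel: k = %d basis functions, d = %d inputs, gamma = %g\n",
              nrow(object@centers), ncol(object@centers), object@gamma))
  if (length(object@featureNames)) {
    cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  }
})

#' Root-mean-squared-error loss
#'
#' `sqrt(mean((y - yhat)^2))`; the training objective of the network.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
rmseLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("length mismatch: ", length(y), " vs ", length(yhat))
  }
  if (length(y) < 1L) stop("need at least one observation")
  sqrt(mean((y - yhat)^2))
}

#' Gradient-training configuration
#'
#' Settings for full-batch RMSprop minimization of the RMSE loss over the
#' output weights. Centers and gamma are never gradient-trained: centers
#' come from K-means and gamma is a hyperparameter tuned by Bayesian
#' optimization.
#'
#' @param learningRate step size eta.
#' @param maxEpochs epoch budget (full-batch steps).
#' @param optimizerDecay squared-gradient smoothing constant in (0, 1).
#' @param epsilon numerical-stability constant.
#' @param seed integer seed for the random weight initialization.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 0.01, maxEpochs = 500L,
                        optimizerDecay = 0.99, epsilon = 1e-8, seed = 1L) {
  stopifnot(learningRate > 0, maxEpochs >= 0,
            optimizerDecay > 0, optimizerDecay < 1, epsilon > 0)
  structure(list(learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 optimizerDecay = optimizerDecay,
                 epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Train the output weights of an RBF network
#'
#' Full-batch gradient descent on the RMSE loss with RMSprop scaling
#' (exponential moving average of squared gradients). Weights are
#' initialized from N(0, 0.1^2) under the config seed; the weight vector
#' achieving the lowest recorded training loss is returned, which need
#' not be the final epoch's. Deterministic given the seed.
#'
#' @param model an [RBFModel-class] with centers and gamma already set.
#' @param X n x d training inputs.
#' @param y length-n training targets.
#' @param config a [trainConfig()].
#' @return `list(model = trained RBFModel, history = TrainHistory)` where
#'   the history holds `loss` (per-epoch), `initialLoss`, `bestEpoch`.
#' @export
trainRBF <- function(model, X, y, config = trainConfig()) {
  stopifnot(inherits(config, "TrainConfig"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("X rows and y length differ")
  G <- interpolationMatrix(X, model@centers, model@gamma)
  k <- ncol(G)
  w <- withSeed(config$seed, stats::rnorm(k, mean = 0, sd = 0.1))
  initialLoss <- rmseLoss(y, as.numeric(G %*% w))
  if (config$maxEpochs == 0L) {
    # no-op training keeps the initial weights untouched
    model@weights <- as.numeric(model@weights)
    history <- structure(list(loss = numeric(0), initialLoss = initialLoss,
                              finalEpoch = 0L, bestEpoch = 0L),
                         class = "TrainHistory")
    return(list(model = model, history = history))
  }
  fit <- .rmsprop_cpp(G, y, w, config$learningRate, config$optimizerDecay,
                      config$epsilon, config$maxEpochs)
  if (isTRUE(fit$diverged)) {
    stop(sprintf(
      "training diverged at epoch %d (learning rate %g): non-finite loss",
      fit$epoch, config$learningRate))
  }
  # the kernel retains the weights of the lowest recorded training loss,
  # which may precede the final epoch (or be the initialization itself)
  losses <- as.numeric(fit$loss)
  bestEpoch <- as.integer(fit$bestEpoch)
  model@weights <- as.numeric(fit$weights)
  validObject(model)
  history <- structure(list(loss = losses, initialLoss = initialLoss,
                            finalEpoch = config$maxEpochs,
                            bestEpoch = bestEpoch),
                       class = "TrainHistory")
  list(model = model, history = history)
}

#' Minimum-norm least-squares weights (testing oracle)
#'
#' With fixed centers the network is linear in its output weights, so the
#' optimal weights solve `G w ~ y` in the least-squares sense. The
#' Moore-Penrose pseudoinverse gives the minimum-norm solution, defined
#' for any rank.
#'
#' @param G n x k interpolation matrix.
#' @param y length-n target vector.
#' @return length-k weight vector.
#' @export
closedFormWeights <- function(G, y) {
  G <- as.matrix(G)
  if (nrow(G) != length(y)) stop("G rows and y length differ")
  as.numeric(MASS::ginv(G) %*% y)
}

#' Serialize / restore an RBF model
#'
#' Writes a single flat JSON file holding the schema tag, feature names
#' and scale tags, centers, gamma, weights, target scale and categorical
#' encoding maps, so a model can be reloaded and applied to new tables.
#'
#' @param model an [RBFModel-class].
#' @param path file path.
#' @return `saveRBFModel`: `path` invisibly. `loadRBFModel`: the model.
#' @export
saveRBFModel <- function(model, path) {
  payload <- list(
    schema = "traitRBF/rbf-model/1",
    featureNames = model@featureNames,
    featureScaleTags = as.list(model@featureScaleTags),
    centers = unclass(model@centers),
    gamma = model@gamma,
    weights = model@weights,
    targetScaleTag = model@targetScaleTag,
    encodingMaps = lapply(model@encodingMaps, as.list)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveRBFModel
#' @export
loadRBFModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "traitRBF/rbf-model/1")) {
    stop("unrecognized model schema: ", p$schema)
  }
  RBFModel(
    centers = matrix(as.numeric(p$centers), nrow = length(p$weights)),
    gamma = p$gamma,
    weights = as.numeric(p$weights),
    featureNames = as.character(p$featureNames),
    featureScaleTags = unlist(p$featureScaleTags) %||% character(),
    encodingMaps = lapply(p$encodingMaps, function(x) unlist(x)),
    targetScaleTag = p$targetScaleTag
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
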