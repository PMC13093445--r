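#' @import methods
NULL

#' TraitTable: specimen-by-trait tables with an explicit missingness mask
#'
#' The central exchange object of the package. Rows are individual
#' specimens, columns are either continuous morphological traits
#' (strictly positive on the raw scale, e.g. wing length in mm) or
#' categorical attributes (species identity, sex). Every cell is either
#' observed or missing; the logical `observed` matrix is the authority,
#' and missing cells hold `NA` in `values`.
#'
#' @slot values data.frame of cell values; continuous columns are numeric,
#'   categorical columns are character before encoding and integer codes
#'   after [encodeCategoricals()].
#' @slot observed logical matrix, same dimensions as `values`; `TRUE`
#'   marks an observed cell.
#' @slot columnKinds named character vector mapping each column to
#'   `"continuous"` or `"categorical"`.
#' @slot scaleTags named character vector over the continuous columns,
#'   `"raw"` or `"log"`; a `"log"` column stores natural-log values of a
#'   strictly positive raw quantity.
#'
#' @seealso [TraitTable()], [readTraitTable()], [logTransform()],
#'   [encodeCategoricals()], [splitTable()]
#' @export
setClass("TraitTable",
  slots = c(
    values = "data.frame",
    observed = "matrix",
    columnKinds = "character",
    scaleTags = "character"
  )
)

setValidity("TraitTable", function(object) {
  v <- object@values
  m <- object@observed
  msgs <- character()
  if (anyDuplicated(colnames(v))) {
    msgs <- c(msgs, "column names must be unique")
  }
  if (!identical(dim(m), dim(as.matrix(v))) && !(nrow(v) == 0L && nrow(m) == 0L)) {
    if (nrow(m) != nrow(v) || ncol(m) != ncol(v)) {
      msgs <- c(msgs, "observed mask dimensions must match values")
    }
  }
  if (!is.logical(m)) msgs <- c(msgs, "observed mask must be logical")
  if (!setequal(names(object@columnKinds), colnames(v))) {
    msgs <- c(msgs, "columnKinds must name every column")
  }
  if (!all(object@columnKinds %in% c("continuous", "categorical"))) {
    msgs <- c(msgs, "columnKinds must be 'continuous' or 'categorical'")
  }
  cont <- names(object@columnKinds)[object@columnKinds == "continuous"]
  if (!all(names(object@scaleTags) %in% cont)) {
    msgs <- c(msgs, "scaleTags may only tag continuous columns")
  }
  if (length(object@scaleTags) && !all(object@scaleTags %in% c("raw", "log"))) {
    msgs <- c(msgs, "scaleTags must be 'raw' or 'log'")
  }
  if (nrow(v) > 0L) {
    for (cn in cont) {
      if (!is.numeric(v[[cn]])) {
        msgs <- c(msgs, sprintf("continuous column '%s' must be numeric", cn))
        next
      }
      obs <- m[, match(cn, colnames(v))]
      if (any(obs & !is.finite(v[[cn]]))) {
        msgs <- c(msgs, sprintf("observed cells in '%s' must be finite", cn))
      }
    }
    # missing cells never carry a value
    for (j in seq_along(v)) {
      if (any(!m[, j] & !is.na(v[[j]]))) {
        msgs <- c(msgs, sprintf(
          "column '%s' has a value in a cell flagged missing", colnames(v)[j]
        ))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TraitTable
#'
#' @param values data.frame of cell values (`NA` for missing cells).
#' @param columnKinds named character vector (`"continuous"` /
#'   `"categorical"`) covering every column; columns absent from the map
#'   default to `"continuous"` when numeric and `"categorical"` otherwise.
#' @param observed optional logical matrix; defaults to `!is.na(values)`.
#' @param scaleTags optional named character vector over continuous
#'   columns; unnamed continuous columns default to `"raw"`.
#' @return A [TraitTable-class] object.
#' @examples
#' tt <- TraitTable(
#'   data.frame(Wing.Length = c(68.1, NA, 70.2), Species = c("a", "b", "a")),
#'   columnKinds = c(Wing.Length = "continuous", Species = "categorical")
#' )
#' nrow(traitValues(tt))
#' @export
TraitTable <- function(values, columnKinds = NULL, observed = NULL,
                       scaleTags = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (is.null(columnKinds)) columnKinds <- character()
  inferred <- vapply(values, function(x) {
    if (is.numeric(x)) "continuous" else "categorical"
  }, character(1))
  missingKinds <- setdiff(colnames(values), names(columnKinds))
  columnKinds <- c(columnKinds, inferred[missingKinds])
  columnKinds <- columnKinds[colnames(values)]
  if (is.null(observed)) {
    observed <- !is.na(as.matrix(values))
    dimnames(observed) <- list(NULL, colnames(values))
  }
  if (nrow(values) == 0L) {
    observed <- matrix(logical(0), nrow = 0L, ncol = ncol(values),
                       dimnames = list(NULL, colnames(values)))
  }
  cont <- names(columnKinds)[columnKinds == "continuous"]
  if (is.null(scaleTags)) scaleTags <- character()
  untagged <- setdiff(cont, names(scaleTags))
  scaleTags <- c(scaleTags, stats::setNames(rep("raw", length(untagged)), untagged))
  scaleTags <- scaleTags[intersect(names(scaleTags), cont)]
  rownames(values) <- NULL
  new("TraitTable", values = values, observed = observed,
      columnKinds = columnKinds, scaleTags = scaleTags)
}

#' RBFModel: a Gaussian radial-basis-function regression network
#'
#' A single-hidden-layer network with `k` hidden units. The prediction
#' for input x is sum_j w_j * exp(-gamma * ||x - c_j||^2): no bias term,
#' a single width gamma shared across units, and centers fixed from
#' K-means clustering of the training inputs. Only the output weights
#' are trained by gradient descent.
#'
#' @slot centers k x d numeric matrix of basis-function centers.
#' @slot gamma positive scalar kernel width.
#' @slot weights length-k numeric vector of output weights.
#' @slot featureNames character vector binding the d center columns to
#'   predictor columns, in order.
#' @slot featureScaleTags named character vector recording the scale
#'   (`"raw"`/`"log"`/`"encoded"`) each feature had at training time.
#' @slot encodingMaps named list of [EncodingMap] objects for the
#'   categorical features, used to encode unseen tables at predict time.
#' @slot targetScaleTag scale of the modeled target (normally `"log"`).
#' @export
setClass("RBFModel",
  slots = c(
    centers = "matrix",
    gamma = "numeric",
    weights = "numeric",
    featureNames = "character",
    featureScaleTags = "character",
    encodingMaps = "list",
    targetScaleTag = "character"
  ),
  prototype = prototype(
    featureScaleTags = character(),
    encodingMaps = list(),
    targetScaleTag = "log"
  )
)

setValidity("RBFModel", function(object) {
  msgs <- character()
  k <- nrow(object@centers)
  if (k < 1L) msgs <- c(msgs, "at least one center required")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0) {
    msgs <- c(msgs, "gamma must be a positive finite scalar")
  }
  if (length(object@weights) != k) {
    msgs <- c(msgs, "weights length must equal the number of centers")
  }
  if (length(object@featureNames) &&
      length(object@featureNames) != ncol(object@centers)) {
    msgs <- c(msgs, "featureNames length must equal center dimension")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RBFModel
#'
#' @param centers k x d numeric matrix of centers.
#' @param gamma positive kernel width.
#' @param weights length-k output weights; defaults to zeros.
#' @param featureNames optional predictor names (length d).
#' @param featureScaleTags,encodingMaps,targetScaleTag optional predict-time
#'   metadata; see [RBFModel-class].
#' @return An [RBFModel-class] object.
#' @examples
#' m <- RBFModel(centers = matrix(0, 1, 2), gamma = 1, weights = 1)
#' rbfForward(m, matrix(0, 1, 2))
#' @export
RBFModel <- function(centers, gamma, weights = rep(0, nrow(centers)),
                     featureNames = character(),
                     featureScaleTags = character(),
                     encodingMaps = list(),
                     targetScaleTag = "log") {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  new("RBFModel", centers = centers, gamma = as.numeric(gamma),
      weights = as.numeric(weights),
      featureNames = as.character(featureNames),
      featureScaleTags = featureScaleTags,
      encodingMaps = encodingMaps,
      targetScaleTag = targetScaleTag)
}

#' KMeansResult: a fitted K-means partition
#'
#' Stores the centroids, assignments and within-cluster sum of squares
#' (inertia) of the best restart of Lloyd's algorithm, plus the
#' per-iteration inertia trace of that restart.
#'
#' @slot centroids k x d numeric matrix.
#' @slot assignments integer vector in 1..k, one per row of the input.
#' @slot inertia total within-cluster sum of squared distances.
#' @slot nIter iterations used by the winning restart.
#' @slot inertiaTrace per-iteration inertia of the winning restart
#'   (non-increasing).
#' @slot seed integer seed used for the restart protocol.
#' @export
setClass("KMeansResult",
  slots = c(
    centroids = "matrix",
    assignments = "integer",
    inertia = "numeric",
    nIter = "integer",
    inertiaTrace = "numeric",
    seed = "integer"
  )
)

setValidity("KMeansResult", function(object) {
  msgs <- character()
  k <- nrow(object@centroids)
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > k)) {
    msgs <- c(msgs, "assignments must lie in 1..k")
  }
  if (object@inertia < -1e-9) msgs <- c(msgs, "inertia must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' BOResult: a Bayesian-optimization run over (k, gamma)
#'
#' @slot trace data.frame with columns `k`, `gamma`, `objective` in
#'   evaluation order.
#' @slot incumbent named numeric vector `c(k = ..., gamma = ...)` of the
#'   best configuration.
#' @slot incumbentObjective objective value of the incumbent (the minimum
#'   over the trace).
#' @slot incumbentModel the trained [RBFModel-class] retained from the
#'   incumbent's evaluation (no retraining).
#' @export
setClass("BOResult",
  slots = c(
    trace = "data.frame",
    incumbent = "numeric",
    incumbentObjective = "numeric",
    incumbentModel = "ANY"
  )
)

setValidity("BOResult", function(object) {
  msgs <- character()
  fin <- is.finite(object@trace$objective)
  if (any(fin) &&
      abs(object@incumbentObjective - min(object@trace$objective[fin])) > 1e-12) {
    msgs <- c(msgs, "incumbent objective must be the trace minimum")
  }
  if (length(msgs)) msgs else TRUE
})

#' MetricsReport: the seven regression evaluation metrics
#'
#' Mean squared error, its square root, mean and median absolute error,
#' mean absolute percentage error, mean squared logarithmic error and the
#' coefficient of determination, together with the sample size, the scale
#' the metrics were computed on, and any domain-violation flags.
#'
#' @slot mse,rmse,mae,medae,mape,msle,r2 numeric scalars (`NA` where a
#'   metric is undefined for the inputs; the reason is flagged).
#' @slot n sample count.
#' @slot scale `"log"` or `"original"`.
#' @slot flags character vector of domain notes (e.g. rows excluded from
#'   MAPE because the true value is zero).
#' @export
setClass("MetricsReport",
  slots = c(
    mse = "numeric", rmse = "numeric", mae = "numeric", medae = "numeric",
    mape = "numeric", msle = "numeric", r2 = "numeric",
    n = "integer", scale = "character", flags = "character"
  )
)

#' ComboResult: one tuned feature combination
#'
#' The outcome of hyperparameter search for a single predictor
#' combination: the incumbent (k, gamma), its trained model, metric
#' reports on the log and original scales, and per-row validation
#' predictions on both scales.
#'
#' @slot target target trait name.
#' @slot features ordered predictor names (2 or 3 of them).
#' @slot incumbent named numeric `c(k=, gamma=)`.
#' @slot model the trained [RBFModel-class].
#' @slot reportLog,reportOriginal [MetricsReport-class] on each scale.
#' @slot valPredictions data.frame with columns `trueLog`, `predLog`,
#'   `trueOriginal`, `predOriginal`.
#' @slot boTrace the Bayesian-optimization trace data.frame.
#' @slot nValExcluded validation rows dropped for missing predictors.
#' @export
setClass("ComboResult",
  slots = c(
    target = "character",
    features = "character",
    incumbent = "numeric",
    model = "ANY",
    reportLog = "ANY",
    reportOriginal = "ANY",
    valPredictions = "data.frame",
    boTrace = "data.frame",
    nValExcluded = "integer"
  )
)

setValidity("ComboResult", function(object) {
  msgs <- character()
  if (length(object@features) < 2L || length(object@features) > 3L) {
    msgs <- c(msgs, "a combination holds 2 or 3 features")
  }
  if (length(msgs)) msgs else TRUE
})
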