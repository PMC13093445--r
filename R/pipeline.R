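#' Enumerate candidate predictor combinations
#'
#' All subsets of the candidate predictors of size 2 and 3 (size-1
#' combinations are never generated), in deterministic lexicographic
#' order over the candidate positions.
#'
#' @param candidates unique predictor names.
#' @param minSize,maxSize subset size bounds (2 and 3 by default; minSize
#'   must be at least 2).
#' @return list of character vectors; length `C(p,2) + C(p,3)` at the
#'   defaults.
#' @examples
#' length(enumerateCombos(paste0("t", 1:7)))  # 56
#' @export
enumerateCombos <- function(candidates, minSize = 2L, maxSize = 3L) {
  if (anyDuplicated(candidates)) stop("candidates must be unique")
  if (minSize < 2L) stop("combinations of size one are excluded; minSize >= 2")
  if (maxSize < minSize) stop("maxSize must be >= minSize")
  if (length(candidates) < minSize) {
    stop("need at least ", minSize, " candidates, got ", length(candidates))
  }
  out <- list()
  for (m in minSize:min(maxSize, length(candidates))) {
    cm <- utils::combn(candidates, m, simplify = FALSE)
    out <- c(out, cm)
  }
  out
}

#' Tune and evaluate one feature combination
#'
#' Restricts the training rows to those where the target and every
#' combination feature are observed, runs the Bayesian (k, gamma) search
#' with [rbfObjective()], and scores the incumbent model on the
#' validation rows (rows lacking any feature are excluded and counted).
#' Metrics are reported on the model (log) scale and, when the target is
#' log-tagged, on the original scale after exponentiating.
#'
#' @param train,val log-transformed, encoded [TraitTable-class] splits.
#' @param target continuous target column (log scale).
#' @param combo 2 or 3 predictor names.
#' @param space a [searchSpace()].
#' @param config a [trainConfig()].
#' @param encodingMap optional `EncodingMap` stored into the model for
#'   predict-time encoding.
#' @return A [ComboResult-class].
#' @export
evaluateCombo <- function(train, val, target, combo,
                          space = searchSpace(), config = trainConfig(),
                          encodingMap = NULL) {
  trainRows <- completeRows(train, c(target, combo))
  if (length(trainRows) < 10L) {
    stop("insufficient data: only ", length(trainRows),
         " usable training rows for combination [",
         paste(combo, collapse = ", "), "]")
  }
  valAll <- completeRows(val, c(target, combo))
  nValExcluded <- nrow(traitValues(val)) - length(valAll)
  if (length(valAll) < 2L) {
    stop("insufficient validation rows for combination [",
         paste(combo, collapse = ", "), "]")
  }
  tr <- preparedData(train, target, combo, trainRows)
  va <- preparedData(val, target, combo, valAll)
  kmCache <- new.env(parent = emptyenv())
  bo <- bayesOptimize(space, function(k, gamma) {
    rbfObjective(k, gamma, tr, va, config, cache = kmCache)
  })
  model <- bo@incumbentModel
  model@featureNames <- combo
  tags <- scaleTags(train)
  kinds <- columnKinds(train)
  model@featureScaleTags <- vapply(combo, function(f) {
    if (identical(kinds[[f]], "categorical")) "encoded"
    else tags[[f]] %||% "raw"
  }, character(1))
  if (!is.null(encodingMap)) {
    model@encodingMaps <- encodingMap[intersect(names(encodingMap), combo)]
  }
  model@targetScaleTag <- scaleTags(train)[[target]] %||% "raw"
  predLog <- rbfForward(model, va$x)
  reportLog <- computeMetrics(va$y, predLog, scale = "log")
  logTarget <- identical(model@targetScaleTag, "log")
  trueOrig <- if (logTarget) exp(va$y) else va$y
  predOrig <- if (logTarget) exp(predLog) else predLog
  reportOriginal <- computeMetrics(trueOrig, predOrig, scale = "original")
  new("ComboResult",
      target = target, features = combo, incumbent = bo@incumbent,
      model = model, reportLog = reportLog, reportOriginal = reportOriginal,
      valPredictions = data.frame(trueLog = va$y, predLog = predLog,
                                  trueOriginal = trueOrig,
                                  predOriginal = predOrig),
      boTrace = bo@trace, nValExcluded = as.integer(nValExcluded))
}

setMethod("show", "ComboResult", function(object) {
  cat(sprintf(
    "ComboResult: %s ~ %s | k = %d, gamma = %.4g | R2(log) = %.4f\n",
    object@target, paste(object@features, collapse = " + "),
    object@incumbent["k"], object@incumbent["gamma"], object@reportLog@r2))
})

#' Rank tuned combinations and keep the best
#'
#' Sorted by validation R-squared on the selection (log) scale,
#' descending; ties broken by fewer features, then lexicographically by
#' feature names. The top `topN` are returned.
#'
#' @param results list of [ComboResult-class].
#' @param topN combinations to retain (default 5).
#' @return ordered list of at most `topN` results.
#' @export
rankAndSelect <- function(results, topN = 5L) {
  if (!length(results)) stop("no combination results to rank")
  r2 <- vapply(results, function(x) x@reportLog@r2, numeric(1))
  sizes <- vapply(results, function(x) length(x@features), integer(1))
  labels <- vapply(results, function(x) paste(x@features, collapse = "|"),
                   character(1))
  ord <- order(-r2, sizes, labels)
  results[ord][seq_len(min(topN, length(results)))]
}

# Model-space predictor matrix for arbitrary table rows, applying the
# model's stored scale tags and encoding maps.
modelInputs <- function(model, table, rows) {
  v <- traitValues(table)
  tags <- scaleTags(table)
  cols <- lapply(model@featureNames, function(f) {
    x <- v[[f]]
    want <- model@featureScaleTags[[f]]
    if (identical(want, "encoded") && is.character(x)) {
      map <- model@encodingMaps[[f]]
      if (is.null(map)) stop("no stored encoding for feature '", f, "'")
      codes <- unname(map[x])
      unseen <- !is.na(x) & is.na(codes)
      if (any(unseen)) {
        warning(sum(unseen), " unseen categor(ies) in '", f,
                "' mapped to reserved code -1")
        codes[unseen] <- -1L
      }
      as.numeric(codes)
    } else if (identical(want, "log") && identical(tags[[f]] %||% NA, "raw")) {
      if (any(!is.na(x) & x <= 0)) {
        stop("feature '", f, "' has non-positive values; cannot log-transform")
      }
      log(x)
    } else {
      as.numeric(x)
    }
  })
  M <- do.call(cbind, cols)
  colnames(M) <- model@featureNames
  M[rows, , drop = FALSE]
}

#' Impute missing target values with a ranked combination cascade
#'
#' Each row with a missing target is imputed by the best-ranked
#' combination whose features are all observed in that row, falling back
#' through the ranking; rows satisfied by no combination are tagged
#' `unimputable`. Observed cells are never modified. Predictions are made
#' on the log scale and back-transformed with `exp` when the table's
#' target column is raw-scale, so every imputed value is finite and
#' strictly positive.
#'
#' @param table a [TraitTable-class]; feature columns may be raw or log
#'   scale (the models' stored tags drive the conversion).
#' @param target target column name.
#' @param ranked nonempty ordered list of [ComboResult-class] from
#'   [rankAndSelect()], or of fitted [RBFModel-class] objects (e.g. from
#'   [loadRBFModel()]), whose stored feature names define each
#'   combination.
#' @return list with `table` (filled [TraitTable-class]), `provenance`
#'   (per-row tag: `observed`, `imputed:<rank>`, `unimputable`), and
#'   `audit` (counts per tag).
#' @export
imputeTraits <- function(table, target, ranked) {
  if (!length(ranked)) stop("ranked combination list is empty")
  v <- traitValues(table)
  m <- observedMask(table)
  tj <- match(target, colnames(v))
  if (is.na(tj)) stop("target column '", target, "' absent")
  targetRaw <- identical(scaleTags(table)[[target]] %||% "raw", "raw")
  prov <- ifelse(m[, tj], "observed", "unimputable")
  todo <- which(!m[, tj])
  for (rank in seq_along(ranked)) {
    if (!length(todo)) break
    res <- ranked[[rank]]
    mod <- if (methods::is(res, "RBFModel")) res else res@model
    feats <- mod@featureNames
    if (!length(feats)) stop("model at rank ", rank, " has no feature names")
    ok <- todo[rowSums(!m[todo, feats, drop = FALSE]) == 0L]
    if (!length(ok)) next
    X <- modelInputs(mod, table, ok)
    predLog <- rbfForward(mod, X)
    filled <- if (identical(mod@targetScaleTag, "log") && targetRaw) {
      exp(predLog)
    } else {
      predLog
    }
    v[[tj]][ok] <- filled
    m[ok, tj] <- TRUE
    prov[ok] <- paste0("imputed:", rank)
    todo <- setdiff(todo, ok)
  }
  out <- TraitTable(v, columnKinds = columnKinds(table), observed = m,
                    scaleTags = scaleTags(table))
  list(table = out, provenance = prov,
       audit = base::table(factor(prov)), nUnimputable = length(todo))
}

#' Export validation predictions of a tuned combination
#'
#' One file per retained combination: per-row true and predicted target
#' values on the original scale (log predictions exponentiated), written
#' as plain CSV.
#'
#' @param result a [ComboResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportPredictions <- function(result, path) {
  df <- result@valPredictions[, c("trueOriginal", "predOriginal")]
  names(df) <- c("true", "predicted")
  if (nrow(df) == 0L) warning("empty validation set: writing header only")
  out <- data.frame(true = sprintf("%.17g", df$true),
                    predicted = sprintf("%.17g", df$predicted))
  if (nrow(df) == 0L) out <- out[0, ]
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Feature-wise mean substitution
#'
#' Replaces each missing cell of the named continuous columns by the mean
#' of that column over the complete-case rows (rows with no missing value
#' in any of the named columns). If no complete case exists, falls back
#' to the per-column observed mean with a warning. Masks are cleared on
#' filled cells.
#'
#' @param table a [TraitTable-class].
#' @param columns continuous columns participating in modeling.
#' @return the filled [TraitTable-class].
#' @export
meanImpute <- function(table, columns) {
  kinds <- columnKinds(table)
  notCont <- columns[kinds[columns] != "continuous"]
  if (length(notCont)) {
    stop("mean imputation applies to continuous columns: ",
         paste(notCont, collapse = ", "))
  }
  v <- traitValues(table)
  m <- observedMask(table)
  cc <- which(rowSums(!m[, columns, drop = FALSE]) == 0L)
  for (cn in columns) {
    j <- match(cn, colnames(v))
    miss <- which(!m[, j])
    if (!length(miss)) next
    fill <- if (length(cc)) {
      mean(v[[j]][cc])
    } else {
      obs <- which(m[, j])
      if (!length(obs)) {
        warning("column '", cn, "' has no observed values; left missing")
        next
      }
      warning("no complete-case rows; using per-column observed mean for '",
              cn, "'")
      mean(v[[j]][obs])
    }
    v[[j]][miss] <- fill
    m[miss, j] <- TRUE
  }
  TraitTable(v, columnKinds = kinds, observed = m, scaleTags = scaleTags(table))
}

#' Complete-case versus mean-imputed training ablation
#'
#' Contrasts two training regimes on one shared test split. The
#' complete-case rows (no missing value among target and features) are
#' split 70/30; scenario `complete_case` trains on the 70%. Scenario
#' `mean_imputed` takes all remaining rows (the shared test rows
#' excluded, avoiding leakage), fills their missing modeling cells by
#' feature-wise means computed from the complete cases, and trains on
#' that. Both models are tuned identically and evaluated on the identical
#' held-out complete-case test rows.
#'
#' @param table a log-transformed, encoded [TraitTable-class] containing
#'   missing values.
#' @param target target column.
#' @param combo predictor names.
#' @param space a [searchSpace()].
#' @param config a [trainConfig()].
#' @param seed split seed.
#' @param trainFraction complete-case fraction used for training.
#' @return list with `reports` (per-scenario [MetricsReport-class] on the
#'   log scale), `testIndices` (shared test rows, indices into `table`),
#'   and `incumbents`.
#' @export
runAblation <- function(table, target, combo, space = searchSpace(),
                        config = trainConfig(), seed = 1L,
                        trainFraction = 0.7) {
  modelCols <- c(target, combo)
  cc <- completeRows(table, modelCols)
  if (length(cc) < 20L) {
    stop("too few complete cases (", length(cc), ") for the ablation")
  }
  nTrain <- round(length(cc) * trainFraction)
  nTrain <- max(1L, min(length(cc) - 1L, nTrain))
  pick <- withSeed(seed, sample.int(length(cc), nTrain))
  trainCC <- cc[sort(pick)]
  testIdx <- setdiff(cc, trainCC)
  test <- preparedData(table, target, combo, testIdx)

  evalArm <- function(trainTable, rows) {
    tr <- preparedData(trainTable, target, combo, rows)
    kmCache <- new.env(parent = emptyenv())
    bo <- bayesOptimize(space, function(k, gamma) {
      rbfObjective(k, gamma, tr, test, config, cache = kmCache)
    })
    model <- bo@incumbentModel
    pred <- rbfForward(model, test$x)
    list(report = computeMetrics(test$y, pred, scale = "log"),
         incumbent = bo@incumbent)
  }

  armA <- evalArm(table, trainCC)

  rest <- setdiff(seq_len(nrow(traitValues(table))), testIdx)
  restTable <- subsetRows(table, rest)
  # means come from the complete cases of the remaining data
  filled <- meanImpute(restTable, modelCols)
  usable <- completeRows(filled, modelCols)
  armB <- evalArm(filled, usable)

  list(reports = list(complete_case = armA$report,
                      mean_imputed = armB$report),
       testIndices = testIdx,
       incumbents = list(complete_case = armA$incumbent,
                         mean_imputed = armB$incumbent))
}

#' Baseline regressors on the identical rows, features and metrics
#'
#' Fits each named baseline on exactly the training rows/features the RBF
#' pipeline would use and scores it with [computeMetrics()] on the
#' identical validation rows. Supported baselines: `knn`
#' (distance-weighted k-nearest neighbors; neighbor search via the FNN
#' package), `random_forest` (randomForest package) and `mean` (predicts
#' the training mean; the no-information reference). Deterministic given
#' `seed`.
#'
#' @param train,val log-transformed, encoded [TraitTable-class] splits.
#' @param target target column.
#' @param combo predictor names.
#' @param baselineSpec named list of per-method settings, e.g.
#'   `list(knn = list(k = 5, weights = "distance"),
#'         random_forest = list(ntree = 100))`.
#' @param seed integer seed (random forest).
#' @return list with `table` (one metrics row per method, log scale) and
#'   `reports` (named [MetricsReport-class] list).
#' @export
compareBaselines <- function(train, val, target, combo,
                             baselineSpec = list(
                               knn = list(k = 5, weights = "distance"),
                               random_forest = list(ntree = 100)),
                             seed = 1L) {
  known <- c("knn", "random_forest", "mean")
  bad <- setdiff(names(baselineSpec), known)
  if (length(bad)) {
    stop("unknown baseline(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(known, collapse = ", "), ")")
  }
  trRows <- completeRows(train, c(target, combo))
  vaRows <- completeRows(val, c(target, combo))
  tr <- preparedData(train, target, combo, trRows)
  va <- preparedData(val, target, combo, vaRows)
  reports <- list()
  for (method in names(baselineSpec)) {
    spec <- baselineSpec[[method]]
    pred <- switch(method,
      knn = {
        kk <- min(spec$k %||% 5L, nrow(tr$x))
        nn <- FNN::get.knnx(tr$x, va$x, k = kk)
        if (identical(spec$weights %||% "distance", "distance")) {
          w <- 1 / pmax(nn$nn.dist, 1e-12)
          rowSums(matrix(tr$y[nn$nn.index], ncol = kk) * w) / rowSums(w)
        } else {
          rowMeans(matrix(tr$y[nn$nn.index], ncol = kk))
        }
      },
      random_forest = withSeed(deriveSeed(seed, 42L), {
        rf <- randomForest::randomForest(
          x = tr$x, y = tr$y, ntree = spec$ntree %||% 100L)
        as.numeric(stats::predict(rf, va$x))
      }),
      mean = rep(mean(tr$y), length(va$y))
    )
    reports[[method]] <- computeMetrics(va$y, pred, scale = "log")
  }
  tab <- do.call(rbind, lapply(names(reports), function(m) {
    cbind(method = m, metricsTable(reports[[m]]))
  }))
  list(table = tab, reports = reports)
}

#' Full feature-combination search for one target trait
#'
#' Orchestrates the end-to-end procedure on an already log-transformed,
#' encoded table: screen candidates by pairwise-complete Pearson
#' correlation with the log target, split 70/30 once (the same split is
#' reused by every combination), enumerate all size-2 and size-3
#' candidate combinations, tune each with the Bayesian (k, gamma) search,
#' rank by validation R-squared and retain the top `topN`. Optionally
#' writes a metrics CSV, per-combination search traces and per-top-combo
#' prediction exports; two runs with identical inputs and seeds produce
#' byte-identical files.
#'
#' @param table log-transformed, encoded [TraitTable-class].
#' @param target continuous (log-scale) target column.
#' @param candidates candidate predictors; default all numeric columns
#'   except the target.
#' @param space a [searchSpace()].
#' @param config a [trainConfig()].
#' @param trainFraction,seed split parameters.
#' @param topN combinations to retain.
#' @param minAbsCorrelation screening threshold on |r| (default 0.1);
#'   candidates below it (or unusable) are dropped.
#' @param encodingMap optional `EncodingMap` embedded in trained models.
#' @param outDir optional output directory for CSV artifacts.
#' @return list with `ranked` (top results), `all` (every evaluated
#'   [ComboResult-class]), `screened` (surviving candidates),
#'   `correlations` (the screening report), `split`, and `skipped`
#'   (combinations aborted for lack of data, with reasons).
#' @export
runSearch <- function(table, target, candidates = NULL,
                      space = searchSpace(), config = trainConfig(),
                      trainFraction = 0.7, seed = 1L, topN = 5L,
                      minAbsCorrelation = 0.1, encodingMap = NULL,
                      outDir = NULL) {
  corr <- pairwisePearson(table, target, candidates)
  keep <- corr$usable & abs(corr$r) >= minAbsCorrelation
  screened <- corr$feature[keep]
  if (length(screened) < 2L) {
    stop("fewer than 2 candidates survive correlation screening")
  }
  sp <- splitTable(table, trainFraction, seed)
  combos <- enumerateCombos(screened)
  results <- list()
  skipped <- list()
  for (combo in combos) {
    res <- tryCatch(
      evaluateCombo(sp$train, sp$validation, target, combo, space, config,
                    encodingMap = encodingMap),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[paste(combo, collapse = "|")]] <- conditionMessage(res)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results)) stop("every combination failed to evaluate")
  ranked <- rankAndSelect(results, topN)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSearchArtifacts(results, ranked, target, outDir)
  }
  list(ranked = ranked, all = results, screened = screened,
       correlations = corr, split = sp, skipped = skipped)
}

# CSV artifacts of a search run (deterministic content, no timestamps).
writeSearchArtifacts <- function(results, ranked, target, outDir) {
  metricRows <- do.call(rbind, lapply(results, function(r) {
    rbind(
      cbind(target = target, combo = paste(r@features, collapse = "|"),
            k = unname(r@incumbent["k"]), gamma = unname(r@incumbent["gamma"]),
            metricsTable(r@reportLog)),
      cbind(target = target, combo = paste(r@features, collapse = "|"),
            k = unname(r@incumbent["k"]), gamma = unname(r@incumbent["gamma"]),
            metricsTable(r@reportOriginal)))
  }))
  utils::write.csv(format(metricRows, digits = 12),
                   file.path(outDir, "metrics.csv"), row.names = FALSE,
                   quote = FALSE)
  traces <- do.call(rbind, lapply(results, function(r) {
    data.frame(combo = paste(r@features, collapse = "|"),
               call = seq_len(nrow(r@boTrace)), r@boTrace)
  }))
  utils::write.csv(format(traces, digits = 12),
                   file.path(outDir, "bo_trace.csv"), row.names = FALSE,
                   quote = FALSE)
  for (i in seq_along(ranked)) {
    exportPredictions(ranked[[i]], file.path(
      outDir, sprintf("predictions_top%d.csv", i)))
  }
  invisible(outDir)
}
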