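# Shared fixtures, built in code.

# A small trait table with one missing continuous cell and categoricals.
makeToyTable <- function() {
  TraitTable(
    data.frame(
      Wing.Length = c(68.1, NA, 70.2, 65.4, 71.0),
      Mass = c(21.5, 19.8, NA, 20.1, 22.3),
      Species = c("sparrow", "crow", "sparrow", "wren", "crow"),
      Sex = c("M", "F", "F", "M", NA),
      stringsAsFactors = FALSE
    ),
    columnKinds = c(Wing.Length = "continuous", Mass = "continuous",
                    Species = "categorical", Sex = "categorical")
  )
}

# Preprocessed (log + encoded) synthetic table ready for modeling.
makePreparedSynthetic <- function(nSpecies = 40, perSpecies = 25, seed = 7,
                                  missingRates = NULL, mechanism = "MCAR") {
  cfg <- syntheticConfig(nSpecies = nSpecies,
                         individualsPerSpecies = perSpecies,
                         missingRates = missingRates,
                         mechanism = mechanism, seed = seed)
  g <- generateTraits(cfg)
  masked <- injectMissingness(g$table, cfg)
  tab <- encodeCategoricals(logTransform(masked$table))$table
  list(table = tab, config = cfg, truth = g$truth, mask = masked$mask)
}

# A minimal ComboResult carrying just ranking-relevant fields.
makeStubCombo <- function(r2, features, target = "t") {
  rep <- new("MetricsReport", mse = 0, rmse = 0, mae = 0, medae = 0,
             mape = 0, msle = 0, r2 = r2, n = 10L, scale = "log",
             flags = character())
  new("ComboResult", target = target, features = features,
      incumbent = c(k = 10, gamma = 0.1),
      model = RBFModel(matrix(0, 1, length(features)), 1, 0),
      reportLog = rep, reportOriginal = rep,
      valPredictions = data.frame(trueLog = numeric(0),
                                  predLog = numeric(0),
                                  trueOriginal = numeric(0),
                                  predOriginal = numeric(0)),
      boTrace = data.frame(k = 10, gamma = 0.1, objective = -r2),
      nValExcluded = 0L)
}
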