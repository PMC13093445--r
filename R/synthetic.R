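#' Configuration for the synthetic avian-trait generator
#'
#' The generator emulates allometric covariation in specimen-level
#' morphology: every continuous trait is log-normal, sharing a latent
#' log-body-size factor, with an additive species-level random effect
#' common to all traits of an individual, a per-trait sex offset, and
#' independent measurement noise. On the log scale, trait t of
#' individual i (species s, sex g in \{0, 1\}) is
#'
#'   intercept_t + loading_t * size_i + species_s + sexEffect_t * g + eps
#'
#' with size_i ~ N(0, 1), species_s ~ N(0, speciesSd^2) and
#' eps ~ N(0, noiseSd^2). Missingness is injected per trait at the
#' configured rates under MCAR or MAR.
#'
#' Default trait names follow the standard avian measurement schema
#' (culmen and nares beak lengths, beak width/depth, tarsus, wing, Kipp's
#' distance, first secondary, hand-wing index, tail, mass). Default
#' missing rates are heterogeneous in the way large trait databases are:
#' one trait near 52\% missing, one near 36\%, the rest at or below
#' 10\%. The default `noiseSd` is solved so that the population
#' R-squared of the best linear predictor of any log trait from three
#' other traits is 0.95 (see [oracleCeiling()]), giving a known accuracy
#' ceiling for every experiment.
#'
#' @param nSpecies number of species.
#' @param individualsPerSpecies specimen records per species (repeated
#'   measurements of conspecific individuals).
#' @param traits character vector of continuous trait names.
#' @param traitLoadings per-trait coefficients on latent log body size.
#' @param traitIntercepts per-trait baseline log values.
#' @param speciesSd standard deviation of the shared species effect (log
#'   scale).
#' @param sexEffect per-trait additive sex offset (log scale); recycled.
#' @param noiseSd measurement-noise standard deviation (log scale);
#'   `NULL` solves for a 0.95 three-predictor ceiling.
#' @param missingRates named per-trait missingness proportions in [0, 1);
#'   unnamed traits default to 0.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param marDriver observed trait conditioning MAR missingness; must
#'   itself have missing rate 0.
#' @param marSlope logistic slope of MAR missingness on the standardized
#'   log driver.
#' @param seed integer seed.
#' @return A `SyntheticConfig` list.
#' @export
syntheticConfig <- function(nSpecies = 40L,
                            individualsPerSpecies = 25L,
                            traits = c("Beak.Length_Culmen",
                                       "Beak.Length_Nares", "Beak.Width",
                                       "Beak.Depth", "Tarsus.Length",
                                       "Wing.Length", "Kipps.Distance",
                                       "Secondary1", "Hand-wing.Index",
                                       "Tail.Length", "Mass"),
                            traitLoadings = 1.0,
                            traitIntercepts = NULL,
                            speciesSd = 0.3,
                            sexEffect = 0.05,
                            noiseSd = NULL,
                            missingRates = NULL,
                            mechanism = c("MCAR", "MAR"),
                            marDriver = "Mass",
                            marSlope = 2,
                            seed = 1L) {
  mechanism <- match.arg(mechanism)
  p <- length(traits)
  loadings <- stats::setNames(rep_len(traitLoadings, p), traits)
  if (is.null(traitIntercepts)) {
    # spread of typical log-millimeter / log-gram magnitudes
    traitIntercepts <- stats::setNames(
      rep_len(c(2.8, 2.2, 1.6, 1.7, 3.2, 4.3, 2.9, 4.0, 3.4, 4.1, 3.0), p),
      traits)
  } else {
    traitIntercepts <- stats::setNames(rep_len(traitIntercepts, p), traits)
  }
  sexEffect <- stats::setNames(rep_len(sexEffect, p), traits)
  if (is.null(noiseSd)) {
    noiseSd <- solveNoiseSd(loadings[1], speciesSd, sexEffect[1],
                            targetCeiling = 0.95, p = 3L)
  }
  stopifnot(speciesSd >= 0, noiseSd >= 0)
  rates <- stats::setNames(rep(0, p), traits)
  if (is.null(missingRates)) {
    rates["Beak.Length_Nares"] <- 0.52
    rates["Kipps.Distance"] <- 0.36
    others <- setdiff(traits, c("Beak.Length_Nares", "Kipps.Distance",
                                marDriver))
    rates[others] <- 0.05
  } else {
    bad <- setdiff(names(missingRates), traits)
    if (length(bad)) stop("missingRates name unknown traits: ",
                          paste(bad, collapse = ", "))
    rates[names(missingRates)] <- missingRates
  }
  if (any(rates < 0 | rates >= 1)) stop("missing rates must lie in [0, 1)")
  if (mechanism == "MAR" && rates[marDriver] > 0) {
    stop("the MAR driver trait '", marDriver,
         "' must stay fully observed (missing rate 0)")
  }
  structure(list(nSpecies = as.integer(nSpecies),
                 individualsPerSpecies = as.integer(individualsPerSpecies),
                 traits = traits, traitLoadings = loadings,
                 traitIntercepts = traitIntercepts,
                 speciesSd = speciesSd, sexEffect = sexEffect,
                 noiseSd = noiseSd, missingRates = rates,
                 mechanism = mechanism, marDriver = marDriver,
                 marSlope = marSlope, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Noise level giving a target best-linear-predictor R2 with p symmetric
# predictor traits: signal s = loading^2 + speciesSd^2 + sexEffect^2 / 4,
# R2(p) = p s^2 / ((q + p s)(s + q)) with q = noiseSd^2.
solveNoiseSd <- function(loading, speciesSd, sexEffect, targetCeiling, p) {
  s <- loading^2 + speciesSd^2 + sexEffect^2 / 4
  f <- function(q) p * s^2 / ((q + p * s) * (s + q)) - targetCeiling
  sqrt(stats::uniroot(f, c(1e-12, 100 * s))$root)
}

#' Generate a complete synthetic trait table with ground truth
#'
#' Draws the latent body sizes, species effects, sexes and measurement
#' noise of [syntheticConfig()]'s model and exponentiates to strictly
#' positive raw-scale traits. Deterministic given the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return `list(table = complete TraitTable (raw scale, with Species and
#'   Sex categorical columns), truth = list(latentSize, speciesEffect,
#'   logValues))`.
#' @export
generateTraits <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nSpecies * config$individualsPerSpecies
  species <- rep(sprintf("sp%03d", seq_len(config$nSpecies)),
                 each = config$individualsPerSpecies)
  draw <- withSeed(config$seed, {
    list(size = stats::rnorm(n),
         spEff = stats::rnorm(config$nSpecies, sd = config$speciesSd),
         sex = stats::rbinom(n, 1L, 0.5),
         eps = matrix(stats::rnorm(n * length(config$traits),
                                   sd = config$noiseSd),
                      n, length(config$traits)))
  })
  spEffRow <- draw$spEff[rep(seq_len(config$nSpecies),
                             each = config$individualsPerSpecies)]
  logVals <- sapply(seq_along(config$traits), function(t) {
    config$traitIntercepts[t] + config$traitLoadings[t] * draw$size +
      spEffRow + config$sexEffect[t] * draw$sex + draw$eps[, t]
  })
  colnames(logVals) <- config$traits
  values <- as.data.frame(exp(logVals))
  colnames(values) <- config$traits
  values$Species <- species
  values$Sex <- ifelse(draw$sex == 1L, "M", "F")
  kinds <- c(stats::setNames(rep("continuous", length(config$traits)),
                             config$traits),
             Species = "categorical", Sex = "categorical")
  table <- TraitTable(values, columnKinds = kinds)
  list(table = table,
       truth = list(latentSize = draw$size, speciesEffect = spEffRow,
                    sex = draw$sex, logValues = logVals))
}

#' Inject MCAR or MAR missingness into a trait table
#'
#' MCAR masks each cell of a trait independently with that trait's rate.
#' MAR masks with probability logistic in the standardized log value of
#' the (fully observed) driver trait, with the intercept solved so the
#' marginal rate matches the requested one. Deterministic given the
#' config seed.
#'
#' @param table a [TraitTable-class] (raw scale).
#' @param config a [syntheticConfig()].
#' @return `list(table = masked TraitTable, mask = logical matrix, TRUE
#'   where a cell was masked)`.
#' @export
injectMissingness <- function(table, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  v <- traitValues(table)
  obs <- observedMask(table)
  n <- nrow(v)
  mask <- matrix(FALSE, n, ncol(v), dimnames = list(NULL, colnames(v)))
  rates <- config$missingRates
  if (config$mechanism == "MAR") {
    if (rates[config$marDriver] > 0) {
      stop("MAR driver must stay fully observed")
    }
    z <- scale(log(v[[config$marDriver]]))[, 1]
  }
  for (tr in names(rates)) {
    rate <- rates[[tr]]
    if (rate <= 0) next
    j <- match(tr, colnames(v))
    drop <- withSeed(deriveSeed(config$seed, 5000L + j), {
      if (config$mechanism == "MCAR") {
        stats::runif(n) < rate
      } else {
        b <- config$marSlope
        a <- stats::uniroot(function(a) mean(stats::plogis(a + b * z)) - rate,
                            c(-50, 50))$root
        stats::runif(n) < stats::plogis(a + b * z)
      }
    })
    v[[j]][drop] <- NA
    obs[drop, j] <- FALSE
    mask[, j] <- drop
  }
  list(table = TraitTable(v, columnKinds = columnKinds(table),
                          observed = obs, scaleTags = scaleTags(table)),
       mask = mask)
}

#' Population accuracy ceiling of a predictor combination
#'
#' The R-squared of the best linear predictor of the log target given the
#' named log-scale features, computed in closed form from the generative
#' model's covariance structure: traits i, j have covariance
#' `l_i l_j + speciesSd^2 + e_i e_j / 4` (plus `noiseSd^2` on the
#' diagonal), and the encoded sex column has variance 1/4 and covariance
#' `e_t / 4` with trait t. Any imputer's achievable validation R-squared
#' on this family is bounded by this ceiling (up to sampling noise).
#'
#' @param config a [syntheticConfig()].
#' @param target target trait name.
#' @param combo feature names (traits and/or `"Sex"`).
#' @return scalar population R-squared in [0, 1].
#' @export
oracleCeiling <- function(config, target, combo) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if ("Species" %in% combo) {
    stop("the closed-form ceiling covers continuous traits and Sex only")
  }
  vars <- c(target, combo)
  l <- config$traitLoadings
  e <- config$sexEffect
  cv <- function(a, b) {
    if (a == "Sex" && b == "Sex") return(0.25)
    if (a == "Sex" || b == "Sex") {
      tr <- if (a == "Sex") b else a
      return(e[[tr]] * 0.25)
    }
    base <- l[[a]] * l[[b]] + config$speciesSd^2 + e[[a]] * e[[b]] * 0.25
    if (a == b) base <- base + config$noiseSd^2
    base
  }
  S <- outer(vars, vars, Vectorize(cv))
  stt <- S[1, 1]
  sft <- S[-1, 1, drop = FALSE]
  sff <- S[-1, -1, drop = FALSE]
  as.numeric(t(sft) %*% solve(sff, sft)) / stt
}
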