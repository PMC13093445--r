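test_that("generation is deterministic in the seed and positive on raw scale", {
  cfg <- syntheticConfig(nSpecies = 5, individualsPerSpecies = 4, seed = 3)
  a <- generateTraits(cfg)
  b <- generateTraits(cfg)
  expect_identical(traitValues(a$table), traitValues(b$table))
  expect_identical(a$truth$latentSize, b$truth$latentSize)
  v <- traitValues(a$table)
  expect_equal(nrow(v), 20L)
  for (tr in cfg$traits) expect_true(all(v[[tr]] > 0))
  expect_equal(length(unique(v$Species)), 5L)
  expect_true(all(v$Sex %in% c("M", "F")))

  c2 <- generateTraits(syntheticConfig(nSpecies = 5,
                                       individualsPerSpecies = 4, seed = 4))
  expect_false(identical(traitValues(c2$table), traitValues(a$table)))
})

test_that("generator limits match the declared linear model", {
  # no noise, one species, no sex effect: log traits are exact affine
  # functions of latent size, so a linear fit is perfect
  cfg <- syntheticConfig(nSpecies = 1, individualsPerSpecies = 60,
                         speciesSd = 0, sexEffect = 0, noiseSd = 0, seed = 5)
  g <- generateTraits(cfg)
  lv <- log(traitValues(g$table)$Wing.Length)
  fit <- stats::lm(lv ~ log(traitValues(g$table)$Mass))
  # summary.lm warns on an exactly perfect fit; the R2 itself is the point
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-10)

  # zero loadings and zero species effect decouple the traits entirely
  cfg0 <- syntheticConfig(nSpecies = 1, individualsPerSpecies = 400,
                          traitLoadings = 0, speciesSd = 0, sexEffect = 0,
                          noiseSd = 0.2, seed = 6)
  g0 <- generateTraits(cfg0)
  r <- stats::cor(log(traitValues(g0$table)$Wing.Length),
                  log(traitValues(g0$table)$Mass))
  expect_lt(abs(r), 0.12)
})

test_that("MCAR hits the requested marginal rate", {
  cfg <- syntheticConfig(nSpecies = 20, individualsPerSpecies = 500,
                         missingRates = c(Wing.Length = 0.5), seed = 9)
  g <- generateTraits(cfg)
  out <- injectMissingness(g$table, cfg)
  n <- nrow(traitValues(g$table))
  hit <- sum(out$mask[, "Wing.Length"])
  # within 3 binomial standard deviations of n * rate
  expect_lt(abs(hit - n * 0.5), 3 * sqrt(n * 0.25))
  # untouched traits stay fully observed
  expect_equal(sum(out$mask[, "Mass"]), 0L)
  # masked cells are NA, mask matches the observed flags
  expect_true(all(is.na(traitValues(out$table)$Wing.Length[
    out$mask[, "Wing.Length"]])))
  expect_identical(unname(!observedMask(out$table)[, "Wing.Length"]),
                   unname(out$mask[, "Wing.Length"]))
})

test_that("MAR missingness depends on the driver and hits the rate", {
  cfg <- syntheticConfig(nSpecies = 20, individualsPerSpecies = 250,
                         missingRates = c(Wing.Length = 0.4),
                         mechanism = "MAR", marDriver = "Mass",
                         marSlope = 2, seed = 10)
  g <- generateTraits(cfg)
  out <- injectMissingness(g$table, cfg)
  n <- nrow(traitValues(g$table))
  hit <- sum(out$mask[, "Wing.Length"])
  expect_lt(abs(hit - n * 0.4), 3 * sqrt(n * 0.4 * 0.6))
  # records missing the trait have systematically larger driver values
  lm <- log(traitValues(g$table)$Mass)
  expect_gt(mean(lm[out$mask[, "Wing.Length"]]),
            mean(lm[!out$mask[, "Wing.Length"]]))
  # a driver with its own missingness is rejected at config time
  expect_error(
    syntheticConfig(missingRates = c(Mass = 0.1, Wing.Length = 0.3),
                    mechanism = "MAR", marDriver = "Mass"),
    "fully observed")
})

test_that("oracle ceiling matches its analytic limits and a large sample", {
  # no measurement noise: one predictor already explains everything
  noiseless <- syntheticConfig(noiseSd = 0, sexEffect = 0)
  expect_equal(oracleCeiling(noiseless, "Wing.Length", "Mass"), 1,
               tolerance = 1e-12)
  # unrelated traits: nothing is explainable
  null <- syntheticConfig(traitLoadings = 0, speciesSd = 0, sexEffect = 0,
                          noiseSd = 0.2)
  expect_equal(oracleCeiling(null, "Wing.Length", "Mass"), 0,
               tolerance = 1e-12)
  # the default noise level is solved for a 0.95 three-predictor ceiling
  def <- syntheticConfig()
  expect_equal(oracleCeiling(def, "Wing.Length",
                             c("Mass", "Tarsus.Length", "Tail.Length")),
               0.95, tolerance = 1e-6)
  # large-sample empirical check of the closed form
  cfg <- syntheticConfig(nSpecies = 200, individualsPerSpecies = 25,
                         seed = 11)
  g <- generateTraits(cfg)
  v <- traitValues(g$table)
  fit <- stats::lm(log(v$Wing.Length) ~ log(v$Mass) + log(v$Tarsus.Length) +
                     log(v$Tail.Length))
  expect_equal(summary(fit)$r.squared,
               oracleCeiling(cfg, "Wing.Length",
                             c("Mass", "Tarsus.Length", "Tail.Length")),
               tolerance = 0.02)
  expect_error(oracleCeiling(cfg, "Wing.Length", "Species"), "Sex only")
})

test_that("default missing rates mirror a heterogeneous trait database", {
  cfg <- syntheticConfig()
  expect_equal(unname(cfg$missingRates["Beak.Length_Nares"]), 0.52)
  expect_equal(unname(cfg$missingRates["Kipps.Distance"]), 0.36)
  expect_equal(unname(cfg$missingRates["Mass"]), 0)
  expect_equal(unname(cfg$missingRates["Wing.Length"]), 0.05)
  expect_error(syntheticConfig(missingRates = c(Nonexistent = 0.5)),
               "unknown")
  expect_error(syntheticConfig(missingRates = c(Wing.Length = 1)),
               "\\[0, 1\\)")
})
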