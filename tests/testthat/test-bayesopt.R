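# A cheap deterministic test objective with a unique minimum inside the
# default box at k = 15, gamma = 0.2.
quadObjective <- function(k, gamma) 0.001 * (k - 15)^2 + (gamma - 0.2)^2

test_that("the incumbent is the exact trace minimum", {
  space <- searchSpace(seed = 1)
  res <- bayesOptimize(space, quadObjective)
  tr <- searchTrace(res)
  expect_equal(nrow(tr), 10L)
  best <- which.min(tr$objective)
  expect_equal(unname(incumbent(res)["k"]), tr$k[best])
  expect_equal(unname(incumbent(res)["gamma"]), tr$gamma[best])
  expect_equal(res@incumbentObjective, min(tr$objective))
  # recomputing the objective at the incumbent reproduces the trace value
  expect_equal(res@incumbentObjective,
               unname(quadObjective(incumbent(res)["k"],
                                    incumbent(res)["gamma"])),
               tolerance = 1e-12)
  # all proposals respect the box
  expect_true(all(tr$k >= 10 & tr$k <= 25))
  expect_true(all(tr$gamma >= 0.05 & tr$gamma <= 0.5))
  expect_true(all(tr$k == round(tr$k)))
})

test_that("model-based proposals never lose to the initial design", {
  for (s in 1:20) {
    res <- bayesOptimize(searchSpace(seed = s), quadObjective)
    tr <- searchTrace(res)
    expect_lte(min(tr$objective), min(tr$objective[1:5]))
  }
})

test_that("optimization is deterministic and seed-sensitive", {
  a <- searchTrace(bayesOptimize(searchSpace(seed = 4), quadObjective))
  b <- searchTrace(bayesOptimize(searchSpace(seed = 4), quadObjective))
  expect_identical(a, b)
  c <- searchTrace(bayesOptimize(searchSpace(seed = 5), quadObjective))
  expect_false(identical(a, c))
})

test_that("guided search beats pure random search on median regret", {
  boBest <- randBest <- numeric(20)
  for (s in 1:20) {
    boBest[s] <- bayesOptimize(searchSpace(seed = s),
                               quadObjective)@incumbentObjective
    # same budget spent entirely on the space-filling design
    randBest[s] <- bayesOptimize(searchSpace(nCalls = 10, nInitial = 10,
                                             seed = s),
                                 quadObjective)@incumbentObjective
  }
  expect_lte(stats::median(boBest), stats::median(randBest))
})

test_that("degenerate spaces and failures are handled", {
  # constant objective: any point is an incumbent, nothing crashes
  res <- bayesOptimize(searchSpace(seed = 2), function(k, gamma) 1)
  expect_equal(res@incumbentObjective, 1)
  # nCalls = nInitial runs the design only
  res2 <- bayesOptimize(searchSpace(nCalls = 5, nInitial = 5, seed = 2),
                        quadObjective)
  expect_equal(nrow(searchTrace(res2)), 5L)
  # failed evaluations (Inf) are excluded; the search still finds the rest
  flaky <- function(k, gamma) if (k %% 2 == 0) Inf else quadObjective(k, gamma)
  res3 <- bayesOptimize(searchSpace(seed = 3), flaky)
  expect_true(is.finite(res3@incumbentObjective))
  expect_equal(res3@incumbent[["k"]] %% 2, 1)
  # every evaluation failing is an error, not a silent incumbent
  expect_error(bayesOptimize(searchSpace(nCalls = 3, nInitial = 3, seed = 1),
                             function(k, gamma) Inf), "failed")
  # no duplicated (k, gamma) pairs are ever evaluated
  tr <- searchTrace(bayesOptimize(searchSpace(seed = 6), quadObjective))
  expect_equal(anyDuplicated(tr[, c("k", "gamma")]), 0L)
})

test_that("the RBF objective is deterministic and carries its model", {
  prep <- makePreparedSynthetic(nSpecies = 8, perSpecies = 15,
                                missingRates = c(Wing.Length = 0))
  dat <- preparedData(prep$table, "Wing.Length",
                      c("Mass", "Tarsus.Length"))
  trainIdx <- seq_len(80)
  train <- list(x = dat$x[trainIdx, ], y = dat$y[trainIdx])
  val <- list(x = dat$x[-trainIdx, ], y = dat$y[-trainIdx])
  cfg <- trainConfig(maxEpochs = 100L, seed = 2L)
  a <- rbfObjective(12, 0.2, train, val, cfg)
  b <- rbfObjective(12, 0.2, train, val, cfg)
  expect_identical(a$objective, b$objective)
  expect_identical(a$model@weights, b$model@weights)
  expect_s4_class(a$model, "RBFModel")
  # the reported objective is the negative validation R2 of that model
  expect_equal(a$objective, -rSquared(val$y, rbfForward(a$model, val$x)),
               tolerance = 1e-12)
  # the per-k cache returns identical centers without refitting
  cache <- new.env()
  c1 <- rbfObjective(12, 0.2, train, val, cfg, cache = cache)
  expect_identical(c1$objective, a$objective)
  expect_equal(cache[["12"]], c1$model@centers)
})
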