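test_that("interpolation matrix matches hand values and a naive oracle", {
  # zero distance activates fully
  expect_equal(interpolationMatrix(matrix(0), matrix(0), 1)[1, 1], 1)
  # unit distance at gamma = 1 gives exp(-1)
  expect_equal(interpolationMatrix(matrix(c(0, 0), 1), matrix(c(1, 0), 1),
                                   1)[1, 1], exp(-1))
  # activations shrink as gamma grows
  X <- matrix(c(0, 0), 1); C <- matrix(c(1, 1), 1)
  expect_lt(interpolationMatrix(X, C, 0.5)[1, 1],
            interpolationMatrix(X, C, 0.1)[1, 1])
  expect_error(interpolationMatrix(matrix(0), matrix(0), -1), "positive")
  expect_error(interpolationMatrix(matrix(1:4, 2, 2), matrix(1:3, 1, 3), 1))

  # independent double-loop reference on random instances
  naive <- function(X, C, g) {
    G <- matrix(0, nrow(X), nrow(C))
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(C))) {
      G[i, j] <- exp(-g * sum((X[i, ] - C[j, ])^2))
    }
    G
  }
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:50, 1); d <- sample(1:5, 1); k <- sample(1:10, 1)
    X <- matrix(rnorm(n * d), n, d)
    C <- matrix(rnorm(k * d), k, d)
    g <- runif(1, 0.01, 2)
    expect_equal(interpolationMatrix(X, C, g), naive(X, C, g),
                 tolerance = 1e-8)
  }
})

test_that("forward pass is G %*% w with no bias", {
  # k = 1: prediction equals w * activation
  m <- RBFModel(matrix(0), gamma = 1, weights = 3)
  expect_equal(rbfForward(m, matrix(0)), 3)
  # two units, hand value 1 + 2 * exp(-1)
  m2 <- RBFModel(matrix(c(0, 1)), gamma = 1, weights = c(1, 2))
  expect_equal(rbfForward(m2, matrix(0)), 1 + 2 * exp(-1), tolerance = 1e-12)
  # zero weights give exactly zero output (no bias term)
  m3 <- RBFModel(matrix(c(0, 1)), gamma = 1, weights = c(0, 0))
  expect_equal(rbfForward(m3, matrix(5)), 0)
  expect_equal(predict(m2, matrix(0)), rbfForward(m2, matrix(0)))

  # named inputs must match the model's feature order
  m4 <- RBFModel(matrix(0, 1, 2), gamma = 1, weights = 1,
                 featureNames = c("a", "b"))
  X <- matrix(0, 1, 2, dimnames = list(NULL, c("b", "a")))
  expect_error(rbfForward(m4, X), "do not match")
})

test_that("predictions are invariant to joint center/weight permutation", {
  set.seed(3)
  C <- matrix(rnorm(8), 4, 2)
  w <- rnorm(4)
  X <- matrix(rnorm(12), 6, 2)
  p <- sample(4)
  a <- rbfForward(RBFModel(C, 0.3, w), X)
  b <- rbfForward(RBFModel(C[p, , drop = FALSE], 0.3, w[p]), X)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("rmse loss matches hand arithmetic and mse", {
  expect_equal(rmseLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmseLoss(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  set.seed(5)
  y <- rnorm(30); yh <- rnorm(30)
  expect_equal(rmseLoss(y, yh)^2, mean((y - yh)^2), tolerance = 1e-12)
  expect_error(rmseLoss(1:3, 1:2), "length mismatch")
})

test_that("closed-form weights solve the least-squares problem", {
  # identity interpolation matrix returns y itself
  expect_equal(closedFormWeights(diag(3), c(1, 2, 3)), c(1, 2, 3))
  # well-conditioned square system is solved exactly
  set.seed(9)
  G <- matrix(rnorm(25), 5, 5) + diag(5)
  w <- rnorm(5)
  expect_equal(closedFormWeights(G, as.numeric(G %*% w)), w,
               tolerance = 1e-8)
  # overdetermined: no perturbation of the solution does better
  G2 <- exp(-0.5 * pairDist2(matrix(rnorm(20), 20, 1),
                             matrix(rnorm(4), 4, 1)))
  y2 <- rnorm(20)
  w2 <- closedFormWeights(G2, y2)
  base <- rmseLoss(y2, as.numeric(G2 %*% w2))
  for (i in 1:10) {
    expect_gte(rmseLoss(y2, as.numeric(G2 %*% (w2 + rnorm(4, sd = 0.05)))),
               base)
  }
})

test_that("gradient training approaches the least-squares optimum", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2)
  C <- matrix(rnorm(10), 5, 2)
  gamma <- 0.4
  G <- interpolationMatrix(X, C, gamma)
  wTrue <- rnorm(5)
  y <- as.numeric(G %*% wTrue) + rnorm(40, sd = 0.01)
  lsLoss <- rmseLoss(y, as.numeric(G %*% closedFormWeights(G, y)))

  # RMSprop with a fixed step plateaus at roughly the learning-rate
  # scale, so a small rate and a generous epoch budget are needed to
  # approach the least-squares optimum tightly
  fit <- trainRBF(RBFModel(C, gamma), X, y,
                  trainConfig(learningRate = 0.001, maxEpochs = 20000L,
                              seed = 2L))
  trained <- rmseLoss(y, rbfForward(fit$model, X))
  expect_lte(trained, lsLoss + 1e-3)
  # returned weights achieve the best recorded loss
  expect_equal(trained, min(fit$history$initialLoss, min(fit$history$loss)),
               tolerance = 1e-10)
  expect_lte(min(fit$history$loss), fit$history$initialLoss)
  expect_true(all(is.finite(fit$history$loss)))

  # determinism: identical seeds give identical weights
  fit2 <- trainRBF(RBFModel(C, gamma), X, y,
                   trainConfig(learningRate = 0.001, maxEpochs = 20000L,
                               seed = 2L))
  expect_identical(fit$model@weights, fit2$model@weights)

  # a zero-epoch budget is a no-op with an empty history
  fit0 <- trainRBF(RBFModel(C, gamma, weights = rep(0, 5)), X, y,
                   trainConfig(maxEpochs = 0L))
  expect_identical(fit0$model@weights, rep(0, 5))
  expect_length(fit0$history$loss, 0L)
})

test_that("models survive a save/load round trip", {
  m <- RBFModel(matrix(c(0.25, 1.5, -2, 3), 2, 2), gamma = 0.2,
                weights = c(1.1, -0.7),
                featureNames = c("Mass", "Species"),
                featureScaleTags = c(Mass = "log", Species = "encoded"),
                encodingMaps = list(Species = c(sparrow = 0L, crow = 1L)),
                targetScaleTag = "log")
  f <- withr::local_tempfile(fileext = ".json")
  saveRBFModel(m, f)
  back <- loadRBFModel(f)
  expect_equal(back@centers, m@centers, tolerance = 1e-15)
  expect_equal(back@gamma, m@gamma)
  expect_equal(back@weights, m@weights, tolerance = 1e-15)
  expect_identical(back@featureNames, m@featureNames)
  expect_equal(back@encodingMaps$Species, m@encodingMaps$Species)
  X <- matrix(c(0.3, 0.9), 1, 2, dimnames = list(NULL, c("Mass", "Species")))
  expect_equal(rbfForward(back, X), rbfForward(m, X), tolerance = 1e-15)

  writeLines('{"schema":"other/1"}', f)
  expect_error(loadRBFModel(f), "schema")
})
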