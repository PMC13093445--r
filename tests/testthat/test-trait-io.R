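test_that("delimited files parse into masked tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Wing.Length,Species", "68.1,a", ",b", "70.2,a"), f)
  tt <- readTraitTable(f, columnKinds = c(Wing.Length = "continuous",
                                          Species = "categorical"))
  expect_equal(nrow(traitValues(tt)), 3L)
  expect_equal(sum(!observedMask(tt)), 1L)
  expect_false(observedMask(tt)[2, "Wing.Length"])
  expect_equal(traitValues(tt)$Wing.Length, c(68.1, NA, 70.2))

  # header-only file gives a 0-row table with columns preserved
  writeLines("Wing.Length,Species", f)
  empty <- readTraitTable(f, columnKinds = c(Wing.Length = "continuous",
                                             Species = "categorical"))
  expect_equal(nrow(traitValues(empty)), 0L)
  expect_equal(colnames(traitValues(empty)), c("Wing.Length", "Species"))

  # sentinel tokens mask cells
  writeLines(c("Wing.Length", "NA", "1.5"), f)
  tt2 <- readTraitTable(f, columnKinds = c(Wing.Length = "continuous"),
                        missingTokens = c("", "NA"))
  expect_false(observedMask(tt2)[1, 1])
  expect_true(observedMask(tt2)[2, 1])

  # a non-numeric, non-missing continuous cell is a named parse error
  writeLines(c("Wing.Length", "abc"), f)
  expect_error(readTraitTable(f, columnKinds = c(Wing.Length = "continuous")),
               "row 1.*Wing.Length")
})

test_that("write/read round trip preserves values, masks and column order", {
  tt <- makeToyTable()
  f <- withr::local_tempfile(fileext = ".csv")
  writeTraitTable(tt, f)
  back <- readTraitTable(f, columnKinds = columnKinds(tt))
  expect_equal(colnames(traitValues(back)), colnames(traitValues(tt)))
  expect_identical(unname(observedMask(back)), unname(observedMask(tt)))
  for (cn in c("Wing.Length", "Mass")) {
    expect_equal(traitValues(back)[[cn]], traitValues(tt)[[cn]],
                 tolerance = 1e-12)
  }
  expect_identical(traitValues(back)$Species, traitValues(tt)$Species)
})

test_that("cleaning rules drop exactly the failing records", {
  tt <- makeToyTable()
  # two rows lack either Wing.Length or Mass
  out <- cleanTable(tt, cleaningConfig(requiredColumns = c("Wing.Length",
                                                           "Mass")))
  expect_equal(nrow(traitValues(out)), 3L)
  expect_equal(traitValues(out)$Wing.Length, c(68.1, 65.4, 71.0))

  # an all-passing QC column leaves the table identical
  v <- traitValues(tt)
  v$qc <- "ok"
  tt2 <- TraitTable(v, columnKinds = c(columnKinds(tt), qc = "categorical"))
  out2 <- cleanTable(tt2, cleaningConfig(qcFlagColumn = "qc",
                                         qcPassValues = "ok",
                                         dropAllMissingRows = FALSE))
  expect_equal(traitValues(out2), traitValues(tt2))

  # a row with every continuous trait missing is dropped
  v2 <- data.frame(a = c(1, NA), b = c(2, NA))
  tt3 <- TraitTable(v2)
  out3 <- cleanTable(tt3, cleaningConfig(dropAllMissingRows = TRUE))
  expect_equal(nrow(traitValues(out3)), 1L)

  expect_error(cleanTable(tt, cleaningConfig(requiredColumns = "absent")),
               "absent")
})

test_that("log transform maps observed values and rejects non-positives", {
  tt <- TraitTable(data.frame(x = c(1, exp(1), NA)))
  out <- logTransform(tt, "x")
  expect_equal(traitValues(out)$x, c(0, 1, NA))
  expect_identical(unname(observedMask(out)), unname(observedMask(tt)))
  expect_equal(unname(scaleTags(out)["x"]), "log")

  bad <- TraitTable(data.frame(x = c(1, -2)))
  expect_error(logTransform(bad, "x"), "row 2.*'x'")
})

test_that("label encoding is first-appearance ordered and round-trips", {
  tt <- TraitTable(data.frame(sp = c("sparrow", "crow", "sparrow")),
                   columnKinds = c(sp = "categorical"))
  enc <- encodeCategoricals(tt, "sp")
  expect_equal(traitValues(enc$table)$sp, c(0L, 1L, 0L))
  expect_equal(decodeCategorical(enc$map, "sp", c(0L, 1L)),
               c("sparrow", "crow"))

  single <- TraitTable(data.frame(sp = c("a", "a", "a")),
                       columnKinds = c(sp = "categorical"))
  expect_equal(traitValues(encodeCategoricals(single, "sp")$table)$sp,
               c(0L, 0L, 0L))

  # unseen tokens under a stored map go to the reserved code with a warning
  new <- TraitTable(data.frame(sp = c("crow", "eagle")),
                    columnKinds = c(sp = "categorical"))
  expect_warning(out <- encodeCategoricals(new, "sp", map = enc$map),
                 "unseen")
  expect_equal(traitValues(out$table)$sp, c(1L, -1L))

  # missing categorical cells stay masked
  wna <- TraitTable(data.frame(sp = c("a", NA)),
                    columnKinds = c(sp = "categorical"))
  outna <- encodeCategoricals(wna, "sp")
  expect_false(observedMask(outna$table)[2, 1])
})

test_that("pairwise Pearson uses complete pairs and matches hand arithmetic", {
  tt <- TraitTable(data.frame(y = c(2, 4, 7), x = c(1, 2, 3),
                              self = c(2, 4, 7)))
  rep <- pairwisePearson(tt, "y", c("x", "self"))
  expect_equal(rep$r[rep$feature == "self"], 1)
  # r = 5 / (sqrt(2) * sqrt(114/9)), computed by hand from the sample
  # correlation formula
  expect_equal(rep$r[rep$feature == "x"], 5 / (sqrt(2) * sqrt(114 / 9)),
               tolerance = 1e-12)
  expect_equal(rep$r[rep$feature == "x"], 0.9934, tolerance = 1e-4)

  # pairwise-complete rule: only the 2 complete pairs are used
  tt2 <- TraitTable(data.frame(x = c(1, 2, 3, 4), y = c(5, NA, 6, NA)))
  rep2 <- pairwisePearson(tt2, "y", "x")
  expect_equal(rep2$nPairs, 2L)
  expect_equal(rep2$r, stats::cor(c(1, 3), c(5, 6)))

  # < 2 pairs or zero variance is reported unusable, not an error
  tt3 <- TraitTable(data.frame(x = c(1, NA, NA), y = c(5, 6, 7),
                               z = c(2, 2, 2)))
  rep3 <- pairwisePearson(tt3, "y", c("x", "z"))
  expect_false(any(rep3$usable))
  expect_true(all(is.na(rep3$r)))

  expect_error(pairwisePearson(tt, "absent", "x"), "absent")
})

test_that("pearson correlation is symmetric and affine-invariant", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    x[sample(n, 3)] <- NA
    tt <- TraitTable(data.frame(x = x, y = y))
    rxy <- pairwisePearson(tt, "y", "x")$r
    ryx <- pairwisePearson(tt, "x", "y")$r
    expect_equal(rxy, ryx, tolerance = 1e-12)
    tt2 <- TraitTable(data.frame(x = -3 * x + 7, y = y))
    expect_equal(abs(pairwisePearson(tt2, "y", "x")$r), abs(rxy),
                 tolerance = 1e-10)
  }
})

test_that("splits are disjoint, sized by rounding, and pure in (seed, n)", {
  tt <- makePreparedSynthetic(nSpecies = 2, perSpecies = 5)$table
  sp <- splitTable(tt, 0.7, seed = 1)
  expect_equal(length(sp$trainIdx), 7L)
  expect_equal(length(sp$valIdx), 3L)
  expect_length(intersect(sp$trainIdx, sp$valIdx), 0L)

  sp2 <- splitTable(tt, 0.7, seed = 1)
  expect_identical(sp$trainIdx, sp2$trainIdx)

  big <- makePreparedSynthetic(nSpecies = 40, perSpecies = 25)$table
  a <- splitTable(big, 0.7, seed = 1)
  b <- splitTable(big, 0.7, seed = 2)
  expect_false(identical(a$trainIdx, b$trainIdx))

  one <- TraitTable(data.frame(x = 1))
  expect_error(splitTable(one, 0.7, 1), "at least 2")
})
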