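test_that("perfect predictions give (1, 0, 0, 0)", {
  e <- c(-3.2, -1.1, 0.4, 2.8)
  s <- evaluatePredictions(e, e)
  expect_equal(s$r2, 1)
  expect_equal(s$sigma, 0)
  expect_equal(s$mue, 0)
  expect_equal(s$deltaMax, 0)
})

test_that("statistics match hand arithmetic, including the signed delta-max", {
  # e = (1,2,3), p = (1,2,6): residuals (0,0,-3)
  s <- evaluatePredictions(predicted = c(1, 2, 6), experimental = c(1, 2, 3),
                           p = 0, sigmaDf = "plain")
  expect_equal(s$mue, 1.0)
  expect_equal(s$deltaMax, -3.0)
  expect_equal(s$r2, 1 - 9 / 2)        # SSres 9, SStot 2
  expect_equal(s$sigma, sqrt(9 / 3))   # plain: sqrt(SSres/n)
  # opposite sign convention
  s2 <- evaluatePredictions(c(1, 2, 6), c(1, 2, 3), sigmaDf = "plain",
                            deltaSign = "pred-minus-exp")
  expect_equal(s2$deltaMax, 3.0)
  # positive residual of largest magnitude keeps its positive sign
  s3 <- evaluatePredictions(predicted = c(0, 0), experimental = c(2, -1),
                            sigmaDf = "plain")
  expect_equal(s3$deltaMax, 2.0)
  # ties in |residual| resolve to the first occurrence
  s4 <- evaluatePredictions(predicted = c(3, -1), experimental = c(0, 2),
                            sigmaDf = "plain")
  expect_equal(s4$deltaMax, -3.0)
})

test_that("degenerate evaluation inputs are rejected", {
  expect_error(evaluatePredictions(1:3, 1:2), "equal length")
  expect_error(evaluatePredictions(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(evaluatePredictions(c(1, NA, 3), c(1, 2, 3)), "missing")
  expect_error(evaluatePredictions(1, 1), "at least 2")
})

test_that("all four statistics are invariant under a joint shift", {
  set.seed(8)
  e <- rnorm(25)
  p <- e + rnorm(25, 0, 0.4)
  a <- evaluatePredictions(p, e, p = 3)
  b <- evaluatePredictions(p + 100, e + 100, p = 3)
  expect_equal(b$r2, a$r2, tolerance = 1e-9)
  expect_equal(b$sigma, a$sigma, tolerance = 1e-9)
  expect_equal(b$mue, a$mue, tolerance = 1e-9)
  expect_equal(b$deltaMax, a$deltaMax, tolerance = 1e-9)
  expect_gte(a$mue, 0)
  expect_lte(a$mue, max(abs(e - p)))
})

test_that("scoring the training set reproduces the training statistics", {
  set <- generateSyntheticSet(syntheticConfig(40, seed = 21, noiseSigma = 0.4))
  model <- trainQSPR(set, defaultSynthSpecs(), algorithm = "mcuv")
  rep <- predictionReport(set, model)
  s <- rep@stats
  ts <- trainStats(model)
  expect_equal(s$r2, ts$r2, tolerance = 1e-10)
  expect_equal(s$sigma, ts$sigma, tolerance = 1e-10)
  expect_equal(s$mue, ts$mue, tolerance = 1e-10)
  expect_equal(s$deltaMax, ts$deltaMax, tolerance = 1e-10)
})

test_that("a noiseless synthetic set scores (1, 0, 0, 0)", {
  set <- generateSyntheticSet(syntheticConfig(25, seed = 4, noiseSigma = 0))
  model <- trainQSPR(set, defaultSynthSpecs())
  s <- predictionReport(set, model)@stats
  expect_equal(s$r2, 1, tolerance = 1e-9)
  expect_equal(s$sigma, 0, tolerance = 1e-7)
  expect_equal(s$mue, 0, tolerance = 1e-8)
  expect_equal(s$deltaMax, 0, tolerance = 1e-7)
})

test_that("a set without property tag yields predictions but no statistics", {
  set <- generateSyntheticSet(syntheticConfig(20, seed = 6, noiseSigma = 0.2))
  model <- trainQSPR(set, defaultSynthSpecs())
  untagged <- set
  untagged@propertyTag <- NA_character_
  rep <- predictionReport(untagged, model)
  expect_length(rep@predicted, 20)
  expect_length(rep@experimental, 0)
  expect_length(rep@residuals, 0)
  expect_length(rep@stats, 0)
  df <- as.data.frame(rep)
  expect_identical(colnames(df), c("molecule", "predicted"))
})

test_that("molecules with uncomputable model descriptors are excluded by name", {
  set <- generateSyntheticSet(syntheticConfig(12, seed = 9, noiseSigma = 0.2))
  flat <- set[[3]]
  flat@atoms$z <- 0
  set@molecules[[3]] <- flat
  specs <- descriptorRegistry()[c("molecular_weight", "radius_of_gyration")]
  model <- suppressMessages(
    fitQSPR(buildDescriptorMatrix(set[-3], specs),
            propertyValues(set)[-3], specs = specs))
  msgs <- capture_messages(rep <- predictionReport(set, model))
  expect_match(paste(msgs, collapse = " "), moleculeNames(set)[3], fixed = TRUE)
  expect_length(rep@predicted, 11)
  expect_identical(rep@excluded$molecule, moleculeNames(set)[3])
  expect_identical(rep@stats$n, 11L)
})

test_that("a model that fails on every molecule aborts the report", {
  set <- generateSyntheticSet(syntheticConfig(8, seed = 2, noiseSigma = 0))
  for (k in seq_along(set@molecules)) set@molecules[[k]]@atoms$z <- 0
  specs <- descriptorRegistry()["radius_of_gyration"]
  model <- new("QSPRModel", algorithm = "mlr",
               descriptorNames = "radius_of_gyration",
               intercept = 0, coefficients = 1,
               columnMeans = numeric(0), columnScales = numeric(0),
               projection = list(), trainStats = list(sigmaDf = "corrected"),
               specs = specs, provenance = "test")
  expect_error(suppressMessages(predictionReport(set, model)), "every molecule")
})

test_that("reports serialise to CSV with a statistics footer and to JSON", {
  set <- generateSyntheticSet(syntheticConfig(15, seed = 3, noiseSigma = 0.3))
  model <- trainQSPR(set, defaultSynthSpecs())
  rep <- predictionReport(set, model)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeReport(rep, csv)
  lines <- readLines(csv)
  expect_identical(lines[1], "molecule,predicted,experimental,residual")
  expect_identical(sum(grepl("^r2,", lines)), 1L)
  expect_identical(sum(grepl("^delta_max,", lines)), 1L)
  js <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, js)
  doc <- jsonlite::fromJSON(js)
  expect_equal(doc$stats$r2, rep@stats$r2, tolerance = 1e-12)
  expect_identical(nrow(doc$predictions), 15L)
})
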