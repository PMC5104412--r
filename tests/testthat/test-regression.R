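test_that("a noiseless linear relation is recovered exactly", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("d1", "d2")))
  y <- 2 * X[, "d1"] - 1
  m <- fitQSPR(X, y, algorithm = "mlr")
  expect_equal(m@intercept, -1, tolerance = 1e-10)
  expect_equal(unname(m@coefficients), c(2, 0), tolerance = 1e-10)
  expect_equal(trainStats(m)$r2, 1, tolerance = 1e-10)
  expect_equal(trainStats(m)$sigma, 0, tolerance = 1e-10)
})

test_that("OLS coefficients agree with the normal-equations oracle", {
  for (seed in 1:50) {
    fixt <- randomFixture(n = 30, p = 4, seed = seed)
    m <- fitQSPR(fixt$X, fixt$y, algorithm = "mlr")
    oracle <- normalEquationsFit(fixt$X, fixt$y)
    expect_equal(unname(c(m@intercept, m@coefficients)), unname(oracle),
                 tolerance = 1e-8, label = paste("seed", seed))
  }
})

test_that("rank deficiency and degenerate designs are hard errors", {
  fixt <- randomFixture(n = 25, p = 3, seed = 2)
  X <- cbind(fixt$X, dup = fixt$X[, 1])
  expect_error(fitQSPR(X, fixt$y), "rank-deficient.*dup|dup.*rank-deficient")
  # constant column: centered fit turns it into a zero column
  Xc <- cbind(fixt$X, flat = 7)
  expect_error(fitQSPR(Xc, fixt$y, algorithm = "centered"), "flat")
  # mcuv refuses zero variance by name
  expect_error(fitQSPR(Xc, fixt$y, algorithm = "mcuv"), "zero-variance.*flat")
  # too few rows
  expect_error(fitQSPR(fixt$X[1:4, ], fixt$y[1:4]), "p \\+ 1")
})

test_that("centering and autoscaling are affine reparameterisations of MLR", {
  for (seed in c(3, 17, 29)) {
    fixt <- randomFixture(n = 40, p = 5, seed = seed)
    mMlr <- fitQSPR(fixt$X, fixt$y, algorithm = "mlr")
    mCen <- fitQSPR(fixt$X, fixt$y, algorithm = "centered")
    mScl <- fitQSPR(fixt$X, fixt$y, algorithm = "mcuv")
    pMlr <- predict(mMlr, fixt$X)
    expect_equal(predict(mCen, fixt$X), pMlr, tolerance = 1e-10)
    expect_equal(predict(mScl, fixt$X), pMlr, tolerance = 1e-10)
    # back-transformed coefficients equal the MLR solution
    for (m in list(mCen, mScl)) {
      rc <- rawCoefficients(m)
      expect_equal(unname(rc$coefficients), unname(mMlr@coefficients),
                   tolerance = 1e-8)
      expect_equal(rc$intercept, mMlr@intercept, tolerance = 1e-8)
    }
    # centered design: intercept is the mean response
    expect_equal(mCen@intercept, mean(fixt$y), tolerance = 1e-10)
  }
})

test_that("fitted models minimise the residual sum of squares locally", {
  fixt <- randomFixture(n = 35, p = 3, seed = 11)
  m <- fitQSPR(fixt$X, fixt$y)
  Z <- cbind(1, fixt$X)
  beta <- c(m@intercept, m@coefficients)
  rss <- function(b) sum((fixt$y - drop(Z %*% b))^2)
  base <- rss(beta)
  for (k in seq_along(beta)) {
    for (d in c(-1e-3, 1e-3)) {
      pert <- beta
      pert[k] <- pert[k] + d
      expect_gte(rss(pert), base)
    }
  }
})

test_that("training r2 equals squared Pearson correlation of y and fitted", {
  fixt <- randomFixture(n = 50, p = 4, seed = 23)
  m <- fitQSPR(fixt$X, fixt$y)
  yhat <- predict(m, fixt$X)
  expect_equal(trainStats(m)$r2, cor(fixt$y, yhat)^2, tolerance = 1e-10)
})

test_that("rows with missing property are excluded and counted", {
  fixt <- randomFixture(n = 30, p = 3, seed = 7)
  y <- fixt$y
  y[c(2, 9, 20)] <- NA
  expect_message(m <- fitQSPR(fixt$X, y), "3 row")
  expect_identical(trainStats(m)$nExcluded, 3L)
  expect_identical(trainStats(m)$n, 27L)
  oracle <- normalEquationsFit(fixt$X[-c(2, 9, 20), ], y[-c(2, 9, 20)])
  expect_equal(unname(c(m@intercept, m@coefficients)), unname(oracle),
               tolerance = 1e-8)
})

test_that("the stereographic projection is an odd monotone bijection", {
  expect_equal(projectProperty(0, scale = 1), 0)
  expect_equal(projectProperty(0, scale = 5), 0)
  # round trip across the full aqueous-solubility range
  grid <- seq(-11.6, 1.6, by = 0.05)
  for (scale in c(0.5, 1, 3)) {
    back <- unprojectProperty(projectProperty(grid, scale), scale)
    expect_lt(max(abs(back - grid)), 1e-10)
  }
  # strictly increasing, bounded in (-pi, pi)
  set.seed(99)
  ys <- sort(runif(200, -20, 20))
  th <- projectProperty(ys)
  expect_true(all(diff(th) > 0))
  expect_true(all(th > -pi & th < pi))
  expect_error(projectProperty(1, scale = 0), "positive")
  expect_error(unprojectProperty(1, scale = -2), "positive")
  # un-projection keeps any finite input finite and ordering-consistent
  wild <- c(-50, -4, -pi, -1, 0, 1, pi, 4, 50)
  out <- unprojectProperty(wild)
  expect_true(all(is.finite(out)))
  expect_true(all(diff(out) >= 0))
})

test_that("klopman fits the projected property and predicts in property units", {
  set.seed(31)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, paste0("d", 1:3)))
  # construct y so that its projection is exactly linear in X
  theta <- drop(cbind(1, X) %*% c(0.2, 0.8, -0.5, 0.3))
  theta <- theta / (max(abs(theta)) / 2.8)  # keep inside (-pi, pi)
  y <- unprojectProperty(theta, scale = 2)
  m <- fitQSPR(X, y, algorithm = "klopman", projectionScale = 2)
  expect_equal(trainStats(m)$r2Projected, 1, tolerance = 1e-8)
  expect_equal(unname(predict(m, X)), unname(y), tolerance = 1e-8)
  expect_identical(m@projection$name, "stereographic")
  expect_equal(m@projection$scale, 2)
})

test_that("the projection changes predictions on a skewed property", {
  # property spanning the tail-heavy solubility range -11 .. 1
  set.seed(13)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- -11 + 12 * plogis(drop(X %*% c(1.5, -1, 0.5)))
  mK <- fitQSPR(X, y, algorithm = "klopman", projectionScale = 3)
  mS <- fitQSPR(X, y, algorithm = "mcuv")
  expect_gt(max(abs(predict(mK, X) - predict(mS, X))), 1e-3)
})

test_that("missing descriptor cells among training rows are refused", {
  fixt <- randomFixture(n = 20, p = 3, seed = 3)
  X <- fixt$X
  X[4, 2] <- NA
  dm <- new("DescriptorMatrix", values = X, missing = is.na(X))
  expect_error(fitQSPR(dm, fixt$y), "missing descriptor cells")
})
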