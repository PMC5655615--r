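test_that("pool reduction removes constants and caps intercorrelation", {
  set.seed(1)
  d <- rnorm(30)
  X <- cbind(c = rep(5, 30), d = d, nearc = c(rep(1, 29), 2))
  t <- DescriptorTable(paste0("r", 1:30), X, cbind(ACT = rnorm(30)))
  r <- reduceDescriptorPool(t, seed = 1)
  expect_equal(descriptorNames(r), "d")

  ## perfectly correlated pair: exactly one survives
  t2 <- DescriptorTable(paste0("r", 1:30), cbind(d = d, d2 = 2 * d),
                        cbind(ACT = rnorm(30)))
  r2 <- reduceDescriptorPool(t2, seed = 2)
  expect_equal(ncol(descriptorMatrix(r2)), 1)

  ## correlated blocks: surviving pool has max |r| <= 0.90 (brute scan)
  t3 <- makeRegressionFixture(n = 40, p = 12,
                              corrBlocks = list(size = 4, rho = 0.95),
                              seed = 3)
  r3 <- reduceDescriptorPool(t3, corrThreshold = 0.90, seed = 4)
  C <- abs(cor(descriptorMatrix(r3)))
  diag(C) <- 0
  expect_lte(max(C), 0.90)
  ## activities untouched
  expect_identical(activityMatrix(r3), activityMatrix(t3))

  tAllConst <- DescriptorTable(paste0("r", 1:5), cbind(c1 = rep(1, 5)),
                               cbind(ACT = rnorm(5)))
  expect_error(reduceDescriptorPool(tAllConst), "empty pool")
})

test_that("OLS recovers exact relations and reports honest errors", {
  x <- 1:10
  fit <- fitOls(cbind(x = x), 2 + 3 * x)
  expect_equal(fit@intercept, 2)
  expect_equal(unname(fit@coefficients["x"]), 3)
  expect_equal(fit@r2Train, 1)

  expect_warning(f0 <- fitOls(cbind(x = rnorm(10)), rep(1, 10)), "constant")
  expect_equal(f0@r2Train, 0)

  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fitOls(X, rnorm(10)), "dependent column.*c")
  expect_error(fitOls(cbind(a = rnorm(4), b = rnorm(4), c = rnorm(4)),
                      rnorm(4)), "n > k")
})

test_that("OLS coefficients and standard errors agree with lm()", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(0.5, -1, 2) + rnorm(20)
  fit <- fitOls(X, drop(y))
  ref <- summary(lm(y ~ X))
  expect_equal(unname(c(fit@intercept, fit@coefficients)),
               unname(ref$coefficients[, 1]))
  expect_equal(unname(fit@stdErrors), unname(ref$coefficients[, 2]))
  expect_equal(fit@r2Train, ref$r.squared)
  ## residual orthogonality to each selected descriptor
  res <- drop(y) - fit@fittedValues
  expect_lt(max(abs(crossprod(X, res))) / sum(abs(res) * max(abs(X))),
            1e-8)
})

test_that("exhaustive search finds planted signals and orders results", {
  t <- makeRegressionFixture(n = 20, p = 5, signal = 1, beta = 2,
                             noiseSd = 0, seed = 4)
  res <- searchLinearModels(t, "ACT", maxVars = 1, topK = 3)
  expect_equal(res[[1]]@selectedDescriptors, "D001")
  expect_equal(res[[1]]@r2Train, 1, tolerance = 1e-12)
  r2s <- vapply(res, function(f) f@r2Train, numeric(1))
  expect_true(all(diff(r2s) <= 0))

  ## exhaustive best equals a literal lm() enumeration oracle
  t2 <- makeRegressionFixture(n = 15, p = 6, signal = 1:2, beta = c(1, 1),
                              noiseSd = 2, seed = 5)
  res2 <- searchLinearModels(t2, "ACT", maxVars = 2, topK = 1)
  expect_equal(res2[[1]]@r2Train,
               bruteBestSubsetR2(descriptorMatrix(t2),
                                 activityMatrix(t2)[, 1], 2),
               tolerance = 1e-10)

  expect_error(searchLinearModels(t, "ACT", topK = 0), "topK")
  expect_error(searchLinearModels(t, "ACT", maxVars = 3,
                                  exhaustiveCap = 10), "genetic")
})

test_that("genetic search never beats the exhaustive oracle", {
  t <- makeRegressionFixture(n = 21, p = 12, signal = 1:2, beta = c(1, -1),
                             noiseSd = 1.5, seed = 6)
  ex <- searchLinearModels(t, "ACT", maxVars = 3, topK = 1,
                           computeQ2 = FALSE)[[1]]@r2Train
  agree <- 0
  for (s in 1:20) {
    set.seed(s)
    ga <- searchLinearModels(t, "ACT", maxVars = 3, method = "genetic",
                             topK = 1, computeQ2 = FALSE,
                             gaControl = list(generations = 40))[[1]]@r2Train
    expect_lte(ga, ex + 1e-12)
    agree <- agree + (abs(ga - ex) < 1e-12)
  }
  expect_gte(agree, 19)
})

test_that("degenerate (constant) responses score r2 = 0 instead of crashing", {
  t <- makeRegressionFixture(n = 10, p = 3, seed = 7)
  t@activities[, 1] <- 5
  expect_warning(res <- searchLinearModels(t, "ACT"), "constant")
  expect_equal(res[[1]]@r2Train, 0)
})

test_that("tree growth matches a brute-force Gini oracle and rpart", {
  ## hand-checkable 8-point set
  X <- cbind(f1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             f2 = c(5, 1, 4, 2, 8, 3, 9, 7))
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  tm <- fitTree(X, y, maxDepth = 1)
  oracle <- bruteBestSplit(X, y)
  expect_equal(tm@root$feature, oracle$feature)
  expect_equal(tm@root$threshold, oracle$threshold)

  ## separable 1-D data: depth 1, perfect training accuracy
  Xs <- cbind(x = c(rnorm(30, -3), rnorm(30, 3)))
  ys <- rep(c(0, 1), each = 30)
  ts <- fitTree(Xs, ys, maxDepth = 3)
  expect_equal(ts@root$type, "split")
  expect_equal(ts@root$left$type, "leaf")
  expect_equal(unname(predict(ts, Xs)), ys)

  ## depth 0: single majority leaf, constant predictions
  t0 <- fitTree(Xs, c(rep(0, 40), rep(1, 20)), maxDepth = 0)
  expect_equal(t0@root$type, "leaf")
  expect_equal(unique(predict(t0, Xs)), 0L)

  expect_error(fitTree(Xs, rep(1, 60)), "both classes")

  ## independent cross-check against rpart on a separable fixture
  ct <- makeClassificationFixture(40, 160, p = 4, signal = 1, shift = 3,
                                  seed = 8)
  Xc <- descriptorMatrix(ct); lab <- activityMatrix(ct)[, 1]
  mine <- predict(fitTree(Xc, lab, maxDepth = 2), Xc)
  rp <- rpart::rpart(factor(lab) ~ ., data = as.data.frame(Xc),
                     method = "class",
                     control = rpart::rpart.control(maxdepth = 2,
                                                    minsplit = 2, cp = 0))
  rpPred <- as.integer(as.character(predict(rp, type = "class")))
  expect_gte(mean(mine == lab), mean(rpPred == lab) - 0.01)
})

test_that("prediction contracts hold for both model kinds", {
  fit <- new("FitResult", selectedDescriptors = "d1", intercept = 2,
             coefficients = c(d1 = 3), stdErrors = numeric(0),
             r2Train = 1, q2Loo = NA_real_, fittedValues = numeric(0))
  expect_equal(unname(predict(fit, cbind(d1 = 1))), 5)
  expect_error(predict(fit, cbind(d2 = 1)), "lacks descriptor")

  t <- makeRegressionFixture(n = 15, p = 4, signal = 1, beta = 1, seed = 9)
  res <- searchLinearModels(t, "ACT", maxVars = 2, topK = 1)[[1]]
  expect_equal(unname(predict(res, descriptorMatrix(t))), res@fittedValues)
})

test_that("best-of-search r2 on pure noise grows with pool size", {
  ## selection effect, small-scale: mean best r2 over replicates is
  ## non-decreasing in p for fixed n
  means <- vapply(c(4, 12, 30), function(p) {
    mean(vapply(1:30, function(r) {
      t <- makeRegressionFixture(n = 21, p = p, seed = 5000 + 100 * p + r)
      searchLinearModels(t, "ACT", maxVars = 3, topK = 1,
                         computeQ2 = FALSE)[[1]]@r2Train
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
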