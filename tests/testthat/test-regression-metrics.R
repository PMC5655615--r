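test_that("r2 matches hand computation and degenerate conventions", {
  expect_equal(rSquared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)), 0.98)
  y <- rnorm(10)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 10)), 0)
  expect_warning(r0 <- rSquared(rep(2, 5), rnorm(5)), "constant")
  expect_equal(r0, 0)
  expect_error(rSquared(1:3, 1:4), "length mismatch")
})

test_that("LOO q2 equals the refit-per-point oracle exactly", {
  set.seed(1)
  ## 5-point toy: quadratic truth fitted by a straight line
  x <- c(-2, -1, 0, 1, 2)
  y <- x^2 + c(0.1, -0.2, 0.05, 0.15, -0.1)
  expect_equal(qSquaredCv(cbind(x = x), y, m = 1),
               naiveLooQ2(cbind(x = x), y), tolerance = 1e-12)

  for (r in 1:10) {
    n <- sample(10:25, 1); k <- sample(1:3, 1)
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    y <- rnorm(n) + X %*% rnorm(k)
    expect_equal(qSquaredCv(X, drop(y), m = 1), naiveLooQ2(X, drop(y)),
                 tolerance = 1e-12)
  }

  ## exact linear relation: q2 = 1
  expect_equal(qSquaredCv(cbind(x = 1:10), 2 + 3 * (1:10), m = 1), 1)
})

test_that("leave-three-out enumerates all triples and matches its oracle", {
  set.seed(2)
  X <- matrix(rnorm(22), 11, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(1, -1)) + rnorm(11)
  expect_equal(qSquaredCv(X, y, m = 3), naiveLmoQ2(X, y, 3),
               tolerance = 1e-12)
  expect_error(qSquaredCv(X, y, m = 3, foldCap = 10), "exceeds the cap")
})

test_that("q2 never exceeds r2 (PRESS residuals dominate LS residuals)", {
  set.seed(3)
  for (r in 1:100) {
    X <- matrix(rnorm(21 * 3), 21, 3, dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(21)
    fit <- fitOls(X, y)
    expect_lt(qSquaredCv(X, y, m = 1), fit@r2Train)
  }
})

test_that("origin regression satisfies its algebra", {
  y <- rnorm(10) + 5
  o <- originRegression(y, y)
  expect_equal(o$k, 1); expect_equal(o$R02, 1)
  expect_equal(originRegression(2 * y, y)$k, 2)
  expect_error(originRegression(y, rep(0, 10)), "all predictions are zero")

  ## R02 <= r2 of the free-intercept fit, across many random pairs
  set.seed(4)
  for (r in 1:1000) {
    yo <- rnorm(10); yp <- rnorm(10)
    free <- lm(yo ~ yp)
    expect_lte(originRegression(yo, yp)$R02,
               summary(free)$r.squared + 1e-12)
  }
})

test_that("Golbraikh-Tropsha criteria apply the stated thresholds", {
  g <- golbraikhTropsha(q2 = 0.805, R2 = 0.732, R02 = 0.70, k = 1.0)
  expect_true(g$q2); expect_true(g$R2); expect_true(g$k)
  expect_false(golbraikhTropsha(0.4, 0.732, 0.7, 1)$q2)
  expect_false(golbraikhTropsha(0.805, 0.6, 0.55, 1)$R2)  # strict
  expect_false(golbraikhTropsha(0.805, 0.732, 0.6, 1)$ratio)
  expect_false(golbraikhTropsha(0.805, 0.732, 0.73, 0.84)$k)
  expect_true(golbraikhTropsha(0.805, 0.732, 0.73, 0.85)$k)
  bad <- golbraikhTropsha(0.805, 0, 0, 1)
  expect_false(bad$ratio)
  expect_match(bad$reason, "R2 == 0")
})

test_that("cRp2 and rm2 satisfy their algebra and domains", {
  expect_equal(cRp2(0.8, 0), 0.8)
  expect_equal(rm2Test(0.75, 0.75), 0.75)
  expect_equal(rm2Test(0.81, 0.77), 0.648)
  expect_equal(rm2Test(0.64, 0.55), 0.448)
  expect_warning(v <- cRp2(0.5, 0.6), "NaN")
  expect_true(is.nan(v))
  expect_warning(w <- rm2Test(0.5, 0.6), "NaN")
  expect_true(is.nan(w))
  expect_error(cRp2(1.2, 0.1), "domain")
  expect_error(cRp2(0.5, -0.1), "domain")
  expect_error(rm2Test(0.5, -0.1), "domain")

  ## cRp2 is monotone increasing in r2 at fixed Rr2; rm2 is monotone
  ## increasing in R02 at fixed R2 (shrinking the gap raises it)
  r2grid <- seq(0.4, 1, by = 0.05)
  expect_true(all(diff(vapply(r2grid, cRp2, numeric(1),
                              rr2Random = 0.3)) > 0))
  R02grid <- seq(0, 0.8, by = 0.05)
  expect_true(all(diff(vapply(R02grid, function(r0)
    rm2Test(0.8, r0), numeric(1))) > 0))
})

test_that("randomization intercepts recover planted lines and verdicts", {
  ## flat line: all permuted values equal the true value c
  expect_equal(randomizationIntercept(c(0.2, 0.5, 0.8),
                                      rep(0.3, 3), 0.3)$intercept, 0.3)
  ## planted line 0.1 + 0.8 * corr
  corr <- c(0.1, 0.3, 0.5, 0.7)
  expect_equal(randomizationIntercept(corr, 0.1 + 0.8 * corr,
                                      0.1 + 0.8 * 1)$intercept, 0.1)
  expect_error(randomizationIntercept(rep(1, 3), rep(0.2, 3), 0.5),
               "identical")

  ## full experiment on a strong planted signal: intercepts below the
  ## 0.4 / 0.05 validity thresholds
  t <- makeRegressionFixture(n = 21, p = 6, signal = 1:3,
                             beta = c(2, 2, 2), noiseSd = 1, seed = 5)
  res <- randomizationInterceptTest(t, "ACT", c("D001", "D002", "D003"),
                                    nPerm = 25, seed = 11)
  expect_true(res$valid["r2"])
  expect_true(res$valid["q2"])
  expect_equal(nrow(res$permutations), 25)
})
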