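## Scalar validation statistics for regression QSAR models: r2, q2 by
## leave-one-out / leave-m-out cross-validation, regression through the
## origin (k, R0^2), the Golbraikh-Tropsha external-validation criteria,
## cRp^2, rm^2(test), and the response-randomization intercepts.

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; defined as 0 (with a
#' warning) for a constant observed response.
#'
#' @param yObs observed values.
#' @param yPred predicted values (same length, >= 2).
#' @return the r2 value.
#' @examples
#' rSquared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
#' @export
rSquared <- function(yObs, yPred) {
  if (length(yObs) != length(yPred)) stop("length mismatch")
  if (length(yObs) < 2) stop("need at least 2 observations")
  sstot <- sum((yObs - mean(yObs))^2)
  if (sstot == 0) {
    warning("constant observed response: r2 defined as 0")
    return(0)
  }
  1 - sum((yObs - yPred)^2) / sstot
}

#' Cross-validated q2 (leave-m-out)
#'
#' `q2 = 1 - PRESS / sum((y - mean(y))^2)` with the full-training-set
#' mean in the denominator (the usual PRESS convention).  For `m = 1`
#' every point is held out once and PRESS is computed from the hat
#' matrix of the single full fit (`e_i / (1 - h_ii)` are the exact LOO
#' residuals of OLS).  For `m > 1` all `choose(n, m)` folds are
#' enumerated; each point's squared held-out errors are averaged over
#' the folds containing it before summation (at n = 21, m = 3 this is
#' 1330 refits).
#'
#' @param X predictor matrix (n x k).
#' @param y response of length n.
#' @param m leave-out size (default 1).
#' @param foldCap refuse enumeration above this many folds.
#' @return the q2 value (may be negative).
#' @export
qSquaredCv <- function(X, y, m = 1, foldCap = 50000) {
  if (is.data.frame(X)) X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  k <- ncol(X)
  if (n - m <= k + 1)
    stop("need n - m > k + 1 (n=", n, ", m=", m, ", k=", k, ")")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("constant response: q2 defined as 0")
    return(0)
  }
  Xd <- cbind(1, X)
  if (m == 1) {
    qrX <- qr(Xd)
    if (qrX$rank < ncol(Xd)) stop("rank-deficient design in full fit")
    res <- y - drop(Xd %*% qr.coef(qrX, y))
    h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
    press <- sum((res / (1 - h))^2)
    return(1 - press / sstot)
  }
  if (choose(n, m) > foldCap)
    stop("leave-", m, "-out enumeration of ", choose(n, m),
         " folds exceeds the cap")
  folds <- combn(n, m)
  errSum <- numeric(n)
  errCnt <- numeric(n)
  for (f in seq_len(ncol(folds))) {
    out <- folds[, f]
    fit <- tryCatch(qr(Xd[-out, , drop = FALSE]),
                    error = function(e) stop("fold ", f, ": ",
                                             conditionMessage(e)))
    if (fit$rank < ncol(Xd))
      stop("fold ", f, " (held out: ", paste(out, collapse = ","),
           ") is rank-deficient")
    beta <- qr.coef(fit, y[-out])
    pred <- drop(Xd[out, , drop = FALSE] %*% beta)
    errSum[out] <- errSum[out] + (y[out] - pred)^2
    errCnt[out] <- errCnt[out] + 1
  }
  press <- sum(errSum / errCnt)
  1 - press / sstot
}

#' Regression of observed on predicted forced through the origin
#'
#' @param yObs observed values.
#' @param yPred predicted values; not all zero.
#' @return list with `k` (slope through the origin,
#'   `sum(yObs*yPred)/sum(yPred^2)`) and `R02`
#'   (`1 - sum((yObs - k*yPred)^2) / sum((yObs - mean(yObs))^2)`).
#' @export
originRegression <- function(yObs, yPred) {
  if (length(yObs) != length(yPred)) stop("length mismatch")
  sp2 <- sum(yPred^2)
  if (sp2 == 0) stop("domain error: all predictions are zero")
  k <- sum(yObs * yPred) / sp2
  sstot <- sum((yObs - mean(yObs))^2)
  R02 <- 1 - sum((yObs - k * yPred)^2) / sstot
  list(k = k, R02 = R02)
}

#' Golbraikh-Tropsha external-validation criteria
#'
#' The four widely used acceptability conditions for a predictive QSAR
#' model: `q2 > 0.5`, `R2 > 0.6`, `(R2 - R02)/R2 < 0.1` and
#' `0.85 <= k <= 1.15` (all inequalities as stated, i.e. strict where
#' strict).
#'
#' @param q2 internal cross-validated q2.
#' @param R2 external coefficient of determination.
#' @param R02 external coefficient of determination through the origin.
#' @param k slope of the regression line through the origin.
#' @return list of per-criterion logicals (`q2`, `R2`, `ratio`, `k`),
#'   `pass` (their conjunction) and `reason` (non-empty when the ratio
#'   criterion is unevaluable because `R2 == 0`).
#' @export
golbraikhTropsha <- function(q2, R2, R02, k) {
  crit <- list(q2 = q2 > 0.5, R2 = R2 > 0.6)
  reason <- character(0)
  if (R2 == 0) {
    crit$ratio <- FALSE
    reason <- "ratio criterion unevaluable: R2 == 0"
  } else {
    crit$ratio <- (R2 - R02) / R2 < 0.1
  }
  crit$k <- k >= 0.85 && k <= 1.15
  crit$pass <- crit$q2 && crit$R2 && crit$ratio && crit$k
  crit$reason <- reason
  crit
}

#' cRp2 non-randomness parameter
#'
#' `cRp2 = sqrt(r2) * sqrt(r2 - Rr2)`, where `Rr2` is the mean r2 of
#' models trained on randomized data.  Values above 0.5 indicate a model
#' unlikely to be a chance correlation.
#'
#' @param r2 training r2 of the real model, in `[0, 1]`.
#' @param rr2Random mean r2 of the randomized models (>= 0).
#' @return the cRp2 value; `NaN` with a warning when
#'   `rr2Random > r2` (the model is no better than its chance models).
#' @examples
#' cRp2(0.811, 0.669)  # 0.339
#' @export
cRp2 <- function(r2, rr2Random) {
  if (r2 < 0 || r2 > 1) stop("domain error: r2 must be in [0, 1]")
  if (rr2Random < 0) stop("domain error: rr2Random must be >= 0")
  if (rr2Random > r2) {
    warning("rr2Random exceeds r2: cRp2 undefined (NaN)")
    return(NaN)
  }
  sqrt(r2) * sqrt(r2 - rr2Random)
}

#' rm2(test) metric
#'
#' `rm2 = R2 * (1 - sqrt(R2 - R02))`, penalizing the gap between the
#' free and the through-origin external determination coefficients;
#' values above 0.5 support prediction of the absolute response values.
#'
#' @param R2 external coefficient of determination, in `[0, 1]`.
#' @param R02 through-origin external coefficient, in `[0, 1]`.
#' @return the rm2 value; `NaN` with a warning when `R02 > R2`.
#' @examples
#' rm2Test(0.81, 0.77)  # 0.648
#' @export
rm2Test <- function(R2, R02) {
  if (R2 < 0 || R2 > 1 || R02 < 0 || R02 > 1)
    stop("domain error: inputs must be in [0, 1]")
  if (R02 > R2) {
    warning("R02 exceeds R2: rm2 undefined (NaN)")
    return(NaN)
  }
  R2 * (1 - sqrt(R2 - R02))
}

#' Intercept of a randomization (permutation) regression line
#'
#' Fits an ordinary least-squares line through the points
#' `(|corr(y, y_perm)|, statistic_perm)`, augmented with the unpermuted
#' anchor point `(1, trueStat)`, and returns its intercept at zero
#' correlation.  Used for the response-randomization intercepts, whose
#' validity thresholds are 0.4 (for r2) and 0.05 (for q2).
#'
#' @param corr absolute correlations between original and permuted
#'   responses (length >= 2).
#' @param stat the statistic (r2 or q2) of each permuted-response fit.
#' @param trueStat the statistic of the unpermuted fit (the anchor).
#' @return list with `intercept` and `slope`.
#' @export
randomizationIntercept <- function(corr, stat, trueStat) {
  if (length(corr) != length(stat)) stop("length mismatch")
  if (length(corr) < 2) stop("need at least 2 permuted points")
  x <- c(corr, 1)
  yv <- c(stat, trueStat)
  if (var(x) == 0) stop("fit error: identical correlation values")
  slope <- sum((x - mean(x)) * (yv - mean(yv))) / sum((x - mean(x))^2)
  list(intercept = mean(yv) - slope * mean(x), slope = slope)
}

#' Response-randomization intercept experiment
#'
#' Refits a fixed descriptor subset on `nPerm` y-scrambled copies of the
#' training data, records each refit's r2 and q2(LOO) together with the
#' absolute correlation between the original and the permuted response,
#' and returns the intercepts of the two regression lines (with the
#' unpermuted fits as anchor points).  A valid model is expected to show
#' `R2int < 0.4` and `Q2int < 0.05`.
#'
#' @param table a [DescriptorTable-class].
#' @param activity activity column name.
#' @param descriptors descriptor subset defining the model to refit.
#' @param nPerm number of permutations (default 25).
#' @param seed master seed for the permutation streams.
#' @return list with `r2Int`, `q2Int`, the per-permutation table
#'   (`corr`, `r2`, `q2`) and logical `valid` flags.
#' @export
randomizationInterceptTest <- function(table, activity, descriptors,
                                       nPerm = 25, seed = 0) {
  stopifnot(is(table, "DescriptorTable"))
  X <- table@descriptors[, descriptors, drop = FALSE]
  y <- table@activities[, activity]
  trueFit <- fitOls(X, y)
  trueQ2 <- qSquaredCv(X, y, m = 1)
  perm <- vapply(seq_len(nPerm), function(i) {
    yp <- .withSeed(seed + i, scrambleColumn(y))
    fit <- fitOls(X, yp)
    c(corr = abs(cor(y, yp)), r2 = fit@r2Train,
      q2 = qSquaredCv(X, yp, m = 1))
  }, numeric(3))
  r2line <- randomizationIntercept(perm["corr", ], perm["r2", ],
                                   trueFit@r2Train)
  q2line <- randomizationIntercept(perm["corr", ], perm["q2", ], trueQ2)
  list(r2Int = r2line$intercept, q2Int = q2line$intercept,
       permutations = as.data.frame(t(perm)),
       valid = c(r2 = r2line$intercept < 0.4,
                 q2 = q2line$intercept < 0.05))
}
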