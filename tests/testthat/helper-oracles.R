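## Independent oracles used across the test files.  These deliberately
## avoid the package's own computational paths.

## leave-one-out q2 by literal refitting with lm()
naiveLooQ2 <- function(X, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    df <- as.data.frame(X)
    fit <- lm(y ~ ., data = cbind(df, y = y)[-i, ])
    press <- press + unname(y[i] - predict(fit, df[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

## leave-m-out q2 by literal enumeration and refitting with lm()
naiveLmoQ2 <- function(X, y, m) {
  n <- length(y)
  folds <- combn(n, m)
  errSum <- numeric(n)
  errCnt <- numeric(n)
  df <- as.data.frame(X)
  for (f in seq_len(ncol(folds))) {
    out <- folds[, f]
    fit <- lm(y ~ ., data = cbind(df, y = y)[-out, ])
    pred <- unname(predict(fit, df[out, , drop = FALSE]))
    errSum[out] <- errSum[out] + (y[out] - pred)^2
    errCnt[out] <- errCnt[out] + 1
  }
  1 - sum(errSum / errCnt) / sum((y - mean(y))^2)
}

## exhaustive best (feature, threshold) split under Gini, brute force
bruteBestSplit <- function(X, labels) {
  n <- length(labels)
  best <- list(impurity = Inf)
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2) next
    for (t in (head(ux, -1) + diff(ux) / 2)) {
      left <- X[, j] <= t
      gini <- function(l) {
        if (sum(l) == 0) return(0)
        p <- mean(labels[l])
        sum(l) / n * (1 - p^2 - (1 - p)^2)
      }
      w <- gini(left) + gini(!left)
      if (w < best$impurity - 1e-12)
        best <- list(feature = colnames(X)[j], threshold = t, impurity = w)
    }
  }
  best
}

## best subset r2 by literal enumeration with lm()
bruteBestSubsetR2 <- function(X, y, maxVars) {
  best <- -Inf
  for (k in seq_len(maxVars)) {
    sets <- combn(ncol(X), k)
    for (c in seq_len(ncol(sets))) {
      fit <- lm(y ~ X[, sets[, c], drop = FALSE])
      best <- max(best, summary(fit)$r.squared)
    }
  }
  best
}
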