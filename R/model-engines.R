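## Model-fitting stand-ins for the chance harness: descriptor-pool
## reduction, OLS with classical standard errors, exhaustive / genetic
## subset search over linear models of up to maxVars descriptors, and a
## depth-limited Gini classification tree.  The exhaustive search is the
## oracle: its best score upper-bounds any other search on the same pool.

#' Reduce a descriptor pool
#'
#' Deletes constant and near-constant descriptors (most frequent value
#' occupying more than 95\% of rows, or sample variance below 1e-12),
#' then repeatedly scans the remaining pairs and, for each pair with
#' absolute Pearson correlation above `corrThreshold`, removes one
#' member at random, until no pair exceeds the threshold.  Activities
#' are untouched.
#'
#' @param table a [DescriptorTable-class] with at least one descriptor.
#' @param corrThreshold intercorrelation cut-off (default 0.90).
#' @param seed optional seed for the random member-of-pair choice; if
#'   `NULL` the current RNG stream is used.
#' @return the reduced [DescriptorTable-class].
#' @export
reduceDescriptorPool <- function(table, corrThreshold = 0.90, seed = NULL) {
  stopifnot(is(table, "DescriptorTable"))
  if (ncol(table@descriptors) < 1) stop("table has no descriptors")
  run <- function() {
    X <- table@descriptors
    n <- nrow(X)
    keep <- vapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      if (var(x) < 1e-12) return(FALSE)
      max(table(x)) <= 0.95 * n
    }, logical(1))
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0) stop("empty pool: all descriptors constant or near-constant")
    repeat {
      C <- abs(suppressWarnings(cor(X)))
      C[!is.finite(C)] <- 0
      diag(C) <- 0
      off <- which(C > corrThreshold, arr.ind = TRUE)
      off <- off[off[, 1] < off[, 2], , drop = FALSE]
      if (nrow(off) == 0) break
      pair <- off[1, ]
      drop <- pair[[if (runif(1) < 0.5) 1 else 2]]
      X <- X[, -drop, drop = FALSE]
      if (ncol(X) == 0) stop("empty pool after correlation filtering")
    }
    out <- table
    out@descriptors <- X
    out
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Ordinary least squares with classical standard errors
#'
#' @param X numeric matrix of predictors (n x k, named columns; a
#'   data.frame is accepted).  An intercept is always included.
#' @param y numeric response of length n.
#' @return a [FitResult-class] with coefficients, standard errors,
#'   training r2 and fitted values.  `r2Train` is defined as 0 (with a
#'   warning) when the response is constant, so chance pipelines on
#'   degenerate scrambles do not crash.
#' @examples
#' X <- cbind(x = 1:10)
#' fitOls(X, 2 + 3 * X[, 1])     # intercept 2, coefficient 3, r2 = 1
#' @export
fitOls <- function(X, y) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= k + 1) stop("need n > k + 1 observations (n=", n, ", k=", k, ")")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(Xd %*% beta)
  resid <- y - fitted
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("constant response: r2 defined as 0")
    0
  } else 1 - sum(resid^2) / sstot
  sigma2 <- sum(resid^2) / (n - k - 1)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(Xd)
  new("FitResult",
      selectedDescriptors = colnames(X),
      intercept = unname(beta[1]),
      coefficients = beta[-1],
      stdErrors = se,
      r2Train = r2,
      q2Loo = NA_real_,
      fittedValues = fitted)
}

.countSubsets <- function(p, maxVars) {
  sum(vapply(seq_len(min(maxVars, p)), function(k) choose(p, k), numeric(1)))
}

#' Search linear models of up to maxVars descriptors
#'
#' Finds the best-scoring (training r2) linear models over all
#' non-empty descriptor subsets of size at most `maxVars`.  The
#' exhaustive method enumerates every subset (the oracle); the genetic
#' method runs a GA over subsets (population 100, 200 generations,
#' tournament selection of size 3, uniform crossover on descriptor index
#' sets, swap mutation with probability 0.1, elitism 5 by default) and
#' is intended for pools where enumeration is infeasible.
#'
#' @param table a [DescriptorTable-class].
#' @param activity name of the activity column to model.
#' @param maxVars maximal number of descriptors per model (default 3).
#' @param method `"exhaustive"` or `"genetic"`.
#' @param topK number of best models to return (default 10).
#' @param gaControl named list overriding GA defaults: `population`,
#'   `generations`, `tournament`, `mutationProb`, `elitism`.
#' @param exhaustiveCap refuse exhaustive enumeration above this many
#'   subsets (default 200000) and instruct use of the genetic method.
#' @param computeQ2 also compute leave-one-out q2 for the returned
#'   models (default TRUE).
#' @return list of [FitResult-class], sorted by decreasing `r2Train`;
#'   for a constant (degenerate) response, a single intercept-only
#'   result with `r2Train = 0` is returned with a warning.
#' @export
searchLinearModels <- function(table, activity, maxVars = 3,
                               method = c("exhaustive", "genetic"),
                               topK = 10, gaControl = list(),
                               exhaustiveCap = 200000, computeQ2 = TRUE) {
  method <- match.arg(method)
  stopifnot(is(table, "DescriptorTable"))
  if (topK < 1) stop("topK must be >= 1")
  if (!activity %in% activityNames(table))
    stop("activity column '", activity, "' not found")
  X <- table@descriptors
  p <- ncol(X)
  if (p < 1) stop("table has no descriptors")
  if (maxVars < 1) stop("maxVars must be >= 1")
  y <- table@activities[, activity]
  yc <- y - mean(y)
  sstot <- sum(yc^2)
  if (sstot == 0) {
    warning("constant response: returning intercept-only model with r2 = 0")
    res <- new("FitResult", selectedDescriptors = character(0),
               intercept = mean(y), coefficients = setNames(numeric(0),
               character(0)), stdErrors = c(`(Intercept)` = 0), r2Train = 0,
               q2Loo = 0, fittedValues = rep(mean(y), length(y)))
    return(list(res))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  G <- crossprod(Xc)
  b <- drop(crossprod(Xc, yc))
  if (method == "exhaustive") {
    if (.countSubsets(p, maxVars) > exhaustiveCap)
      stop("exhaustive enumeration of ", .countSubsets(p, maxVars),
           " subsets exceeds the cap (", exhaustiveCap,
           "); use method = 'genetic'")
    hit <- .cppExhaustiveSearch(G, b, sstot, as.integer(maxVars),
                                as.integer(topK))
    subsets <- hit$subsets
  } else {
    subsets <- .gaSearch(G, b, sstot, p, maxVars, topK, gaControl)
  }
  .buildFitResults(table, X, y, subsets, computeQ2)
}

.buildFitResults <- function(table, X, y, subsets, computeQ2) {
  out <- vector("list", nrow(subsets))
  for (r in seq_len(nrow(subsets))) {
    idx <- subsets[r, ]
    idx <- idx[idx > 0]
    fr <- fitOls(X[, idx, drop = FALSE], y)
    if (computeQ2)
      fr@q2Loo <- qSquaredCv(X[, idx, drop = FALSE], y, m = 1)
    out[[r]] <- fr
  }
  out[order(vapply(out, function(f) f@r2Train, numeric(1)),
            decreasing = TRUE)]
}

## GA over descriptor-index sets.  Chromosomes are 0-padded sorted
## integer rows; fitness is the Gram-based r2 of the subset.
.gaSearch <- function(G, b, sstot, p, maxVars, topK, control = list()) {
  ctl <- modifyList(list(population = 100, generations = 200,
                         tournament = 3, mutationProb = 0.1,
                         elitism = 5), control)
  pad <- function(s) c(sort(s), rep(0L, maxVars - length(s)))
  randomSubset <- function() {
    k <- sample.int(maxVars, 1)
    pad(sample.int(p, min(k, p)))
  }
  pop <- t(vapply(seq_len(ctl$population), function(i) randomSubset(),
                  integer(maxVars)))
  bestSeen <- matrix(0L, 0, maxVars)
  bestSeenR2 <- numeric(0)
  for (gen in seq_len(ctl$generations)) {
    fit <- .cppScoreSubsets(G, b, sstot, pop)
    ord <- order(fit, decreasing = TRUE)
    ## archive distinct top chromosomes
    keep <- unique(rbind(bestSeen, pop[ord[seq_len(min(topK, nrow(pop)))], ,
                                       drop = FALSE]))
    keepR2 <- .cppScoreSubsets(G, b, sstot, keep)
    ko <- order(keepR2, decreasing = TRUE)
    keep <- keep[ko[seq_len(min(topK, nrow(keep)))], , drop = FALSE]
    bestSeen <- keep
    bestSeenR2 <- keepR2[ko[seq_len(nrow(keep))]]
    if (gen == ctl$generations) break
    elite <- pop[ord[seq_len(ctl$elitism)], , drop = FALSE]
    children <- t(vapply(seq_len(ctl$population - ctl$elitism), function(i) {
      tourney <- function() {
        cand <- sample.int(nrow(pop), ctl$tournament)
        pop[cand[which.max(fit[cand])], ]
      }
      p1 <- tourney(); p2 <- tourney()
      s1 <- p1[p1 > 0]; s2 <- p2[p2 > 0]
      pool <- union(s1, s2)
      size <- if (runif(1) < 0.5) length(s1) else length(s2)
      child <- sample(pool, min(size, length(pool)))
      if (runif(1) < ctl$mutationProb) {
        outside <- setdiff(seq_len(p), child)
        if (length(outside) > 0 && length(child) > 0) {
          child[sample.int(length(child), 1)] <-
            outside[sample.int(length(outside), 1)]
          child <- unique(child)
        }
      }
      pad(child)
    }, integer(maxVars)))
    pop <- rbind(elite, children)
  }
  bestSeen
}

## ---- classification tree -------------------------------------------

#' Fit a depth-limited binary classification tree
#'
#' Greedy CART-style growth under Gini impurity.  Candidate thresholds
#' are midpoints of consecutive sorted unique feature values; ties are
#' broken deterministically towards the lowest feature index, then the
#' lowest threshold, so the fit is a pure function of its inputs.
#'
#' @param X numeric feature matrix (n x p, named columns).
#' @param labels binary (0/1) vector of length n; both classes must be
#'   present.
#' @param maxDepth depth cap (default 3); `maxDepth = 0` yields a
#'   single majority-class leaf.
#' @param minSplit minimum node size to attempt a split (default 2).
#' @return a [TreeModel-class].
#' @export
fitTree <- function(X, labels, maxDepth = 3, minSplit = 2) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training labels")
  root <- .growNode(X, labels, depth = 0, maxDepth = maxDepth,
                    minSplit = minSplit)
  new("TreeModel", root = root, maxDepth = as.integer(maxDepth),
      featureNames = colnames(X))
}

.leaf <- function(labels) {
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  list(type = "leaf", class = if (n1 > n0) 1L else 0L,
       n = length(labels), counts = c(`0` = n0, `1` = n1))
}

.bestSplit <- function(X, labels) {
  n <- length(labels)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- labels[ord]
    cut <- which(xs[-n] < xs[-1])          # split after these positions
    if (length(cut) == 0) next
    c1 <- cumsum(ys)[cut]                  # positives left of each split
    nL <- cut; nR <- n - nL
    p1 <- sum(ys)
    giniL <- 1 - (c1 / nL)^2 - ((nL - c1) / nL)^2
    giniR <- 1 - ((p1 - c1) / nR)^2 - ((nR - p1 + c1) / nR)^2
    w <- (nL * giniL + nR * giniR) / n
    i <- which.min(w)                      # ties -> lowest threshold
    if (is.null(best) || w[i] < best$impurity - 1e-12) {
      best <- list(feature = j,
                   threshold = (xs[cut[i]] + xs[cut[i] + 1]) / 2,
                   impurity = w[i])
    }
  }
  best
}

.growNode <- function(X, labels, depth, maxDepth, minSplit) {
  n1 <- sum(labels)
  if (depth >= maxDepth || n1 == 0 || n1 == length(labels) ||
      length(labels) < minSplit)
    return(.leaf(labels))
  sp <- .bestSplit(X, labels)
  if (is.null(sp)) return(.leaf(labels))
  left <- X[, sp$feature] <= sp$threshold
  list(type = "split", feature = colnames(X)[sp$feature],
       threshold = sp$threshold,
       left = .growNode(X[left, , drop = FALSE], labels[left],
                        depth + 1, maxDepth, minSplit),
       right = .growNode(X[!left, , drop = FALSE], labels[!left],
                         depth + 1, maxDepth, minSplit))
}

#' @describeIn fitOls Predict from a fitted linear model; `newdata`
#'   must cover the model's descriptors by name.
#' @param object a fitted model.
#' @param newdata matrix or data.frame of descriptor values.
#' @param ... unused.
#' @export
setMethod("predict", "FitResult", function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  missing <- setdiff(object@selectedDescriptors, colnames(newdata))
  if (length(missing))
    stop("newdata lacks descriptor column(s): ",
         paste(missing, collapse = ", "))
  if (length(object@selectedDescriptors) == 0)
    return(rep(object@intercept, nrow(newdata)))
  drop(object@intercept +
       newdata[, object@selectedDescriptors, drop = FALSE] %*%
       object@coefficients[object@selectedDescriptors])
})

#' @describeIn fitTree Predict class labels: rows are routed from the
#'   root, going left when `value <= threshold`.
#' @param object a [TreeModel-class].
#' @param newdata matrix or data.frame of descriptor values.
#' @param ... unused.
#' @export
setMethod("predict", "TreeModel", function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  used <- .treeFeatures(object@root)
  missing <- setdiff(used, colnames(newdata))
  if (length(missing))
    stop("newdata lacks descriptor column(s): ",
         paste(missing, collapse = ", "))
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object@root
    while (node$type == "split") {
      node <- if (newdata[i, node$feature] <= node$threshold)
        node$left else node$right
    }
    node$class
  }, integer(1))
})

.treeFeatures <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$feature, .treeFeatures(node$left), .treeFeatures(node$right)))
}
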