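## The headline procedure: fit models on every randomized set exactly as
## on the real data, collect each set's best statistics, and summarize
## chance performance as mean-highest +/- k*SD thresholds.

#' Model-engine configurations for the chance harness
#'
#' `mlrEngine` is the subset-search linear-regression engine (pool
#' reduction, then exhaustive or genetic search over models of up to
#' `maxVars` descriptors).  `fixedEngine` refits one fixed descriptor
#' subset with no search (the null-calibration engine: under a pure
#' null, E[r2] = k/(n-1) for k predictors).  `treeEngine` is the
#' depth-limited classification tree, collecting confusion counts and
#' the six threshold metrics per set.
#'
#' @param maxVars maximal model size for the subset search.
#' @param method `"exhaustive"` or `"genetic"`.
#' @param topK models retained per set (the best one defines the set's
#'   score).
#' @param corrFilter intercorrelation threshold for pool reduction, or
#'   `NA` to skip reduction.
#' @param gaControl GA settings override (see [searchLinearModels()]).
#' @param descriptors fixed descriptor subset for `fixedEngine`.
#' @param maxDepth depth cap for `treeEngine`.
#' @param computeQ2 whether regression engines also compute q2(LOO).
#' @return an engine configuration list for [runChanceTest()].
#' @export
mlrEngine <- function(maxVars = 3, method = c("exhaustive", "genetic"),
                      topK = 1, corrFilter = 0.90, gaControl = list(),
                      computeQ2 = TRUE) {
  list(type = "mlr-subset", maxVars = maxVars, method = match.arg(method),
       topK = topK, corrFilter = corrFilter, gaControl = gaControl,
       computeQ2 = computeQ2)
}

#' @rdname mlrEngine
#' @export
fixedEngine <- function(descriptors, computeQ2 = TRUE) {
  list(type = "fixed", descriptors = descriptors, computeQ2 = computeQ2)
}

#' @rdname mlrEngine
#' @export
treeEngine <- function(maxDepth = 3, corrFilter = NA) {
  list(type = "tree", maxDepth = maxDepth, corrFilter = corrFilter)
}

#' Run an engine once on a table
#'
#' Applies the engine's full pipeline (pool reduction where configured,
#' then fit/search) to one table, seeding the engine's own randomness
#' (pool-reduction tie-breaks, GA) with `seed`.  This is the exact
#' procedure [runChanceTest()] applies to every randomized set, exposed
#' so the real-data run is guaranteed identical.
#'
#' @param table a [DescriptorTable-class].
#' @param engine an engine configuration from [mlrEngine()] and
#'   friends.
#' @param activity name of the activity column to model (regression) or
#'   of the binary label column (classification).
#' @param seed engine seed.
#' @return for regression engines, a list with `scores` (named vector;
#'   `r2` and possibly `q2`) and `models` (list of [FitResult-class]);
#'   for the tree engine, `scores` (counts and the six metrics) and
#'   `models` (the [TreeModel-class]).
#' @export
runEngine <- function(table, engine, activity, seed = 0) {
  .withSeed(seed, {
    tbl <- table
    if (!is.null(engine$corrFilter) && !is.na(engine$corrFilter))
      tbl <- reduceDescriptorPool(tbl, engine$corrFilter)
    switch(engine$type,
      "mlr-subset" = {
        models <- searchLinearModels(tbl, activity,
                                     maxVars = engine$maxVars,
                                     method = engine$method,
                                     topK = engine$topK,
                                     gaControl = engine$gaControl,
                                     computeQ2 = engine$computeQ2)
        best <- models[[1]]
        scores <- c(r2 = best@r2Train)
        if (engine$computeQ2) {
          scores["q2"] <- best@q2Loo
          scores["maxQ2"] <- max(vapply(models, function(m) m@q2Loo,
                                        numeric(1)))
        }
        list(scores = scores, models = models)
      },
      "fixed" = {
        X <- tbl@descriptors[, engine$descriptors, drop = FALSE]
        y <- tbl@activities[, activity]
        fit <- fitOls(X, y)
        scores <- c(r2 = fit@r2Train)
        if (engine$computeQ2) {
          fit@q2Loo <- qSquaredCv(X, y, m = 1)
          scores["q2"] <- fit@q2Loo
        }
        list(scores = scores, models = list(fit))
      },
      "tree" = {
        X <- tbl@descriptors
        labels <- tbl@activities[, activity]
        model <- fitTree(X, labels, maxDepth = engine$maxDepth)
        counts <- confusionCounts(labels, predict(model, X))
        scores <- c(tp = counts@tp, tn = counts@tn, fp = counts@fp,
                    fn = counts@fn, classificationMetrics(counts))
        list(scores = scores, models = model)
      },
      stop("unknown engine type: ", engine$type))
  })
}

#' Run the full chance-correlation test
#'
#' Generates the plan's randomized tables, applies the engine to each
#' one exactly as it would be applied to the real data (same pool
#' reduction, same search settings; engine randomness seeded per set),
#' collects each set's best scores, and summarizes them as
#' mean-highest values with sample-SD thresholds at +1, +2.3 and +3 SD
#' (2.3 SD being the usual normal-theory stand-in for the 99th
#' percentile).
#'
#' For regression engines the per-set score is the highest training r2
#' among the models the search returned, together with *that* model's
#' q2; with `collect = "max-q2"` the set's maximal q2 over the retained
#' models is recorded instead.  A set whose scramble degenerates (e.g. a
#' constant permuted response) records r2 = 0 with a warning rather
#' than aborting, so exactly `nSets` entries are always present.
#'
#' @param table the real-data [DescriptorTable-class]; never mutated.
#' @param plan a [RandomizationPlan-class].
#' @param engine an engine configuration from [mlrEngine()] and
#'   friends.
#' @param activity activity/label column name (defaults to the plan's
#'   target for y-scrambling, else the table's first activity).
#' @param collect `"best-r2"` (default) or `"max-q2"`.
#' @return a [ChanceSummary-class].
#' @export
runChanceTest <- function(table, plan, engine,
                          activity = NULL, collect = c("best-r2", "max-q2")) {
  collect <- match.arg(collect)
  stopifnot(is(table, "DescriptorTable"), is(plan, "RandomizationPlan"))
  if (is.null(activity)) {
    activity <- if (plan@mode == "y_scramble") plan@targetFields[1]
                else activityNames(table)[1]
  }
  sets <- generateSets(table, plan)
  perSet <- lapply(seq_along(sets), function(i) {
    runEngine(sets[[i]], engine, activity,
              seed = plan@masterSeed + 500000 + i)$scores
  })
  nm <- names(perSet[[1]])
  scores <- lapply(nm, function(s)
    vapply(perSet, function(v) unname(v[s]), numeric(1)))
  names(scores) <- nm
  if (engine$type != "tree") {
    keep <- c("r2", if ("q2" %in% nm)
      if (collect == "max-q2") "maxQ2" else "q2")
    scores <- scores[keep]
    names(scores) <- sub("maxQ2", "q2", names(scores))
  }
  summary <- do.call(rbind, lapply(scores, function(s)
    as.data.frame(as.list(summarizeScores(s, naRm = TRUE)))))
  rownames(summary) <- names(scores)
  new("ChanceSummary", mode = plan@mode, family = plan@family,
      nSets = plan@nSets, scores = scores, summary = summary)
}

#' Mean, SD and +k*SD thresholds of chance scores
#'
#' @param bestScores numeric vector of per-set best scores (length
#'   >= 2).
#' @param k threshold multipliers (default 1, 2.3 and 3).
#' @param naRm drop NA/NaN entries before summarizing.
#' @return named numeric vector: `mean`, `sd`, then `plus<k>sd` for
#'   each k (sample SD, n-1 denominator).
#' @examples
#' summarizeScores(c(0.5, 0.55, 0.6))
#' @export
summarizeScores <- function(bestScores, k = c(1, 2.3, 3), naRm = FALSE) {
  if (naRm) bestScores <- bestScores[is.finite(bestScores)]
  if (length(bestScores) < 2)
    stop("need at least 2 scores to summarize")
  m <- mean(bestScores)
  s <- sd(bestScores)
  thr <- m + k * s
  names(thr) <- paste0("plus", k, "sd")
  c(mean = m, sd = s, thr)
}

#' Compare a real-data statistic with its chance distribution
#'
#' @param realStat the statistic (e.g. training r2) of the model fitted
#'   on the real data.
#' @param summary a [ChanceSummary-class].
#' @param k SD multiplier for the threshold (default 2.3, the
#'   normal-theory 99th percentile).
#' @param statistic which collected score to compare against (default
#'   `"r2"`).
#' @return list with the `threshold` (`mean + k*sd`), logical
#'   `betterThanChance` (strict inequality), the `margin`
#'   (`realStat - threshold`) and the `percentile` of `realStat` within
#'   the empirical chance scores.
#' @export
compareToChance <- function(realStat, summary, k = 2.3, statistic = "r2") {
  stopifnot(is(summary, "ChanceSummary"))
  if (!statistic %in% names(summary@scores))
    stop("no collected scores for statistic '", statistic, "'")
  s <- summary@scores[[statistic]]
  s <- s[is.finite(s)]
  realStat <- unname(realStat)
  thr <- mean(s) + k * sd(s)
  list(threshold = thr,
       betterThanChance = realStat > thr,
       margin = realStat - thr,
       percentile = 100 * mean(s < realStat))
}
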