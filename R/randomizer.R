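## Randomization of descriptor tables: y-scrambling, x-scrambling and
## pseudo-descriptor sampling.  All randomness is drawn from R's
## Mersenne-Twister 19937 generator; randomized set i of a plan is
## generated from a stream seeded with masterSeed + i, so a run is a
## pure function of (table, plan).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Permute a column in place (Fisher-Yates shuffle)
#'
#' Draws a uniformly random permutation of the input from the current
#' RNG stream.  The multiset of values is conserved exactly; identity
#' permutations are allowed (rejecting them would bias the null).
#'
#' @param column non-empty numeric vector.
#' @return a permutation of `column`.
#' @examples
#' set.seed(1); scrambleColumn(1:5)
#' @export
scrambleColumn <- function(column) {
  n <- length(column)
  if (n < 1) stop("cannot scramble an empty column")
  if (n == 1) return(column)
  for (i in n:2) {
    j <- min(floor(runif(1) * i) + 1, i)
    tmp <- column[i]; column[i] <- column[j]; column[j] <- tmp
  }
  column
}

#' Fit distribution parameters to a column
#'
#' Moment-style fits used to parameterize pseudo-descriptor sampling:
#' uniform uses the column range; normal the sample mean and SD (n-1
#' denominator); poisson and exponential the sample mean; binomial takes
#' `trials = round(max)` and `prob = mean/trials` clamped to `[0, 1]`.
#'
#' @param column non-empty numeric vector.
#' @param family one of `"uniform"`, `"normal"`, `"binomial"`,
#'   `"poisson"`, `"exponential"`.
#' @return a [DistributionSpec-class].
#' @examples
#' fitDistributionParams(c(1, 3), "normal")  # mean 2, sd sqrt(2)
#' @export
fitDistributionParams <- function(column, family) {
  if (length(column) < 1) stop("empty column")
  if (family %in% c("poisson", "exponential", "binomial") && any(column < 0))
    stop("domain error: ", family, " requires non-negative values")
  switch(family,
    uniform = DistributionSpec("uniform", lower = min(column),
                               upper = max(column)),
    normal = DistributionSpec("normal", mean = mean(column),
                              sd = if (length(column) > 1) sd(column) else 0),
    poisson = DistributionSpec("poisson", rate = mean(column)),
    exponential = {
      m <- mean(column)
      if (m == 0) stop("domain error: zero mean column for exponential")
      DistributionSpec("exponential", rate = 1 / m)
    },
    binomial = {
      trials <- max(1, round(max(column)))
      DistributionSpec("binomial", trials = trials,
                       prob = min(1, max(0, mean(column) / trials)))
    },
    stop("unknown family: ", family))
}

#' Draw pseudo-descriptor values from a distribution
#'
#' @param spec a [DistributionSpec-class].
#' @param n number of draws (>= 1), taken from the current RNG stream.
#' @return numeric vector of length `n` within the family's support.
#' @export
samplePseudo <- function(spec, n) {
  stopifnot(is(spec, "DistributionSpec"))
  validObject(spec)
  if (n < 1) stop("n must be >= 1")
  p <- spec@parameters
  switch(spec@family,
    uniform = runif(n, p["lower"], p["upper"]),
    normal = rnorm(n, p["mean"], p["sd"]),
    binomial = as.numeric(rbinom(n, p["trials"], p["prob"])),
    poisson = as.numeric(rpois(n, p["rate"])),
    exponential = rexp(n, p["rate"]),
    stop("cannot sample family '", spec@family, "'"))
}

#' Generate randomized copies of a table
#'
#' Produces `nSets(plan)` randomized tables.  In `y_scramble` mode every
#' target activity column is independently permuted and the descriptor
#' matrix is left bit-identical; in `x_scramble` mode (equivalently,
#' pseudo mode with family `"original"`) each target descriptor column
#' is independently permuted and the activities are untouched; in
#' `pseudo` mode each target descriptor column is replaced by draws from
#' the chosen family with parameters fitted to the original column.
#' Set i uses a Mersenne-Twister stream seeded with `masterSeed + i`,
#' so replicates are reproducible and mutually independent, and every
#' set permutes the *original* column (permutations are not chained).
#'
#' @param table a [DescriptorTable-class].
#' @param plan a [RandomizationPlan-class]; its target fields must exist
#'   in `table` (activities for y-scrambling, descriptors otherwise).
#' @return list of `nSets` [DescriptorTable-class] objects.
#' @examples
#' t <- makeRegressionFixture(n = 6, p = 3, seed = 1)
#' sets <- generateSets(t, RandomizationPlan("y_scramble", "ACT",
#'                                           nSets = 3, masterSeed = 7))
#' @export
generateSets <- function(table, plan) {
  stopifnot(is(table, "DescriptorTable"), is(plan, "RandomizationPlan"))
  validObject(plan)
  pool <- if (plan@mode == "y_scramble") activityNames(table)
          else descriptorNames(table)
  missing <- setdiff(plan@targetFields, pool)
  if (length(missing))
    stop("configuration error: target field(s) not available for mode ",
         plan@mode, ": ", paste(missing, collapse = ", "))
  lapply(seq_len(plan@nSets), function(i) {
    .withSeed(plan@masterSeed + i, .randomizeOnce(table, plan))
  })
}

.randomizeOnce <- function(table, plan) {
  out <- table
  if (plan@mode == "y_scramble") {
    for (f in plan@targetFields)
      out@activities[, f] <- scrambleColumn(table@activities[, f])
  } else {
    n <- nCompounds(table)
    for (f in plan@targetFields) {
      if (plan@family == "original") {
        out@descriptors[, f] <- scrambleColumn(table@descriptors[, f])
      } else {
        spec <- fitDistributionParams(table@descriptors[, f], plan@family)
        out@descriptors[, f] <- samplePseudo(spec, n)
      }
    }
  }
  out
}

#' Write randomized sets to disk
#'
#' Convenience wrapper used by the command-line tool: generates the
#' randomized sets and writes each as `<stem>_set<i>.<ext>` (i
#' zero-padded from 001), in CSV or, when the table carries SD payloads,
#' SDF.
#'
#' @param table a [DescriptorTable-class].
#' @param plan a [RandomizationPlan-class].
#' @param outDir output directory (created if needed).
#' @param stem file-name stem.
#' @param format `"csv"` or `"sdf"`.
#' @return invisibly, the vector of files written.
#' @export
writeRandomizedSets <- function(table, plan, outDir, stem = "random",
                                format = c("csv", "sdf")) {
  format <- match.arg(format)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  sets <- generateSets(table, plan)
  files <- vapply(seq_along(sets), function(i) {
    f <- file.path(outDir, sprintf("%s_set%03d.%s", stem, i, format))
    if (format == "csv") writeDescriptorCsv(sets[[i]], f)
    else writeDescriptorSdf(sets[[i]], f)
    f
  }, character(1))
  invisible(files)
}
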