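#' @import methods
#' @importFrom stats cor predict rbinom rexp rnorm rpois runif sd
#'   setNames var
#' @importFrom utils combn head modifyList
#' @useDynLib ChanceQSAR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' DescriptorTable: compounds by (descriptors + activities)
#'
#' Central container of the package: one row per compound, a numeric
#' descriptor matrix, one or more numeric activity columns (binary 0/1
#' allowed), and, for tables read from an MDL SD file, the verbatim
#' per-record payload needed to write the file back byte-identically.
#'
#' @slot recordIds unique compound identifiers (molblock title line for
#'   SDF input, id column for CSV input).
#' @slot descriptors numeric matrix, n compounds x p descriptors, with
#'   unique column names.
#' @slot activities numeric matrix, n compounds x a activities; column
#'   names disjoint from the descriptor names.
#' @slot sdfRecords list of parsed SD records (length n) when the table
#'   came from an SD file, otherwise empty.  Molblocks are opaque text.
#' @slot metadata free-form list; synthetic fixtures store their
#'   generating truth (signal subset, coefficients, population R2) here.
#'
#' @seealso [readDescriptorCsv()], [readDescriptorSdf()],
#'   [makeRegressionFixture()]
#' @export
setClass("DescriptorTable",
  representation(
    recordIds   = "character",
    descriptors = "matrix",
    activities  = "matrix",
    sdfRecords  = "list",
    metadata    = "list"
  ),
  prototype(
    recordIds   = character(0),
    descriptors = matrix(numeric(0), 0, 0),
    activities  = matrix(numeric(0), 0, 0),
    sdfRecords  = list(),
    metadata    = list()
  )
)

setValidity("DescriptorTable", function(object) {
  msg <- character(0)
  n <- length(object@recordIds)
  if (nrow(object@descriptors) != n)
    msg <- c(msg, "nrow(descriptors) must equal length(recordIds)")
  if (nrow(object@activities) != n)
    msg <- c(msg, "nrow(activities) must equal length(recordIds)")
  if (anyDuplicated(object@recordIds))
    msg <- c(msg, "record ids must be unique")
  dn <- colnames(object@descriptors)
  an <- colnames(object@activities)
  if (ncol(object@descriptors) > 0 && is.null(dn))
    msg <- c(msg, "descriptor columns must be named")
  if (ncol(object@activities) > 0 && is.null(an))
    msg <- c(msg, "activity columns must be named")
  if (anyDuplicated(dn)) msg <- c(msg, "descriptor names must be unique")
  if (anyDuplicated(an)) msg <- c(msg, "activity names must be unique")
  if (length(intersect(dn, an)) > 0)
    msg <- c(msg, "descriptor and activity names must be disjoint")
  if (!is.numeric(object@descriptors))
    msg <- c(msg, "descriptors must be numeric")
  if (!is.numeric(object@activities))
    msg <- c(msg, "activities must be numeric")
  if (length(object@sdfRecords) > 0 && length(object@sdfRecords) != n)
    msg <- c(msg, "sdfRecords, when present, must have one entry per record")
  if (length(msg)) msg else TRUE
})

#' Construct a DescriptorTable
#'
#' @param recordIds character vector of unique compound ids.
#' @param descriptors numeric matrix (or data.frame) of descriptors.
#' @param activities numeric matrix (or data.frame) of activities.
#' @param sdfRecords optional list of SD records (internal use).
#' @param metadata optional list of free-form metadata.
#' @return a validated [DescriptorTable-class] object.
#' @examples
#' DescriptorTable(c("a", "b"),
#'                 cbind(d1 = c(1, 2), d2 = c(3, 4)),
#'                 cbind(act = c(0.1, 0.9)))
#' @export
DescriptorTable <- function(recordIds, descriptors, activities,
                            sdfRecords = list(), metadata = list()) {
  descriptors <- .asNamedMatrix(descriptors, length(recordIds))
  activities <- .asNamedMatrix(activities, length(recordIds))
  new("DescriptorTable", recordIds = as.character(recordIds),
      descriptors = descriptors, activities = activities,
      sdfRecords = sdfRecords, metadata = metadata)
}

.asNamedMatrix <- function(x, n) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x)) x <- matrix(numeric(0), n, 0)
  if (!is.matrix(x)) stop("expected a matrix or data.frame")
  storage.mode(x) <- "double"
  rownames(x) <- NULL
  x
}

#' RandomizationPlan: what to randomize and how
#'
#' @slot mode one of `"y_scramble"`, `"x_scramble"`, `"pseudo"`.
#' @slot targetFields columns to randomize (activities for y-scrambling,
#'   descriptors otherwise).
#' @slot family distribution family for pseudo-descriptors: one of
#'   `"uniform"`, `"normal"`, `"binomial"`, `"poisson"`, `"exponential"`,
#'   `"original"`.  `"original"` keeps each column's own values and is
#'   equivalent to per-column permutation (x-scrambling).
#' @slot nSets number of randomized tables to generate.
#' @slot masterSeed master seed; randomized set i uses a Mersenne-Twister
#'   stream seeded with `masterSeed + i`.
#' @export
setClass("RandomizationPlan",
  representation(
    mode         = "character",
    targetFields = "character",
    family       = "character",
    nSets        = "integer",
    masterSeed   = "integer"
  )
)

setValidity("RandomizationPlan", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("y_scramble", "x_scramble", "pseudo"))
    msg <- c(msg, "mode must be y_scramble, x_scramble or pseudo")
  if (!object@family %in% c("uniform", "normal", "binomial", "poisson",
                            "exponential", "original"))
    msg <- c(msg, "unknown distribution family")
  if (object@mode == "x_scramble" && object@family != "original")
    msg <- c(msg, "x_scramble implies family 'original'")
  if (length(object@targetFields) < 1)
    msg <- c(msg, "targetFields must be non-empty")
  if (object@nSets < 1L) msg <- c(msg, "nSets must be >= 1")
  if (object@masterSeed < 0L) msg <- c(msg, "masterSeed must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a RandomizationPlan
#'
#' @param mode `"y_scramble"`, `"x_scramble"` or `"pseudo"`.
#' @param targetFields columns to randomize.
#' @param family pseudo-descriptor distribution family; forced to
#'   `"original"` for the scrambling modes.
#' @param nSets number of randomized sets (default 300, the usual scale
#'   of a y-randomization experiment).
#' @param masterSeed non-negative integer master seed.
#' @return a [RandomizationPlan-class] object.
#' @examples
#' RandomizationPlan("y_scramble", "act", nSets = 300, masterSeed = 42)
#' @export
RandomizationPlan <- function(mode, targetFields, family = "uniform",
                              nSets = 300L, masterSeed = 0L) {
  if (mode %in% c("y_scramble", "x_scramble")) family <- "original"
  new("RandomizationPlan", mode = mode,
      targetFields = as.character(targetFields), family = family,
      nSets = as.integer(nSets), masterSeed = as.integer(masterSeed))
}

#' DistributionSpec: a fitted (or user-given) sampling distribution
#'
#' @slot family distribution family tag.
#' @slot parameters named numeric vector of family-specific parameters:
#'   uniform `(lower, upper)`, normal `(mean, sd)`, binomial
#'   `(trials, prob)`, poisson `(rate)`, exponential `(rate)`.
#' @export
setClass("DistributionSpec",
  representation(family = "character", parameters = "numeric")
)

setValidity("DistributionSpec", function(object) {
  p <- object@parameters
  ok <- switch(object@family,
    uniform = all(c("lower", "upper") %in% names(p)) && p["lower"] <= p["upper"],
    normal = all(c("mean", "sd") %in% names(p)) && p["sd"] >= 0,
    binomial = all(c("trials", "prob") %in% names(p)) &&
      p["trials"] >= 1 && p["prob"] >= 0 && p["prob"] <= 1,
    poisson = "rate" %in% names(p) && p["rate"] >= 0,
    exponential = "rate" %in% names(p) && p["rate"] > 0,
    FALSE)
  if (isTRUE(ok)) TRUE else "invalid or incomplete distribution parameters"
})

#' @rdname DistributionSpec-class
#' @param family distribution family tag.
#' @param ... named parameters (see slot documentation).
#' @export
DistributionSpec <- function(family, ...) {
  new("DistributionSpec", family = family, parameters = unlist(list(...)))
}

#' FitResult: a fitted linear model with its training statistics
#'
#' @slot selectedDescriptors names of the descriptors in the model.
#' @slot intercept intercept estimate.
#' @slot coefficients named coefficient estimates (one per descriptor).
#' @slot stdErrors named standard errors, intercept first.
#' @slot r2Train training-set coefficient of determination.
#' @slot q2Loo leave-one-out cross-validated q2 (NA until computed).
#' @slot fittedValues fitted values on the training set.
#' @export
setClass("FitResult",
  representation(
    selectedDescriptors = "character",
    intercept    = "numeric",
    coefficients = "numeric",
    stdErrors    = "numeric",
    r2Train      = "numeric",
    q2Loo        = "numeric",
    fittedValues = "numeric"
  )
)

setValidity("FitResult", function(object) {
  if (!identical(sort(names(object@coefficients)),
                 sort(object@selectedDescriptors)))
    return("coefficient names must match selectedDescriptors")
  if (length(object@r2Train) == 1 && !is.na(object@r2Train) &&
      object@r2Train > 1 + 1e-12)
    return("r2Train cannot exceed 1")
  TRUE
})

#' TreeModel: a depth-limited binary classification tree
#'
#' Internal nodes are lists `(feature, threshold, left, right)`; leaves
#' carry a class label and the training counts that support it.  A row is
#' routed left when its feature value is `<=` the node threshold.
#'
#' @slot root recursive node list.
#' @slot maxDepth the depth cap the tree was grown under.
#' @slot featureNames descriptor names the tree may reference.
#' @export
setClass("TreeModel",
  representation(root = "list", maxDepth = "integer",
                 featureNames = "character")
)

#' ConfusionCounts: the four cells of a binary confusion matrix
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0L)) "counts must be non-negative" else TRUE
})

#' ChanceSummary: chance-model score distributions and SD thresholds
#'
#' The machine form of a chance-test summary table: for each collected
#' statistic (best r2 / q2 per randomized set for regression engines;
#' ACC, PREC, ... per set for classification engines) the per-set values,
#' their mean and sample SD, and mean + k*SD thresholds for
#' k in \{1, 2.3, 3\} (2.3 SD is the usual normal-theory shorthand for
#' the 99th percentile).
#'
#' @slot mode,family the randomization mode/family the scores came from.
#' @slot nSets number of randomized sets.
#' @slot scores named list of per-set numeric score vectors.
#' @slot summary data.frame with one row per statistic: mean, sd,
#'   plus1sd, plus2.3sd, plus3sd.
#' @export
setClass("ChanceSummary",
  representation(mode = "character", family = "character",
                 nSets = "integer", scores = "list",
                 summary = "data.frame")
)

setValidity("ChanceSummary", function(object) {
  msg <- character(0)
  for (s in object@scores)
    if (length(s) != object@nSets)
      msg <- c(msg, "each score vector must have one entry per set")
  if (length(msg)) unique(msg) else TRUE
})
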