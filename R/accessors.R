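#' @name DescriptorTable-accessors
#' @title Accessors for DescriptorTable objects
#' @param x,object a [DescriptorTable-class].
#' @param value replacement value.
#' @description `recordIds`, `descriptorNames`, `activityNames`,
#'   `descriptorMatrix`, `activityMatrix` extract the corresponding
#'   pieces; `hasPayloads` reports whether the table carries verbatim SD
#'   records (and can therefore be written back to SDF).
NULL

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("recordIds", "DescriptorTable", function(x) x@recordIds)

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("descriptorNames", "DescriptorTable",
          function(x) colnames(x@descriptors) %||% character(0))

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("activityNames", function(x) standardGeneric("activityNames"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("activityNames", "DescriptorTable",
          function(x) colnames(x@activities) %||% character(0))

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("descriptorMatrix", "DescriptorTable", function(x) x@descriptors)

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("activityMatrix", "DescriptorTable", function(x) x@activities)

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("hasPayloads", function(x) standardGeneric("hasPayloads"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("hasPayloads", "DescriptorTable",
          function(x) length(x@sdfRecords) > 0)

#' @rdname DescriptorTable-accessors
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))
#' @rdname DescriptorTable-accessors
#' @export
setMethod("nCompounds", "DescriptorTable", function(x) length(x@recordIds))

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf(
    "DescriptorTable: %d compounds, %d descriptors, %d activity column(s)\n",
    length(object@recordIds), ncol(object@descriptors),
    ncol(object@activities)))
  if (ncol(object@activities) > 0)
    cat("  activities:", paste(colnames(object@activities), collapse = ", "),
        "\n")
  if (hasPayloads(object))
    cat("  carries verbatim SD records (SDF output available)\n")
})

setMethod("show", "RandomizationPlan", function(object) {
  cat(sprintf("RandomizationPlan: mode=%s family=%s nSets=%d masterSeed=%d\n",
              object@mode, object@family, object@nSets, object@masterSeed))
  cat("  target fields:", paste(object@targetFields, collapse = ", "), "\n")
})

setMethod("show", "FitResult", function(object) {
  terms <- sprintf("%+.4g x %s", object@coefficients,
                   object@selectedDescriptors)
  cat("FitResult:", sprintf("%.4g", object@intercept),
      paste(terms, collapse = " "), "\n")
  cat(sprintf("  r2 = %.3f", object@r2Train))
  if (!is.na(object@q2Loo)) cat(sprintf("  q2(LOO) = %.3f", object@q2Loo))
  cat("\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
              object@tp, object@tn, object@fp, object@fn))
})

setMethod("show", "TreeModel", function(object) {
  cat(sprintf("TreeModel: depth cap %d\n", object@maxDepth))
  .printNode <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s* class %d (n=%d)\n", pad, node$class, node$n))
    } else {
      cat(sprintf("%s%s <= %.4g ?\n", pad, node$feature, node$threshold))
      .printNode(node$left, indent + 1)
      .printNode(node$right, indent + 1)
    }
  }
  .printNode(object@root, 1)
})

setMethod("show", "ChanceSummary", function(object) {
  cat(sprintf("ChanceSummary: mode=%s family=%s, %d randomized sets\n",
              object@mode, object@family, object@nSets))
  print(round(object@summary, 3))
})

#' @rdname ChanceSummary-class
#' @param x a [ChanceSummary-class].
#' @export
setGeneric("chanceScores", function(x) standardGeneric("chanceScores"))
#' @rdname ChanceSummary-class
#' @export
setMethod("chanceScores", "ChanceSummary", function(x) x@scores)

#' @rdname ChanceSummary-class
#' @export
setGeneric("chanceTable", function(x) standardGeneric("chanceTable"))
#' @rdname ChanceSummary-class
#' @export
setMethod("chanceTable", "ChanceSummary", function(x) x@summary)
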