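# Accessors and show() methods for the S4 classes. Slot access from user code
# should go through these.

#' @describeIn MaskedDataset-accessors The incomplete matrix (NA at masked cells).
#' @export
setGeneric("maskedValues", function(x) standardGeneric("maskedValues"))

#' @describeIn MaskedDataset-accessors The complete pre-masking matrix.
#' @export
setGeneric("truthValues", function(x) standardGeneric("truthValues"))

#' @describeIn MaskedDataset-accessors The logical mask (TRUE = masked).
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @describeIn MaskedDataset-accessors Generator provenance as a list.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn MaskedDataset-accessors Achieved missing ratio, percent of all cells.
#' @export
setGeneric("achievedRatio", function(x) standardGeneric("achievedRatio"))

#' Accessors for MaskedDataset
#'
#' @param x a [MaskedDataset-class] object (or, for `achievedRatio`, a logical
#'   mask matrix).
#' @return `maskedValues`/`truthValues`: numeric matrix; `missingMask`:
#'   logical matrix; `provenance`: named list; `achievedRatio`: numeric
#'   percentage 100 * MV / (N * M).
#' @name MaskedDataset-accessors
#' @aliases maskedValues truthValues missingMask provenance achievedRatio
NULL

#' @export
setMethod("maskedValues", "MaskedDataset", function(x) x@data)
#' @export
setMethod("truthValues", "MaskedDataset", function(x) x@truth)
#' @export
setMethod("missingMask", "MaskedDataset", function(x) x@mask)
#' @export
setMethod("provenance", "MaskedDataset", function(x) {
  list(mechanism = x@mechanism, mdr = x@mdr, nAttrs = x@nAttrs, seed = x@seed)
})
#' @export
setMethod("achievedRatio", "MaskedDataset", function(x) {
  100 * sum(x@mask) / length(x@mask)
})
#' @export
setMethod("achievedRatio", "matrix", function(x) {
  if (!is.logical(x)) .errShape("achievedRatio expects a logical mask matrix")
  100 * sum(x) / length(x)
})

setMethod("show", "MaskedDataset", function(object) {
  cat(sprintf(
    "MaskedDataset: %d x %d, %s, requested %.4g%%, achieved %.4g%% (%d cells), seed %d\n",
    nrow(object@data), ncol(object@data), object@mechanism, object@mdr,
    achievedRatio(object), sum(object@mask), object@seed
  ))
})

#' @describeIn KSelection-accessors The selected k.
#' @export
setGeneric("bestK", function(x) standardGeneric("bestK"))

#' @describeIn KSelection-accessors The per-k error curve (named numeric).
#' @export
setGeneric("errorCurve", function(x) standardGeneric("errorCurve"))

#' Accessors for KSelection
#'
#' @param x a [KSelection-class] object.
#' @name KSelection-accessors
#' @aliases bestK errorCurve
#' @return `bestK`: integer; `errorCurve`: named numeric vector keyed by k.
NULL

#' @export
setMethod("bestK", "KSelection", function(x) x@bestK)
#' @export
setMethod("errorCurve", "KSelection", function(x) x@errorCurve)

setMethod("show", "KSelection", function(object) {
  cat(sprintf(
    "KSelection: probe column %d, AV = %.6g, k in [%s, %s], best k = %d (error %.6g)\n",
    object@probeAttr, object@actualValue,
    names(object@errorCurve)[1L], names(object@errorCurve)[length(object@errorCurve)],
    object@bestK, object@errorCurve[[as.character(object@bestK)]]
  ))
})

#' @describeIn FCMModel-accessors Cluster centroid matrix (c x M).
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @describeIn FCMModel-accessors Membership matrix (N x c, rows sum to 1).
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @describeIn FCMModel-accessors Per-iteration objective values.
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' Accessors for FCMModel
#'
#' @param x an [FCMModel-class] object.
#' @name FCMModel-accessors
#' @aliases centroids membership objectiveTrace
#' @return `centroids`: numeric matrix; `membership`: numeric matrix;
#'   `objectiveTrace`: numeric vector.
NULL

#' @export
setMethod("centroids", "FCMModel", function(x) x@centroids)
#' @export
setMethod("membership", "FCMModel", function(x) x@membership)
#' @export
setMethod("objectiveTrace", "FCMModel", function(x) x@objectiveTrace)

setMethod("show", "FCMModel", function(object) {
  cat(sprintf(
    "FCMModel: %d clusters on %d records, m' = %.3g, %d iterations, final objective %.6g\n",
    nrow(object@centroids), nrow(object@membership), object@fuzzifier,
    length(object@objectiveTrace), utils::tail(object@objectiveTrace, 1L)
  ))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport over %d masked cells: RMSE %.6g, NRMSE %s, MAE %.6g (range %.6g)\n",
    object@nCells, object@rmse,
    if (is.na(object@nrmse)) "NA" else sprintf("%.6g", object@nrmse),
    object@mae, object@oRange
  ))
})

#' @describeIn ImputationResult-accessors The completed matrix.
#' @export
setGeneric("imputedValues", function(x) standardGeneric("imputedValues"))

#' @describeIn ImputationResult-accessors Per-record imputation log.
#' @export
setGeneric("recordLog", function(x) standardGeneric("recordLog"))

#' Accessors for ImputationResult
#'
#' @param x an [ImputationResult-class] object.
#' @name ImputationResult-accessors
#' @aliases imputedValues recordLog
#' @return `imputedValues`: complete numeric matrix; `recordLog`: data.frame.
NULL

#' @export
setMethod("imputedValues", "ImputationResult", function(x) x@imputed)
#' @export
setMethod("recordLog", "ImputationResult", function(x) x@log)

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf(
    "ImputationResult: %d x %d complete matrix, %d records imputed by '%s'%s\n",
    nrow(object@imputed), ncol(object@imputed), nrow(object@log),
    if (is.null(object@config$method)) "?" else object@config$method,
    if (any(object@log$fallback != "none")) sprintf(
      " (%d fallback)", sum(object@log$fallback != "none")) else ""
  ))
})
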