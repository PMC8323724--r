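#' @import methods
NULL

#' Masked dataset: data with injected missingness plus its provenance
#'
#' Pairs an incomplete numeric matrix with the boolean mask of injected
#' missing cells, the pre-masking truth, and the generator provenance
#' (mechanism, target ratio, number of affected attributes, seed). Produced by
#' [generateMCAR()], [generateMAR()] and [generateMNAR()]; consumed by
#' [evaluateMasked()] and the benchmark harness.
#'
#' @slot data numeric matrix with `NA` at masked cells.
#' @slot truth numeric matrix of pre-masking values (same shape).
#' @slot mask logical matrix, `TRUE` at masked cells.
#' @slot mechanism character, one of `"MCAR"`, `"MAR"`, `"MNAR"`.
#' @slot mdr numeric, requested missing-data ratio in percent of all cells.
#' @slot nAttrs integer, number of attributes losing values (`NA_integer_`
#'   for MCAR, where every attribute may be hit).
#' @slot seed integer seed that drove the generator.
#' @exportClass MaskedDataset
setClass("MaskedDataset",
  representation(
    data = "matrix",
    truth = "matrix",
    mask = "matrix",
    mechanism = "character",
    mdr = "numeric",
    nAttrs = "integer",
    seed = "integer"
  )
)

setValidity("MaskedDataset", function(object) {
  msgs <- character()
  d <- object@data; t <- object@truth; m <- object@mask
  if (!identical(dim(d), dim(t)) || !identical(dim(d), dim(m))) {
    msgs <- c(msgs, "data, truth and mask must share one shape")
  } else {
    if (!is.logical(m)) msgs <- c(msgs, "mask must be logical")
    if (any(!is.na(d[m]))) msgs <- c(msgs, "every masked cell must carry NA in data")
    obs <- !m
    if (!isTRUE(all(d[obs] == t[obs]))) {
      msgs <- c(msgs, "data and truth must agree on every non-masked cell")
    }
  }
  if (!object@mechanism %in% c("MCAR", "MAR", "MNAR")) {
    msgs <- c(msgs, "mechanism must be MCAR, MAR or MNAR")
  }
  if (length(msgs)) msgs else TRUE
})

#' Automatic-k search record
#'
#' Result of [selectBestK()]: the probe attribute, the withheld actual value,
#' the per-k single-value error curve over k = 2..(Np-1), and the selected k
#' (smallest arg-min on ties).
#'
#' @slot probeAttr integer column index of the probe attribute.
#' @slot actualValue numeric withheld value.
#' @slot errorCurve named numeric vector, names are k values.
#' @slot bestK integer selected k.
#' @exportClass KSelection
setClass("KSelection",
  representation(
    probeAttr = "integer",
    actualValue = "numeric",
    errorCurve = "numeric",
    bestK = "integer"
  )
)

setValidity("KSelection", function(object) {
  msgs <- character()
  ks <- as.integer(names(object@errorCurve))
  if (length(ks) == 0L || any(is.na(ks))) {
    msgs <- c(msgs, "errorCurve must be named by integer k values")
  } else {
    if (!object@bestK %in% ks) msgs <- c(msgs, "bestK must be a key of errorCurve")
    mn <- min(object@errorCurve)
    winners <- ks[object@errorCurve == mn]
    if (length(winners) && object@bestK != min(winners)) {
      msgs <- c(msgs, "bestK must be the smallest arg-min of errorCurve")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fuzzy c-means fit
#'
#' Converged state of [fcmFit()]: cluster centroids, the row-stochastic
#' membership matrix, the fuzzifier, and the per-iteration objective trace.
#'
#' @slot centroids c x M numeric matrix of cluster prototypes.
#' @slot membership N x c numeric matrix of membership degrees in [0, 1].
#' @slot fuzzifier numeric > 1 overlap exponent.
#' @slot objectiveTrace numeric, objective value after each iteration.
#' @slot seed integer seed used to initialise the memberships.
#' @exportClass FCMModel
setClass("FCMModel",
  representation(
    centroids = "matrix",
    membership = "matrix",
    fuzzifier = "numeric",
    objectiveTrace = "numeric",
    seed = "integer"
  )
)

setValidity("FCMModel", function(object) {
  msgs <- character()
  u <- object@membership
  if (ncol(u) != nrow(object@centroids)) {
    msgs <- c(msgs, "membership columns must match centroid rows")
  }
  if (any(u < -1e-12) || any(u > 1 + 1e-12)) {
    msgs <- c(msgs, "memberships must lie in [0, 1]")
  }
  if (any(abs(rowSums(u) - 1) > 1e-9)) {
    msgs <- c(msgs, "membership rows must sum to 1 within 1e-9")
  }
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-9)) {
    msgs <- c(msgs, "objective trace must be non-increasing within 1e-9")
  }
  if (object@fuzzifier <= 1) msgs <- c(msgs, "fuzzifier must exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' Imputation error metrics over masked cells
#'
#' RMSE, range-normalised RMSE and MAE computed between imputed and true
#' values at artificially masked positions.
#'
#' @slot rmse numeric root-mean-square error.
#' @slot nrmse numeric RMSE divided by the observed range (`NA` when the
#'   masked true values are constant).
#' @slot mae numeric mean absolute error.
#' @slot nCells integer number of masked cells entering the metrics.
#' @slot oRange numeric range (max - min) of the masked true values.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    rmse = "numeric",
    nrmse = "numeric",
    mae = "numeric",
    nCells = "integer",
    oRange = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  msgs <- character()
  if (object@rmse < object@mae - 1e-12) {
    msgs <- c(msgs, "rmse must be >= mae")
  }
  if (object@oRange > 0 && !is.na(object@nrmse) &&
      abs(object@nrmse - object@rmse / object@oRange) > 1e-9) {
    msgs <- c(msgs, "nrmse must equal rmse / oRange when the range is positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of an imputation run
#'
#' The completed matrix plus a per-record log (selected k, pool size, cluster
#' routing, fallback use) and an echo of the configuration and seed.
#'
#' @slot imputed numeric matrix with every missing cell replaced.
#' @slot log data.frame with one row per imputed record: `record`, `bestK`,
#'   `poolSize`, `clusterId`, `fallback`.
#' @slot config list echoing the effective parameters.
#' @exportClass ImputationResult
setClass("ImputationResult",
  representation(
    imputed = "matrix",
    log = "data.frame",
    config = "list"
  )
)

setValidity("ImputationResult", function(object) {
  if (anyNA(object@imputed)) "imputed matrix must be complete" else TRUE
})
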