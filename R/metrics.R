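# Imputation error metrics between predicted and observed values.

.checkPairs <- function(pred, obs) {
  if (length(pred) != length(obs)) .errShape("pred and obs must have equal length")
  if (length(pred) == 0L) .errShape("pred and obs must be non-empty")
}

#' Root-mean-square error
#'
#' `sqrt(mean((pred - obs)^2))`.
#'
#' @param pred,obs numeric vectors of equal, non-zero length.
#' @return a non-negative scalar.
#' @examples
#' rmse(c(2, 4), c(1, 2))  # sqrt(2.5)
#' @export
rmse <- function(pred, obs) {
  .checkPairs(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' Range-normalised root-mean-square error
#'
#' [rmse()] divided by `max(obs) - min(obs)`; scale-invariant.
#'
#' @inheritParams rmse
#' @return a non-negative scalar.
#' @export
nrmse <- function(pred, obs) {
  .checkPairs(pred, obs)
  rng <- max(obs) - min(obs)
  if (rng <= 0) .errDegenerateRange("observed values are constant; NRMSE is undefined")
  rmse(pred, obs) / rng
}

#' Mean absolute error
#'
#' `mean(abs(pred - obs))`.
#'
#' @inheritParams rmse
#' @return a non-negative scalar.
#' @export
mae <- function(pred, obs) {
  .checkPairs(pred, obs)
  mean(abs(pred - obs))
}

#' Score an imputation over the masked cells
#'
#' Collects the (predicted, true) pairs at exactly the masked positions and
#' computes RMSE, NRMSE and MAE. The normalising range is taken over the
#' masked cells' true values (the observed vector entering the metric);
#' when those are constant NRMSE is reported as `NA`.
#'
#' @param truth complete numeric matrix of true values, or a
#'   [MaskedDataset-class] (whose truth and mask are then used).
#' @param mask logical matrix, `TRUE` at masked cells (ignored when `truth`
#'   is a MaskedDataset).
#' @param imputed complete numeric matrix from an imputer.
#' @return a [MetricsReport-class].
#' @export
evaluateMasked <- function(truth, mask, imputed) {
  if (is(truth, "MaskedDataset")) {
    if (missing(imputed)) { imputed <- mask }
    mask <- truth@mask
    truth <- truth@truth
  }
  if (is(imputed, "ImputationResult")) imputed <- imputed@imputed
  if (!identical(dim(truth), dim(mask)) || !identical(dim(truth), dim(imputed))) {
    .errShape("truth, mask and imputed must share one shape")
  }
  if (!any(mask)) .errEmptyMask("no masked cells to evaluate")
  if (anyNA(imputed[mask])) .errShape("imputed matrix still has NA at masked cells")
  p <- imputed[mask]
  o <- truth[mask]
  rng <- max(o) - min(o)
  r <- rmse(p, o)
  new("MetricsReport",
      rmse = r,
      nrmse = if (rng > 0) r / rng else NA_real_,
      mae = mae(p, o),
      nCells = as.integer(sum(mask)),
      oRange = rng)
}
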