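# Missing-aware nearest-neighbour machinery: partial Euclidean distance,
# k-nearest-neighbour search with stable tie-breaking, the kNNI single-value
# estimate, and the self-probe automatic-k selection.

#' Partial (missing-aware) Euclidean distance between two records
#'
#' Over the columns observed in both records (`m_obs` of the `M` columns) the
#' squared differences are summed and rescaled by `M / m_obs`
#' (Hathaway-Bezdek partial distance), keeping distances comparable across
#' donors with different observed supports. With no co-observed column the
#' distance is `+Inf`. On complete records this is the classical Euclidean
#' distance.
#'
#' @param a,b numeric vectors of equal length (NA = missing).
#' @return a non-negative scalar, possibly `Inf`.
#' @examples
#' pairwiseDistance(c(0, 0), c(3, 4))   # 5
#' pairwiseDistance(c(0, NA), c(3, 4))  # sqrt(2/1 * 9)
#' @export
pairwiseDistance <- function(a, b) {
  if (length(a) != length(b)) .errShape("records must have the same length")
  co <- !is.na(a) & !is.na(b)
  m <- sum(co)
  if (m == 0L) return(Inf)
  sqrt(length(a) / m * sum((a[co] - b[co])^2))
}

#' k nearest neighbours of a record within a pool
#'
#' Ranks the pool rows by [pairwiseDistance()] to the target; ties break to
#' the lower row position and `+Inf` rows rank last. The row at
#' `excludeIndex` (the query itself, when it sits in the pool) is never
#' returned.
#'
#' @param target numeric record (NA allowed).
#' @param pool numeric matrix of candidate donors.
#' @param k number of neighbours, `1 <= k <=` pool size after self-exclusion.
#' @param excludeIndex optional pool row to exclude (the query itself).
#' @return a list with `indices` (pool row positions) and `distances`
#'   (matching, non-decreasing).
#' @export
findKNN <- function(target, pool, k, excludeIndex = NULL) {
  pool <- .asDataset(pool, "pool")
  if (length(target) != ncol(pool)) .errShape("target length must match pool columns")
  keep <- seq_len(nrow(pool))
  if (!is.null(excludeIndex)) keep <- keep[keep != excludeIndex]
  if (length(keep) == 0L) .errSpec("pool is empty after self-exclusion")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(keep)) {
    .errSpec(sprintf("k must lie in [1, %d]", length(keep)))
  }
  d <- .distToPool(target, pool[keep, , drop = FALSE])
  if (all(is.infinite(d))) {
    .errNoComparableDonors("no pool record shares an observed column with the target")
  }
  ord <- order(d)[seq_len(k)]   # order() is stable: ties go to the lower row
  list(indices = unname(keep[ord]), distances = unname(d[ord]))
}

#' kNNI estimate of one attribute from a neighbour set
#'
#' The mean of `attr` over the neighbours that observe it; if none do, the
#' supplied pool-level column mean is used instead.
#'
#' @param neighbors numeric matrix of neighbour records.
#' @param attr column index to estimate.
#' @param poolMean fallback mean of the attribute over the donor pool
#'   (`NA` to disable the fallback).
#' @return a scalar estimate.
#' @export
knniEstimate <- function(neighbors, attr, poolMean = NA_real_) {
  if (nrow(neighbors) == 0L) .errSpec("neighbour set is empty")
  v <- neighbors[, attr]
  v <- v[!is.na(v)]
  if (length(v)) return(mean(v))
  if (is.na(poolMean)) {
    .errColumnAllMissing(sprintf("attribute %d observed in no neighbour and no fallback supplied", attr))
  }
  poolMean
}

#' Automatic k selection by self-probing (the KI inner loop)
#'
#' One observed attribute z of the target is drawn at random (consuming the
#' caller's RNG stream) and its value AV withheld. For every
#' k in 2..(Np - 1), where Np counts the pool including the target, the kNNI
#' estimate of the probe from the target's k nearest donors is computed and
#' scored by the single-value error |AV - estimate| (the RMSE of a length-1
#' vector). The k attaining the smallest error wins, smallest k on ties.
#'
#' One distance sort is performed; the per-k estimates are running means over
#' the sorted donor order.
#'
#' @param target numeric record with at least one observed attribute.
#' @param donors numeric matrix of the pool excluding the target itself
#'   (so `Np = nrow(donors) + 1`); donors may have missing cells.
#' @return a [KSelection-class].
#' @export
selectBestK <- function(target, donors) {
  donors <- .asDataset(donors, "donor pool")
  if (length(target) != ncol(donors)) .errShape("target length must match donor columns")
  np <- nrow(donors) + 1L
  if (np < 3L) .errPoolTooSmall(sprintf("pool holds %d records; at least 3 are required", np))
  obsIdx <- which(!is.na(target))
  if (length(obsIdx) == 0L) .errPoolTooSmall("target has no observed attribute to probe")
  z <- obsIdx[sample.int(length(obsIdx), 1L)]
  av <- target[z]
  probe <- target
  probe[z] <- NA_real_
  d <- .distToPool(probe, donors)
  ord <- order(d)
  colVals <- donors[ord, z]
  obs <- !is.na(colVals)
  poolMean <- if (any(obs)) mean(colVals[obs]) else NA_real_
  if (is.na(poolMean)) {
    .errColumnAllMissing(sprintf("probe attribute %d is observed in no pool record", z))
  }
  ks <- 2:(np - 1L)
  csum <- cumsum(ifelse(obs, colVals, 0))
  ccnt <- cumsum(obs)
  est <- ifelse(ccnt[ks] > 0L, csum[ks] / ccnt[ks], poolMean)
  curve <- abs(av - est)
  names(curve) <- as.character(ks)
  best <- ks[which.min(curve)]   # which.min returns the first minimum
  new("KSelection", probeAttr = as.integer(z), actualValue = as.numeric(av),
      errorCurve = curve, bestK = as.integer(best))
}
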