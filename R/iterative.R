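#' Configuration for round-robin iterative imputation
#'
#' @param maxRounds maximum number of full passes over the incomplete columns.
#' @param tol relative-change stopping threshold: iteration stops when the
#'   largest absolute change of any imputed cell, divided by its column's
#'   observed range, falls below `tol`.
#' @param ridgeLambda lower bound of the ridge penalty grid searched by
#'   generalised cross-validation in each per-column fit; a tiny positive
#'   value keeps collinear donor subsets solvable without materially biasing
#'   clean fits, while GCV raises the penalty automatically when the donor
#'   subset is small or noisy.
#' @param clipToObservedRange logical; clip predictions into the column's
#'   observed min/max (off by default).
#' @return a classed list of class `"IterConfig"`.
#' @export
iterConfig <- function(maxRounds = 10L, tol = 1e-3, ridgeLambda = 1e-6,
                       clipToObservedRange = FALSE) {
  if (maxRounds < 1L) .errSpec("maxRounds must be at least 1")
  if (!is.numeric(tol) || tol <= 0) .errSpec("tol must be positive")
  if (ridgeLambda < 0) .errSpec("ridgeLambda must be non-negative")
  structure(
    list(maxRounds = as.integer(maxRounds), tol = tol,
         ridgeLambda = ridgeLambda,
         clipToObservedRange = isTRUE(clipToObservedRange)),
    class = "IterConfig"
  )
}

# Ridge-regularised least squares with the penalty chosen by generalised
# cross-validation. Predictors are standardised (so one isotropic penalty is
# meaningful) and the response centred; the intercept is unpenalised. The
# penalty grid is floored at lambdaFloor and capped where the fit would
# interpolate (effective df within 0.5 of n), so the degenerate GCV 0/0 at
# full interpolation is never scored. Exactly collinear clean subsets get a
# near-zero penalty and reproduce the least-squares prediction; small or
# noisy subsets (donor pools with about as many rows as attributes) are
# shrunk towards the subset column mean instead of extrapolating wildly.
# The predictor scale is taken over every row of the subset (prediction rows
# included), not the training rows alone: the training rows are nearest
# neighbours whose spread can be arbitrarily small, and scaling by it would
# turn a query sitting just outside that spread into an extreme standardised
# point and amplify the extrapolation. Centring stays on the training rows
# so the unpenalised intercept absorbs their mean exactly. Returns the
# coefficient vector c(intercept, slopes) on the raw scale.
.ridgeFit <- function(X, y, lambdaFloor, scaleRows = X) {
  n <- nrow(X)
  p <- ncol(X)
  mx <- colMeans(X)
  sx <- apply(scaleRows, 2L, stats::sd)
  sx[sx == 0 | is.na(sx)] <- 1
  Xs <- sweep(sweep(X, 2L, mx), 2L, sx, "/")
  my <- mean(y)
  yc <- y - my
  sv <- svd(Xs)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  grid <- 10^seq(log10(max(lambdaFloor, 1e-8)), 4, length.out = 40L)
  bestLam <- NA_real_
  bestG <- Inf
  for (lam in grid) {
    shrink <- d2 / (d2 + lam)
    df <- 1 + sum(shrink)               # +1 for the intercept
    if (df >= n - 0.5) next
    rss <- sum((yc - sv$u %*% (shrink * uty))^2)
    g <- n * rss / (n - df)^2
    if (g < bestG) {
      bestG <- g
      bestLam <- lam
    }
  }
  if (is.na(bestLam)) bestLam <- grid[length(grid)]
  beta <- drop(sv$v %*% ((sv$d / (d2 + bestLam)) * uty))
  slopes <- beta / sx
  c(my - sum(slopes * mx), slopes)
}

#' Round-robin regression imputation of a small record subset
#'
#' Missing cells start at their column's observed mean within the subset.
#' Each round visits every column holding missing cells (fewest missing
#' first, ties by column index), regresses it on all other columns by
#' ridge-regularised least squares over the rows where it is observed, and
#' replaces its missing cells by the predictions. Iteration stops after
#' `config$maxRounds` rounds or when the largest range-relative change of any
#' imputed cell drops below `config$tol`. Deterministic; observed cells are
#' returned bit-identical.
#'
#' @param subset numeric matrix with >= 2 rows, >= 2 columns and at least one
#'   observed value per column.
#' @param config an [iterConfig()] list.
#' @return the completed matrix.
#' @examples
#' s <- rbind(c(1, 2), c(2, 4), c(4, 8), c(3, NA))
#' iterativeImpute(s)[4, 2]  # ~6 (y = 2x is exactly collinear)
#' @export
iterativeImpute <- function(subset, config = iterConfig()) {
  subset <- .asDataset(subset, "subset")
  if (nrow(subset) < 2L) .errSubsetTooSmall("iterative imputation needs at least 2 rows")
  if (ncol(subset) < 2L) .errSubsetTooSmall("iterative imputation needs at least 2 columns")
  colMu <- .columnMeans(subset)           # errors if a column is all missing
  miss <- is.na(subset)
  if (!any(miss)) return(subset)
  obsRange <- apply(subset, 2L, function(v) diff(range(v, na.rm = TRUE)))
  denom <- ifelse(obsRange > 0, obsRange, 1)
  obsMin <- apply(subset, 2L, min, na.rm = TRUE)
  obsMax <- apply(subset, 2L, max, na.rm = TRUE)

  X <- subset
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- colMu[j]

  cols <- which(colSums(miss) > 0L)
  cols <- cols[order(colSums(miss)[cols], cols)]   # fewest missing first

  for (round in seq_len(config$maxRounds)) {
    delta <- 0
    for (j in cols) {
      rowsObs <- which(!miss[, j])
      beta <- .ridgeFit(X[rowsObs, -j, drop = FALSE], X[rowsObs, j],
                        config$ridgeLambda, scaleRows = X[, -j, drop = FALSE])
      pred <- drop(cbind(1, X[miss[, j], -j, drop = FALSE]) %*% beta)
      if (config$clipToObservedRange) {
        pred <- pmin(pmax(pred, obsMin[j]), obsMax[j])
      }
      delta <- max(delta, max(abs(pred - X[miss[, j], j]) / denom[j]))
      X[miss[, j], j] <- pred
    }
    if (delta < config$tol) break
  }
  X
}
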