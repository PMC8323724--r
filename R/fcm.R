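# Fuzzy c-means on possibly-incomplete data via the partial-distance
# strategy, elbow selection of the cluster count, and hard assignment by
# highest membership.

# Squared partial distances of every record to every centroid: N x c matrix.
# Scale M/m_obs is per record; records observing nothing get +Inf.
.fcmDist2 <- function(X, C) {
  N <- nrow(X); M <- ncol(X); cc <- nrow(C)
  O <- !is.na(X)
  mObs <- rowSums(O)
  Xz <- X
  Xz[!O] <- 0
  out <- matrix(0, N, cc)
  for (k in seq_len(cc)) {
    diff <- sweep(Xz, 2L, C[k, ], "-")
    diff[!O] <- 0
    out[, k] <- rowSums(diff * diff)
  }
  scale <- ifelse(mObs == 0L, Inf, M / mObs)
  out * scale
}

# Membership update from squared distances; rows with a zero distance get all
# their mass split over the coincident centroids; all-Inf rows go uniform.
.fcmMembership <- function(D2, mPrime) {
  expo <- 1 / (mPrime - 1)
  U <- matrix(0, nrow(D2), ncol(D2))
  for (i in seq_len(nrow(D2))) {
    d <- D2[i, ]
    if (all(is.infinite(d))) {
      U[i, ] <- 1 / length(d)
    } else if (any(d == 0)) {
      z <- d == 0
      U[i, z] <- 1 / sum(z)
    } else {
      w <- (1 / d)^expo
      U[i, ] <- w / sum(w)
    }
  }
  U
}

#' Fit fuzzy c-means on (possibly incomplete) data
#'
#' Alternating optimisation of the fuzzified within-cluster squared-distance
#' objective: membership update
#' \eqn{\delta_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m'-1)}} and weighted
#' centroid update with weights \eqn{\delta_{ik}^{m'}}. Missing cells enter
#' through partial distances (co-observed squared differences rescaled by
#' `M/m_obs`) and are skipped in the centroid averages; the per-record scale
#' is carried into the centroid weights so each half-step exactly minimises
#' the objective, making the trace non-increasing. On complete data this is
#' standard FCM. Records observing no attribute receive uniform membership
#' and zero weight.
#'
#' Memberships are initialised from a flat Dirichlet under `seed`. A record
#' coinciding with a centroid gets membership 1 there (split over ties).
#'
#' @param data numeric matrix, NA allowed; every column needs at least one
#'   observed value.
#' @param c number of clusters, in `[2, N]`.
#' @param mPrime fuzzifier > 1 (default 2, the conventional choice).
#' @param tol stop when the largest membership change falls below this.
#' @param maxIter iteration cap.
#' @param seed integer seed for the membership initialisation.
#' @return an [FCMModel-class].
#' @export
fcmFit <- function(data, c, mPrime = 2, tol = 1e-4, maxIter = 100L, seed = 1L) {
  data <- .asDataset(data)
  N <- nrow(data); M <- ncol(data)
  if (!is.numeric(c) || length(c) != 1L || c < 2 || c > N) {
    .errSpec(sprintf("c must lie in [2, %d]", N))
  }
  if (mPrime <= 1) .errSpec("the fuzzifier mPrime must exceed 1")
  .columnMeans(data)                      # errors on an all-missing column
  c <- as.integer(c)
  U <- .withSeed(seed, {
    g <- matrix(stats::rgamma(N * c, shape = 1), N, c)
    g / rowSums(g)
  })
  O <- !is.na(data)
  mObs <- rowSums(O)
  recScale <- ifelse(mObs == 0L, 0, M / mObs)   # weight 0 for empty records
  Xz <- data
  Xz[!O] <- 0
  trace <- numeric(0L)
  C <- matrix(0, c, M)
  for (it in seq_len(maxIter)) {
    W <- U^mPrime * recScale               # N x c effective weights
    for (k in seq_len(c)) {
      wk <- W[, k]
      num <- colSums(Xz * (wk * O))
      den <- colSums(wk * O)
      C[k, ] <- ifelse(den > 0, num / den, C[k, ])
    }
    D2 <- .fcmDist2(data, C)
    Unew <- .fcmMembership(D2, mPrime)
    fin <- is.finite(D2)
    trace <- c(trace, sum((Unew^mPrime * D2)[fin]))
    shift <- max(abs(Unew - U))
    U <- Unew
    if (shift < tol) break
  }
  colnames(C) <- colnames(data)
  new("FCMModel", centroids = C, membership = U, fuzzifier = mPrime,
      objectiveTrace = trace, seed = as.integer(seed))
}

#' Elbow selection of the cluster count
#'
#' Fits FCM for every `c` in `[cMin, cMax]`, records the converged objective
#' `J(c)`, and returns the interior `c` maximising the discrete second
#' difference `J(c-1) - 2 J(c) + J(c+1)` (the sharpest bend of the curve).
#' If no second difference is positive the curve has no elbow and `cMin` is
#' returned.
#'
#' @param data numeric matrix (NA allowed).
#' @param cMin smallest candidate (>= 2).
#' @param cMax largest candidate; default `min(10, floor(sqrt(N/2)))`,
#'   bounding the sweep on small datasets.
#' @param mPrime,tol,maxIter,seed passed to [fcmFit()] (per-c seeds are
#'   derived deterministically from `seed`).
#' @return the selected integer `c`, with the objective curve attached as
#'   attribute `"objective"`.
#' @export
elbowSelectC <- function(data, cMin = 2L, cMax = NULL, mPrime = 2,
                         tol = 1e-4, maxIter = 100L, seed = 1L) {
  data <- .asDataset(data)
  N <- nrow(data)
  if (is.null(cMax)) cMax <- min(10L, floor(sqrt(N / 2)))
  cMin <- as.integer(cMin); cMax <- as.integer(cMax)
  if (cMin < 2L || cMin >= cMax || cMax > N || cMax - cMin < 2L) {
    .errSpec(sprintf("need 2 <= cMin < cMax <= N with cMax - cMin >= 2 (got [%d, %d], N = %d)",
                     cMin, cMax, N))
  }
  cs <- cMin:cMax
  J <- vapply(cs, function(ci) {
    fit <- fcmFit(data, ci, mPrime = mPrime, tol = tol, maxIter = maxIter,
                  seed = .deriveSeed(seed, ci))
    utils::tail(fit@objectiveTrace, 1L)
  }, numeric(1L))
  names(J) <- cs
  structure(.elbowFromCurve(J, cs), objective = J)
}

# Discrete-second-difference elbow: the interior c maximising
# J(c-1) - 2 J(c) + J(c+1); the smallest candidate when none is positive.
.elbowFromCurve <- function(J, cs) {
  interior <- seq(2L, length(cs) - 1L)
  d2 <- J[interior - 1L] - 2 * J[interior] + J[interior + 1L]
  if (length(d2) == 0L || max(d2) <= 0) return(as.integer(cs[1L]))
  as.integer(cs[interior][which.max(d2)])
}

#' Hard cluster assignment by highest membership
#'
#' @param model a converged [FCMModel-class].
#' @return a list with `labels` (length-N integer vector, ties to the lowest
#'   cluster index) and `clusters` (list of row-index vectors partitioning
#'   the records).
#' @export
hardAssign <- function(model) {
  stopifnot(is(model, "FCMModel"))
  labels <- max.col(model@membership, ties.method = "first")
  cc <- ncol(model@membership)
  clusters <- lapply(seq_len(cc), function(k) which(labels == k))
  list(labels = labels, clusters = clusters)
}
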