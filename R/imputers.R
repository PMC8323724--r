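# The KI and FCKI imputation algorithms plus the mean and global-kNNI
# baselines. All imputers take a numeric matrix with NA and return an
# ImputationResult whose matrix is complete, shape- and order-preserving,
# with observed cells bit-identical to the input.

.emptyLog <- function() {
  data.frame(record = integer(0L), bestK = integer(0L), poolSize = integer(0L),
             clusterId = integer(0L), fallback = character(0L),
             stringsAsFactors = FALSE)
}

.logRow <- function(record, bestK, poolSize, clusterId, fallback) {
  data.frame(record = as.integer(record), bestK = as.integer(bestK),
             poolSize = as.integer(poolSize), clusterId = as.integer(clusterId),
             fallback = fallback, stringsAsFactors = FALSE)
}

# Impute one incomplete record R_i using donors drawn from donorRows of D.
# Returns list(record=..., bestK=, poolSize=) or NULL when the pool supports
# no auto-k selection (caller walks the fallback ladder). Consumes the global
# RNG stream (probe draw).
.kiImputeOne <- function(D, i, donorRows, config) {
  aMis <- which(is.na(D[i, ]))
  target <- D[i, ]
  # pool: donors observed on every attribute R_i is missing (they may be
  # missing elsewhere); this lets KI run with zero fully-complete records
  if (length(donorRows)) {
    sub <- D[donorRows, aMis, drop = FALSE]
    pool <- donorRows[rowSums(is.na(sub)) == 0L]
  } else {
    pool <- integer(0L)
  }
  np <- length(pool) + 1L
  if (np < 3L || ncol(D) < 2L || all(is.na(target))) return(NULL)
  donors <- D[pool, , drop = FALSE]
  sel <- tryCatch(selectBestK(target, donors), fcki_error = function(e) NULL)
  if (is.null(sel)) return(NULL)
  # probe restored: neighbours of the full R_i within P
  d <- .distToPool(target, donors)
  if (all(is.infinite(d))) return(NULL)
  ord <- order(d)[seq_len(sel@bestK)]
  S <- rbind(donors[ord, , drop = FALSE], target)
  rownames(S) <- c(rownames(donors)[ord], rownames(D)[i])
  imp <- tryCatch(iterativeImpute(S, config), fcki_error = function(e) NULL)
  if (is.null(imp)) return(NULL)
  list(record = imp[nrow(imp), ], bestK = sel@bestK, poolSize = np)
}

# Sequential KI pass over the incomplete records among `rows`, donors
# restricted to `rows`. When a record cannot be handled within `rows` and
# `retryRows` is supplied, the whole-dataset pool is tried; the final rung
# fills with observed column means of the full matrix. Imputed records
# rejoin D immediately and may donate to later records.
.kiRows <- function(D, rows, config, retryRows = NULL, clusterId = NA_integer_) {
  log <- .emptyLog()
  misRows <- rows[rowSums(is.na(D[rows, , drop = FALSE])) > 0L]
  for (i in sort(misRows)) {
    res <- .kiImputeOne(D, i, setdiff(rows, i), config)
    fallback <- "none"
    if (is.null(res) && !is.null(retryRows)) {
      res <- .kiImputeOne(D, i, setdiff(retryRows, i), config)
      fallback <- "whole-dataset"
    }
    if (is.null(res)) {
      mu <- .columnMeans(D)
      aMis <- is.na(D[i, ])
      rec <- D[i, ]
      rec[aMis] <- mu[aMis]
      res <- list(record = rec, bestK = NA_integer_, poolSize = NA_integer_)
      fallback <- "column-mean"
    }
    D[i, ] <- res$record
    log <- rbind(log, .logRow(i, res$bestK, res$poolSize, clusterId, fallback))
  }
  list(D = D, log = log)
}

#' KI: automatic-k nearest-neighbour donor selection + iterative imputation
#'
#' Processes incomplete records in ascending row order. For each record the
#' donor pool is every other row observed on all of the record's missing
#' attributes; the best k is chosen by the self-probe search
#' ([selectBestK()]); the record's best-k nearest donors together with the
#' record form the subset handed to [iterativeImpute()]; only the record's
#' own cells are accepted. Each imputed record rejoins the data immediately,
#' so later records may use earlier imputations as donors. Records whose
#' pool is too small for the auto-k search (fewer than 3 pool members
#' including the record) are filled with observed column means and flagged
#' in the log.
#'
#' @param data numeric matrix with NA; every column needs at least one
#'   observed value.
#' @param config an [iterConfig()] for the regression stage.
#' @param seed integer seed driving the probe draws.
#' @return an [ImputationResult-class].
#' @examples
#' x <- cbind(a = c(1, 2, 4, 3, 5, 6), b = c(2, 4, 8, NA, 10, 12))
#' imputedValues(kiImpute(x, seed = 1))[4, "b"]  # ~6
#' @export
kiImpute <- function(data, config = iterConfig(), seed = 1L) {
  data <- .asDataset(data)
  .columnMeans(data)                      # reject all-missing columns up front
  if (nrow(data) < 2L) .errSubsetTooSmall("KI needs at least 2 records")
  res <- .withSeed(seed, .kiRows(data, seq_len(nrow(data)), config))
  new("ImputationResult", imputed = res$D, log = res$log,
      config = list(method = "ki", seed = as.integer(seed), iter = unclass(config)))
}

#' FCKI: fuzzy-cluster routing + per-cluster KI
#'
#' Two levels of similarity: records are first soft-clustered by fuzzy
#' c-means on the incomplete data (partial distances) and hard-assigned to
#' their highest-membership cluster; the KI procedure then runs within each
#' cluster independently, so donors are drawn from the routed cluster only.
#' The cluster count comes from the elbow sweep ([elbowSelectC()]) unless
#' `c` is fixed. A record whose within-cluster pool is too small falls back
#' to a whole-dataset KI pass, then to column means; fallbacks are logged.
#' With `c = 1` the clustering is bypassed and the output is identical to
#' [kiImpute()] under the same seed and config.
#'
#' @param data numeric matrix with NA.
#' @param config an [iterConfig()].
#' @param c fixed cluster count, or `NULL` to select it by the elbow rule.
#' @param mPrime,fcmTol,fcmMaxIter fuzzy c-means parameters (see [fcmFit()]).
#' @param cMin,cMax elbow sweep range (see [elbowSelectC()]).
#' @param seed integer seed (clustering init and probe draws).
#' @return an [ImputationResult-class].
#' @export
fckiImpute <- function(data, config = iterConfig(), c = NULL, mPrime = 2,
                       fcmTol = 1e-4, fcmMaxIter = 100L,
                       cMin = 2L, cMax = NULL, seed = 1L) {
  data <- .asDataset(data)
  .columnMeans(data)
  if (nrow(data) < 2L) .errSubsetTooSmall("FCKI needs at least 2 records")
  if (!is.null(c) && c == 1L) {
    res <- .withSeed(seed, .kiRows(data, seq_len(nrow(data)), config))
    return(new("ImputationResult", imputed = res$D, log = res$log,
               config = list(method = "fcki", c = 1L, seed = as.integer(seed),
                             iter = unclass(config))))
  }
  if (is.null(c)) {
    c <- as.integer(elbowSelectC(data, cMin = cMin, cMax = cMax,
                                 mPrime = mPrime, tol = fcmTol,
                                 maxIter = fcmMaxIter, seed = .deriveSeed(seed, 104729L)))
  }
  model <- fcmFit(data, c, mPrime = mPrime, tol = fcmTol,
                  maxIter = fcmMaxIter, seed = .deriveSeed(seed, 15485863L))
  part <- hardAssign(model)
  allRows <- seq_len(nrow(data))
  out <- .withSeed(seed, {
    log <- .emptyLog()
    D <- data
    for (k in seq_along(part$clusters)) {
      rows <- part$clusters[[k]]
      if (length(rows) == 0L) next
      r <- .kiRows(D, rows, config, retryRows = allRows, clusterId = k)
      D <- r$D
      log <- rbind(log, r$log)
    }
    list(D = D, log = log)
  })
  log <- out$log[order(out$log$record), , drop = FALSE]
  rownames(log) <- NULL
  new("ImputationResult", imputed = out$D, log = log,
      config = list(method = "fcki", c = c, mPrime = mPrime,
                    seed = as.integer(seed), iter = unclass(config)))
}

#' Mean imputation baseline
#'
#' Every missing cell receives its column's observed mean; all missing cells
#' of one column therefore share one value, ignoring inter-feature
#' correlation.
#'
#' @param data numeric matrix with NA.
#' @return an [ImputationResult-class].
#' @export
meanImpute <- function(data) {
  data <- .asDataset(data)
  mu <- .columnMeans(data)
  miss <- is.na(data)
  out <- data
  for (j in seq_len(ncol(data))) out[miss[, j], j] <- mu[j]
  misRows <- which(rowSums(miss) > 0L)
  log <- if (length(misRows)) {
    do.call(rbind, lapply(misRows, .logRow, bestK = NA_integer_,
                          poolSize = NA_integer_, clusterId = NA_integer_,
                          fallback = "none"))
  } else .emptyLog()
  new("ImputationResult", imputed = out, log = log,
      config = list(method = "mean"))
}

#' Global k-nearest-neighbour imputation baseline
#'
#' For each incomplete record, the k nearest records over the whole dataset
#' (partial distance) supply each missing cell with the observed mean of
#' that attribute among the neighbours; the column's overall observed mean
#' backs the estimate when no neighbour observes it.
#'
#' @param data numeric matrix with NA.
#' @param k number of neighbours, `1 <= k < N`.
#' @return an [ImputationResult-class].
#' @export
knniImputeGlobal <- function(data, k) {
  data <- .asDataset(data)
  N <- nrow(data)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k >= N) {
    .errSpec(sprintf("k must lie in [1, %d]", N - 1L))
  }
  mu <- .columnMeans(data)
  miss <- is.na(data)
  out <- data
  log <- .emptyLog()
  for (i in which(rowSums(miss) > 0L)) {
    fallback <- "none"
    nn <- tryCatch(findKNN(data[i, ], data, k, excludeIndex = i),
                   fcki_no_comparable_donors_error = function(e) NULL)
    for (j in which(miss[i, ])) {
      if (is.null(nn)) {
        out[i, j] <- mu[j]
        fallback <- "column-mean"
      } else {
        out[i, j] <- knniEstimate(data[nn$indices, , drop = FALSE], j, mu[j])
      }
    }
    log <- rbind(log, .logRow(i, k, N - 1L, NA_integer_, fallback))
  }
  new("ImputationResult", imputed = out, log = log,
      config = list(method = "knni", k = as.integer(k)))
}

#' Run an imputation method by name
#'
#' @param data numeric matrix with NA.
#' @param method one of `"ki"`, `"fcki"`, `"mean"`, `"knni"`.
#' @param ... passed to the method (`seed`, `config`, `k`, `c`, ...).
#' @return an [ImputationResult-class].
#' @export
imputeMissing <- function(data, method = c("ki", "fcki", "mean", "knni"), ...) {
  method <- match.arg(method)
  switch(method,
    ki = kiImpute(data, ...),
    fcki = fckiImpute(data, ...),
    mean = meanImpute(data),
    knni = knniImputeGlobal(data, ...)
  )
}
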