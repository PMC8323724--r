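#' Synthetic correlated Gaussian-mixture datasets
#'
#' Generates a complete numeric dataset from `nClusters` multivariate
#' Gaussians whose within-cluster covariance is the equicorrelation matrix
#' `noiseSigma^2 * ((1 - correlation) I + correlation J)` (every feature pair
#' shares the target correlation) and whose centroids sit
#' `separation * noiseSigma` apart along the alternating-sign unit direction
#' `(1, -1, 1, -1, ...) / sqrt(m)`. Every feature thereby carries part of the
#' cluster separation (as in real clustered tables, where groups differ
#' across many variables, so a record missing any one feature can still be
#' routed to its cluster from the rest), while the between-cluster axis
#' stays clear of the equicorrelation structure's leading principal axis
#' (the all-ones direction): the nominal separation-to-spread ratio then
#' holds at any correlation, instead of silently collapsing as the
#' correlation grows. Rows are
#' assigned to clusters as evenly as the row count allows and returned in
#' cluster order together with their generating labels, so cluster-recovery
#' tests can compare against the truth.
#'
#' This stands in for real benchmark tables: it reproduces the two features
#' the imputation methods exploit (inter-feature correlation for the
#' regression stage, cluster structure for the routing stage) but not the
#' heavy tails, mixed scales or discreteness of field data.
#'
#' @param n number of rows.
#' @param m number of features.
#' @param nClusters number of mixture components (>= 1).
#' @param separation inter-centroid distance in units of `noiseSigma`.
#' @param correlation target pairwise feature correlation in `[0, 1)`.
#' @param noiseSigma within-cluster standard deviation of every feature.
#' @param seed integer seed.
#' @return a list with `data` (complete `n x m` matrix) and `labels`
#'   (integer vector of generating components).
#' @examples
#' s <- makeSynthetic(60, 4, nClusters = 2, separation = 10, seed = 1)
#' table(s$labels)
#' @export
makeSynthetic <- function(n, m, nClusters = 1L, separation = 6,
                          correlation = 0.5, noiseSigma = 1, seed = 1L) {
  if (n < 1L || m < 1L) .errSpec("n and m must be positive")
  if (nClusters < 1L || nClusters > n) .errSpec("nClusters must lie in [1, n]")
  if (correlation < 0 || correlation >= 1) .errSpec("correlation must lie in [0, 1)")
  if (noiseSigma <= 0) .errSpec("noiseSigma must be positive")
  Sigma <- noiseSigma^2 * ((1 - correlation) * diag(m) + correlation)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) .errSpec("correlation is infeasible for this feature count")
  sizes <- rep(n %/% nClusters, nClusters)
  if (n %% nClusters) sizes[seq_len(n %% nClusters)] <- sizes[seq_len(n %% nClusters)] + 1L
  labels <- rep(seq_len(nClusters), sizes)
  X <- .withSeed(seed, {
    u <- rep_len(c(1, -1), m) / sqrt(m)
    blocks <- lapply(seq_len(nClusters), function(k) {
      mu <- (k - 1L) * separation * noiseSigma * u
      matrix(MASS::mvrnorm(sizes[k], mu = mu, Sigma = Sigma), ncol = m)
    })
    do.call(rbind, blocks)
  })
  dimnames(X) <- list(as.character(seq_len(n)), paste0("V", seq_len(m)))
  list(data = X, labels = labels)
}
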