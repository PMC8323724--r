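# Programmatic fixtures and independent oracle implementations used across
# the suite. Oracles are written naively (loops, full sorts) on purpose, so
# they never share code with the package paths they check.

completeMatrix <- function(n, m, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * m, -5, 5), n, m))
}

# Sprinkle NA into a complete matrix, guaranteeing every column keeps at
# least one observed value.
holeyMatrix <- function(n, m, frac = 0.15, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(n * m, -5, 5), n, m)
    idx <- sample(n * m, max(1L, round(frac * n * m)))
    x[idx] <- NA_real_
    for (j in seq_len(m)) {
      if (all(is.na(x[, j]))) x[sample(n, 1L), j] <- stats::runif(1)
    }
    x
  })
}

# Oracle: partial Euclidean distance, naive loop form.
oracleDist <- function(a, b) {
  M <- length(a)
  s <- 0
  cnt <- 0L
  for (j in seq_len(M)) {
    if (!is.na(a[j]) && !is.na(b[j])) {
      s <- s + (a[j] - b[j])^2
      cnt <- cnt + 1L
    }
  }
  if (cnt == 0L) Inf else sqrt(M / cnt * s)
}

# Oracle: full distance sort with stable ties, self-exclusion by index.
oracleKNN <- function(target, pool, k, excludeIndex = NULL) {
  idx <- seq_len(nrow(pool))
  if (!is.null(excludeIndex)) idx <- idx[idx != excludeIndex]
  d <- vapply(idx, function(i) oracleDist(target, pool[i, ]), numeric(1))
  ord <- idx[order(d)]
  ord[seq_len(k)]
}

# Oracle: exhaustive auto-k search given a fixed probe column. Recomputes
# neighbours from scratch for every k (no incremental shortcuts).
oracleBestK <- function(target, donors, z) {
  av <- target[z]
  probe <- target
  probe[z] <- NA_real_
  np <- nrow(donors) + 1L
  errs <- numeric(0)
  poolCol <- donors[, z]
  poolMean <- mean(poolCol[!is.na(poolCol)])
  for (k in 2:(np - 1L)) {
    nn <- oracleKNN(probe, donors, k)
    vals <- donors[nn, z]
    vals <- vals[!is.na(vals)]
    est <- if (length(vals)) mean(vals) else poolMean
    errs <- c(errs, abs(av - est))
  }
  ks <- 2:(np - 1L)
  list(bestK = ks[which(errs == min(errs))[1L]], curve = errs)
}

# Two exactly collinear, far-separated clusters (y = 2x near the origin,
# y = -3x around x = 100) with one missing y in each; used by the FCKI
# per-cluster slope checks.
twoSlopeClusters <- function() {
  xa <- 1:8
  xb <- 100 + 1:8
  d <- rbind(cbind(xa, 2 * xa), cbind(xb, -3 * xb))
  colnames(d) <- c("x", "y")
  truthA <- d[3, "y"]
  truthB <- d[8 + 3, "y"]
  d[3, "y"] <- NA
  d[8 + 3, "y"] <- NA
  list(data = d, missRows = c(3L, 11L), truth = unname(c(truthA, truthB)))
}
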