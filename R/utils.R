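# Internal helpers shared across modules.

# Validate a numeric dataset matrix: rectangular numeric matrix, N>=1, M>=1,
# cells finite or NA. Returns the matrix with row/column names guaranteed.
.asDataset <- function(x, what = "dataset") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    .errShape(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    .errEmptyInput(sprintf("%s must have at least one row and one column", what))
  }
  if (any(is.infinite(x))) {
    .errParse(sprintf("%s contains non-finite (infinite) cells", what))
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) .errShape("row identifiers must be unique")
  if (anyDuplicated(colnames(x))) .errShape("column names must be unique")
  x
}

.checkComplete <- function(x, what = "dataset") {
  if (anyNA(x)) {
    .errPrefilled(sprintf("%s already contains missing cells; a complete dataset is required", what))
  }
  invisible(x)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic derived seed from a master seed and integer coordinates,
# kept strictly below 2^31 (R integers are 32-bit).
.deriveSeed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

# Squared partial (missing-aware) Euclidean distances from one query record to
# every row of a pool matrix: (M/m_co) * sum over co-observed columns of the
# squared difference; +Inf when no column is co-observed.
.dist2ToPool <- function(target, pool) {
  M <- length(target)
  obsT <- !is.na(target)
  diff <- sweep(pool, 2L, target, "-")
  co <- !is.na(pool) & rep(obsT, each = nrow(pool))
  diff[!co] <- 0
  mCo <- rowSums(co)
  d2 <- rowSums(diff * diff)
  out <- ifelse(mCo == 0L, Inf, (M / mCo) * d2)
  out
}

.distToPool <- function(target, pool) sqrt(.dist2ToPool(target, pool))

# Observed-column means; error if a column has no observed value.
.columnMeans <- function(x, require_all = TRUE) {
  m <- colMeans(x, na.rm = TRUE)
  if (require_all && any(is.nan(m))) {
    bad <- colnames(x)[is.nan(m)][1L]
    .errColumnAllMissing(sprintf("column '%s' has no observed values", bad))
  }
  m
}
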