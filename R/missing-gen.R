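# Seeded MCAR / MAR / MNAR missingness generators. All three inject NA into a
# complete matrix until the achieved ratio of missing cells first reaches the
# requested percentage MDR of the V = N*M cells, and return a MaskedDataset
# carrying mask, truth and provenance.

.checkMdr <- function(mdr) {
  if (!is.numeric(mdr) || length(mdr) != 1L || is.na(mdr) ||
      mdr <= 0 || mdr >= 100) {
    .errSpec("mdr must lie strictly between 0 and 100 percent")
  }
}

.newMasked <- function(truth, mask, mechanism, mdr, nAttrs, seed) {
  data <- truth
  data[mask] <- NA_real_
  new("MaskedDataset",
      data = data, truth = truth, mask = mask,
      mechanism = mechanism, mdr = as.numeric(mdr),
      nAttrs = as.integer(nAttrs), seed = as.integer(seed))
}

# Distinct attribute draw shared by MAR and MNAR: nAttrs distinct column
# indices, uniform, sequentially (rejection on repeats) so the draw order
# matches the generating pseudo-random stream exactly across mechanisms.
.drawAttrs <- function(M, nAttrs) {
  out <- integer(0L)
  while (length(out) < nAttrs) {
    y <- sample.int(M, 1L)
    if (!y %in% out) out <- c(out, y)
  }
  out
}

#' Inject MCAR missingness
#'
#' Masks a uniformly random set of exactly `ceiling(mdr * N * M / 100)`
#' distinct cells, the smallest count whose ratio reaches `mdr`. Sampling
#' distinct positions without replacement is distributionally identical to
#' redrawing random coordinates until the ratio is reached, but always
#' terminates.
#'
#' @param data complete numeric matrix.
#' @param mdr target missing ratio in percent of all cells, in (0, 100).
#' @param seed integer seed; identical seeds give identical masks.
#' @return a [MaskedDataset-class].
#' @examples
#' md <- generateMCAR(matrix(rnorm(100), 10), mdr = 10, seed = 1)
#' sum(missingMask(md))  # 10
#' @export
generateMCAR <- function(data, mdr, seed) {
  data <- .asDataset(data)
  .checkComplete(data)
  .checkMdr(mdr)
  V <- length(data)
  nMask <- ceiling(mdr * V / 100)
  mask <- matrix(FALSE, nrow(data), ncol(data), dimnames = dimnames(data))
  .withSeed(seed, {
    mask[sample.int(V, nMask)] <- TRUE
  })
  .newMasked(data, mask, "MCAR", mdr, NA_integer_, seed)
}

# Number of records to mask so that masking nAttrs cells per record first
# reaches the ratio: smallest count with 100 * count * nAttrs / V >= mdr.
.recordCount <- function(mdr, V, nAttrs) {
  as.integer(ceiling(mdr * V / (100 * nAttrs)))
}

.checkNa <- function(nAttrs, M) {
  if (!is.numeric(nAttrs) || length(nAttrs) != 1L || is.na(nAttrs) ||
      nAttrs < 1 || nAttrs != round(nAttrs)) {
    .errSpec("nAttrs must be a positive integer")
  }
  if (nAttrs > M) .errSpec(sprintf("nAttrs (%d) exceeds the number of attributes (%d)", nAttrs, M))
}

#' Inject MAR missingness
#'
#' A causative attribute is drawn uniformly; `nAttrs` distinct dependent
#' attributes are drawn uniformly (the causative itself may be among them
#' unless `excludeCausative`); the records holding the smallest causative
#' values (ties to the lowest row index) lose their values on every dependent
#' attribute, adding records until the missing ratio first reaches `mdr`.
#'
#' @param data complete numeric matrix.
#' @param mdr target missing ratio in percent, in (0, 100).
#' @param nAttrs number of attributes losing values, in 1..M.
#' @param seed integer seed.
#' @param excludeCausative logical; if `TRUE` the dependent attributes are
#'   redrawn so the causative attribute never loses its own values (off by
#'   default: masking the causative is permitted, though it makes the
#'   mechanism behave like MNAR on those cells).
#' @return a [MaskedDataset-class]. `provenance(x)$causative` is recorded via
#'   the attribute `"causative"` on the mask for inspection.
#' @export
generateMAR <- function(data, mdr, nAttrs, seed, excludeCausative = FALSE) {
  data <- .asDataset(data)
  .checkComplete(data)
  .checkMdr(mdr)
  M <- ncol(data); N <- nrow(data); V <- N * M
  .checkNa(nAttrs, if (excludeCausative) M - 1L else M)
  res <- .withSeed(seed, {
    causative <- sample.int(M, 1L)
    repeat {
      attrs <- .drawAttrs(M, nAttrs)
      if (!excludeCausative || !causative %in% attrs) break
    }
    list(causative = causative, attrs = attrs)
  })
  count <- .recordCount(mdr, V, nAttrs)
  if (count > N) .errSpec("mdr not reachable: more records required than the dataset holds")
  # argmin-prefix of the causative column, stable on ties (order() is stable)
  rows <- order(data[, res$causative])[seq_len(count)]
  mask <- matrix(FALSE, N, M, dimnames = dimnames(data))
  mask[rows, res$attrs] <- TRUE
  out <- .newMasked(data, mask, "MAR", mdr, nAttrs, seed)
  attr(out@mask, "causative") <- res$causative
  out
}

#' Inject MNAR missingness
#'
#' Like [generateMAR()] but with no observable causative attribute: the
#' records losing their values on the `nAttrs` drawn dependent attributes are
#' selected uniformly at random, added until the ratio first reaches `mdr`.
#'
#' @inheritParams generateMAR
#' @return a [MaskedDataset-class].
#' @export
generateMNAR <- function(data, mdr, nAttrs, seed) {
  data <- .asDataset(data)
  .checkComplete(data)
  .checkMdr(mdr)
  M <- ncol(data); N <- nrow(data); V <- N * M
  .checkNa(nAttrs, M)
  count <- .recordCount(mdr, V, nAttrs)
  if (count > N) .errSpec("mdr not reachable: more records required than the dataset holds")
  drawn <- .withSeed(seed, {
    attrs <- .drawAttrs(M, nAttrs)
    rows <- integer(0L)
    while (length(rows) < count) {
      x <- sample.int(N, 1L)
      if (!x %in% rows) rows <- c(rows, x)
    }
    list(attrs = attrs, rows = rows)
  })
  mask <- matrix(FALSE, N, M, dimnames = dimnames(data))
  mask[drawn$rows, drawn$attrs] <- TRUE
  .newMasked(data, mask, "MNAR", mdr, nAttrs, seed)
}

#' Dispatch a missingness generator by mechanism name
#'
#' @param data complete numeric matrix.
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR"` (case-insensitive).
#' @param mdr target missing ratio in percent.
#' @param nAttrs attributes losing values (ignored for MCAR).
#' @param seed integer seed.
#' @param excludeCausative passed to [generateMAR()].
#' @return a [MaskedDataset-class].
#' @export
generateMissing <- function(data, mechanism, mdr, nAttrs = NULL, seed = 1L,
                            excludeCausative = FALSE) {
  switch(toupper(mechanism),
    MCAR = generateMCAR(data, mdr, seed),
    MAR = {
      if (is.null(nAttrs)) .errSpec("MAR requires nAttrs")
      generateMAR(data, mdr, nAttrs, seed, excludeCausative)
    },
    MNAR = {
      if (is.null(nAttrs)) .errSpec("MNAR requires nAttrs")
      generateMNAR(data, mdr, nAttrs, seed)
    },
    .errSpec(sprintf("unknown mechanism '%s'", mechanism))
  )
}
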