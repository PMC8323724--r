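# KI, FCKI and the mean / global-kNNI baselines.

test_that("KI returns complete data, leaves observed cells untouched", {
  x <- completeMatrix(6, 3, seed = 2)
  r <- kiImpute(x, seed = 1)
  expect_identical(imputedValues(r), fcki:::.asDataset(x))
  expect_equal(nrow(recordLog(r)), 0L)

  y <- holeyMatrix(15, 4, frac = 0.15, seed = 3)
  r2 <- kiImpute(y, seed = 1)
  out <- imputedValues(r2)
  expect_false(anyNA(out))
  obs <- !is.na(y)
  expect_identical(out[obs], y[obs])
  # deterministic under a fixed seed
  expect_identical(out, imputedValues(kiImpute(y, seed = 1)))
  expect_false(identical(out, imputedValues(kiImpute(y, seed = 2))))
})

test_that("KI recovers a withheld collinear value through its donors", {
  x <- cbind(a = c(1, 2, 4, 3, 5, 6), b = c(2, 4, 8, NA, 10, 12))
  r <- kiImpute(x, seed = 1)
  expect_equal(imputedValues(r)[4, "b"], 6, tolerance = 0.1)
  log <- recordLog(r)
  expect_equal(log$record, 4L)
  expect_equal(log$fallback, "none")
  expect_true(log$bestK >= 2)
})

test_that("an empty donor pool falls back to column means and is logged", {
  # rows 1-3 all miss column 2, so each has a single-donor pool (row 4)
  x <- rbind(c(1, NA), c(2, NA), c(3, NA), c(4, 8))
  r <- kiImpute(x, seed = 1)
  expect_equal(unname(imputedValues(r)[1:3, 2]), rep(8, 3))
  # record 1 has a single-donor pool and must take the mean fallback;
  # later records may reuse earlier imputations as donors
  expect_equal(recordLog(r)$fallback[1], "column-mean")

  # a record missing every attribute is still imputed via the ladder
  y <- completeMatrix(5, 3, seed = 4)
  y[2, ] <- NA
  r2 <- kiImpute(y, seed = 1)
  expect_false(anyNA(imputedValues(r2)))
  expect_equal(recordLog(r2)$fallback, "column-mean")
})

test_that("sequentially imputed records can donate to later records", {
  # record 2's only same-pattern donors appear after record 1 is filled
  x <- holeyMatrix(12, 3, frac = 0.25, seed = 8)
  r <- kiImpute(x, seed = 3)
  expect_false(anyNA(imputedValues(r)))
  # the log processes incomplete records in ascending row order
  expect_identical(recordLog(r)$record, sort(recordLog(r)$record))
})

test_that("FCKI with a single cluster reduces exactly to KI", {
  for (s in 1:5) {
    y <- holeyMatrix(14, 4, frac = 0.2, seed = 40 + s)
    a <- kiImpute(y, seed = s)
    b <- fckiImpute(y, c = 1, seed = s)
    expect_identical(imputedValues(a), imputedValues(b))
  }
})

test_that("FCKI imputes within the routed cluster and respects its slope", {
  fix <- twoSlopeClusters()
  r <- fckiImpute(fix$data, c = 2, seed = 1)
  got <- imputedValues(r)[fix$missRows, "y"]
  expect_equal(unname(got), fix$truth, tolerance = 0.1)
  log <- recordLog(r)
  # routing follows the highest-membership cluster of the FCM fit
  model <- fcmFit(fix$data, 2, seed = fcki:::.deriveSeed(1, 15485863L))
  labels <- hardAssign(model)$labels
  expect_equal(log$clusterId, labels[log$record])
  expect_true(all(log$fallback == "none"))
})

test_that("mean imputation fills each column with one shared value", {
  x <- cbind(c(1, 2, NA, 3), c(5, NA, NA, 7))
  r <- meanImpute(x)
  expect_equal(imputedValues(r)[3, 1], 2)
  expect_equal(unname(imputedValues(r)[2:3, 2]), c(6, 6))
  expect_identical(imputedValues(meanImpute(completeMatrix(3, 2))),
                   fcki:::.asDataset(completeMatrix(3, 2)))
  expect_error(meanImpute(matrix(c(1, 2, NA, NA), 2)),
               class = "fcki_column_all_missing_error")
})

test_that("global kNNI averages the k nearest observed neighbours", {
  x <- rbind(c(0, NA), c(0, 1), c(0.1, 3), c(9, 50))
  r <- knniImputeGlobal(x, k = 2)
  expect_equal(imputedValues(r)[1, 2], 2)

  # k = N - 1 on one incomplete record equals the column mean without it
  y <- completeMatrix(8, 3, seed = 5)
  y[2, 3] <- NA
  r2 <- knniImputeGlobal(y, k = 7)
  expect_equal(imputedValues(r2)[2, 3], mean(y[-2, 3]))

  expect_error(knniImputeGlobal(y, k = 8), class = "fcki_spec_error")
})

test_that("global kNNI matches a brute-force re-implementation", {
  for (rep in 1:50) {
    x <- holeyMatrix(12, 4, frac = 0.15, seed = 600 + rep)
    k <- sample(1:6, 1)
    got <- imputedValues(knniImputeGlobal(x, k))
    mu <- colMeans(x, na.rm = TRUE)
    want <- x
    for (i in seq_len(nrow(x))) {
      if (!anyNA(x[i, ])) next
      idx <- setdiff(seq_len(nrow(x)), i)
      ds <- vapply(idx, function(p) oracleDist(x[i, ], x[p, ]), numeric(1))
      if (all(is.infinite(ds))) {
        # no comparable donor: documented column-mean fallback
        want[i, is.na(x[i, ])] <- mu[is.na(x[i, ])]
        next
      }
      nn <- idx[order(ds)][seq_len(k)]
      for (j in which(is.na(x[i, ]))) {
        v <- x[nn, j]
        v <- v[!is.na(v)]
        want[i, j] <- if (length(v)) mean(v) else mu[j]
      }
    }
    expect_equal(unname(got), unname(want))
  }
})

test_that("both hybrids beat mean imputation on correlated data", {
  rs <- sapply(1:3, function(s) {
    syn <- makeSynthetic(120, 6, nClusters = 2, separation = 8,
                         correlation = 0.9, seed = s)
    md <- generateMCAR(syn$data, 10, seed = 100 + s)
    dm <- maskedValues(md)
    c(ki = evaluateMasked(md, imputed = kiImpute(dm, seed = s))@rmse,
      fcki = evaluateMasked(md, imputed = fckiImpute(dm, c = 2, seed = s))@rmse,
      mean = evaluateMasked(md, imputed = meanImpute(dm))@rmse)
  })
  m <- rowMeans(rs)
  expect_lt(m["ki"], m["mean"])
  expect_lt(m["fcki"], m["mean"])
})
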