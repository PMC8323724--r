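# MCAR / MAR / MNAR missingness generators.

test_that("MCAR masks exactly the smallest cell count reaching the ratio", {
  x <- completeMatrix(10, 10, seed = 1)
  md <- generateMCAR(x, mdr = 10, seed = 7)
  expect_equal(sum(missingMask(md)), 10L)
  expect_equal(achievedRatio(md), 10)

  # 4x5 at 17%: each cell is 5% of V = 20, first count with ratio >= 17 is 4
  md2 <- generateMCAR(completeMatrix(4, 5, seed = 2), mdr = 17, seed = 7)
  expect_equal(sum(missingMask(md2)), 4L)
  expect_equal(achievedRatio(md2), 20)

  # seed contract
  a <- generateMCAR(x, 10, seed = 3)
  b <- generateMCAR(x, 10, seed = 3)
  cc <- generateMCAR(x, 10, seed = 4)
  expect_identical(missingMask(a), missingMask(b))
  expect_false(identical(missingMask(a), missingMask(cc)))

  # data and truth agree off-mask; masked cells are NA
  expect_true(all(maskedValues(a)[!missingMask(a)] == truthValues(a)[!missingMask(a)]))
  expect_true(all(is.na(maskedValues(a)[missingMask(a)])))

  expect_error(generateMCAR(x, 0, seed = 1), class = "fcki_spec_error")
  expect_error(generateMCAR(x, 100, seed = 1), class = "fcki_spec_error")
  xm <- x; xm[1, 1] <- NA
  expect_error(generateMCAR(xm, 10, seed = 1), class = "fcki_prefilled_input_error")
})

test_that("MAR masks the argmin-prefix of the causative column", {
  x <- completeMatrix(10, 5, seed = 3)
  md <- generateMAR(x, mdr = 20, nAttrs = 2, seed = 11)
  m <- missingMask(md)
  expect_equal(sum(m), 10L)                       # 5 records x 2 attributes
  expect_equal(achievedRatio(md), 20)
  expect_equal(sum(rowSums(m) > 0), 5L)
  expect_equal(sum(colSums(m) > 0), 2L)

  # independent sort oracle over many seeds, including tied causative values
  for (s in 1:25) {
    y <- completeMatrix(12, 4, seed = 100 + s)
    if (s %% 3 == 0) y[, 2] <- round(y[, 2])      # force ties sometimes
    g <- generateMAR(y, mdr = 25, nAttrs = 2, seed = s)
    cz <- attr(g@mask, "causative")
    rows <- which(rowSums(missingMask(g)) > 0)
    nRec <- length(rows)
    oracle <- sort(order(y[, cz])[seq_len(nRec)]) # stable ties: first occurrence
    expect_equal(sort(unname(rows)), oracle)
  }

  # nAttrs = M: masked rows lose every value, causative included
  g2 <- generateMAR(x, mdr = 20, nAttrs = 5, seed = 5)
  rows <- which(rowSums(missingMask(g2)) > 0)
  expect_true(all(missingMask(g2)[rows, ]))

  expect_error(generateMAR(x, 20, nAttrs = 6, seed = 1), class = "fcki_spec_error")
})

test_that("MNAR masks random records on a fixed attribute set", {
  x <- completeMatrix(10, 5, seed = 4)
  md <- generateMNAR(x, mdr = 20, nAttrs = 2, seed = 13)
  m <- missingMask(md)
  expect_equal(sum(m), 10L)
  expect_equal(sum(colSums(m) > 0), 2L)           # cells lie in exactly na columns
  expect_equal(sum(rowSums(m) > 0), 5L)
  expect_identical(missingMask(generateMNAR(x, 20, 2, seed = 13)), m)
})

test_that("achieved ratio overshoot stays below one step's share", {
  set.seed(900)
  for (rep in 1:150) {
    n <- sample(5:25, 1)
    m <- sample(2:8, 1)
    mdr <- stats::runif(1, 1, 60)
    na <- sample.int(m, 1)
    mech <- sample(c("MCAR", "MAR", "MNAR"), 1)
    x <- completeMatrix(n, m, seed = rep)
    step <- if (mech == "MCAR") 1 else na
    if (mech != "MCAR" && ceiling(mdr * n * m / (100 * na)) > n) next
    md <- generateMissing(x, mech, mdr, nAttrs = na, seed = rep)
    r <- achievedRatio(md)
    expect_gte(r, mdr)
    expect_lt(r, mdr + 100 * step / (n * m))
    expect_true(all(maskedValues(md)[!missingMask(md)] ==
                    truthValues(md)[!missingMask(md)]))
  }
})

test_that("MCAR and MNAR cell selection is exchangeable across cells", {
  x <- completeMatrix(20, 5, seed = 5)
  nRep <- 1000L
  freq <- matrix(0, 20, 5)
  for (s in seq_len(nRep)) {
    freq <- freq + missingMask(generateMCAR(x, mdr = 10, seed = s))
  }
  p <- 10 / 100  # 10 of 100 cells each replicate
  sigma <- sqrt(nRep * p * (1 - p))
  expect_true(all(abs(freq - nRep * p) <= 4 * sigma))

  # MNAR row draw uniformity (columns are redrawn each replicate)
  rowFreq <- numeric(20)
  for (s in seq_len(nRep)) {
    m <- missingMask(generateMNAR(x, mdr = 10, nAttrs = 2, seed = 10000 + s))
    rowFreq <- rowFreq + (rowSums(m) > 0)
  }
  pr <- 5 / 20   # 5 of 20 rows per replicate
  sr <- sqrt(nRep * pr * (1 - pr))
  expect_true(all(abs(rowFreq - nRep * pr) <= 4 * sr))
})

test_that("a logical mask reports its ratio like a brute-force count", {
  m <- matrix(FALSE, 10, 10)
  expect_equal(achievedRatio(m), 0)
  m[sample(100, 10)] <- TRUE
  expect_equal(achievedRatio(m), 10)
  cnt <- 0L
  for (i in 1:10) for (j in 1:10) if (m[i, j]) cnt <- cnt + 1L
  expect_equal(achievedRatio(m), 100 * cnt / 100)
})
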