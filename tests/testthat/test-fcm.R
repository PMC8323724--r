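# Fuzzy c-means on (in)complete data, elbow rule, hard assignment.

test_that("two far-separated blobs are recovered with near-crisp memberships", {
  set.seed(51)
  x <- matrix(c(-10 + stats::runif(20, -0.1, 0.1),
                 10 + stats::runif(20, -0.1, 0.1)), ncol = 1)
  fit <- fcmFit(x, c = 2, seed = 3)
  u <- membership(fit)
  own <- cbind(u[1:20, max.col(u[1:20, , drop = FALSE])[1]],
               u[21:40, max.col(u[21:40, , drop = FALSE])[1]])
  expect_true(all(pmax(u[1:20, 1], u[1:20, 2]) >= 0.99))
  expect_true(all(pmax(u[21:40, 1], u[21:40, 2]) >= 0.99))
  expect_equal(sort(as.numeric(centroids(fit))), c(-10, 10), tolerance = 0.2)
})

test_that("membership rows are stochastic and the objective never rises", {
  x <- holeyMatrix(40, 3, frac = 0.1, seed = 6)
  fit <- fcmFit(x, c = 3, seed = 9)
  expect_true(all(abs(rowSums(membership(fit)) - 1) <= 1e-9))
  expect_true(all(diff(objectiveTrace(fit)) <= 1e-9))
  expect_true(all(membership(fit) >= 0 & membership(fit) <= 1))
})

test_that("a point equidistant from symmetric centroids splits 0.5/0.5", {
  x <- matrix(c(rep(-2, 10), rep(2, 10), 0), ncol = 1)
  fit <- fcmFit(x, c = 2, seed = 2, tol = 1e-9, maxIter = 500)
  u <- membership(fit)[21, ]
  expect_equal(unname(u), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("converged fits satisfy the fixed-point equations", {
  # independent check: recompute memberships from the returned centroids via
  # the closed-form update and compare
  x <- completeMatrix(30, 4, seed = 8)
  fit <- fcmFit(x, c = 3, seed = 4, tol = 1e-9, maxIter = 500)
  C <- centroids(fit)
  U <- membership(fit)
  for (i in seq_len(nrow(x))) {
    d2 <- apply(C, 1L, function(ck) sum((x[i, ] - ck)^2))
    expected <- if (any(d2 == 0)) as.numeric(d2 == 0) / sum(d2 == 0) else {
      w <- (1 / d2)^(1 / (2 - 1)); w / sum(w)
    }
    expect_equal(unname(U[i, ]), unname(expected), tolerance = 1e-5)
  }
})

test_that("partial-distance FCM matches a reference fit on complete data", {
  skip_if_not_installed("e1071")
  s <- makeSynthetic(80, 3, nClusters = 2, separation = 12, correlation = 0.2,
                     seed = 14)
  fit <- fcmFit(s$data, c = 2, seed = 5, tol = 1e-9, maxIter = 500)
  ref <- withr::with_seed(6, e1071::cmeans(s$data, centers = 2, m = 2))
  ours <- centroids(fit)[order(centroids(fit)[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("cluster labels are recovered exactly at 10-sigma separation", {
  for (s in 1:10) {
    syn <- makeSynthetic(60, 4, nClusters = 2, separation = 10,
                         correlation = 0.3, seed = s)
    fit <- fcmFit(syn$data, c = 2, seed = 1000 + s)
    labels <- hardAssign(fit)$labels
    agree <- max(mean(labels == syn$labels), mean(labels == 3 - syn$labels))
    expect_equal(agree, 1)
  }
})

test_that("the elbow rule picks the largest second difference", {
  # hand case: J = {80, 20, 18, 17} over c = 2..5 -> second differences
  # 58 at c = 3 and 1 at c = 4, so the elbow is 3
  expect_equal(fcki:::.elbowFromCurve(c(80, 20, 18, 17), 2:5), 3L)
  # strictly linear curve has no positive second difference -> cMin
  expect_equal(fcki:::.elbowFromCurve(c(30, 20, 10, 0), 2:5), 2L)

  syn <- makeSynthetic(120, 4, nClusters = 3, separation = 12,
                       correlation = 0.2, seed = 9)
  cSel <- elbowSelectC(syn$data, cMin = 2, cMax = 6, seed = 3)
  expect_true(cSel >= 2 && cSel <= 6)
  expect_equal(as.integer(cSel), 3L)
})

test_that("hard assignment takes the highest membership, first on ties", {
  model <- new("FCMModel",
               centroids = matrix(0, 2, 1),
               membership = rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8)),
               fuzzifier = 2, objectiveTrace = c(1, 0.5), seed = 1L)
  pa <- hardAssign(model)
  expect_equal(pa$labels, c(1L, 1L, 2L))
  # brute-force row-max scan oracle
  for (i in 1:3) {
    expect_equal(pa$labels[i], which.max(membership(model)[i, ]))
  }
  expect_equal(sort(unlist(pa$clusters)), 1:3)
})

test_that("invalid cluster counts are rejected", {
  x <- completeMatrix(10, 2, seed = 1)
  expect_error(fcmFit(x, c = 1), class = "fcki_spec_error")
  expect_error(fcmFit(x, c = 11), class = "fcki_spec_error")
  expect_error(elbowSelectC(x, cMin = 2, cMax = 3), class = "fcki_spec_error")
})
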