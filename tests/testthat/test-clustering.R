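test_that("k-means separates well-separated pairs and handles one cluster", {
  r <- kmeans_cluster(c(0, 0, 10, 10), 2, seed = 1)
  expect_equal(sort(r$centers), c(0, 10))
  expect_equal(r$cost_trace[length(r$cost_trace)], 0)
  expect_equal(r$labels[1], r$labels[2])
  expect_equal(r$labels[3], r$labels[4])
  r1 <- kmeans_cluster(c(1, 2, 3, 10), 1, seed = 1)
  expect_equal(r1$centers, 4)
  expect_error(kmeans_cluster(c(1, 1, 1), 2, seed = 1), "distinct")
  expect_error(kmeans_cluster(numeric(0), 2, seed = 1), "empty")
})

test_that("k-means cost trace is non-increasing and never beats the enumerated optimum", {
  set.seed(100)
  for (i in 1:100) {
    v <- round(runif(sample(4:8, 1), 0, 100), 2)
    if (length(unique(v)) < 2) next
    r <- kmeans_cluster(v, 2, seed = i)
    expect_true(all(diff(r$cost_trace) <= 1e-9))
    opt <- best_two_partition_cost(v)
    expect_gte(r$cost_trace[length(r$cost_trace)], opt - 1e-9)
  }
})

test_that("k-means attains the enumerated optimum on separated data", {
  set.seed(3)
  v <- c(rnorm(6, 0, 0.5), rnorm(2, 50, 0.5))
  r <- kmeans_cluster(v, 2, seed = 1)
  expect_equal(r$cost_trace[length(r$cost_trace)],
               best_two_partition_cost(v), tolerance = 1e-9)
})

test_that("identical inputs and seed reproduce the clustering bit-for-bit", {
  set.seed(9); v <- runif(200, 0, 255)
  expect_identical(kmeans_cluster(v, 2, seed = 7), kmeans_cluster(v, 2, seed = 7))
  expect_identical(fcm_cluster(v, 2, seed = 7), fcm_cluster(v, 2, seed = 7))
})

test_that("FCM memberships are normalized, equidistance splits 0.5/0.5, zero distance is crisp", {
  set.seed(21); v <- runif(50, 0, 255)
  r <- fcm_cluster(v, 3, seed = 2)
  expect_true(all(r$memberships >= 0 & r$memberships <= 1))
  expect_equal(rowSums(r$memberships), rep(1, 50), tolerance = 1e-9)
  u <- gaborEdge:::fcm_memberships(matrix(c(5, 5), 1, 2), fuzziness = 2)
  expect_equal(as.numeric(u), c(0.5, 0.5))
  u0 <- gaborEdge:::fcm_memberships(matrix(c(0, 7), 1, 2), fuzziness = 2)
  expect_equal(as.numeric(u0), c(1, 0))
  u00 <- gaborEdge:::fcm_memberships(matrix(c(0, 0, 3), 1, 3), fuzziness = 2)
  expect_equal(as.numeric(u00), c(0.5, 0.5, 0))
})

test_that("FCM rejects invalid fuzziness and degenerate input", {
  expect_error(fcm_cluster(1:5, 2, fuzziness = 1), "fuzziness")
  expect_error(fcm_cluster(rep(3, 10), 2), "degenerate")
})

test_that("FCM converges to the independently coded fixed point", {
  set.seed(2026)
  v <- runif(20, 0, 10)
  r <- fcm_cluster(v, 2, fuzziness = 2, seed = 5, tol = 1e-10, max_iter = 2000)
  # replay the package's membership initialization, then iterate the update
  # equations with the loop-coded oracle to tight tolerance
  set.seed(5)
  u0 <- matrix(runif(20 * 2), 20, 2); u0 <- u0 / rowSums(u0)
  o <- fcm_oracle(v, u0, m = 2, tol = 1e-10)
  expect_equal(r$centers, o$centers, tolerance = 1e-6)
  expect_equal(r$memberships, o$u, tolerance = 1e-5)
  # and the result satisfies both update equations as a fixed point
  um <- r$memberships^2
  expect_equal(as.numeric(crossprod(um, v) / colSums(um)), r$centers,
               tolerance = 1e-6)
})

test_that("FCM agrees with e1071::cmeans on well-separated data", {
  skip_if_not_installed("e1071")
  set.seed(8)
  v <- c(rnorm(30, 10, 1), rnorm(30, 100, 1))
  r <- fcm_cluster(v, 2, fuzziness = 2, seed = 1, tol = 1e-9)
  cm <- e1071::cmeans(matrix(v), centers = 2, m = 2)
  expect_equal(sort(r$centers), sort(as.numeric(cm$centers)), tolerance = 1e-3)
})

test_that("FCM hard labels approach the k-means partition as fuzziness drops to 1", {
  v <- c(0, 0, 10, 10)
  r <- fcm_cluster(v, 2, fuzziness = 1.05, seed = 3)
  expect_equal(r$labels[1], r$labels[2])
  expect_equal(r$labels[3], r$labels[4])
  expect_true(r$labels[1] != r$labels[3])
  expect_equal(sort(r$centers), c(0, 10), tolerance = 1e-3)
})

test_that("binarize picks the brighter cluster under any label permutation", {
  mk <- function(centers, labels) structure(
    list(centers = centers, labels = labels, method = "kmeans"),
    class = "cluster_result")
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  a <- binarize(mk(c(3, 90), lab))
  b <- binarize(mk(c(90, 3), matrix(c(2L, 2L, 1L, 1L), 2, 2)))
  expect_identical(a, b)
  expect_equal(a, matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_error(binarize(mk(c(1, 2, 3), lab)), "2 clusters")
})

test_that("binarize of a clustered toy grid matches the hand-assigned mask", {
  vals <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 10, 10, 10, 10, 10, 10, 10, 10), 4, 4)
  r <- kmeans_cluster(vals, 2, seed = 1)
  expect_equal(binarize(r), (vals == 10) + 0L)
  expect_true(is.matrix(binarize(r)))
})
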