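test_that("kernel centre, degenerate frequency and argument checks follow the definition", {
  for (th in c(0, pi / 3, pi)) for (u in c(0, 0.5, 4)) {
    k <- gabor_kernel(sigma = 0.1, freq = u, theta = th, support = 9)
    expect_equal(k[5, 5], complex(real = 1 / (2 * pi * 0.1^2)), tolerance = 1e-14)
  }
  k0 <- gabor_kernel(sigma = 0.2, freq = 0, theta = 1.1, support = 7)
  expect_true(all(Im(k0) == 0))
  expect_true(all(Re(k0) > 0))
  expect_error(gabor_kernel(-1, 1, 0), "sigma")
  expect_error(gabor_kernel(0.1, 1, 0, support = 8), "support")
  expect_error(gabor_kernel(0.1, 1, 0, support = 1), "support")
})

test_that("theta and theta + pi give conjugate kernels and equal magnitude responses", {
  for (th in c(0, 0.7, pi / 2)) {
    k1 <- gabor_kernel(0.15, 3, th, support = 11)
    k2 <- gabor_kernel(0.15, 3, th + pi, support = 11)
    expect_equal(k2, Conj(k1), tolerance = 1e-12)
  }
  set.seed(42)
  img <- matrix(runif(15 * 15, 0, 255), 15, 15)
  m1 <- Mod(gabor_filter(img, 0.15, 3, 0.7, support = 7))
  m2 <- Mod(gabor_filter(img, 0.15, 3, 0.7 + pi, support = 7))
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("convolution with an impulse reproduces the kernel", {
  img <- matrix(0, 11, 11); img[6, 6] <- 1
  k <- gabor_kernel(0.2, 2, pi / 4, support = 5)
  resp <- gabor_filter(img, 0.2, 2, pi / 4, support = 5)
  for (di in -2:2) for (dj in -2:2)
    expect_equal(resp[6 + di, 6 + dj], k[3 + di, 3 + dj], tolerance = 1e-10)
})

test_that("constant image with a pure-Gaussian kernel gives kernel-sum response", {
  img <- matrix(7, 10, 12)
  k <- gabor_kernel(0.2, 0, 0, support = 5)
  resp <- gabor_filter(img, 0.2, 0, 0, support = 5)
  expect_equal(Re(resp), matrix(7 * sum(Re(k)), 10, 12), tolerance = 1e-9)
  expect_equal(max(abs(Im(resp))), 0, tolerance = 1e-9)
})

test_that("convolution matches the direct-sum oracle, including the quadruple-loop form", {
  set.seed(7)
  img <- matrix(runif(49, 0, 255), 7, 7)
  k <- gabor_kernel(0.15, 2.5, 1.0, support = 5)
  fast <- gaborEdge::convolve2(img, k)
  expect_equal(fast, conv2_oracle(img, k), tolerance = 1e-9)
  expect_equal(fast, conv2_oracle_slow(img, k), tolerance = 1e-9)
})

test_that("fusion adds orientation magnitudes and degenerates correctly", {
  set.seed(11)
  img <- matrix(runif(12 * 14, 0, 100), 12, 14)
  one <- gabor_fuse(img, 0.15, 3, thetas = pi / 3, support = 7)
  expect_equal(one$fused, one$magnitudes[[1]], tolerance = 1e-12)
  two <- gabor_fuse(img, 0.15, 3, thetas = c(0.4, 1.9), support = 7)
  m1 <- Mod(gabor_filter(img, 0.15, 3, 0.4, support = 7))
  m2 <- Mod(gabor_filter(img, 0.15, 3, 1.9, support = 7))
  expect_equal(two$fused, m1 + m2, tolerance = 1e-10)
  expect_true(all(two$fused >= 0))
  z <- gabor_fuse(matrix(0, 9, 9), 0.15, 3, support = 7)
  expect_equal(max(abs(z$fused)), 0, tolerance = 1e-12)
  expect_error(gabor_fuse(img, 0.15, 3, thetas = numeric(0)), "thetas")
  mx <- gabor_fuse(img, 0.15, 3, thetas = c(0.4, 1.9), support = 7,
                   fusion = "max")
  expect_equal(mx$fused, pmax(m1, m2), tolerance = 1e-10)
})

test_that("magnitude responses scale linearly with image intensity", {
  set.seed(5)
  img <- matrix(runif(100, 0, 50), 10, 10)
  r1 <- gabor_fuse(img, 0.12, 4, support = 7)
  r2 <- gabor_fuse(2 * img, 0.12, 4, support = 7)
  expect_equal(r2$fused, 2 * r1$fused, tolerance = 1e-9)
})

test_that("the strongest oriented response has its wave vector perpendicular to a step edge", {
  img <- matrix(0, 40, 40); img[, 21:40] <- 100  # vertical edge, normal = x
  edge_cols <- 19:22
  mean_resp <- sapply(c(pi / 4, pi / 2, 3 * pi / 4, pi), function(th)
    mean(Mod(gabor_filter(img, 0.12, 4, th, support = 15))[, edge_cols]))
  # theta = pi points the wave vector along x, perpendicular to the edge
  expect_equal(which.max(mean_resp), 4L)
  expect_gt(mean_resp[4], 2 * mean_resp[2])  # parallel orientation is weak
})
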