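test_that("phantom specs are validated", {
  expect_error(phantom_spec(ellipses = data.frame()), "at least one row")
  expect_error(phantom_spec(
    ellipses = data.frame(cx = 1, cy = 1, a = -2, b = 1, rot = 0,
                          intensity = 10)), "semi-axes")
  expect_s3_class(phantom_paperlike(), "phantom_spec")
  expect_gte(nrow(phantom_paperlike()$ellipses), 4)
})

test_that("a rasterized circle covers the analytic area within 2 percent", {
  spec <- phantom_spec(size = c(128, 128),
                       ellipses = data.frame(cx = 64, cy = 64, a = 30, b = 30,
                                             rot = 0, intensity = 200),
                       background = 0)
  ph <- render_phantom(spec)
  expect_lt(abs(sum(ph$truth_regions == 1) - pi * 30^2) / (pi * 30^2), 0.02)
})

test_that("a nested same-intensity ellipse still contributes an internal contour", {
  spec <- phantom_spec(size = c(96, 96),
                       ellipses = data.frame(
                         cx = c(48, 48), cy = c(48, 48), a = c(35, 15),
                         b = c(28, 10), rot = c(0, 0.4),
                         intensity = c(150, 150)),
                       background = 10)
  ph <- render_phantom(spec)
  expect_equal(sort(unique(as.integer(ph$truth_regions))), c(0L, 1L, 2L))
  # two closed contours in the truth edge map
  expect_equal(max(gaborEdge:::label_components(ph$truth_edge)), 2L)
})

test_that("truth edges sit exactly where a 4-neighbour has a smaller region label", {
  ph <- render_phantom(phantom_paperlike())
  reg <- ph$truth_regions
  h <- nrow(reg); w <- ncol(reg)
  pad <- matrix(NA_integer_, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- reg
  has_lower <- matrix(FALSE, h, w)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[(2 + d[1]):(h + 1 + d[1]), (2 + d[2]):(w + 1 + d[2])]
    has_lower <- has_lower | (!is.na(nb) & nb < reg)
  }
  expect_identical(ph$truth_edge, has_lower + 0L)
  # every edge pixel borders a different region; rendering is deterministic
  expect_identical(render_phantom(phantom_paperlike()), ph)
})

test_that("noise calibration hits the target PSNR and clips to range", {
  ph <- render_phantom(phantom_paperlike())
  noisy <- add_gaussian_noise(ph$image, 35.01, peak = 255, seed = 1)
  expect_lt(abs(attr(noisy, "achieved_psnr") - 35.01), 0.2)
  expect_true(all(noisy >= 0 & noisy <= 255))
  # sigma formula: 255 / 10^(35.01/20) ~ 4.53
  expect_equal(255 / 10^(35.01 / 20), 4.525, tolerance = 1e-3)
  same <- add_gaussian_noise(ph$image, 23, seed = 5)
  again <- add_gaussian_noise(ph$image, 23, seed = 5)
  expect_identical(same, again)
  clean <- add_gaussian_noise(ph$image, Inf, seed = 1)
  expect_equal(clean, ph$image, ignore_attr = TRUE)
  expect_error(add_gaussian_noise(ph$image, 30, peak = -1), "peak")
})

test_that("median filter matches the sort-based oracle and rejects outliers", {
  flat <- matrix(5, 7, 7)
  expect_equal(median_filter(flat, 3), flat)
  imp <- flat; imp[4, 4] <- 500
  expect_equal(median_filter(imp, 3), flat)
  set.seed(19)
  img <- matrix(runif(81, 0, 255), 9, 9)
  expect_equal(median_filter(img, 3), median_oracle(img, 3), tolerance = 1e-12)
  expect_equal(median_filter(img, 5), median_oracle(img, 5), tolerance = 1e-12)
  expect_error(median_filter(img, 4), "odd")
})
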