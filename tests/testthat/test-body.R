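test_that("weighted regression recovers exact linear data", {
  x <- seq(0, 5, by = 0.5)
  fit <- weighted_linear_slope(x, 3 + 2 * x, runif(length(x), 0.1, 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-12)
  expect_equal(weighted_linear_slope(x, rep(7, length(x)))$slope, 0)
})

test_that("weighted regression matches the normal-equations oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n); w <- runif(n, 0.01, 2)
    fit <- weighted_linear_slope(x, y, w)
    want <- wls_oracle(x, y, w)
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
  }
})

test_that("weighted regression degeneracies are errors", {
  expect_error(weighted_linear_slope(1:5, 1:5, rep(0, 5)), "degenerate")
  expect_error(weighted_linear_slope(rep(2, 5), rnorm(5), rep(1, 5)),
               "degenerate")
  # only one point with positive weight
  expect_error(weighted_linear_slope(1:5, 1:5, c(1, 0, 0, 0, 0)),
               "degenerate")
})

test_that("weighted regression equivariances hold", {
  set.seed(32)
  x <- rnorm(20); y <- rnorm(20); w <- runif(20, 0.1, 1)
  f0 <- weighted_linear_slope(x, y, w)
  expect_equal(weighted_linear_slope(3 * x, y, w)$slope, f0$slope / 3,
               tolerance = 1e-9)
  expect_equal(weighted_linear_slope(x, y + 11, w)$slope, f0$slope,
               tolerance = 1e-9)
  f_dup <- weighted_linear_slope(c(x, x), c(y, y), c(w, w))
  expect_equal(f_dup$slope, f0$slope, tolerance = 1e-9)
  expect_equal(f_dup$intercept, f0$intercept, tolerance = 1e-9)
})

test_that("weight rate of change converts per-minute samples to g/day", {
  per <- make_period(2)
  t <- as.numeric(per$start) + seq(30, 2 * 86400 - 30, by = 60)
  # uniform loss of 0.001 g per minute = 1.44 g/day
  g <- 40 - 0.001 * (t - as.numeric(per$start)) / 60
  ch <- channel("weight", data.frame(time = t, grams = g,
                                     weight_w = rep(1, length(t))))
  expect_equal(weight_rate_of_change(ch, per), -1.44, tolerance = 1e-9)

  ch2 <- channel("weight", data.frame(time = t, grams = rep(30, length(t)),
                                      weight_w = rep(0.5, length(t))))
  expect_equal(weight_rate_of_change(ch2, per), 0)

  # all-zero confidence weights degrade to a missing value
  ch3 <- channel("weight", data.frame(time = t[1:10], grams = g[1:10],
                                      weight_w = rep(0, 10)))
  expect_true(is.na(weight_rate_of_change(ch3, per)))
})

test_that("slope recovery is unbiased under confidence-weighted noise", {
  per <- make_period(2)
  t <- as.numeric(per$start) + seq(30, 2 * 86400 - 30, by = 300)
  days <- (t - as.numeric(per$start)) / 86400
  set.seed(33)
  est <- replicate(100, {
    w <- runif(length(t), 0.1, 1)
    g <- 30 - 0.5 * days + rnorm(length(t), 0, 0.5 / sqrt(w))
    ch <- channel("weight", data.frame(time = t, grams = pmax(g, 1),
                                       weight_w = w))
    weight_rate_of_change(ch, per)
  })
  expect_lt(abs(mean(est) - (-0.5)), 0.05 * 0.5)
})

test_that("sobel roughness matches a per-pixel convolution oracle", {
  flat <- matrix(137, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(sobel_roughness(flat, mask), 0)

  # vertical step edge 0|255
  step <- matrix(0, 8, 8); step[, 5:8] <- 255
  expect_equal(sobel_roughness(step, matrix(TRUE, 8, 8)),
               sobel_oracle(step, matrix(TRUE, 8, 8)), tolerance = 1e-12)

  set.seed(34)
  for (i in 1:5) {
    img <- matrix(runif(16 * 16, 0, 255), 16, 16)
    mask <- matrix(runif(16 * 16) > 0.3, 16, 16)
    mask[2, 2] <- TRUE  # guarantee an interior pixel
    expect_equal(sobel_roughness(img, mask), sobel_oracle(img, mask),
                 tolerance = 1e-12)
  }
})

test_that("sobel roughness shifts and scales with intensity as a gradient", {
  set.seed(35)
  img <- matrix(runif(100, 0, 200), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  r <- sobel_roughness(img, mask)
  expect_equal(sobel_roughness(img + 40, mask), r, tolerance = 1e-9)
  expect_equal(sobel_roughness(img * 2.5, mask), 2.5 * r, tolerance = 1e-9)
})

test_that("border-only masks are rejected", {
  img <- matrix(runif(64), 8, 8)
  border <- matrix(TRUE, 8, 8); border[2:7, 2:7] <- FALSE
  expect_error(sobel_roughness(img, border), "interior")
  expect_error(sobel_roughness(img, matrix(TRUE, 8, 7)), "shapes")
})

test_that("PNG image/mask pairs feed the roughness operator", {
  set.seed(37)
  img <- matrix(runif(144), 12, 12)
  mask <- matrix(FALSE, 12, 12); mask[4:9, 4:9] <- TRUE
  ip <- withr::local_tempfile(fileext = ".png")
  mp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, ip)
  png::writePNG(mask * 1, mp)
  mi <- read_masked_image(ip, mp)
  expect_equal(dim(mi$img), c(12, 12))
  expect_equal(mi$mask, mask)
  # writePNG quantises to 8 bits; compare against the oracle on the
  # quantised image
  expect_equal(sobel_roughness(mi$img, mi$mask),
               sobel_oracle(mi$img, mi$mask), tolerance = 1e-12)
})

test_that("coat metric is the median roughness with a sample floor", {
  per <- make_period(2)
  t <- as.numeric(per$start) + seq(60, 2 * 86400, by = 60)
  ch <- channel("coat", data.frame(time = t,
                                   roughness = rep(4.2, length(t))))
  expect_equal(coat_metric(ch, per), 4.2)

  set.seed(36)
  vals <- rgamma(length(t), 9, 0.75)
  ch2 <- channel("coat", data.frame(time = t, roughness = vals))
  kept <- vals[t < as.numeric(per$end)]  # 2879 in-period samples (odd)
  expect_equal(coat_metric(ch2, per), sort(kept)[(length(kept) + 1) / 2])

  ch3 <- channel("coat", data.frame(time = t[1:50], roughness = vals[1:50]))
  r <- coat_metric(ch3, per, min_samples = 100)
  expect_true(is.na(r))
  expect_match(missing_reason(r), "coat samples")
})
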