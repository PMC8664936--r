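test_that("curve files read back identically in both dialects", {
  plain <- tempfile(fileext = ".txt")
  writeLines(c("cal_bp c14 sigma", "100 110 5", "200 190 5", "300 310 5"),
             plain)
  cv <- load_calcurve(plain, "plain")
  expect_s3_class(cv, "cal_curve")
  expect_equal(nrow(cv), 3L)
  expect_equal(cv$c14_age, c(110, 190, 310))

  intcal <- tempfile(fileext = ".14c")
  writeLines(c("# synthetic toy curve", "# CAL BP, 14C age, Error, extra",
               "100,110,5,9", "200,190,5,9", "300,310,5,9"), intcal)
  cv2 <- load_calcurve(intcal, "intcal")
  expect_equal(as.data.frame(cv2), as.data.frame(cv))

  one_row <- tempfile()
  writeLines(c("a b c", "100 110 5"), one_row)
  expect_error(load_calcurve(one_row, "plain"), "2 usable rows")
})

test_that("curve interpolation is linear in mean and sigma", {
  cv <- cal_curve(c(100, 200, 300), c(110, 190, 310), c(5, 7, 9))
  expect_equal(curve_at(cv, 150)$mu, 150)          # midpoint of 110, 190
  expect_equal(curve_at(cv, 200)$mu, 190)          # stored grid value
  expect_equal(curve_at(cv, 200)$sd, 7)
  expect_equal(curve_at(cv, 250)$mu, 250)          # (190 + 310) / 2
  expect_equal(curve_at(cv, 250)$sd, 8)
  expect_error(curve_at(cv, 99), "span")
})

test_that("calibration against a near-identity curve is Gaussian", {
  cv <- flat_curve(sigma = 1e-6)
  d <- calibrate(5000, 20, cv, grid = c(4800, 5200))
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  expect_equal(d$cal_bp[which.max(d$prob)], 5000)
  ref <- dnorm(d$cal_bp, 5000, 20)
  expect_equal(d$prob, ref / sum(ref), tolerance = 1e-6)

  d_res <- calibrate(5000, 20, cv, grid = c(4800, 5200),
                     res = reservoir_correction(100, 0))
  expect_equal(d_res$cal_bp[which.max(d_res$prob)], 4900)
})

test_that("calibration on a wiggly toy curve matches the direct formula", {
  cv <- cal_curve(c(100, 150, 200, 250, 300),
                  c(105, 160, 150, 260, 310), c(8, 10, 12, 9, 7))
  d <- calibrate(150, 10, cv, grid = c(100, 300))
  tt <- d$cal_bp
  ca <- curve_at(cv, tt)
  raw <- dnorm(150, ca$mu, sqrt(10^2 + ca$sd^2))
  expect_equal(d$prob, raw / sum(raw), tolerance = 1e-12)
  # one grid year checked fully by hand: t = 200, mu = 150, sd^2 = 100+144
  i <- which(tt == 200)
  expect_equal(raw[i], exp(-0^2 / (2 * 244)) / sqrt(2 * pi * 244))
})

test_that("dates incompatible with the window come back flagged empty", {
  cv <- flat_curve(sigma = 1e-6)
  d <- calibrate(9000, 5, cv, grid = c(3000, 7000))
  expect_true(attr(d, "empty"))
  expect_true(all(d$prob == 0))
})

test_that("zero reservoir correction is the identity", {
  cv <- make_calcurve(span = c(500, 9500), wiggle_amplitude = 30, sigma = 12)
  d0 <- calibrate(4500, 30, cv, grid = c(3500, 5500))
  d1 <- calibrate(4500, 30, cv, grid = c(3500, 5500),
                  res = reservoir_correction(0, 0))
  expect_identical(d0$prob, d1$prob)
})

test_that("sample_cra has the right mean, degenerate limit and determinism", {
  cv <- flat_curve(sigma = 1e-9)
  expect_equal(sample_cra(4000, 1e-9, cv, seed = 1), 4000)
  cv2 <- make_calcurve(span = c(500, 9500), wiggle_amplitude = 25, sigma = 10)
  set.seed(2)
  draws <- sample_cra(rep(4000, 10000), 20, cv2)
  mu <- curve_at(cv2, 4000)$mu
  se <- sqrt(20^2 + 10^2) / sqrt(10000)
  expect_lt(abs(mean(draws) - mu), 3 * se + 0.5)   # 0.5 for integer rounding
  expect_identical(sample_cra(4000, 20, cv2, seed = 99),
                   sample_cra(4000, 20, cv2, seed = 99))
})

test_that("calibrate then sample_cra round trip recovers a sharp date", {
  cv <- flat_curve(sigma = 1e-6)
  set.seed(3)
  for (truth in c(3500, 5000, 6400)) {
    cra <- sample_cra(truth, 1, cv)
    d <- calibrate(cra, 1, cv, grid = c(3000, 7000))
    expect_lte(abs(d$cal_bp[which.max(d$prob)] - truth), 2)
  }
})

test_that("density HPD is greedy-by-mass and matches the exhaustive oracle", {
  # symmetric unimodal: single interval symmetric about the mode
  tt <- 100:120
  p <- dnorm(tt, 110, 3); p <- p / sum(p)
  d <- structure(data.frame(cal_bp = tt, prob = p),
                 class = c("cal_density", "data.frame"))
  h <- hpd_interval(d, 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$lower - 100, 120 - h$upper)

  # discrete golf: {p(1)=.5, p(2)=.3, p(3)=.2} at level .8 -> {1, 2}
  d2 <- structure(data.frame(cal_bp = 1:3, prob = c(.5, .3, .2)),
                  class = c("cal_density", "data.frame"))
  h2 <- hpd_interval(d2, 0.8)
  expect_equal(c(h2$lower, h2$upper), c(1, 2))

  # bimodal (unequal modes, so masses are tie-free): two disjoint
  # intervals; minimal point count vs brute force
  tt <- 1:24
  p <- dnorm(tt, 6, 1.5) + 0.7 * dnorm(tt, 18, 1.8); p <- p / sum(p)
  d3 <- structure(data.frame(cal_bp = tt, prob = p),
                  class = c("cal_density", "data.frame"))
  h3 <- hpd_interval(d3, 0.5)
  expect_equal(nrow(h3), 2L)
  expect_gte(attr(h3, "mass"), 0.5)
  n_points <- sum(h3$upper - h3$lower + 1)
  # oracle: smallest number of grid points (any subset; contiguity never
  # helps) reaching the level
  ps <- sort(p, decreasing = TRUE)
  oracle_points <- which(cumsum(ps) >= 0.5 - 1e-12)[1]
  expect_equal(n_points, oracle_points)
})

test_that("sample HPD is the shortest interval and attains the level", {
  set.seed(4)
  x <- rnorm(20000)
  h <- hpd_interval(x, 0.9)
  expect_gte(attr(h, "mass"), 0.9)
  expect_equal(h$lower, -1.645, tolerance = 0.1)
  expect_equal(h$upper, 1.645, tolerance = 0.1)
  expect_error(hpd_interval(numeric(0)), "empty")
})
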