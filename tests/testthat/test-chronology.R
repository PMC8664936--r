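test_that("exactly dated tiepoints give deterministic linear interpolation", {
  cv <- flat_curve(sigma = 1e-9)
  core <- proxy_core(depths = seq(0, 100, 5), proxy = rep(1, 21),
                     tiepoints = data.frame(depth = c(0, 100),
                                            cra = c(3000, 4000),
                                            error = 1e-9,
                                            curve_kind = "atmospheric"))
  ens <- fit_age_depth(core, cv, n_draws = 50, seed = 60)
  i50 <- which(core$depths == 50)
  expect_true(all(ens$ages[, i50] == 3500))
  # monotone in depth in every retained draw
  expect_true(all(apply(ens$ages, 1, function(v) all(diff(v) >= 0))))
})

test_that("stratigraphic order is enforced on noisy tiepoints", {
  cv <- flat_curve(sigma = 5)
  # overlapping densities: many raw draws violate order, none retained
  core <- proxy_core(depths = 0:10, proxy = rep(1, 11),
                     tiepoints = data.frame(depth = c(0, 5, 10),
                                            cra = c(4000, 4010, 4020),
                                            error = 40,
                                            curve_kind = "atmospheric"))
  ens <- fit_age_depth(core, cv, n_draws = 200, seed = 61)
  expect_true(all(apply(ens$tp_ages, 1, function(v) all(diff(v) >= 0))))
  expect_equal(nrow(ens$ages), 200L)
})

test_that("a known linear age-depth relation is recovered", {
  cv <- flat_curve(sigma = 5)
  sim <- simulate_core(length_cm = 100, rate_yr_per_cm = 10,
                       n_tiepoints = 5, tiepoint_error = 20,
                       event_true_date = 3500, curve = cv,
                       surface_age = 3000, seed = 62)
  ens <- fit_age_depth(sim$core, cv, n_draws = 500, seed = 63)
  for (d in c(10, 30, 50, 90)) {
    i <- which(sim$core$depths == d)
    truth <- 3000 + 10 * d
    expect_lt(abs(median(ens$ages[, i]) - truth), 50)
  }
  # event at depth 30: 300 yr offset from the surface age
  ep <- event_dates(ens, 30, "f1")
  expect_lt(abs(median(ep$samples) - 3300), 50)
})

test_that("events at tiepoint depths inherit the tiepoint's sampled ages", {
  cv <- flat_curve(sigma = 5)
  core <- proxy_core(depths = 0:20, proxy = rep(1, 21),
                     tiepoints = data.frame(depth = c(0, 10, 20),
                                            cra = c(3500, 4500, 5500),
                                            error = 25,
                                            curve_kind = "atmospheric"))
  ens <- fit_age_depth(core, cv, n_draws = 100, seed = 64)
  ep <- event_dates(ens, 10, "tie")
  expect_equal(ep$samples, unname(ens$tp_ages[, 2]))
  ep2 <- event_dates(ens, 10, "tie_again")
  expect_identical(ep$samples, ep2$samples)
  expect_error(event_dates(ens, 25, "off"), "span")
})

test_that("marine tiepoints are calibrated with their reservoir offset", {
  cv <- flat_curve(sigma = 1e-6)
  # marine CRA = true age + 400 (reservoir); Delta-R = 400 corrects it
  core <- proxy_core(depths = c(0, 10), proxy = c(1, 1),
                     tiepoints = data.frame(depth = c(0, 10),
                                            cra = c(3000 + 400, 4000 + 400),
                                            error = 1,
                                            curve_kind = "marine",
                                            delta_r = 400,
                                            delta_r_sigma = 0))
  ens <- fit_age_depth(core, cv, marine_curve = cv, n_draws = 50, seed = 65)
  expect_lt(abs(median(ens$tp_ages[, 1]) - 3000), 3)
  expect_lt(abs(median(ens$tp_ages[, 2]) - 4000), 3)
})

test_that("temporal differences follow the BP-scale convention", {
  A <- event_posterior("A", rep(4500, 10))
  B <- event_posterior("B", rep(4700, 10))
  res <- temporal_difference(A, B, n = 1000, seed = 70)
  expect_true(all(res$diff_samples == -200))
  expect_equal(res$p_A_after_B, 1)   # smaller cal BP = more recent = after

  set.seed(71)
  same <- rnorm(5000, 4600, 100)
  res2 <- temporal_difference(event_posterior("A", same),
                              event_posterior("B", same), n = 5000, seed = 72)
  expect_lt(abs(res2$p_A_after_B - 0.5), 0.02)

  # uniform on {1,2,3}: exhaustive enumeration gives P(diff < 0) = 3/9
  U <- event_posterior("U", 1:3); V <- event_posterior("V", 1:3)
  res3 <- temporal_difference(U, V, n = 20000, seed = 73)
  pairs <- expand.grid(a = 1:3, b = 1:3)
  p_oracle <- mean(pairs$a - pairs$b < 0)
  expect_equal(res3$p_A_after_B, p_oracle, tolerance = 0.02)
  expect_equal(res3$p_A_after_B + res3$p_B_after_A + res3$p_tie, 1)

  # antisymmetry in distribution
  res_ab <- temporal_difference(U, V, n = 20000, seed = 74)
  res_ba <- temporal_difference(V, U, n = 20000, seed = 75)
  expect_equal(mean(res_ab$diff_samples), -mean(res_ba$diff_samples),
               tolerance = 0.05)
})
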