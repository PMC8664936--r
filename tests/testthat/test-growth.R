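test_that("growth PMF matches its closed forms and normalizes", {
  # r1 = r2 = 0: uniform over a - b + 1 years
  p <- growth_pmf(growth_params(0, 0, 5000))
  expect_equal(unclass(p), rep(1 / 4001, 4001), ignore_attr = TRUE)

  # hand-derived toy: a=5, b=0, c=3, r1=1, r2=0 -> weights (1,2,4,4,4,4)
  p2 <- growth_pmf(growth_params(1.0, 0, 3, a = 5, b = 0))
  expect_equal(unclass(p2), c(1, 2, 4, 4, 4, 4) / 19, ignore_attr = TRUE)
  expect_equal(p2[1], 1 / 19, ignore_attr = TRUE)

  # random valid parameter sets: proper PMF, monotone on each side of c
  set.seed(20)
  for (i in 1:50) {
    r1 <- runif(1, -0.004, 0.004); r2 <- runif(1, -0.004, 0.004)
    cc <- runif(1, 3000, 7000)
    p <- growth_pmf(growth_params(r1, r2, cc))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    tt <- attr(p, "cal_bp")
    pre <- tt > ceiling(cc); post <- tt <= floor(cc)
    if (r1 > 0) expect_true(all(diff(p[pre]) > 0))    # grows toward present
    if (r2 > 0) expect_true(all(diff(p[post]) > 0))
  }
  expect_error(growth_params(-1.5, 0, 5000), "1 \\+ r")
})

test_that("marginal log-likelihood has its closed forms and factorizes", {
  cv <- flat_curve(sigma = 1e-6)
  par0 <- growth_params(0, 0, 5000)
  # uniform PMF, identity curve: log of the mean Gaussian density
  ll <- marginal_loglik(4500, 30, cv, par0)
  ref <- log(mean(dnorm(4500, 7000:3000, sqrt(30^2 + 1e-12))))
  expect_equal(ll, ref, tolerance = 1e-9)

  # extreme rates concentrate the PMF at the young boundary
  par_ext <- growth_params(5, 5, 5000)
  ll_ext <- marginal_loglik(3000, 30, cv, par_ext)
  expect_equal(ll_ext, dnorm(3000, 3000, sqrt(30^2 + 1e-12), log = TRUE),
               tolerance = 1e-3)

  # independence: joint equals the sum of single-date likelihoods
  par <- growth_params(0.002, -0.001, 5200)
  cras <- c(3800, 4700, 5600); errs <- c(20, 35, 50)
  joint <- marginal_loglik(cras, errs, cv, par)
  singles <- sum(vapply(1:3, function(j)
    marginal_loglik(cras[j], errs[j], cv, par), 0))
  expect_equal(joint, singles, tolerance = 1e-9)
})

test_that("split-chain Gelman-Rubin behaves at its limits", {
  expect_equal(gelman_rubin(matrix(5, 100, 3)), 1)
  set.seed(21)
  m <- matrix(rnorm(20000), 10000, 2)
  expect_lt(gelman_rubin(m), 1.01)
  sep <- cbind(rnorm(1000), rnorm(1000, 100))
  expect_gt(gelman_rubin(sep), 1.1)
  expect_error(gelman_rubin(matrix(1:6, 3, 2)), "length")
})

test_that("Rhat agrees loosely with the coda diagnostic on mixed chains", {
  skip_if_not_installed("coda")
  set.seed(22)
  chains <- matrix(rnorm(6000), 2000, 3)
  ours <- gelman_rubin(chains)
  theirs <- coda::gelman.diag(coda::mcmc.list(
    lapply(1:3, function(k) coda::mcmc(chains[, k]))))$psrf[1]
  expect_equal(ours, theirs, tolerance = 0.02)
})

test_that("effective sample size tracks independence and AR(1) theory", {
  set.seed(23)
  N <- 8000
  x <- rnorm(N)
  e <- effective_sample_size(x)
  expect_gt(e, 0.75 * N); expect_lt(e, 1.25 * N)

  phi <- 0.9
  y <- as.numeric(stats::arima.sim(list(ar = phi), N))
  e_ar <- effective_sample_size(y)
  theory <- N * (1 - phi) / (1 + phi)
  expect_gt(e_ar, theory / 1.5); expect_lt(e_ar, theory * 1.5)

  expect_equal(effective_sample_size(rep(2, 100)), 0)
})

test_that("ESS agrees in order of magnitude with coda", {
  skip_if_not_installed("coda")
  set.seed(24)
  y <- as.numeric(stats::arima.sim(list(ar = 0.8), 5000))
  ours <- effective_sample_size(y)
  theirs <- as.numeric(coda::effectiveSize(y))
  expect_lt(abs(log(ours / theirs)), log(1.6))
})

test_that("MCMC draws are bit-identical under a fixed seed", {
  cv <- flat_curve(sigma = 5)
  rec <- toy_records(c(4200, 4800, 5400, 6000), error = 30)
  # convergence warnings are expected at these deliberately tiny settings
  f1 <- suppressWarnings(
    fit_growth(rec, cv, chains = 2, iterations = 600, burnin = 100,
               thin = 2, seed = 31))
  f2 <- suppressWarnings(
    fit_growth(rec, cv, chains = 2, iterations = 600, burnin = 100,
               thin = 2, seed = 31))
  expect_identical(f1$draws, f2$draws)
  # retained draw count: chains x (iterations - burnin) / thin
  expect_equal(nrow(f1$draws), 2 * (600 - 100) / 2)
  expect_true(all(f1$draws$c >= 3000 & f1$draws$c <= 7000))
})

test_that("a single date returns prior-dominated posteriors", {
  cv <- flat_curve(sigma = 5)
  rec <- toy_records(5000, error = 40)
  f <- suppressWarnings(
    fit_growth(rec, cv, chains = 1, iterations = 12000, burnin = 2000,
               thin = 2, seed = 32))
  # truncated-Normal(5000, 1000) on [3000, 7000]: sd from the closed form
  al <- -2; be <- 2; Z <- pnorm(be) - pnorm(al)
  sd_prior <- 1000 * sqrt(1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                            ((dnorm(al) - dnorm(be)) / Z)^2)
  expect_lt(abs(sd(f$draws$c) - sd_prior) / sd_prior, 0.2)
})

test_that("the sampler recovers generating parameters from synthetic data", {
  cv <- flat_curve(sigma = 1)
  truth <- growth_params(0.002, -0.0015, 5000)
  sim <- simulate_dataset(sim_config(growth = truth, n_dates = 400,
                                     error_range = c(20, 20), seed = 33), cv)
  fit <- fit_growth(sim$records, cv, chains = 2, iterations = 8000,
                    burnin = 2000, thin = 3, seed = 34)
  s <- summary(fit, level = 0.95)
  for (p in c("r1", "r2", "c")) {
    row <- s[s$param == p, ]
    expect_gte(truth[[p]], row$hpd_lower)
    expect_lte(truth[[p]], row$hpd_upper)
  }
  expect_true(all(fit$rhat < 1.05))
})

test_that("latent and marginal samplers agree on a small window", {
  cv <- flat_curve(sigma = 2)
  rec <- toy_records(c(4995, 5005), error = 10)
  win <- c(5010, 4990)
  fl <- fit_growth(rec, cv, window = win, chains = 1, iterations = 40000,
                   burnin = 5000, thin = 2, seed = 35, method = "latent")
  fm <- fit_growth(rec, cv, window = win, chains = 1, iterations = 40000,
                   burnin = 5000, thin = 2, seed = 36, method = "marginal")
  # c posteriors close in distribution (both near the prior restricted to
  # the window, modulated by two dates)
  qs <- seq(0.1, 0.9, 0.2)
  expect_equal(quantile(fl$draws$c, qs), quantile(fm$draws$c, qs),
               tolerance = 0.05)
})

test_that("predictive envelopes collapse at n_sims = 1 and track the PMF", {
  cv <- flat_curve(sigma = 1)
  draws <- data.frame(r1 = 0.002, r2 = -0.0015, c = 5000)
  e1 <- predictive_spd(draws, n_dates = 50, errors = 20, curve = cv,
                       n_sims = 1, seed = 41)
  expect_equal(e1$lo, e1$hi)

  env <- predictive_spd(draws, n_dates = 4000, errors = 20, curve = cv,
                        n_sims = 20, seed = 42)
  pmf <- growth_pmf(growth_params(0.002, -0.0015, 5000))
  expect_gt(cor(env$med, as.numeric(pmf)), 0.95)
})
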