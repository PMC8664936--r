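#' Parameters of the truncated double-exponential growth model
#'
#' The model gives the probability of sampling a 14C date from calendar
#' year t inside a window bounded by \code{a} (old) and \code{b} (young):
#' per-year weights follow a cumulative product of (1 + r) factors starting
#' at \code{t = a}, with the annual rate switching from \code{r1} to
#' \code{r2} once \code{t <= c}. Weights are normalized to a proper PMF.
#' With \code{r1 = r2 = r} this reduces to the single-exponential form
#' (1 + r)^i / sum_i (1 + r)^i.
#'
#' @param r1 annual growth rate before the change point (t > c).
#' @param r2 annual growth rate from the change point on (t <= c).
#' @param c change point, cal BP; must satisfy \code{b <= c <= a}.
#' @param a,b old and young window boundaries, cal BP (defaults 7000, 3000).
#' @return object of class \code{growth_params}.
#' @export
growth_params <- function(r1, r2, c, a = 7000, b = 3000) {
  if (a <= b) stop("a must be > b (a is the older boundary)")
  if (c < b || c > a) stop("change point c must lie in [b, a]")
  if (1 + r1 <= 0 || 1 + r2 <= 0) stop("1 + r must be > 0")
  structure(list(r1 = r1, r2 = r2, c = c, a = a, b = b),
            class = "growth_params")
}

#' Priors for the growth model
#'
#' Defaults: r1, r2 ~ Normal(0, 0.0004), covering growth-rate magnitudes
#' typically inferred from date-frequency data; c ~ TruncatedNormal(5000,
#' 1000) on [3000, 7000], weakly informative with slightly reduced mass at
#' the window boundaries.
#'
#' @param r_mean,r_sd Normal prior on both rates.
#' @param c_mean,c_sd,c_bounds truncated-Normal prior on the change point.
#' @return object of class \code{prior_spec}.
#' @export
prior_spec <- function(r_mean = 0, r_sd = 0.0004,
                       c_mean = 5000, c_sd = 1000, c_bounds = c(3000, 7000)) {
  if (r_sd <= 0 || c_sd <= 0) stop("prior sds must be > 0")
  if (c_bounds[1] >= c_bounds[2]) stop("c_bounds must be ordered")
  structure(list(r_mean = r_mean, r_sd = r_sd, c_mean = c_mean, c_sd = c_sd,
                 c_bounds = c_bounds), class = "prior_spec")
}

# truncated normal helpers
rtrunc_norm <- function(n, mu, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mu, sd),
                            stats::pnorm(hi, mu, sd)), mu, sd)
}
dtrunc_norm_log <- function(x, mu, sd, lo, hi) {
  ifelse(x < lo | x > hi, -Inf,
         stats::dnorm(x, mu, sd, log = TRUE) -
           log(stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log PMF over t = a, a-1, ..., b; the change point is floored to the year
# grid. The rate governing the step from year t to t-1 is r(t): r1 while
# t > cfloor, r2 once t <= cfloor, so growth switches in the step leaving c.
log_growth_pmf <- function(r1, r2, cfloor, a, b) {
  ti <- a:(b + 1)
  rate <- ifelse(ti > cfloor, r1, r2)
  logw <- c(0, cumsum(log1p(rate)))
  logw - log_sum_exp(logw)
}

#' Per-year sampling probabilities of the growth model
#'
#' @param params a \code{\link{growth_params}}.
#' @return numeric vector of probabilities over t = a, a-1, ..., b
#'   (old to young), summing to one, with attribute \code{cal_bp}.
#' @export
growth_pmf <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  p <- exp(log_growth_pmf(params$r1, params$r2, floor(params$c),
                          params$a, params$b))
  attr(p, "cal_bp") <- params$a:params$b
  p
}

# log-likelihood matrix: rows = dates, cols = grid t = a..b (descending)
loglik_matrix <- function(cra, error, curve, a, b) {
  tt <- a:b
  ca <- curve_at(curve, tt)
  n <- length(cra)
  out <- matrix(0, n, length(tt))
  for (j in seq_len(n))
    out[j, ] <- stats::dnorm(cra[j], mean = ca$mu,
                             sd = sqrt(error[j]^2 + ca$sd^2), log = TRUE)
  out
}

#' Marginal log-likelihood of dates under the growth model
#'
#' Integrates the latent calendar age over the window grid:
#' log sum_t p(t) * Normal(cra; mu(t), sqrt(error^2 + sd(t)^2)), summed
#' over the supplied dates (independence). Evaluated with log-sum-exp so
#' the result is finite whenever any term is positive.
#'
#' @param cra,error vectors of CRAs and lab errors.
#' @param curve a \code{\link{cal_curve}} spanning the model window.
#' @param params a \code{\link{growth_params}}.
#' @return scalar joint log-likelihood.
#' @export
marginal_loglik <- function(cra, error, curve, params) {
  stopifnot(inherits(params, "growth_params"))
  ll <- loglik_matrix(cra, error, curve, params$a, params$b)
  logp <- log_growth_pmf(params$r1, params$r2, floor(params$c),
                         params$a, params$b)
  sum(apply(ll, 1L, function(row) log_sum_exp(row + logp)))
}

# one MCMC chain of the latent-age Metropolis-within-Gibbs sampler
run_chain_latent <- function(llmat, priors, a, b, iterations, burnin, thin,
                             init, keep_latent = FALSE) {
  n <- nrow(llmat); G <- ncol(llmat)
  clo <- max(priors$c_bounds[1], b); chi <- min(priors$c_bounds[2], a)
  r1 <- init$r1; r2 <- init$r2; cc <- init$c; idx <- init$idx
  logp <- log_growth_pmf(r1, r2, floor(cc), a, b)
  jj <- seq_len(n)
  ll_cur <- llmat[cbind(jj, idx)]
  lp_r1 <- stats::dnorm(r1, priors$r_mean, priors$r_sd, log = TRUE)
  lp_r2 <- stats::dnorm(r2, priors$r_mean, priors$r_sd, log = TRUE)
  lp_c <- dtrunc_norm_log(cc, priors$c_mean, priors$c_sd, clo, chi)
  if (!is.finite(lp_c + sum(logp[idx]) + sum(ll_cur)))
    stop("non-finite posterior at initialization")

  sc <- c(theta = 40, r1 = 2e-4, r2 = 2e-4, c = 150)   # proposal scales
  acc <- c(theta = 0, r1 = 0, r2 = 0, c = 0)
  bat <- c(theta = 0, r1 = 0, r2 = 0, c = 0)
  batch_len <- 50L; nbatch <- 0L

  keep <- seq.int(burnin + thin, iterations, by = thin)
  out <- matrix(NA_real_, length(keep), 3L,
                dimnames = list(NULL, c("r1", "r2", "c")))
  lat <- if (keep_latent) matrix(NA_integer_, length(keep), n) else NULL
  ki <- 1L

  for (it in seq_len(iterations)) {
    ## latent calendar ages, vectorized random-walk MH
    pidx <- idx + as.integer(round(stats::rnorm(n, 0, sc["theta"])))
    ok <- pidx >= 1L & pidx <= G
    if (any(ok)) {
      lo <- which(ok)
      ll_new <- llmat[cbind(lo, pidx[lo])]
      la <- logp[pidx[lo]] + ll_new - logp[idx[lo]] - ll_cur[lo]
      take <- lo[log(stats::runif(length(lo))) < la]
      if (length(take)) {
        ll_cur[take] <- llmat[cbind(take, pidx[take])]
        idx[take] <- pidx[take]
        bat["theta"] <- bat["theta"] + length(take) / n
      }
    }
    acc["theta"] <- acc["theta"] + 1

    sum_logp_idx <- sum(logp[idx])

    ## r1
    p1 <- r1 + stats::rnorm(1, 0, sc["r1"])
    if (1 + p1 > 0) {
      logp_new <- log_growth_pmf(p1, r2, floor(cc), a, b)
      lp_new <- stats::dnorm(p1, priors$r_mean, priors$r_sd, log = TRUE)
      la <- sum(logp_new[idx]) + lp_new - sum_logp_idx - lp_r1
      if (log(stats::runif(1)) < la) {
        r1 <- p1; logp <- logp_new; lp_r1 <- lp_new
        sum_logp_idx <- sum(logp[idx]); bat["r1"] <- bat["r1"] + 1
      }
    }
    ## r2
    p2 <- r2 + stats::rnorm(1, 0, sc["r2"])
    if (1 + p2 > 0) {
      logp_new <- log_growth_pmf(r1, p2, floor(cc), a, b)
      lp_new <- stats::dnorm(p2, priors$r_mean, priors$r_sd, log = TRUE)
      la <- sum(logp_new[idx]) + lp_new - sum_logp_idx - lp_r2
      if (log(stats::runif(1)) < la) {
        r2 <- p2; logp <- logp_new; lp_r2 <- lp_new
        sum_logp_idx <- sum(logp[idx]); bat["r2"] <- bat["r2"] + 1
      }
    }
    ## c (continuous; floored on the grid inside the PMF)
    pc <- cc + stats::rnorm(1, 0, sc["c"])
    lp_new <- dtrunc_norm_log(pc, priors$c_mean, priors$c_sd, clo, chi)
    if (is.finite(lp_new)) {
      logp_new <- log_growth_pmf(r1, r2, floor(pc), a, b)
      la <- sum(logp_new[idx]) + lp_new - sum_logp_idx - lp_c
      if (log(stats::runif(1)) < la) {
        cc <- pc; logp <- logp_new; lp_c <- lp_new
        bat["c"] <- bat["c"] + 1
      }
    }

    ## adapt proposal scales during burn-in only
    if (it <= burnin && it %% batch_len == 0L) {
      nbatch <- nbatch + 1L
      gam <- min(0.5, 1 / sqrt(nbatch))
      rate <- bat / batch_len
      sc <- sc * exp(gam * (rate - 0.3))
      sc["theta"] <- max(sc["theta"], 1)
      bat[] <- 0
    }

    if (it > burnin && (it - burnin) %% thin == 0L) {
      out[ki, ] <- c(r1, r2, cc)
      if (keep_latent) lat[ki, ] <- idx
      ki <- ki + 1L
    }
  }
  list(draws = out, latent = lat, scales = sc)
}

# one chain of the grid-marginalized sampler (latent ages integrated out)
run_chain_marginal <- function(lik_sc, row_max, priors, a, b, iterations,
                               burnin, thin, init) {
  clo <- max(priors$c_bounds[1], b); chi <- min(priors$c_bounds[2], a)
  r1 <- init$r1; r2 <- init$r2; cc <- init$c
  loglik <- function(r1, r2, cc) {
    p <- exp(log_growth_pmf(r1, r2, floor(cc), a, b))
    sum(log(as.vector(lik_sc %*% p))) + sum(row_max)
  }
  ll_cur <- loglik(r1, r2, cc)
  lp_cur <- stats::dnorm(r1, priors$r_mean, priors$r_sd, log = TRUE) +
    stats::dnorm(r2, priors$r_mean, priors$r_sd, log = TRUE) +
    dtrunc_norm_log(cc, priors$c_mean, priors$c_sd, clo, chi)
  if (!is.finite(ll_cur + lp_cur)) stop("non-finite posterior at initialization")
  sc <- c(r1 = 2e-4, r2 = 2e-4, c = 150)
  bat <- c(r1 = 0, r2 = 0, c = 0); batch_len <- 50L; nbatch <- 0L
  keep <- seq.int(burnin + thin, iterations, by = thin)
  out <- matrix(NA_real_, length(keep), 3L,
                dimnames = list(NULL, c("r1", "r2", "c")))
  ki <- 1L
  for (it in seq_len(iterations)) {
    for (w in 1:3) {
      prop <- c(r1, r2, cc)
      prop[w] <- prop[w] + stats::rnorm(1, 0, sc[w])
      if (w < 3 && 1 + prop[w] <= 0) next
      lp_new <- stats::dnorm(prop[1], priors$r_mean, priors$r_sd, log = TRUE) +
        stats::dnorm(prop[2], priors$r_mean, priors$r_sd, log = TRUE) +
        dtrunc_norm_log(prop[3], priors$c_mean, priors$c_sd, clo, chi)
      if (!is.finite(lp_new)) next
      ll_new <- loglik(prop[1], prop[2], prop[3])
      if (log(stats::runif(1)) < ll_new + lp_new - ll_cur - lp_cur) {
        r1 <- prop[1]; r2 <- prop[2]; cc <- prop[3]
        ll_cur <- ll_new; lp_cur <- lp_new; bat[w] <- bat[w] + 1
      }
    }
    if (it <= burnin && it %% batch_len == 0L) {
      nbatch <- nbatch + 1L
      gam <- min(0.5, 1 / sqrt(nbatch))
      sc <- sc * exp(gam * (bat / batch_len - 0.3))
      bat[] <- 0
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      out[ki, ] <- c(r1, r2, cc); ki <- ki + 1L
    }
  }
  list(draws = out, scales = sc)
}

#' Fit the truncated double-exponential growth model by MCMC
#'
#' Metropolis-within-Gibbs sampling of (r1, r2, c) together with one latent
#' calendar age per date (\code{method = "latent"}, the default), or a
#' random-walk Metropolis sampler on the grid-marginalized likelihood
#' (\code{method = "marginal"}; useful as an exact cross-check on small
#' windows). Latent ages carry the growth PMF as prior and a Gaussian CRA
#' likelihood through the calibration curve. Proposal scales are adapted
#' toward 20--40\% acceptance during burn-in and frozen afterwards.
#'
#' Chain 1 starts at the canonical initialization (rates 0, c at the prior
#' mean, latent ages at each date's calibrated median); further chains
#' start from draws of the prior, giving overdispersed initializations for
#' convergence checking.
#'
#' @param records thinned \code{\link{c14_records}} (see
#'   \code{\link{thin_bins}}).
#' @param curve a \code{\link{cal_curve}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param window length-2 calendar window, cal BP; the model boundaries
#'   (a = old end, b = young end).
#' @param chains,iterations,burnin,thin MCMC settings (defaults 3 chains of
#'   100000 iterations, burn-in 10000, thinning 6).
#' @param seed optional integer seed.
#' @param method \code{"latent"} or \code{"marginal"}.
#' @param keep_latent retain latent calendar-age draws (latent method only).
#' @return object of class \code{growth_posterior}: list with \code{draws}
#'   (data frame chain/iteration/r1/r2/c), \code{rhat}, \code{ess},
#'   \code{settings}, \code{priors}, and optionally \code{latent}.
#'   A warning (not an error) is raised when any split-Rhat exceeds 1.01.
#' @export
fit_growth <- function(records, curve, priors = prior_spec(),
                       window = c(7000, 3000), chains = 3L,
                       iterations = 100000L, burnin = 10000L, thin = 6L,
                       seed = NULL, method = c("latent", "marginal"),
                       keep_latent = FALSE) {
  method <- match.arg(method)
  records <- c14_records(records)
  if (nrow(records) < 1L) stop("need at least one record")
  if (!is.null(seed)) set.seed(seed)
  a <- max(window); b <- min(window)
  llmat <- loglik_matrix(records$cra, records$error, curve, a, b)
  row_max <- apply(llmat, 1L, max)
  if (any(!is.finite(row_max)))
    stop("some records have zero marginal likelihood on the window")
  n <- nrow(llmat); G <- ncol(llmat)

  # canonical latent init: calibrated posterior median on the window
  med_idx <- vapply(seq_len(n), function(j) {
    w <- exp(llmat[j, ] - row_max[j]); w <- w / sum(w)
    which(cumsum(w) >= 0.5)[1L]
  }, 1L)

  clo <- max(priors$c_bounds[1], b); chi <- min(priors$c_bounds[2], a)
  res <- vector("list", chains)
  for (k in seq_len(chains)) {
    init <- if (k == 1L) {
      list(r1 = 0, r2 = 0, c = priors$c_mean, idx = med_idx)
    } else {
      list(r1 = stats::rnorm(1, priors$r_mean, priors$r_sd),
           r2 = stats::rnorm(1, priors$r_mean, priors$r_sd),
           c = rtrunc_norm(1, priors$c_mean, priors$c_sd, clo, chi),
           idx = med_idx)
    }
    init$c <- min(max(init$c, clo), chi)
    res[[k]] <- if (method == "latent") {
      run_chain_latent(llmat, priors, a, b, iterations, burnin, thin, init,
                       keep_latent)
    } else {
      lik_sc <- exp(llmat - row_max)
      run_chain_marginal(lik_sc, row_max, priors, a, b, iterations, burnin,
                         thin, init)
    }
  }

  per_chain <- lapply(res, `[[`, "draws")
  nkeep <- nrow(per_chain[[1L]])
  draws <- do.call(rbind, per_chain)
  draws <- data.frame(chain = rep(seq_len(chains), each = nkeep),
                      iteration = rep(seq_len(nkeep), chains),
                      draws)
  rhat <- ess <- c(r1 = NA_real_, r2 = NA_real_, c = NA_real_)
  for (p in c("r1", "r2", "c")) {
    mat <- sapply(per_chain, function(d) d[, p])
    if (chains >= 2L) rhat[p] <- gelman_rubin(mat)
    ess[p] <- effective_sample_size(mat)
  }
  if (chains >= 2L && any(rhat > 1.01, na.rm = TRUE))
    warning("possible non-convergence: split-Rhat > 1.01 for ",
            paste(names(rhat)[which(rhat > 1.01)], collapse = ", "))
  out <- list(draws = draws,
              latent = if (keep_latent && method == "latent")
                lapply(res, function(r) a - (r$latent - 1L)) else NULL,
              rhat = rhat, ess = ess,
              settings = list(chains = chains, iterations = iterations,
                              burnin = burnin, thin = thin, method = method,
                              window = c(a, b), n = n),
              priors = priors)
  class(out) <- "growth_posterior"
  out
}

#' Split-chain Gelman-Rubin diagnostic (potential scale reduction factor)
#'
#' Each chain is split in half before computing the classic PSRF, so
#' within-chain trends register as apparent non-convergence.
#'
#' @param chains a matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of length >= 10.
#' @return scalar Rhat. Zero within-chain variance gives 1 when the chains
#'   agree exactly, \code{Inf} otherwise.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L || nrow(chains) < 10L)
    stop("need >= 2 chains of length >= 10")
  half <- floor(nrow(chains) / 2L)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(nrow(chains) - half + 1L):nrow(chains), , drop = FALSE])
  n <- nrow(split); m <- ncol(split)
  mu <- colMeans(split)
  W <- mean(apply(split, 2L, stats::var))
  B <- n * stats::var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size via Geyer's initial positive sequence
#'
#' Combines chains in the usual split-free multi-chain form: lag
#' autocorrelations are estimated from within-chain autocovariances scaled
#' by the pooled variance, summed in pairs and truncated at the first
#' negative pair.
#'
#' @param chains matrix (iterations x chains), list of equal-length
#'   vectors, or a single numeric vector.
#' @return scalar ESS; 0 for a constant chain.
#' @export
effective_sample_size <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (n < 4L) stop("chains too short for ESS estimation")
  W <- mean(apply(chains, 2L, stats::var))
  B_over_n <- if (m > 1L) stats::var(colMeans(chains)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus == 0) return(0)
  lag_max <- min(n - 2L, 2000L)
  acov <- sapply(seq_len(m), function(k)
    stats::acf(chains[, k], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L])
  acov <- if (m > 1L) rowMeans(acov) else as.vector(acov)
  rho <- 1 - (W - acov[-1L]) / var_plus
  # Geyer: sum consecutive pairs, truncate at first negative pair
  npair <- floor(length(rho) / 2L)
  tau <- 1
  for (k in seq_len(npair)) {
    g <- rho[2L * k - 1L] + rho[2L * k]
    if (g < 0) break
    tau <- tau + 2 * g
  }
  max(m * n / tau, 0)
}

#' Prior or posterior predictive SPD envelope
#'
#' For each simulation a parameter draw is taken (a posterior draw, or a
#' fresh draw from the prior), \code{n_dates} calendar ages are sampled
#' from the implied growth PMF, back-projected to CRAs through the curve
#' with lab errors resampled from \code{errors}, calibrated, and summed.
#' The envelope is the pointwise 2.5\%/97.5\% quantile band.
#'
#' @param draws a \code{growth_posterior}, a data frame with columns r1,
#'   r2, c, or a \code{\link{prior_spec}} (prior predictive).
#' @param n_dates dates per simulated SPD.
#' @param errors pool of lab errors resampled with replacement.
#' @param curve a \code{\link{cal_curve}}.
#' @param window length-2 calendar window, cal BP.
#' @param n_sims number of simulated SPDs (default 500).
#' @param seed optional integer seed.
#' @return object of class \code{predictive_envelope}: data frame
#'   \code{(cal_bp, lo, med, hi)}.
#' @export
predictive_spd <- function(draws, n_dates, errors, curve,
                           window = c(7000, 3000), n_sims = 500,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- max(window); b <- min(window)
  tt <- a:b
  from_prior <- inherits(draws, "prior_spec")
  if (inherits(draws, "growth_posterior")) draws <- draws$draws
  sims <- matrix(NA_real_, n_sims, length(tt))
  for (s in seq_len(n_sims)) {
    if (from_prior) {
      pr <- draws
      r1 <- stats::rnorm(1, pr$r_mean, pr$r_sd)
      r2 <- stats::rnorm(1, pr$r_mean, pr$r_sd)
      cc <- rtrunc_norm(1, pr$c_mean, pr$c_sd,
                        max(pr$c_bounds[1], b), min(pr$c_bounds[2], a))
      while (1 + r1 <= 0) r1 <- stats::rnorm(1, pr$r_mean, pr$r_sd)
      while (1 + r2 <= 0) r2 <- stats::rnorm(1, pr$r_mean, pr$r_sd)
    } else {
      i <- sample.int(nrow(draws), 1L)
      r1 <- draws$r1[i]; r2 <- draws$r2[i]; cc <- draws$c[i]
    }
    p <- exp(log_growth_pmf(r1, r2, floor(cc), a, b))
    ages <- sample(tt, n_dates, replace = TRUE, prob = p)
    err <- sample(errors, n_dates, replace = TRUE)
    cra <- sample_cra(ages, err, curve)
    rec <- data.frame(lab_id = as.character(seq_len(n_dates)), cra = cra,
                      error = err, site_id = "s", lat = 0, lon = 0)
    cr <- calibrated_rows(c14_records(rec), curve, window)
    sims[s, ] <- colSums(cr$dens)
  }
  qs <- apply(sims, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  out <- data.frame(cal_bp = tt, lo = qs[1L, ], med = qs[2L, ], hi = qs[3L, ])
  class(out) <- c("predictive_envelope", "data.frame")
  out
}

#' @export
print.growth_posterior <- function(x, ...) {
  s <- x$settings
  cat("Truncated double-exponential growth model fit\n")
  cat("  window:", s$window[1], "-", s$window[2], "cal BP;", s$n, "dates\n")
  cat("  MCMC:", s$chains, "chains x", s$iterations, "iterations (burn-in",
      s$burnin, ", thin", s$thin, ",", s$method, "sampler)\n")
  qs <- t(apply(x$draws[, c("r1", "r2", "c")], 2L, stats::quantile,
                probs = c(0.05, 0.5, 0.95)))
  tab <- cbind(round(qs, 6), rhat = round(x$rhat, 4),
               ess = round(x$ess))
  print(tab)
  invisible(x)
}

#' @export
summary.growth_posterior <- function(object, level = 0.90, ...) {
  out <- lapply(c("r1", "r2", "c"), function(p) {
    v <- object$draws[[p]]
    h <- hpd_interval(v, level = level)
    data.frame(param = p, median = stats::median(v), mean = mean(v),
               hpd_lower = h$lower[1], hpd_upper = h$upper[1],
               rhat = object$rhat[[p]], ess = object$ess[[p]])
  })
  do.call(rbind, out)
}

#' Plot marginal posterior densities of a growth-model fit
#'
#' @param x a \code{growth_posterior}.
#' @param level HPD level to shade (default 0.90).
#' @param ... unused.
#' @export
plot.growth_posterior <- function(x, level = 0.90, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  for (p in c("r1", "r2", "c")) {
    v <- x$draws[[p]]
    d <- stats::density(v)
    h <- hpd_interval(v, level = level)
    graphics::plot(d, main = p, xlab = if (p == "c") "cal BP" else "rate / yr")
    sel <- d$x >= h$lower[1] & d$x <= h$upper[1]
    graphics::polygon(c(d$x[sel], rev(d$x[sel])),
                      c(d$y[sel], rep(0, sum(sel))),
                      col = "lightsteelblue", border = NA)
    graphics::lines(d)
  }
  invisible(x)
}
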