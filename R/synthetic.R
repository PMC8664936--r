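#' Configuration for a synthetic radiocarbon dataset
#'
#' Bundles the generating truth for \code{\link{simulate_dataset}}. The
#' defaults mirror a realistic regional inventory: a boom-and-bust
#' double-exponential density (growth 0.18\%/yr, decline -0.14\%/yr,
#' change point 5000 cal BP), lab errors uniform on 20-60 14C yr, sites in
#' tight clusters a few hundred metres across, and a millet mark at a
#' constant 6.6\% proportion.
#'
#' @param growth a \code{\link{growth_params}} truth.
#' @param n_dates number of dates.
#' @param error_range lab-error range, 14C yr.
#' @param n_sites,n_clusters number of sites and of spatial clusters the
#'   sites are grouped into.
#' @param cluster_spread_km within-cluster standard deviation of site
#'   placement, km.
#' @param millet_prop Bernoulli probability of the millet mark.
#' @param event_true_date true climatic-event date carried along for
#'   end-to-end checks, cal BP (inside the growth window).
#' @param seed optional integer seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(growth = growth_params(0.0018, -0.0014, 5000),
                       n_dates = 500L, error_range = c(20, 60),
                       n_sites = 100L, n_clusters = 35L,
                       cluster_spread_km = 0.3, millet_prop = 0.066,
                       event_true_date = 4600, seed = NULL) {
  stopifnot(inherits(growth, "growth_params"))
  if (n_dates < 1L) stop("n_dates must be >= 1")
  if (millet_prop < 0 || millet_prop > 1) stop("millet_prop must be in [0,1]")
  if (event_true_date < growth$b || event_true_date > growth$a)
    stop("event_true_date must lie inside the growth window")
  structure(list(growth = growth, n_dates = as.integer(n_dates),
                 error_range = error_range, n_sites = as.integer(n_sites),
                 n_clusters = as.integer(n_clusters),
                 cluster_spread_km = cluster_spread_km,
                 millet_prop = millet_prop,
                 event_true_date = event_true_date, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic calibration curve
#'
#' Curve mean = identity + sinusoidal wiggles + optional random-walk
#' roughness; constant curve standard deviation. With
#' \code{wiggle_amplitude = 0} and \code{walk_sd = 0} the curve is the
#' identity, which makes calibration collapse to a plain Gaussian -- handy
#' for analytic checks.
#'
#' @param span length-2 calendar span, cal BP (default \code{c(500, 9500)});
#'   must cover at least 500 years.
#' @param wiggle_amplitude sinusoid amplitude, 14C yr.
#' @param wiggle_period sinusoid period, yr.
#' @param sigma constant curve standard deviation, 14C yr.
#' @param walk_sd per-step standard deviation of the random-walk component
#'   (default 0).
#' @param step grid step, yr.
#' @param seed optional integer seed.
#' @return a \code{\link{cal_curve}}.
#' @export
make_calcurve <- function(span = c(500, 9500), wiggle_amplitude = 0,
                          wiggle_period = 500, sigma = 10, walk_sd = 0,
                          step = 1, seed = NULL) {
  if (diff(range(span)) < 500) stop("curve span must cover >= 500 years")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(min(span), max(span), by = step)
  mu <- tt + wiggle_amplitude * sin(2 * pi * tt / wiggle_period)
  if (walk_sd > 0) mu <- mu + cumsum(stats::rnorm(length(tt), 0, walk_sd))
  cal_curve(tt, mu, rep(sigma, length(tt)))
}

#' Simulate a radiocarbon dataset from known growth parameters
#'
#' Calendar ages are drawn from the growth PMF, back-projected to CRAs
#' through the calibration curve with Gaussian lab error, and attached to
#' sites placed in Gaussian spatial clusters. Clusters alternate between
#' \code{"coastal"} and \code{"inland"} region labels; each record gets a
#' millet mark at constant probability.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param curve a \code{\link{cal_curve}} spanning the growth window.
#' @return list with \code{records} (a \code{\link{c14_records}}) and
#'   \code{truth} (the generating values, including true calendar ages).
#' @export
simulate_dataset <- function(cfg, curve) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- cfg$growth
  tt <- g$a:g$b
  pmf <- growth_pmf(g)
  ages <- sample(tt, cfg$n_dates, replace = TRUE, prob = pmf)
  errors <- round(stats::runif(cfg$n_dates, cfg$error_range[1],
                               cfg$error_range[2]))
  cra <- sample_cra(ages, errors, curve)

  # cluster centres on a ~100 km box around 36N 128E; 1 degree lat = 111 km
  km_per_deg <- 111.32
  ctr_lat <- 36 + stats::runif(cfg$n_clusters, 0, 1)
  ctr_lon <- 128 + stats::runif(cfg$n_clusters, 0, 1)
  site_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_sites)
  site_lat <- ctr_lat[site_cluster] +
    stats::rnorm(cfg$n_sites, 0, cfg$cluster_spread_km / km_per_deg)
  site_lon <- ctr_lon[site_cluster] +
    stats::rnorm(cfg$n_sites, 0, cfg$cluster_spread_km /
                   (km_per_deg * cos(36 * pi / 180)))
  region_of_cluster <- ifelse(seq_len(cfg$n_clusters) %% 2L == 0L,
                              "coastal", "inland")
  site_of_record <- sample.int(cfg$n_sites, cfg$n_dates, replace = TRUE)
  millet <- stats::runif(cfg$n_dates) < cfg$millet_prop

  rec <- data.frame(
    lab_id = sprintf("SIM-%05d", seq_len(cfg$n_dates)),
    cra = cra, error = errors,
    site_id = sprintf("S%03d", site_of_record),
    lat = site_lat[site_of_record], lon = site_lon[site_of_record],
    region = region_of_cluster[site_cluster[site_of_record]],
    millet = millet,
    material = ifelse(millet, "millet", "charcoal"),
    origin_known = TRUE, marine = FALSE,
    stringsAsFactors = FALSE)
  list(records = c14_records(rec),
       truth = list(growth = g, ages = ages,
                    site_cluster = site_cluster,
                    cluster_centres = data.frame(lat = ctr_lat, lon = ctr_lon),
                    region_of_cluster = region_of_cluster,
                    millet_prop = cfg$millet_prop))
}

#' Simulate a proxy core with a known event date
#'
#' Linear true age-depth relation; tie-point CRAs generated through the
#' calibration curve; proxy series is a smoothed step dropping at the depth
#' whose true age equals \code{event_true_date}.
#'
#' @param length_cm core length, cm.
#' @param rate_yr_per_cm true accumulation rate, yr/cm.
#' @param n_tiepoints number of dated tie-points (equally spaced,
#'   including both ends).
#' @param tiepoint_error lab error of every tie-point, 14C yr.
#' @param event_true_date true event date, cal BP; must fall inside the
#'   core's true age span.
#' @param curve a \code{\link{cal_curve}}.
#' @param surface_age true age at depth 0, cal BP (default 3000).
#' @param seed optional integer seed.
#' @return list with \code{core} (a \code{\link{proxy_core}}) and
#'   \code{truth} (event depth, true ages at tie-points, rate).
#' @export
simulate_core <- function(length_cm = 100, rate_yr_per_cm = 40,
                          n_tiepoints = 5L, tiepoint_error = 20,
                          event_true_date = 4600, curve,
                          surface_age = 3000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age_at <- function(d) surface_age + rate_yr_per_cm * d
  span <- c(age_at(0), age_at(length_cm))
  if (event_true_date < span[1] || event_true_date > span[2])
    stop("event_true_date outside the core's true age span [",
         span[1], ", ", span[2], "]")
  depths <- seq(0, length_cm, by = 1)
  event_depth <- (event_true_date - surface_age) / rate_yr_per_cm
  width <- length_cm / 25
  # deeper = older = high proxy; the drop toward the present is centred at
  # the event depth
  proxy <- 0.4 + 0.4 / (1 + exp(-(depths - event_depth) / width))
  tp_depth <- seq(0, length_cm, length.out = n_tiepoints)
  tp_cra <- sample_cra(age_at(tp_depth), tiepoint_error, curve)
  tp <- data.frame(depth = tp_depth, cra = tp_cra,
                   error = tiepoint_error, curve_kind = "atmospheric",
                   delta_r = 0, delta_r_sigma = 0)
  list(core = proxy_core(depths, proxy, tp),
       truth = list(event_depth = event_depth,
                    event_true_date = event_true_date,
                    rate_yr_per_cm = rate_yr_per_cm,
                    surface_age = surface_age,
                    tp_true_age = age_at(tp_depth)))
}
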