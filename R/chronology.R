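#' Assemble a proxy core with dated tie-points
#'
#' A sediment (or similar) core carrying a palaeoclimatic proxy series and
#' radiocarbon-dated tie-points used to build an age-depth model.
#'
#' @param depths strictly increasing depths, cm.
#' @param proxy proxy values at each depth (AP/TP ratio, SST degC, ...).
#' @param tiepoints data frame with columns \code{depth} (cm), \code{cra},
#'   \code{error} (14C yr), \code{curve_kind}
#'   (\code{"atmospheric"}/\code{"marine"}), and optionally \code{delta_r},
#'   \code{delta_r_sigma} (reservoir correction for marine tie-points).
#'   At least two tie-points, depths within the core span.
#' @return object of class \code{proxy_core}.
#' @export
proxy_core <- function(depths, proxy, tiepoints) {
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (length(proxy) != length(depths))
    stop("proxy and depths must have equal length")
  tiepoints <- as.data.frame(tiepoints)
  need <- c("depth", "cra", "error", "curve_kind")
  if (!all(need %in% names(tiepoints)))
    stop("tiepoints needs columns: ", paste(need, collapse = ", "))
  if (nrow(tiepoints) < 2L) stop("need >= 2 tiepoints")
  if (any(tiepoints$depth < min(depths) | tiepoints$depth > max(depths)))
    stop("tiepoint depths must lie within the core span")
  if (!"delta_r" %in% names(tiepoints)) tiepoints$delta_r <- 0
  if (!"delta_r_sigma" %in% names(tiepoints)) tiepoints$delta_r_sigma <- 0
  tiepoints <- tiepoints[order(tiepoints$depth), , drop = FALSE]
  structure(list(depths = depths, proxy = proxy, tiepoints = tiepoints),
            class = "proxy_core")
}

# piecewise-linear age at arbitrary depths; beyond the outermost tiepoints
# the nearest segment's accumulation rate is extended
interp_ages <- function(tp_depth, tp_age, depths) {
  k <- length(tp_depth)
  out <- stats::approx(tp_depth, tp_age, xout = depths, rule = 1)$y
  below <- depths < tp_depth[1L]
  above <- depths > tp_depth[k]
  if (any(below)) {
    rate <- (tp_age[2L] - tp_age[1L]) / (tp_depth[2L] - tp_depth[1L])
    out[below] <- tp_age[1L] + rate * (depths[below] - tp_depth[1L])
  }
  if (any(above)) {
    rate <- (tp_age[k] - tp_age[k - 1L]) / (tp_depth[k] - tp_depth[k - 1L])
    out[above] <- tp_age[k] + rate * (depths[above] - tp_depth[k])
  }
  out
}

#' Fit a simplified age-depth model by ordered calibration
#'
#' Each tie-point's calendar age is sampled from its calibrated density
#' (marine tie-points via reservoir-corrected calibration against the
#' marine curve); joint draws violating stratigraphic order (deeper =
#' older) are rejected; retained draws are interpolated piecewise-linearly
#' to every core depth, extending the nearest segment's accumulation rate
#' beyond the outermost tie-points. This is a deliberately simple,
#' order-constrained model; posterior age ensembles produced by external
#' age-depth software can be supplied to downstream functions instead (see
#' \code{\link{event_dates}}).
#'
#' @param core a \code{\link{proxy_core}}.
#' @param curve atmospheric \code{\link{cal_curve}}.
#' @param marine_curve marine \code{\link{cal_curve}}; defaults to
#'   \code{curve} (required only when marine tie-points are present).
#' @param n_draws retained posterior draws (default 1000).
#' @param seed optional integer seed.
#' @return object of class \code{age_ensemble}: list with \code{depths}
#'   and \code{ages} (matrix \code{n_draws} x \code{length(depths)}, cal
#'   BP), plus the tie-point age draws in \code{tp_ages}.
#' @export
fit_age_depth <- function(core, curve, marine_curve = curve,
                          n_draws = 1000L, seed = NULL) {
  stopifnot(inherits(core, "proxy_core"))
  if (!is.null(seed)) set.seed(seed)
  tp <- core$tiepoints
  k <- nrow(tp)
  dens <- vector("list", k)
  for (i in seq_len(k)) {
    marine <- tp$curve_kind[i] == "marine"
    dens[[i]] <- calibrate(tp$cra[i], tp$error[i],
                           if (marine) marine_curve else curve,
                           res = reservoir_correction(tp$delta_r[i],
                                                      tp$delta_r_sigma[i]))
    if (isTRUE(attr(dens[[i]], "empty")))
      stop("tiepoint ", i, " has an empty calibrated density")
  }
  kept <- matrix(NA_real_, 0L, k)
  tried <- 0L
  while (nrow(kept) < n_draws) {
    batch <- max(n_draws, 1000L)
    draws <- sapply(dens, function(d)
      sample(d$cal_bp, batch, replace = TRUE, prob = d$prob))
    ok <- apply(draws, 1L, function(v) all(diff(v) >= 0))
    kept <- rbind(kept, draws[ok, , drop = FALSE])
    tried <- tried + batch
    if (tried >= 1000L && nrow(kept) / tried < 0.001)
      stop("tiepoint densities incompatible with stratigraphic order ",
           "(rejection rate > 99.9%)")
  }
  kept <- kept[seq_len(n_draws), , drop = FALSE]
  ages <- t(apply(kept, 1L, function(v) interp_ages(tp$depth, v, core$depths)))
  structure(list(depths = core$depths, ages = ages, tp_depth = tp$depth,
                 tp_ages = kept),
            class = "age_ensemble")
}

#' Posterior calendar dates of an event at a given core depth
#'
#' @param ensemble an \code{age_ensemble} from \code{\link{fit_age_depth}},
#'   or any list with \code{depths} and an \code{ages} draw matrix
#'   (externally produced ensembles are accepted).
#' @param event_depth depth of the (visually identified) event, cm; must
#'   lie within the ensemble's depth span.
#' @param label event label (e.g. \code{"d1"}, \code{"f2"},
#'   \code{"c_inland"}).
#' @return an \code{\link{event_posterior}}.
#' @export
event_dates <- function(ensemble, event_depth, label = "event") {
  depths <- ensemble$depths
  if (event_depth < min(depths) || event_depth > max(depths))
    stop("event depth outside the ensemble span")
  samples <- apply(ensemble$ages, 1L, function(a)
    stats::approx(depths, a, xout = event_depth)$y)
  event_posterior(label, samples)
}

#' Posterior calendar-date samples for a named event
#'
#' Container for posterior dates of a climatic or demographic event,
#' either produced by \code{\link{event_dates}} or supplied directly (e.g.
#' posterior change-point draws, or samples imported from external
#' age-depth software).
#'
#' @param label event name.
#' @param samples calendar dates, cal BP.
#' @return object of class \code{event_posterior}.
#' @export
event_posterior <- function(label, samples) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples)) stop("empty or NA samples")
  structure(list(label = label, samples = samples), class = "event_posterior")
}

#' Posterior temporal difference between two dated events
#'
#' Samples \code{n} pairs independently (with replacement) from the two
#' posteriors and studies the distribution of the difference A - B in
#' calendar years. Convention: on the cal BP scale smaller is more recent,
#' so "A occurred after B" means A - B < 0. Exact ties (possible on
#' integer-year grids) are counted as neither after nor before and
#' reported separately.
#'
#' @param eventA,eventB \code{\link{event_posterior}} objects.
#' @param n number of sampled pairs (default 5000).
#' @param seed optional integer seed.
#' @return object of class \code{ordering_result}: list with \code{pair},
#'   \code{diff_samples} (years, A - B), \code{p_A_after_B},
#'   \code{p_B_after_A}, \code{p_tie}, and \code{hpd90} of the difference.
#' @export
temporal_difference <- function(eventA, eventB, n = 5000L, seed = NULL) {
  stopifnot(inherits(eventA, "event_posterior"),
            inherits(eventB, "event_posterior"))
  if (!is.null(seed)) set.seed(seed)
  da <- sample(eventA$samples, n, replace = TRUE)
  db <- sample(eventB$samples, n, replace = TRUE)
  diff <- da - db
  out <- list(pair = c(eventA$label, eventB$label),
              diff_samples = diff,
              p_A_after_B = mean(diff < 0),
              p_B_after_A = mean(diff > 0),
              p_tie = mean(diff == 0),
              hpd90 = hpd_interval(diff, level = 0.90))
  class(out) <- "ordering_result"
  out
}

#' @export
print.event_posterior <- function(x, ...) {
  h <- hpd_interval(x$samples, 0.90)
  cat("Event", x$label, ":", length(x$samples), "posterior dates; median",
      round(stats::median(x$samples)), "cal BP; 90% HPD [",
      round(h$lower[1]), ",", round(h$upper[1]), "]\n")
  invisible(x)
}

#' @export
print.ordering_result <- function(x, ...) {
  cat("Temporal difference", x$pair[1], "-", x$pair[2], "(cal yr):\n")
  cat("  median", round(stats::median(x$diff_samples)),
      "; 90% HPD [", round(x$hpd90$lower[1]), ",",
      round(x$hpd90$upper[1]), "]\n")
  cat(sprintf("  P(%s after %s) = %.3f   P(%s after %s) = %.3f   P(tie) = %.3f\n",
              x$pair[1], x$pair[2], x$p_A_after_B,
              x$pair[2], x$pair[1], x$p_B_after_A, x$p_tie))
  cat("  (cal BP scale: 'after' = more recent = smaller value)\n")
  invisible(x)
}
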