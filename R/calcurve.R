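#' Construct a calibration curve object
#'
#' A calibration curve maps calendar age (cal BP) to the expected
#' conventional radiocarbon age (CRA, 14C yr BP) together with the curve's
#' own 1-sigma uncertainty. Curves such as IntCal20 or Marine20 are
#' distributed in this form.
#'
#' @param cal_bp numeric vector of calendar years BP; strictly monotone
#'   (ascending or descending), length >= 2.
#' @param c14_age numeric vector of curve mean CRAs (14C yr BP).
#' @param sigma_curve numeric vector of curve standard deviations (14C yr),
#'   all > 0.
#' @return An object of class \code{cal_curve}: a data frame with columns
#'   \code{cal_bp}, \code{c14_age}, \code{sigma_curve}, sorted by ascending
#'   \code{cal_bp}.
#' @export
cal_curve <- function(cal_bp, c14_age, sigma_curve) {
  cal_bp <- as.numeric(cal_bp)
  c14_age <- as.numeric(c14_age)
  sigma_curve <- as.numeric(sigma_curve)
  n <- length(cal_bp)
  if (n < 2L || length(c14_age) != n || length(sigma_curve) != n)
    stop("calibration curve needs >= 2 rows with equal-length columns")
  if (anyNA(cal_bp) || anyNA(c14_age) || anyNA(sigma_curve))
    stop("calibration curve contains non-numeric or missing values")
  d <- diff(cal_bp)
  if (!(all(d > 0) || all(d < 0)))
    stop("cal_bp grid must be strictly monotone")
  if (any(sigma_curve <= 0))
    stop("sigma_curve must be > 0 everywhere")
  o <- order(cal_bp)
  out <- data.frame(cal_bp = cal_bp[o], c14_age = c14_age[o],
                    sigma_curve = sigma_curve[o])
  class(out) <- c("cal_curve", "data.frame")
  out
}

#' Read a calibration curve file
#'
#' Supports the standard IntCal distribution format (comma-separated, header
#' lines prefixed with \code{#}, columns CAL BP / 14C age / Error, any
#' further columns ignored) and a plain whitespace- or comma-delimited
#' 3-column headered table.
#'
#' @param path path to the curve file.
#' @param dialect \code{"intcal"} or \code{"plain"}.
#' @return A \code{\link{cal_curve}}.
#' @export
load_calcurve <- function(path, dialect = c("intcal", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("calibration curve file not found: ", path)
  if (dialect == "intcal") {
    tab <- utils::read.table(path, sep = ",", comment.char = "#",
                             header = FALSE, fill = TRUE,
                             stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             sep = if (grepl(",", readLines(path, n = 2L)[2L])) "," else "")
  }
  if (ncol(tab) < 3L) stop("curve file must have at least 3 columns")
  tab <- tab[, 1:3]
  # rows with non-numeric fields (stray headers etc.) are rejected
  for (j in 1:3) tab[[j]] <- suppressWarnings(as.numeric(tab[[j]]))
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 2L) stop("curve file has fewer than 2 usable rows")
  cal_curve(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Evaluate a calibration curve at arbitrary calendar ages
#'
#' Linear interpolation of both the curve mean and its standard deviation
#' between bracketing grid points.
#'
#' @param curve a \code{\link{cal_curve}}.
#' @param t calendar age(s), cal BP; must lie within the curve's span.
#' @return list with numeric vectors \code{mu} (14C yr BP) and \code{sd}
#'   (14C yr), one element per \code{t}.
#' @export
curve_at <- function(curve, t) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_bp)
  if (any(t < rng[1L] | t > rng[2L]))
    stop("calendar age outside the calibration curve span [",
         rng[1L], ", ", rng[2L], "]")
  list(mu = stats::approx(curve$cal_bp, curve$c14_age, xout = t)$y,
       sd = stats::approx(curve$cal_bp, curve$sigma_curve, xout = t)$y)
}

#' Marine reservoir correction
#'
#' A local offset (Delta-R) subtracted from a marine sample's CRA before
#' calibration against a marine curve, with its own Gaussian uncertainty
#' added in quadrature.
#'
#' @param delta_r offset, 14C yr.
#' @param delta_r_sigma standard deviation of the offset, 14C yr (>= 0).
#' @return object of class \code{reservoir_correction}.
#' @export
reservoir_correction <- function(delta_r = 0, delta_r_sigma = 0) {
  if (delta_r_sigma < 0) stop("delta_r_sigma must be >= 0")
  structure(list(delta_r = delta_r, delta_r_sigma = delta_r_sigma),
            class = "reservoir_correction")
}

#' Calibrate a conventional radiocarbon age
#'
#' Converts a CRA and its lab error into a per-calendar-year probability
#' mass function on an integer cal BP grid. The unnormalized mass at
#' calendar year t is the Gaussian density of \code{cra - delta_r} with mean
#' \code{curve_at(t)$mu} and standard deviation
#' \code{sqrt(error^2 + curve_at(t)$sd^2 + delta_r_sigma^2)}; masses are
#' normalized to sum to one over the grid.
#'
#' @param cra conventional radiocarbon age, 14C yr BP.
#' @param error lab error, 14C yr (> 0).
#' @param curve a \code{\link{cal_curve}}.
#' @param grid length-2 numeric: calendar window (cal BP, either order);
#'   defaults to the curve span.
#' @param step grid step in years (default 1).
#' @param res optional \code{\link{reservoir_correction}}.
#' @return object of class \code{cal_density}: data frame with columns
#'   \code{cal_bp} (descending, old to young) and \code{prob}. If the date
#'   is incompatible with the window (all-zero density) the returned object
#'   carries attribute \code{empty = TRUE} and zero probabilities.
#' @export
calibrate <- function(cra, error, curve, grid = NULL, step = 1,
                      res = reservoir_correction()) {
  stopifnot(inherits(curve, "cal_curve"))
  if (error <= 0) stop("error must be > 0")
  span <- range(curve$cal_bp)
  if (is.null(grid)) grid <- span
  lo <- min(grid); hi <- max(grid)
  if (lo < span[1L] || hi > span[2L])
    stop("calibration grid extends beyond the curve span")
  tt <- seq(hi, lo, by = -step)
  ca <- curve_at(curve, tt)
  sd_tot <- sqrt(error^2 + ca$sd^2 + res$delta_r_sigma^2)
  # work in logs to survive dates far from the window
  logd <- stats::dnorm(cra - res$delta_r, mean = ca$mu, sd = sd_tot, log = TRUE)
  m <- max(logd)
  empty <- !is.finite(m) || m < log(.Machine$double.xmin) + 50
  prob <- if (empty) rep(0, length(tt)) else {
    w <- exp(logd - m)
    w / sum(w)
  }
  out <- data.frame(cal_bp = tt, prob = prob)
  class(out) <- c("cal_density", "data.frame")
  attr(out, "empty") <- empty
  out
}

#' Sample a conventional radiocarbon age for a known calendar age
#'
#' The generative direction of calibration, used by simulation and
#' predictive checks: a draw from
#' Normal(\code{curve_at(t)$mu}, \code{sqrt(error^2 + curve_at(t)$sd^2)}),
#' rounded to an integer 14C year.
#'
#' @param t calendar age(s), cal BP, within the curve span.
#' @param error lab error(s), 14C yr (recycled against \code{t}).
#' @param curve a \code{\link{cal_curve}}.
#' @param seed optional integer; if supplied the RNG is seeded first.
#' @return integer CRA(s), 14C yr BP.
#' @export
sample_cra <- function(t, error, curve, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ca <- curve_at(curve, t)
  round(stats::rnorm(length(t), mean = ca$mu,
                     sd = sqrt(error^2 + ca$sd^2)))
}

#' Highest posterior density interval(s)
#'
#' For a discrete density on a grid, returns the smallest set of grid
#' intervals whose total probability reaches \code{level} (grid points
#' ranked by mass; contiguous selected points merged into intervals). For a
#' numeric sample, returns the single shortest interval containing a
#' \code{level} fraction of the draws.
#'
#' @param x a \code{cal_density}, or a numeric vector of samples.
#' @param level coverage fraction in (0, 1); default 0.90.
#' @param ... unused.
#' @return data frame with columns \code{lower}, \code{upper} (cal BP,
#'   \code{lower <= upper} numerically), one row per disjoint interval,
#'   with attribute \code{mass} giving the attained total probability.
#' @export
hpd_interval <- function(x, level = 0.90, ...) UseMethod("hpd_interval")

#' @rdname hpd_interval
#' @export
hpd_interval.cal_density <- function(x, level = 0.90, ...) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (nrow(x) == 0L || sum(x$prob) == 0) stop("empty density")
  o <- order(x$prob, decreasing = TRUE)
  cum <- cumsum(x$prob[o])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(o)
  # exact ties at the margin are kept together (a symmetric density keeps a
  # symmetric interval on a discrete grid)
  pk <- x$prob[o[k]]
  while (k < length(o) &&
         abs(x$prob[o[k + 1L]] - pk) <= 1e-12 * max(pk, 1e-300)) {
    k <- k + 1L
  }
  cum <- cum[1L:k]
  sel <- sort(x$cal_bp[o[seq_len(k)]])
  step <- if (length(x$cal_bp) > 1L) min(abs(diff(sort(x$cal_bp)))) else 1
  brk <- which(diff(sel) > step + 1e-9)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(sel))
  out <- data.frame(lower = sel[starts], upper = sel[ends])
  attr(out, "mass") <- cum[k]
  attr(out, "level") <- level
  out
}

#' @rdname hpd_interval
#' @export
hpd_interval.numeric <- function(x, level = 0.90, ...) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty sample")
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(level * n))
  if (k >= n) {
    out <- data.frame(lower = xs[1L], upper = xs[n])
  } else {
    widths <- xs[(k + 1L):n] - xs[1:(n - k)]
    i <- which.min(widths)
    out <- data.frame(lower = xs[i], upper = xs[i + k])
  }
  attr(out, "mass") <- k / n
  attr(out, "level") <- level
  out
}

#' @export
print.cal_density <- function(x, ...) {
  emp <- isTRUE(attr(x, "empty"))
  cat("Calibrated density on", nrow(x), "calendar years (",
      max(x$cal_bp), "-", min(x$cal_bp), "cal BP )",
      if (emp) "[EMPTY: date incompatible with window]" else "", "\n")
  if (!emp) {
    md <- x$cal_bp[which.max(x$prob)]
    cat("  mode:", md, "cal BP; total mass:", format(sum(x$prob)), "\n")
  }
  invisible(x)
}
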