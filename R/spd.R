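# Shared machinery: per-record calibrated densities on a common grid.
#
# Densities are computed on the analysis window padded by `pad` years on
# both sides (clipped to the curve span) and normalized there, a practical
# stand-in for "the full curve span": any date whose window mass matters
# has negligible probability beyond the padding. Columns are then sliced to
# the window, so a boundary-straddling date keeps its partial mass.
cal_grid <- function(window, step = 1) seq(max(window), min(window), by = -step)

density_matrix <- function(cra, error, curve, tt) {
  ca <- curve_at(curve, tt)
  n <- length(cra)
  out <- matrix(0, n, length(tt))
  for (j in seq_len(n)) {
    sd_tot <- sqrt(error[j]^2 + ca$sd^2)
    logd <- stats::dnorm(cra[j], mean = ca$mu, sd = sd_tot, log = TRUE)
    m <- max(logd)
    if (is.finite(m)) out[j, ] <- exp(logd - m)
  }
  out
}

# rows normalized over the padded grid; returns list(window matrix, window
# mass per record, grid)
calibrated_rows <- function(records, curve, window, step = 1, pad = 2000) {
  span <- range(curve$cal_bp)
  ext <- c(max(span[1], min(window) - pad), min(span[2], max(window) + pad))
  tt_ext <- cal_grid(ext, step)
  dm <- density_matrix(records$cra, records$error, curve, tt_ext)
  tot <- rowSums(dm)
  tot[tot == 0] <- Inf   # empty density row stays all-zero
  dm <- dm / tot
  inwin <- tt_ext <= max(window) & tt_ext >= min(window)
  list(dens = dm[, inwin, drop = FALSE],
       window_mass = rowSums(dm[, inwin, drop = FALSE]),
       cal_bp = tt_ext[inwin])
}

#' Build a summed probability distribution (SPD)
#'
#' Each record is calibrated to a per-year density summing to one over its
#' own support; within every spatio-temporal bin the member densities are
#' averaged (so a bin fully inside the window contributes total mass one,
#' whatever its dating intensity); the SPD is the sum of the bin curves
#' over the analysis window.
#'
#' @param records a \code{\link{c14_records}} data frame.
#' @param bins a \code{\link{assign_bins}} result, or \code{NULL} to treat
#'   every record as its own bin (no normalization).
#' @param curve a \code{\link{cal_curve}}.
#' @param window length-2 calendar window, cal BP (default \code{c(7000, 3000)}).
#' @param step grid step in years.
#' @return object of class \code{spd_curve}: data frame \code{(cal_bp,
#'   density)} on the window grid (old to young) with attribute
#'   \code{n_bins}.
#' @export
build_spd <- function(records, bins = NULL, curve, window = c(7000, 3000),
                      step = 1) {
  records <- c14_records(records)
  cr <- calibrated_rows(records, curve, window, step)
  if (is.null(bins)) {
    bin_id <- as.character(seq_len(nrow(records)))
  } else {
    bin_id <- bins$bin_id[match(records$lab_id, bins$lab_id)]
    if (anyNA(bin_id)) stop("records without a bin assignment")
  }
  dens <- numeric(length(cr$cal_bp))
  ub <- unique(bin_id)
  for (b in ub) {
    idx <- which(bin_id == b)
    bm <- colSums(cr$dens[idx, , drop = FALSE]) / length(idx)
    if (sum(bm) == 0)
      message("bin ", b, " has no calibratable mass in the window; contributes zero")
    dens <- dens + bm
  }
  out <- data.frame(cal_bp = cr$cal_bp, density = dens)
  class(out) <- c("spd_curve", "data.frame")
  attr(out, "n_bins") <- length(ub)
  out
}

#' Thin records to one date per bin and drop poorly-supported dates
#'
#' The model-fitting thinning rule: keep, in each spatio-temporal bin, the
#' date with the smallest lab error (ties broken by smallest CRA, then
#' input order), then exclude any survivor whose calibrated probability
#' mass inside the analysis window (as a fraction of its whole calibrated
#' density) falls below \code{min_mass}.
#'
#' @inheritParams build_spd
#' @param bins a \code{\link{assign_bins}} result.
#' @param min_mass minimum window mass fraction (default 0.5).
#' @return the surviving records (one per retained bin), in input order,
#'   with the bin label attached as column \code{bin_id}.
#' @export
thin_bins <- function(records, bins, curve, window = c(7000, 3000),
                      min_mass = 0.5) {
  records <- c14_records(records)
  bin_id <- bins$bin_id[match(records$lab_id, bins$lab_id)]
  if (anyNA(bin_id)) stop("records without a bin assignment")
  n <- nrow(records)
  ord <- order(bin_id, records$error, records$cra, seq_len(n))
  keep_idx <- ord[!duplicated(bin_id[ord])]
  keep_idx <- sort(keep_idx)
  out <- records[keep_idx, , drop = FALSE]
  out$bin_id <- bin_id[keep_idx]
  cr <- calibrated_rows(out, curve, window)
  out <- out[cr$window_mass >= min_mass, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

#' @export
print.spd_curve <- function(x, ...) {
  cat("SPD over", max(x$cal_bp), "-", min(x$cal_bp), "cal BP;",
      attr(x, "n_bins"), "bins; total mass", format(sum(x$density)), "\n")
  invisible(x)
}

#' Plot an SPD as a filled curve
#'
#' @param x an \code{spd_curve}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.spd_curve <- function(x, ...) {
  graphics::plot(x$cal_bp, x$density, type = "n", xlim = rev(range(x$cal_bp)),
                 xlab = "cal BP", ylab = "summed probability", ...)
  graphics::polygon(c(x$cal_bp, rev(x$cal_bp)),
                    c(x$density, rep(0, nrow(x))), col = "grey70", border = NA)
  graphics::lines(x$cal_bp, x$density, col = "grey30")
  invisible(x)
}
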