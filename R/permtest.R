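# group SPD on the window grid, optionally bin-normalized, scaled to unit
# mass so groups of different sizes are comparable in shape
group_spd_vec <- function(dens, members, bin_id = NULL) {
  if (length(members) == 0L) stop("empty mark group")
  if (is.null(bin_id)) {
    v <- colSums(dens[members, , drop = FALSE])
  } else {
    v <- numeric(ncol(dens))
    for (b in unique(bin_id[members])) {
      idx <- members[bin_id[members] == b]
      v <- v + colSums(dens[idx, , drop = FALSE]) / length(idx)
    }
  }
  tot <- sum(v)
  if (tot == 0) stop("mark group with zero calibratable mass in the window")
  v / tot
}

#' Mark-permutation test between SPDs of labelled date subsets
#'
#' Compares the shape of each mark group's SPD against the distribution of
#' SPDs obtained by randomly reassigning the marks across records. Group
#' SPDs are normalized to unit mass, so the test addresses shape (when
#' dates fall), not abundance. For each group the simulation envelope is
#' the pointwise alpha/2 and 1-alpha/2 quantile band over permutations; the
#' global statistic is the summed out-of-envelope deviation
#' \eqn{\sum_t \max(0, obs_t - hi_t) + \max(0, lo_t - obs_t)}, and the
#' global p-value is \code{(\#\{perm stat >= observed\} + 1) / (n_perm + 1)}.
#'
#' @param records a \code{\link{c14_records}} data frame.
#' @param marks per-record group labels (>= 2 non-empty groups), or the
#'   name of a column of \code{records}.
#' @param curve a \code{\link{cal_curve}}.
#' @param window length-2 calendar window, cal BP.
#' @param n_perm number of random permutations (default 1000), or
#'   \code{"exhaustive"} to enumerate all distinct relabellings (2-group
#'   case; the observed labelling is part of the enumeration, so the
#'   p-value is the exact enumeration fraction without the +1 correction).
#' @param alpha envelope tail level (default 0.05).
#' @param bins optional \code{\link{assign_bins}} result; when supplied,
#'   each group's SPD is bin-normalized (regional comparisons); when
#'   \code{NULL} raw summation is used (e.g. the millet test).
#' @param seed optional integer seed.
#' @param step grid step, years.
#' @return object of class \code{perm_test}: list with \code{cal_bp},
#'   per-group \code{observed}, \code{lo}, \code{hi} envelopes,
#'   \code{global_p}, \code{n_perm}, \code{alpha}.
#' @export
mark_permutation_test <- function(records, marks, curve,
                                  window = c(7000, 3000), n_perm = 1000,
                                  alpha = 0.05, bins = NULL, seed = NULL,
                                  step = 1) {
  records <- c14_records(records)
  if (is.character(marks) && length(marks) == 1L) marks <- records[[marks]]
  marks <- as.character(marks)
  if (length(marks) != nrow(records))
    stop("marks must have one label per record")
  groups <- unique(marks)
  if (length(groups) < 2L) stop("need >= 2 mark groups")
  if (!is.null(seed)) set.seed(seed)

  cr <- calibrated_rows(records, curve, window, step)
  bin_id <- if (is.null(bins)) NULL else
    bins$bin_id[match(records$lab_id, bins$lab_id)]
  n <- nrow(records)

  obs <- lapply(groups, function(g)
    group_spd_vec(cr$dens, which(marks == g), bin_id))
  names(obs) <- groups

  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    if (length(groups) != 2L)
      stop("exhaustive enumeration implemented for 2 groups")
    k <- sum(marks == groups[1L])
    sets <- utils::combn(n, k, simplify = FALSE)
    perm_marks <- lapply(sets, function(s) {
      m <- rep(groups[2L], n); m[s] <- groups[1L]; m
    })
  } else {
    perm_marks <- replicate(n_perm, sample(marks), simplify = FALSE)
  }
  np <- length(perm_marks)

  perm <- lapply(groups, function(g) matrix(NA_real_, length(cr$cal_bp), np))
  names(perm) <- groups
  for (i in seq_len(np)) {
    pm <- perm_marks[[i]]
    for (g in groups)
      perm[[g]][, i] <- group_spd_vec(cr$dens, which(pm == g), bin_id)
  }

  lo <- hi <- vector("list", length(groups)); names(lo) <- names(hi) <- groups
  global_p <- stats::setNames(numeric(length(groups)), groups)
  exceed <- function(v, l, h) sum(pmax(0, v - h) + pmax(0, l - v))
  for (g in groups) {
    qs <- apply(perm[[g]], 1L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2))
    lo[[g]] <- qs[1L, ]; hi[[g]] <- qs[2L, ]
    stat_obs <- exceed(obs[[g]], lo[[g]], hi[[g]])
    stat_perm <- apply(perm[[g]], 2L, exceed, l = lo[[g]], h = hi[[g]])
    global_p[g] <- if (exhaustive) {
      mean(stat_perm >= stat_obs - 1e-12)
    } else {
      (sum(stat_perm >= stat_obs - 1e-12) + 1) / (np + 1)
    }
  }

  out <- list(cal_bp = cr$cal_bp, observed = obs, lo = lo, hi = hi,
              global_p = global_p, n_perm = np, alpha = alpha,
              binned = !is.null(bins))
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Mark-permutation test (", x$n_perm, " permutations, alpha = ",
      x$alpha, if (x$binned) ", bin-normalized" else "", ")\n", sep = "")
  for (g in names(x$global_p))
    cat(sprintf("  group %-12s global p = %.4g\n", g, x$global_p[g]))
  invisible(x)
}

#' Plot a mark-permutation test: observed SPD against its null envelope
#'
#' @param x a \code{perm_test}.
#' @param group which mark group to draw (default: first).
#' @param ... passed to \code{plot.default}.
#' @export
plot.perm_test <- function(x, group = names(x$observed)[1L], ...) {
  yl <- range(0, x$hi[[group]], x$observed[[group]])
  graphics::plot(x$cal_bp, x$observed[[group]], type = "n",
                 xlim = rev(range(x$cal_bp)), ylim = yl,
                 xlab = "cal BP", ylab = "normalized summed probability",
                 main = paste0(group, " (global p = ",
                               signif(x$global_p[group], 3), ")"), ...)
  graphics::polygon(c(x$cal_bp, rev(x$cal_bp)),
                    c(x$lo[[group]], rev(x$hi[[group]])),
                    col = "grey85", border = NA)
  graphics::lines(x$cal_bp, x$observed[[group]], col = "firebrick")
  invisible(x)
}

#' Export a permutation test as a JSON summary plus envelope table
#'
#' @param x a \code{perm_test}.
#' @param json_path,table_path output file paths (either may be NULL).
#' @return invisibly, the summary list.
#' @export
export_perm_test <- function(x, json_path = NULL, table_path = NULL) {
  smry <- list(n_perm = x$n_perm, alpha = x$alpha, binned = x$binned,
               global_p = as.list(x$global_p))
  if (!is.null(json_path))
    jsonlite::write_json(smry, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(table_path)) {
    tab <- data.frame(cal_bp = x$cal_bp)
    for (g in names(x$observed)) {
      tab[[paste0(g, "_obs")]] <- x$observed[[g]]
      tab[[paste0(g, "_lo")]] <- x$lo[[g]]
      tab[[paste0(g, "_hi")]] <- x$hi[[g]]
    }
    utils::write.csv(tab, table_path, row.names = FALSE)
  }
  invisible(smry)
}
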