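#' Assemble a table of radiocarbon date records
#'
#' Validates and normalizes a data frame of 14C dates. Required columns:
#' \code{lab_id}, \code{cra}, \code{error}, \code{site_id}, \code{lat},
#' \code{lon}. Optional columns (created with defaults when absent):
#' \code{region} (\code{"coastal"}/\code{"inland"}; region is an input
#' label, not computed from a coastline), \code{millet} (logical),
#' \code{material}, \code{origin_known} (default \code{TRUE}) and
#' \code{marine} (default \code{FALSE}). Extra columns are preserved.
#'
#' @param x data frame of dates.
#' @return the validated data frame with class \code{c14_records}.
#' @export
c14_records <- function(x) {
  x <- as.data.frame(x)
  need <- c("lab_id", "cra", "error", "site_id", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"region" %in% names(x)) x$region <- NA_character_
  if (!"millet" %in% names(x)) x$millet <- FALSE
  if (!"material" %in% names(x)) x$material <- NA_character_
  if (!"origin_known" %in% names(x)) x$origin_known <- TRUE
  if (!"marine" %in% names(x)) x$marine <- FALSE
  x$millet <- as.logical(x$millet)
  x$origin_known <- as.logical(x$origin_known)
  x$marine <- as.logical(x$marine)
  if (any(x$error <= 0)) stop("all errors must be > 0")
  if (any(x$lat < -90 | x$lat > 90)) stop("lat out of [-90, 90]")
  if (any(x$lon < -180 | x$lon > 180)) stop("lon out of [-180, 180]")
  class(x) <- c("c14_records", "data.frame")
  x
}

#' Read radiocarbon records from a delimited table
#'
#' @param path path to a headered CSV or TSV file with the
#'   \code{\link{c14_records}} columns.
#' @return a \code{c14_records} data frame.
#' @export
read_c14_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  c14_records(utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE))
}

#' Apply the standard inclusion filters to a set of dates
#'
#' Retains records of known origin, not dated on marine specimens, with CRA
#' inside the closed bracket \code{[cra_min, cra_max]}. Record order is
#' preserved; the filter is idempotent.
#'
#' @param records a \code{\link{c14_records}} data frame.
#' @param cra_min,cra_max inclusive CRA bracket, 14C yr BP (defaults
#'   2800 and 6200).
#' @return the retained records.
#' @export
filter_dates <- function(records, cra_min = 2800, cra_max = 6200) {
  records <- c14_records(records)
  keep <- records$origin_known & !records$marine &
    records$cra >= cra_min & records$cra <= cra_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

# great-circle distance matrix in km (spherical Earth, r = 6371 km)
geo_dist_km <- function(lat, lon) {
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371))
  m
}

#' Spatial clustering of sites (DBSCAN, great-circle distances)
#'
#' Density-based clustering of site coordinates with DBSCAN. With
#' \code{min_pts = 1} (the default) every site is a core point, so the
#' algorithm reduces to the connected components of the graph joining sites
#' closer than \code{eps_km}; there are no noise points. Cluster ids are
#' contiguous integers numbered by first appearance in input order.
#'
#' @param sites data frame with columns \code{site_id}, \code{lat},
#'   \code{lon} (one row per site; duplicated \code{site_id}s collapsed to
#'   their first occurrence).
#' @param eps_km neighbourhood radius in km (default 1).
#' @param min_pts minimum neighbourhood size (point itself included) for a
#'   core point (default 1).
#' @return data frame \code{(site_id, cluster_id)}; with \code{min_pts > 1}
#'   non-core, non-reachable sites get \code{cluster_id = NA} (noise).
#' @export
cluster_sites <- function(sites, eps_km = 1.0, min_pts = 1L) {
  sites <- as.data.frame(sites)
  sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
  n <- nrow(sites)
  if (n == 0L) return(data.frame(site_id = character(), cluster_id = integer()))
  if (n == 1L) return(data.frame(site_id = sites$site_id, cluster_id = 1L))
  d <- geo_dist_km(sites$lat, sites$lon)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps_km))  # includes self
  core <- vapply(nb, length, 1L) >= min_pts
  cl <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cl[i]) || !core[i]) next
    next_id <- next_id + 1L
    cl[i] <- next_id
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (is.na(cl[j])) {
        cl[j] <- next_id
        if (core[j]) queue <- c(queue, nb[[j]][is.na(cl[nb[[j]]])])
      }
    }
  }
  data.frame(site_id = sites$site_id, cluster_id = cl)
}

#' Temporal binning of dates within a site cluster
#'
#' Complete-linkage agglomerative clustering of CRA values (uncalibrated
#' 14C scale), with the tree cut at height \code{h}: two dates share a bin
#' only if every pairwise CRA difference within the bin is <= \code{h}.
#'
#' @param cra numeric vector of CRAs for the records of one cluster.
#' @param h cut height in 14C years (default 100).
#' @return integer bin labels (1-based, in order of each bin's first
#'   appearance in the input).
#' @export
temporal_bins <- function(cra, h = 100) {
  n <- length(cra)
  if (n == 0L) stop("temporal_bins needs at least one record")
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(cra), method = "complete")
  raw <- stats::cutree(hc, h = h)
  # relabel by first appearance so labels are deterministic in input order
  as.integer(factor(raw, levels = unique(raw)))
}

#' Assign every record to a spatio-temporal bin
#'
#' Combines \code{\link{cluster_sites}} (DBSCAN on site coordinates) and
#' \code{\link{temporal_bins}} (complete linkage on CRA within each spatial
#' cluster) into the bin labels used for SPD normalization and model-fitting
#' thinning.
#'
#' @param records a \code{\link{c14_records}} data frame.
#' @param eps_km,min_pts DBSCAN parameters (defaults 1 km, 1).
#' @param h temporal cut height, 14C years (default 100).
#' @return data frame \code{(lab_id, cluster_id, bin_id)} with class
#'   \code{bin_assignment}, one row per record, in record order;
#'   \code{bin_id} is \code{"<cluster>.<ordinal>"}.
#' @export
assign_bins <- function(records, eps_km = 1.0, min_pts = 1L, h = 100) {
  records <- c14_records(records)
  sites <- unique(records[, c("site_id", "lat", "lon")])
  cl <- cluster_sites(sites, eps_km = eps_km, min_pts = min_pts)
  cluster_id <- cl$cluster_id[match(records$site_id, cl$site_id)]
  bin_id <- character(nrow(records))
  for (g in unique(cluster_id)) {
    idx <- which(cluster_id == g)
    bin_id[idx] <- paste0(g, ".", temporal_bins(records$cra[idx], h = h))
  }
  out <- data.frame(lab_id = records$lab_id, cluster_id = cluster_id,
                    bin_id = bin_id, stringsAsFactors = FALSE)
  class(out) <- c("bin_assignment", "data.frame")
  out
}
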