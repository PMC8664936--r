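# Shared fixtures, all built in code.

# near-identity curve: mu(t) = t, constant sigma
flat_curve <- function(sigma = 1, span = c(500, 9500))
  make_calcurve(span = span, sigma = sigma)

# minimal records table around given CRAs
toy_records <- function(cra, error = 20, site_id = "S1",
                        lat = 36, lon = 128, ...) {
  n <- length(cra)
  c14_records(data.frame(
    lab_id = sprintf("T-%03d", seq_len(n)),
    cra = cra, error = rep_len(error, n),
    site_id = rep_len(site_id, n),
    lat = rep_len(lat, n), lon = rep_len(lon, n), ...))
}

# place a site at a given great-circle offset (km) east of a reference
offset_site <- function(lat0 = 36, lon0 = 128, km = 1)
  c(lat = lat0, lon = lon0 + km / (111.32 * cos(lat0 * pi / 180)))

# trivial one-bin-per-record assignment
singleton_bins <- function(records)
  structure(data.frame(lab_id = records$lab_id,
                       cluster_id = seq_len(nrow(records)),
                       bin_id = as.character(seq_len(nrow(records)))),
            class = c("bin_assignment", "data.frame"))
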