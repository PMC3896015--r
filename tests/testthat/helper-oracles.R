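# Independent oracles and fixture builders. Oracles deliberately avoid the
# package's own code paths: brute-force scans, explicit double loops and
# direct enumeration over small inputs.

# Interval-scan cell lookup: try every candidate cell and return the one
# whose half-open interval contains the point.
brute_bin <- function(lat, lon, cs = 5) {
  lon <- lon %% 360
  lat_candidates <- seq(-90, 90 - cs, by = cs)
  lon_candidates <- seq(0, 360 - cs, by = cs)
  for (la in lat_candidates) {
    for (lo in lon_candidates) {
      hit_lat <- (lat >= la && lat < la + cs) || (lat == 90 && la == 90 - cs)
      hit_lon <- lon >= lo && lon < lo + cs
      if (hit_lat && hit_lon) return(c(lat_lo = la, lon_lo = lo))
    }
  }
  stop("no cell found")
}

# Explicit double-loop interaction index over every cell-quarter of a dense
# little grid; completely separate from the vectorized implementation.
brute_interaction <- function(pt_df, pe_df) {
  cells <- unique(rbind(pt_df[c("lat_lo", "lon_lo")], pe_df[c("lat_lo", "lon_lo")]))
  lookup <- function(df, la, lo, qq) {
    row <- df$lat_lo == la & df$lon_lo == lo & df$quarter == qq
    if (any(row)) df$value[row] else NA_real_
  }
  out <- NULL
  denom <- 0
  for (r in seq_len(nrow(cells))) {
    for (qq in 1:4) {
      a <- lookup(pt_df, cells$lat_lo[r], cells$lon_lo[r], qq)
      b <- lookup(pe_df, cells$lat_lo[r], cells$lon_lo[r], qq)
      if (!is.na(a) && !is.na(b)) {
        out <- rbind(out, data.frame(lat_lo = cells$lat_lo[r],
                                     lon_lo = cells$lon_lo[r],
                                     quarter = qq, value = a * b))
        denom <- denom + a * b
      }
    }
  }
  out$value <- out$value / denom
  out[order(out$quarter, out$lat_lo, out$lon_lo), , drop = FALSE]
}

# Random small non-negative field on an nlat x nlon grid with partial mask.
random_small_field <- function(nlat = 4, nlon = 4, keep_prob = 0.7, cs = 5) {
  g <- expand.grid(lat_lo = seq(0, by = cs, length.out = nlat),
                   lon_lo = seq(0, by = cs, length.out = nlon),
                   quarter = 1:4)
  g <- g[runif(nrow(g)) < keep_prob, , drop = FALSE]
  g$value <- runif(nrow(g))
  g
}

# Build a track data frame from daily offsets relative to a start date.
make_track <- function(id, pop, day_offsets, start = as.Date("2000-01-01"),
                       lat = 0, lon = 180) {
  n <- length(day_offsets)
  data.frame(turtle_id = id, population = pop,
             date = start + day_offsets,
             lat = rep_len(lat, n), lon = rep_len(lon, n))
}

# The canonical two-turtle example: one EP turtle tracked days 1..5 and one
# tracked days 1..10, all positions in one cell-quarter.
two_turtle_tracks <- function() {
  rbind(make_track("a", "EP", 0:4), make_track("b", "EP", 0:9))
}
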