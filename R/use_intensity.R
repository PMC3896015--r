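#' Count individuals per population and relative track day
#'
#' The per-day sample size n_jt: the number of distinct individuals of
#' population j that have a position estimate on relative track day t. Days
#' removed by gap filtering do not count, so n_jt need not be non-increasing
#' in t.
#'
#' @param tracks Preprocessed track data frame with `population` and
#'   `relative_day` columns (see [preprocess_tracks()]).
#' @return A data frame with columns `population`, `relative_day`, `n`.
#' @export
count_individuals_per_day <- function(tracks) {
  stopifnot(all(c("turtle_id", "population", "relative_day") %in% names(tracks)))
  u <- unique(tracks[, c("turtle_id", "population", "relative_day")])
  agg <- stats::aggregate(turtle_id ~ population + relative_day, data = u,
                          FUN = length)
  names(agg)[names(agg) == "turtle_id"] <- "n"
  agg <- agg[order(agg$population, agg$relative_day), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Threshold relative track day
#'
#' Inverse-sample-size weighting gives high leverage to the few positions
#' from the longest tracks. To cap that leverage, positions beyond a
#' threshold relative day receive the same weight as on the threshold day.
#' The threshold is the `q`-quantile (default 85th percentile) of the
#' position-day distribution: the smallest day d such that the cumulative
#' fraction of all position-days at days <= d reaches `q`.
#'
#' @param counts Per-day sample sizes from [count_individuals_per_day()].
#' @param population Population label to compute the threshold for.
#' @param q Cumulative-fraction cutoff in (0, 1\]. Default 0.85.
#' @return A single integer relative day.
#' @export
threshold_day <- function(counts, population, q = 0.85) {
  stopifnot(q > 0, q <= 1)
  cc <- counts[counts$population == population, , drop = FALSE]
  if (!nrow(cc)) {
    stop(sprintf("no positions for population '%s'", population), call. = FALSE)
  }
  cc <- cc[order(cc$relative_day), , drop = FALSE]
  frac <- cumsum(cc$n) / sum(cc$n)
  cc$relative_day[which(frac >= q)[1L]]
}

#' Threshold days for every population present
#'
#' @inheritParams threshold_day
#' @return A data frame with columns `population`, `threshold_day`.
#' @export
threshold_days <- function(counts, q = 0.85) {
  pops <- unique(counts$population)
  data.frame(
    population = pops,
    threshold_day = vapply(pops, function(p) threshold_day(counts, p, q),
                           numeric(1))
  )
}

#' Inverse-sample-size weight for one relative day
#'
#' The weight for a position at relative day t of a turtle in population j is
#' 1 / n_jt for t at or below the population's threshold day T_j, and
#' 1 / n_(j,T_j) beyond it. Summed over the n_jt individuals present on any
#' day t <= T_j the weights add to exactly 1, so each tracked day of the
#' population contributes equally regardless of how many tags were still
#' transmitting.
#'
#' @param counts Per-day sample sizes from [count_individuals_per_day()].
#' @param population Population label.
#' @param t Relative track day (vectorized).
#' @param T_j The population's threshold day from [threshold_day()].
#' @return Numeric vector of weights.
#' @export
daily_weight <- function(counts, population, t, T_j) {
  cc <- counts[counts$population == population, , drop = FALSE]
  t_eff <- pmin(t, T_j)
  n <- cc$n[match(t_eff, cc$relative_day)]
  if (anyNA(n) || any(n < 1)) {
    stop(sprintf("no sample-size entry for population '%s' at day(s) %s",
                 population,
                 paste(utils::head(unique(t_eff[is.na(n)]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  1 / n
}

#' Attach weights, cells and quarters to track positions
#'
#' Computes the per-day sample-size table and threshold days, evaluates the
#' inverse-sample-size weight for every position, and bins each position into
#' its grid cell and calendar quarter.
#'
#' @param tracks Preprocessed track data frame (see [preprocess_tracks()]).
#' @param spec A [grid_spec()].
#' @param q Threshold-day cumulative fraction; default 0.85.
#' @return A data frame of weighted positions: `turtle_id`, `population`,
#'   `date`, `relative_day`, `lat`, `lon`, `lat_lo`, `lon_lo`, `quarter`,
#'   `omega`. Threshold days are attached as attribute `threshold_days`.
#' @export
weight_positions <- function(tracks, spec = grid_spec(), q = 0.85) {
  counts <- count_individuals_per_day(tracks)
  thr <- threshold_days(counts, q)
  omega <- numeric(nrow(tracks))
  for (p in thr$population) {
    rows <- tracks$population == p
    T_j <- thr$threshold_day[thr$population == p]
    omega[rows] <- daily_weight(counts, p, tracks$relative_day[rows], T_j)
  }
  cells <- bin_position(tracks$lat, tracks$lon, spec)
  out <- data.frame(
    turtle_id = tracks$turtle_id,
    population = tracks$population,
    date = tracks$date,
    relative_day = tracks$relative_day,
    lat = tracks$lat, lon = tracks$lon,
    lat_lo = cells$lat_lo, lon_lo = cells$lon_lo,
    quarter = quarter_of(tracks$date),
    omega = omega
  )
  attr(out, "threshold_days") <- thr
  out
}

#' Quarterly cross-population inflation factors
#'
#' Tag deployments are not balanced across populations, so within each
#' quarter the population with fewer raw position estimates is inflated by
#' x / y, where x and y are the larger and smaller raw position counts for
#' that quarter. The better-sampled population gets factor 1, as does a
#' population alone in a quarter. Counts are raw positions, not weights.
#'
#' @param positions Weighted positions from [weight_positions()] (only the
#'   `population` and `quarter` columns are used).
#' @return A data frame with columns `population`, `quarter`, `n_positions`,
#'   `inflation`.
#' @export
quarter_inflation <- function(positions) {
  if (!nrow(positions)) {
    return(data.frame(population = character(), quarter = integer(),
                      n_positions = integer(), inflation = numeric()))
  }
  tab <- stats::aggregate(rep(1L, nrow(positions)),
                          by = list(population = positions$population,
                                    quarter = positions$quarter),
                          FUN = sum)
  names(tab)[names(tab) == "x"] <- "n_positions"
  tab$inflation <- 1
  for (qtr in unique(tab$quarter)) {
    rows <- which(tab$quarter == qtr)
    if (length(rows) < 2L) next
    n <- tab$n_positions[rows]
    x <- max(n)
    tab$inflation[rows] <- ifelse(n < x, x / n, 1)
  }
  tab <- tab[order(tab$quarter, tab$population), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Accumulate weighted positions into per-population use-intensity fields
#'
#' Sums omega x inflation over the positions binned into each (cell, quarter)
#' separately for each population. Cell-quarters never visited by a
#' population are absent from its field, i.e. masked as no-data.
#'
#' @param positions Weighted positions from [weight_positions()].
#' @param spec A [grid_spec()].
#' @param inflation Quarterly inflation factors; defaults to
#'   [quarter_inflation()] of `positions`. Pass a table with all factors 1 to
#'   skip inflation.
#' @return A named list of `quarterly_field` objects, one per population.
#' @export
accumulate_use <- function(positions, spec = grid_spec(),
                           inflation = quarter_inflation(positions)) {
  key <- paste(positions$population, positions$quarter)
  ikey <- paste(inflation$population, inflation$quarter)
  fac <- inflation$inflation[match(key, ikey)]
  fac[is.na(fac)] <- 1
  contrib <- positions$omega * fac
  pops <- sort(unique(positions$population))
  out <- lapply(pops, function(p) {
    rows <- positions$population == p
    df <- data.frame(lat_lo = positions$lat_lo[rows],
                     lon_lo = positions$lon_lo[rows],
                     quarter = positions$quarter[rows],
                     value = contrib[rows])
    agg <- stats::aggregate(value ~ lat_lo + lon_lo + quarter, data = df,
                            FUN = sum)
    as_quarterly_field(agg, spec)
  })
  names(out) <- pops
  out
}

#' End-to-end use-intensity surfaces from preprocessed tracks
#'
#' Convenience wrapper: weight positions, compute quarterly inflation, and
#' accumulate per-population use-intensity fields.
#'
#' @inheritParams weight_positions
#' @return A list with elements `fields` (named list of `quarterly_field`),
#'   `positions` (the weighted-position table), `inflation` and
#'   `threshold_days` (diagnostics tables).
#' @export
use_intensity_fields <- function(tracks, spec = grid_spec(), q = 0.85) {
  positions <- weight_positions(tracks, spec, q)
  infl <- quarter_inflation(positions)
  fields <- accumulate_use(positions, spec, infl)
  list(fields = fields, positions = positions, inflation = infl,
       threshold_days = attr(positions, "threshold_days"))
}
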