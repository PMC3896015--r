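#' Assign relative track days
#'
#' Relative track day counts calendar days since each turtle's first position
#' (day 1 = first position), so holes left by removed or missing days persist
#' as holes rather than being renumbered. This keeps the per-day sample-size
#' table consistent with "individuals tracked on the same relative day".
#'
#' @param tracks Track data frame with columns `turtle_id`, `population`,
#'   `date`, `lat`, `lon`.
#' @return The same data frame, date-sorted within turtle, with an integer
#'   `relative_day` column added.
#' @export
assign_relative_days <- function(tracks) {
  stopifnot(all(c("turtle_id", "date") %in% names(tracks)))
  tracks <- tracks[order(tracks$turtle_id, tracks$date), , drop = FALSE]
  dup <- tapply(tracks$date, tracks$turtle_id, anyDuplicated)
  if (any(dup > 0)) {
    stop("duplicate dates within track(s): ",
         paste(names(dup)[dup > 0], collapse = ", "), call. = FALSE)
  }
  first <- stats::ave(as.numeric(tracks$date), tracks$turtle_id, FUN = min)
  tracks$relative_day <- as.integer(as.numeric(tracks$date) - first) + 1L
  rownames(tracks) <- NULL
  tracks
}

#' Remove daily positions inside long observation gaps
#'
#' Daily position estimates are produced by a track filter even across spells
#' when the tag did not transmit; positions falling strictly inside an
#' inter-observation gap longer than `max_gap_days` days are too uncertain
#' and are removed. Positions on the bounding observation days are kept, and
#' `relative_day` values are preserved (not renumbered), so removal leaves
#' holes in the day sequence.
#'
#' Observation days are taken from, in order of preference: the
#' `observation_dates` argument (a data frame with columns `turtle_id`,
#' `date`); a logical `observed` column on `tracks`; or, for pre-regularized
#' input with neither, the dates present in the track itself (in which case
#' gaps are already holes and nothing can fall inside one).
#'
#' @param tracks Track data frame, typically from [assign_relative_days()].
#' @param max_gap_days Gaps of more than this many missing days trigger
#'   removal. Default 20.
#' @param observation_dates Optional data frame of raw transmission days.
#' @return The filtered track data frame. Turtles whose positions are all
#'   removed are dropped with a message.
#' @export
remove_gap_positions <- function(tracks, max_gap_days = 20,
                                 observation_dates = NULL) {
  stopifnot(all(c("turtle_id", "date") %in% names(tracks)))
  if (!is.null(observation_dates)) {
    stopifnot(all(c("turtle_id", "date") %in% names(observation_dates)))
    obs_split <- split(as.Date(observation_dates$date),
                       observation_dates$turtle_id)
  } else if ("observed" %in% names(tracks)) {
    kept <- tracks[tracks$observed, c("turtle_id", "date")]
    obs_split <- split(as.Date(kept$date), kept$turtle_id)
  } else {
    obs_split <- split(as.Date(tracks$date), tracks$turtle_id)
  }
  keep <- rep(TRUE, nrow(tracks))
  for (id in unique(tracks$turtle_id)) {
    rows <- which(tracks$turtle_id == id)
    obs <- sort(unique(obs_split[[as.character(id)]]))
    if (length(obs) < 2L) next
    d <- tracks$date[rows]
    gap_len <- as.integer(diff(obs)) - 1L  # missing days between observations
    long <- which(gap_len > max_gap_days)
    for (g in long) {
      keep[rows[d > obs[g] & d < obs[g + 1L]]] <- FALSE
    }
  }
  dropped_all <- setdiff(unique(tracks$turtle_id),
                         unique(tracks$turtle_id[keep]))
  if (length(dropped_all)) {
    message("dropping track(s) with no positions left after gap removal: ",
            paste(dropped_all, collapse = ", "))
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess raw daily tracks for the use-intensity analysis
#'
#' Runs the standard ingest sequence: sort and assign calendar-based relative
#' track days, then remove positions inside observation gaps longer than
#' `max_gap_days`.
#'
#' @inheritParams remove_gap_positions
#' @return The preprocessed track data frame with `relative_day` set.
#' @export
preprocess_tracks <- function(tracks, max_gap_days = 20,
                              observation_dates = NULL) {
  tracks <- assign_relative_days(tracks)
  remove_gap_positions(tracks, max_gap_days = max_gap_days,
                       observation_dates = observation_dates)
}

#' Per-track quality-control summary
#'
#' @param raw,clean Track data frames before and after preprocessing.
#' @return A data frame with one row per turtle: population, deployment date,
#'   duration in days, positions before and after gap removal, and positions
#'   removed.
#' @export
track_qc <- function(raw, clean) {
  ids <- unique(raw$turtle_id)
  do.call(rbind, lapply(ids, function(id) {
    r <- raw[raw$turtle_id == id, ]
    k <- clean[clean$turtle_id == id, ]
    data.frame(
      turtle_id = id,
      population = r$population[1],
      deployed = min(r$date),
      duration_days = as.integer(max(r$date) - min(r$date)) + 1L,
      n_raw = nrow(r),
      n_kept = nrow(k),
      n_removed = nrow(r) - nrow(k)
    )
  }))
}
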