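#' Convert a raw field to relative probabilities
#'
#' Divides every non-masked value by the field total so the result sums to
#' one over all cells and all four quarters combined. Applied to a use
#' surface this is the likelihood that a turtle occupies cell i in quarter t
#' relative to all other cell-quarters; applied to effective effort it is
#' the corresponding probability of fishing effort. Normalizing across
#' quarters jointly (rather than within each quarter) keeps the four
#' seasonal maps directly comparable.
#'
#' @param f A `quarterly_field` with non-negative values and positive total.
#' @return A `quarterly_field` whose values sum to 1; the mask (absent rows)
#'   is preserved.
#' @export
relative_probability <- function(f) {
  stopifnot(inherits(f, "quarterly_field"))
  if (!nrow(f)) stop("field has no non-masked cells", call. = FALSE)
  if (any(f$value < 0)) stop("field values must be non-negative", call. = FALSE)
  total <- field_sum(f)
  if (total <= 0) stop("field total must be positive", call. = FALSE)
  out <- as.data.frame(f)
  out$value <- out$value / total
  as_quarterly_field(out, attr(f, "grid_spec"))
}

#' Normalized turtle-fishery interaction index
#'
#' The interaction index in cell i, quarter t is the product of the turtle
#' occupancy probability and the effort probability there, renormalized so
#' the index sums to one over all jointly non-masked cell-quarters. It is a
#' relative bycatch-risk surface: the share of expected turtle-hook
#' co-occurrence attributable to each cell-quarter, not an absolute bycatch
#' rate. A cell-quarter masked in either input is masked in the output and
#' excluded from the denominator.
#'
#' @param pt Turtle relative-probability field from [relative_probability()].
#' @param pe Effort relative-probability field on the same [grid_spec()].
#' @return A `quarterly_field` summing to 1 over its support, with attribute
#'   `provenance` carrying input identifiers when supplied.
#' @param provenance Optional character vector recorded on the result.
#' @export
interaction_index <- function(pt, pe, provenance = NULL) {
  stopifnot(inherits(pt, "quarterly_field"), inherits(pe, "quarterly_field"))
  if (!identical(attr(pt, "grid_spec"), attr(pe, "grid_spec"))) {
    stop("inputs are on different grid specs", call. = FALSE)
  }
  key_t <- paste(pt$lat_lo, pt$lon_lo, pt$quarter)
  key_e <- paste(pe$lat_lo, pe$lon_lo, pe$quarter)
  m <- match(key_t, key_e)
  joint <- which(!is.na(m))
  prod_val <- pt$value[joint] * pe$value[m[joint]]
  denom <- sum(prod_val)
  if (!length(joint) || denom <= 0) {
    stop(sprintf(paste0(
      "no joint support between turtle and effort fields ",
      "(turtle: %d cell-quarters, effort: %d, overlapping: %d, ",
      "overlap product total: %g)"),
      nrow(pt), nrow(pe), length(joint),
      if (length(joint)) denom else 0), call. = FALSE)
  }
  out <- data.frame(lat_lo = pt$lat_lo[joint], lon_lo = pt$lon_lo[joint],
                    quarter = pt$quarter[joint], value = prod_val / denom)
  out <- as_quarterly_field(out, attr(pt, "grid_spec"))
  attr(out, "provenance") <- provenance
  out
}

#' Rank bycatch-risk hotspots
#'
#' Orders cell-quarters by descending interaction index. Ties are broken by
#' ascending quarter, then cell latitude, then longitude, so rankings are
#' deterministic. Select either the top `k` entries or all entries at or
#' above the upper quantile `q` of the index values.
#'
#' @param surface An interaction surface (any `quarterly_field`).
#' @param k Number of top entries to return.
#' @param q Alternatively, an upper quantile in (0, 1): return entries with
#'   index >= `quantile(value, q)`.
#' @return A data frame `rank`, `lat_lo`, `lon_lo`, `quarter`, `value` sorted
#'   by rank. If `k` exceeds the support size all entries are returned with a
#'   warning.
#' @export
top_hotspots <- function(surface, k = NULL, q = NULL) {
  stopifnot(inherits(surface, "quarterly_field"))
  if (is.null(k) == is.null(q)) {
    stop("supply exactly one of `k` or `q`", call. = FALSE)
  }
  o <- order(-surface$value, surface$quarter, surface$lat_lo, surface$lon_lo)
  ranked <- as.data.frame(surface)[o, , drop = FALSE]
  if (!is.null(k)) {
    stopifnot(k >= 1)
    if (k > nrow(ranked)) {
      warning(sprintf("k = %d exceeds support size %d; returning all entries",
                      k, nrow(ranked)))
      k <- nrow(ranked)
    }
    ranked <- ranked[seq_len(k), , drop = FALSE]
  } else {
    stopifnot(q > 0, q < 1)
    cut <- stats::quantile(surface$value, q, names = FALSE)
    ranked <- ranked[ranked$value >= cut, , drop = FALSE]
  }
  out <- cbind(rank = seq_len(nrow(ranked)), ranked)
  rownames(out) <- NULL
  out
}
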