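#' Read and write quarterly fields as delimited text
#'
#' Fields serialize to tab-separated text with columns `lat_lo`, `lon_lo`,
#' `quarter`, `value`; absent rows are masked (no-data) cell-quarters.
#'
#' @param f A `quarterly_field`.
#' @param path File path.
#' @param spec The [grid_spec()] to validate against when reading.
#' @return `write_field()` returns `path` invisibly; `read_field()` returns a
#'   `quarterly_field`.
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "quarterly_field"))
  utils::write.table(as.data.frame(f), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, spec = grid_spec()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_quarterly_field(df, spec)
}

#' Export a quarterly field as GeoJSON cell polygons
#'
#' Writes one polygon feature per non-masked cell-quarter with properties
#' `lat_lo`, `lon_lo`, `quarter` and `value`, for choropleth mapping in any
#' GeoJSON-aware tool. Longitudes at or beyond 180 are shifted to the
#' \[-180, 180\] convention GeoJSON expects.
#'
#' @param f A `quarterly_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
field_to_geojson <- function(f, path) {
  stopifnot(inherits(f, "quarterly_field"))
  cs <- attr(f, "grid_spec")$cell_size
  gj_lon <- function(l) ifelse(l >= 180, l - 360, l)
  features <- lapply(seq_len(nrow(f)), function(i) {
    la <- f$lat_lo[i]
    lo <- gj_lon(f$lon_lo[i])
    ring <- list(c(lo, la), c(lo + cs, la), c(lo + cs, la + cs),
                 c(lo, la + cs), c(lo, la))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(lat_lo = f$lat_lo[i], lon_lo = f$lon_lo[i],
                       quarter = f$quarter[i], value = f$value[i])
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write daily track tables
#'
#' Tracks serialize to tab-separated text with columns `turtle_id`,
#' `population`, `date` (ISO-8601), `lat`, `lon` and optionally `observed`
#' (logical: whether the tag actually transmitted that day, as opposed to a
#' model-interpolated daily estimate). Validation errors name the offending
#' line so problems in hand-edited inputs can be located.
#'
#' @param tracks A track data frame.
#' @param path File path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()` returns
#'   a validated track data frame with `date` parsed to `Date`.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("turtle_id", "population", "date", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop(sprintf("unparseable date at line(s): %s",
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df$date <- dates
  bad <- which(!is.finite(df$lat) | !is.finite(df$lon) | abs(df$lat) > 90)
  if (length(bad)) {
    stop(sprintf("invalid coordinates at line(s): %s",
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read and write gridded catch tables
#'
#' Catch tables are tab-separated with columns `lat_lo`, `lon_lo`, `quarter`,
#' `species_group`, `tonnes`; several rows per cell-quarter (e.g. per species
#' or per year) are allowed and are pooled downstream.
#'
#' @param catch A catch data frame.
#' @param path File path.
#' @return `write_catch()` returns `path` invisibly; `read_catch()` returns
#'   the validated data frame.
#' @export
write_catch <- function(catch, path) {
  utils::write.table(catch, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_catch
#' @export
read_catch <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lat_lo", "lon_lo", "quarter", "species_group", "tonnes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("catch file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$tonnes) | df$tonnes < 0)) {
    stop("catch tonnage must be finite and non-negative", call. = FALSE)
  }
  df
}
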