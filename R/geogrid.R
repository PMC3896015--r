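#' Grid specification for quarterly 5-degree fields
#'
#' Defines the spatial binning convention shared by every gridded quantity in
#' the package: square cells of `cell_size` degrees, anchored at multiples of
#' the cell size, with longitudes handled internally on \[0, 360) so the
#' Pacific basin (and the antimeridian) is contiguous.
#'
#' @param cell_size Cell edge length in degrees. Must divide both 360 and 180
#'   evenly. The default of 5 matches the resolution at which public longline
#'   effort statistics are reported.
#' @param lon_origin Longitude of the western edge of the first cell column,
#'   in degrees on \[0, 360). Cells are anchored at
#'   `lon_origin + k * cell_size`.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec()
#' grid_spec(cell_size = 10)
#' @export
grid_spec <- function(cell_size = 5, lon_origin = 0) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (360 %% cell_size != 0 || 180 %% cell_size != 0) {
    stop("`cell_size` must divide both 360 and 180 evenly", call. = FALSE)
  }
  if (!is.numeric(lon_origin) || length(lon_origin) != 1L || !is.finite(lon_origin)) {
    stop("`lon_origin` must be a single finite number", call. = FALSE)
  }
  structure(
    list(cell_size = cell_size, lon_origin = lon_origin %% 360),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %g x %g degree cells, lon origin %g, lon on [0,360)>\n",
              x$cell_size, x$cell_size, x$lon_origin))
  invisible(x)
}

#' Map longitudes onto the internal \[0, 360) convention
#'
#' Accepts longitudes given on either \[-180, 180\] or \[0, 360) and returns
#' the equivalent value on \[0, 360). Idempotent.
#'
#' @param lon Numeric vector of longitudes in degrees.
#' @return Numeric vector on \[0, 360).
#' @export
wrap_lon <- function(lon) {
  lon %% 360
}

#' Assign positions to grid cells
#'
#' Bins point coordinates into half-open cells
#' `[lat_lo, lat_lo + cs) x [lon_lo, lon_lo + cs)`. Longitudes are first
#' remapped to \[0, 360); `lat = 90` is folded into the topmost row so every
#' valid point belongs to exactly one cell.
#'
#' @param lat,lon Numeric vectors of coordinates in degrees; `lat` on
#'   \[-90, 90\], `lon` on either \[-180, 180\] or \[0, 360).
#' @param spec A [grid_spec()].
#' @return A data frame with columns `lat_lo` and `lon_lo` (cell lower edges,
#'   one row per input point).
#' @examples
#' bin_position(c(0.1, -12.3), c(180, -80))
#' @export
bin_position <- function(lat, lon, spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(lat) != length(lon)) {
    stop("`lat` and `lon` must have the same length", call. = FALSE)
  }
  bad <- which(!is.finite(lat) | !is.finite(lon))
  if (length(bad)) {
    stop(sprintf("non-finite coordinates at record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out_of_range <- which(abs(lat) > 90)
  if (length(out_of_range)) {
    stop(sprintf("latitude outside [-90, 90] at record(s): %s",
                 paste(utils::head(out_of_range, 5L), collapse = ", ")),
         call. = FALSE)
  }
  cs <- spec$cell_size
  lon <- (wrap_lon(lon) - spec$lon_origin) %% 360
  lat_lo <- pmin(floor(lat / cs) * cs, 90 - cs)  # fold lat = 90 into top row
  lon_lo <- (floor(lon / cs) * cs + spec$lon_origin) %% 360
  data.frame(lat_lo = lat_lo, lon_lo = lon_lo)
}

#' Calendar quarter of a date
#'
#' Quarters follow the annual convention Q1 = January--March,
#' Q2 = April--June, Q3 = July--September, Q4 = October--December.
#'
#' @param dates A `Date` vector (or something coercible via [as.Date()]).
#' @return Integer vector with values in 1:4.
#' @examples
#' quarter_of(as.Date(c("1995-01-15", "2008-12-31")))
#' @export
quarter_of <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date(s) in input", call. = FALSE)
  as.integer(as.POSIXlt(dates)$mon %/% 3L + 1L)
}

#' Construct a quarterly gridded field
#'
#' The shared container for every gridded quantity in the pipeline: use
#' intensity, hooks, effective effort, relative probabilities and the
#' interaction index. A field is a long-format data frame with one row per
#' non-masked (cell, quarter); cell-quarters *absent* from the table are
#' masked as no-data and excluded from all sums and normalizations. A stored
#' zero is a real zero, not missing data.
#'
#' @param lat_lo,lon_lo Cell lower edges in degrees (multiples of the cell
#'   size; `lon_lo` on \[0, 360)).
#' @param quarter Integer quarter in 1:4.
#' @param value Finite numeric values.
#' @param spec The [grid_spec()] the cells refer to.
#' @return An object of classes `quarterly_field` and `data.frame` with
#'   columns `lat_lo`, `lon_lo`, `quarter`, `value` and a `grid_spec`
#'   attribute.
#' @export
quarterly_field <- function(lat_lo = numeric(), lon_lo = numeric(),
                            quarter = integer(), value = numeric(),
                            spec = grid_spec()) {
  df <- data.frame(lat_lo = as.numeric(lat_lo), lon_lo = as.numeric(lon_lo),
                   quarter = as.integer(quarter), value = as.numeric(value))
  as_quarterly_field(df, spec)
}

#' Validate and class a data frame as a quarterly field
#'
#' @param df Data frame with columns `lat_lo`, `lon_lo`, `quarter`, `value`.
#' @param spec The [grid_spec()] the cells refer to.
#' @return A `quarterly_field`.
#' @export
as_quarterly_field <- function(df, spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  need <- c("lat_lo", "lon_lo", "quarter", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("field is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$quarter <- as.integer(df$quarter)
  cs <- spec$cell_size
  if (nrow(df)) {
    if (!all(df$quarter %in% 1:4)) stop("quarter must be in 1:4", call. = FALSE)
    if (!all(is.finite(df$value))) stop("field values must be finite", call. = FALSE)
    edges_ok <- abs((df$lat_lo / cs) - round(df$lat_lo / cs)) < 1e-9 &
      abs(((df$lon_lo - spec$lon_origin) / cs) -
            round((df$lon_lo - spec$lon_origin) / cs)) < 1e-9
    if (!all(edges_ok)) {
      stop("cell edges must be multiples of the cell size", call. = FALSE)
    }
    key <- paste(df$lat_lo, df$lon_lo, df$quarter)
    if (anyDuplicated(key)) {
      stop("duplicate (cell, quarter) entries in field", call. = FALSE)
    }
    o <- order(df$quarter, df$lat_lo, df$lon_lo)
    df <- df[o, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, grid_spec = spec, class = c("quarterly_field", "data.frame"))
}

#' @export
print.quarterly_field <- function(x, ...) {
  spec <- attr(x, "grid_spec")
  cat(sprintf("<quarterly_field: %d non-masked cell-quarters, %g-degree cells, total %.6g>\n",
              nrow(x), spec$cell_size, field_sum(x)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Total of a quarterly field over its non-masked support
#'
#' Masked (absent) cell-quarters contribute nothing. This is the denominator
#' used when converting raw fields to relative probabilities.
#'
#' @param f A `quarterly_field`.
#' @return A single number.
#' @export
field_sum <- function(f) {
  stopifnot(inherits(f, "quarterly_field"))
  # base sum() accumulates in extended precision, which serves as the
  # compensated-summation policy for all denominators
  sum(f$value)
}

#' Merge quarterly fields additively
#'
#' Values for cell-quarters present in several inputs are summed; the merged
#' support is the union of the inputs' supports. Used, for example, to build
#' a combined-population use surface from per-population fields.
#'
#' @param ... `quarterly_field` objects on the same [grid_spec()].
#' @return A `quarterly_field`.
#' @export
field_merge <- function(...) {
  fields <- list(...)
  if (!length(fields)) stop("no fields to merge", call. = FALSE)
  stopifnot(all(vapply(fields, inherits, logical(1), "quarterly_field")))
  specs <- lapply(fields, attr, "grid_spec")
  same <- vapply(specs, function(s) identical(s, specs[[1]]), logical(1))
  if (!all(same)) stop("fields are on different grid specs", call. = FALSE)
  df <- do.call(rbind, lapply(fields, as.data.frame))
  agg <- stats::aggregate(value ~ lat_lo + lon_lo + quarter, data = df, FUN = sum)
  as_quarterly_field(agg, specs[[1]])
}
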