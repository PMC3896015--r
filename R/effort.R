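#' Gear parameters for longline bycatch probability
#'
#' Longline sets rigged for billfish fish shallower than sets rigged for
#' tuna, and epipelagic turtles are far more likely to encounter shallow
#' hooks. The defaults are published fleet-average values: capture rates of
#' 0.0246 and 0.0048 turtles per set in billfish and tuna configurations,
#' and typical set sizes of 850 hooks (billfish) and 1124 hooks (tuna).
#'
#' @param rate_billfish_per_set Turtles captured per billfish-configured set.
#' @param rate_tuna_per_set Turtles captured per tuna-configured set.
#' @param hooks_per_set_tuna Hooks in a typical tuna set.
#' @param hooks_per_set_billfish Hooks in a typical billfish set.
#' @return An object of class `gear_params`.
#' @export
gear_params <- function(rate_billfish_per_set = 0.0246,
                        rate_tuna_per_set = 0.0048,
                        hooks_per_set_tuna = 1124,
                        hooks_per_set_billfish = 850) {
  vals <- c(rate_billfish_per_set, rate_tuna_per_set,
            hooks_per_set_tuna, hooks_per_set_billfish)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("all gear parameters must be positive and finite", call. = FALSE)
  }
  structure(
    list(rate_billfish_per_set = rate_billfish_per_set,
         rate_tuna_per_set = rate_tuna_per_set,
         hooks_per_set_tuna = hooks_per_set_tuna,
         hooks_per_set_billfish = hooks_per_set_billfish),
    class = "gear_params"
  )
}

#' Relative catchability index of billfish versus tuna gear
#'
#' Per-set capture rates are converted to a per-hook basis using the typical
#' hooks per set of each configuration, and the index is the per-hook capture
#' rate in billfish sets divided by that in tuna sets. With the default
#' parameters the index is about 6.8: a turtle is roughly 6.8 times more
#' likely to be caught on a billfish-set hook than on a tuna-set hook.
#'
#' @param g A [gear_params()] object.
#' @return A single positive number (tuna-hook-equivalents per billfish hook).
#' @examples
#' round(catchability_index(gear_params()), 1)
#' @export
catchability_index <- function(g = gear_params()) {
  stopifnot(inherits(g, "gear_params"))
  per_hook_billfish <- g$rate_billfish_per_set / g$hooks_per_set_billfish
  per_hook_tuna <- g$rate_tuna_per_set / g$hooks_per_set_tuna
  per_hook_billfish / per_hook_tuna
}

#' Default species-group lookup for catch tables
#'
#' Maps the species labels found in public longline catch statistics onto
#' the two gear-relevant groups. Extend or replace to match a given catch
#' table's species list.
#'
#' @return A named character vector: names are species labels (lower case),
#'   values are `"tuna"` or `"billfish"`.
#' @export
default_species_lookup <- function() {
  c(tuna = "tuna", albacore = "tuna", bigeye = "tuna", yellowfin = "tuna",
    skipjack = "tuna", bluefin = "tuna",
    billfish = "billfish", swordfish = "billfish", marlin = "billfish",
    sailfish = "billfish", spearfish = "billfish")
}

#' Billfish fraction of the catch per cell-quarter
#'
#' Pools catch tonnage over all rows (years, species within group) for each
#' cell-quarter and returns the billfish proportion of the total catch by
#' weight, used as an estimate of the relative effort targeting billfish.
#' Cell-quarters with zero total catch are masked (absent from the result).
#'
#' @param catch Data frame with columns `lat_lo`, `lon_lo`, `quarter`,
#'   `species_group`, `tonnes`.
#' @param lookup Named character vector mapping species labels to `"tuna"` or
#'   `"billfish"`; see [default_species_lookup()].
#' @return A data frame with columns `lat_lo`, `lon_lo`, `quarter`,
#'   `billfish_t`, `tuna_t`, `p` (billfish fraction in \[0, 1\]), with the
#'   basin-wide pooled fraction attached as attribute `pooled_p`.
#' @export
billfish_fraction <- function(catch, lookup = default_species_lookup()) {
  need <- c("lat_lo", "lon_lo", "quarter", "species_group", "tonnes")
  stopifnot(all(need %in% names(catch)))
  if (any(!is.finite(catch$tonnes) | catch$tonnes < 0)) {
    stop("catch tonnage must be finite and non-negative", call. = FALSE)
  }
  grp <- unname(lookup[tolower(catch$species_group)])
  unknown <- unique(catch$species_group[is.na(grp)])
  if (length(unknown)) {
    stop("species group(s) not in lookup: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(lat_lo = catch$lat_lo, lon_lo = catch$lon_lo,
                   quarter = as.integer(catch$quarter), group = grp,
                   tonnes = catch$tonnes)
  agg <- stats::aggregate(tonnes ~ lat_lo + lon_lo + quarter + group,
                          data = df, FUN = sum)
  wide <- stats::reshape(agg, direction = "wide", timevar = "group",
                         idvar = c("lat_lo", "lon_lo", "quarter"))
  bt <- wide[["tonnes.billfish"]]
  tt <- wide[["tonnes.tuna"]]
  if (is.null(bt)) bt <- rep(0, nrow(wide))
  if (is.null(tt)) tt <- rep(0, nrow(wide))
  bt[is.na(bt)] <- 0
  tt[is.na(tt)] <- 0
  total <- bt + tt
  out <- data.frame(lat_lo = wide$lat_lo, lon_lo = wide$lon_lo,
                    quarter = wide$quarter,
                    billfish_t = bt, tuna_t = tt)
  out <- out[total > 0, , drop = FALSE]
  out$p <- out$billfish_t / (out$billfish_t + out$tuna_t)
  out <- out[order(out$quarter, out$lat_lo, out$lon_lo), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pooled_p") <- sum(out$billfish_t) / sum(out$billfish_t + out$tuna_t)
  out
}

#' Adjust raw hooks for gear-specific bycatch probability
#'
#' Converts raw hooks to effective effort in tuna-hook-equivalent units. In
#' the default `"mix"` mode each cell-quarter's hooks are split by the local
#' billfish catch fraction p into a billfish-targeted share (scaled by the
#' catchability index c) and a tuna-targeted share (the reference gear,
#' scaled by 1): E = hooks x (p c + (1 - p)). The `"literal"` mode instead
#' multiplies every cell's hooks by c regardless of composition; with a
#' spatially constant p the two modes yield identical normalized effort
#' probabilities.
#'
#' Cell-quarters with hooks but no catch-composition estimate get the
#' fallback fraction `fill_p` (default: the basin-wide pooled fraction from
#' `comp`) rather than being dropped, so patchy catch reporting does not
#' silently shrink the effort surface. The output is masked exactly where
#' `hooks` is masked.
#'
#' @param hooks A `quarterly_field` of raw hooks.
#' @param comp Catch composition from [billfish_fraction()] (ignored in
#'   `"literal"` mode).
#' @param c_index Catchability index from [catchability_index()].
#' @param mode `"mix"` (composition-weighted, default) or `"literal"`.
#' @param fill_p Billfish fraction for cells lacking composition data.
#' @return A `quarterly_field` of effective effort.
#' @export
adjust_effort <- function(hooks, comp, c_index = catchability_index(),
                          mode = c("mix", "literal"), fill_p = NULL) {
  stopifnot(inherits(hooks, "quarterly_field"))
  mode <- match.arg(mode)
  if (!is.finite(c_index) || c_index <= 0) {
    stop("catchability index must be positive", call. = FALSE)
  }
  if (any(hooks$value < 0)) stop("hooks must be non-negative", call. = FALSE)
  if (mode == "literal") {
    out <- as.data.frame(hooks)
    out$value <- out$value * c_index
    return(as_quarterly_field(out, attr(hooks, "grid_spec")))
  }
  if (is.null(fill_p)) fill_p <- attr(comp, "pooled_p")
  if (is.null(fill_p) || !is.finite(fill_p)) {
    stop("no composition data and no `fill_p` fallback", call. = FALSE)
  }
  stopifnot(fill_p >= 0, fill_p <= 1)
  key_h <- paste(hooks$lat_lo, hooks$lon_lo, hooks$quarter)
  key_c <- paste(comp$lat_lo, comp$lon_lo, comp$quarter)
  p <- comp$p[match(key_h, key_c)]
  p[is.na(p)] <- fill_p
  out <- as.data.frame(hooks)
  out$value <- out$value * (p * c_index + (1 - p))
  as_quarterly_field(out, attr(hooks, "grid_spec"))
}
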