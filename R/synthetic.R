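#' Configuration for the synthetic track generator
#'
#' The generator emulates the daily position estimates a state-space track
#' filter would produce for satellite-tagged sea turtles: staggered
#' deployments over a multi-year window, one position per deployment day,
#' heavy-tailed track durations, transmission gaps, and movement from a
#' two-state switching correlated random walk (fast, directed transiting
#' toward waypoints versus slow, high-turning area-restricted search inside
#' a population's foraging region). Two populations with non-overlapping
#' geographies mirror the East Pacific (EP) and West Pacific (WP) nesting
#' stocks.
#'
#' Track durations are drawn from a lognormal truncated to
#' `[duration_min, duration_max]` days; the default meanlog/sdlog give a
#' truncated mean of about 209 days with a minimum of 4 and maximum of 948,
#' matching published Pacific leatherback tracking summaries. Transmission
#' gaps start with probability `gap_start_prob` per day and have geometric
#' lengths with mean `gap_mean_length`, giving appreciable mass beyond 20
#' days so the long-gap removal rule is exercised.
#'
#' @param n_ep,n_wp Number of turtles per population (either may be 0, not
#'   both).
#' @param deployment_start,deployment_end Deployment window (`Date`).
#' @param duration_meanlog,duration_sdlog Lognormal parameters of track
#'   duration in days.
#' @param duration_min,duration_max Truncation bounds in days.
#' @param gap_start_prob Daily probability that a transmission gap begins.
#' @param gap_mean_length Mean gap length in days (geometric).
#' @param gap_max_length Cap on gap length in days.
#' @param deploy_jitter SD in degrees of the deployment-location scatter.
#' @param geographies Population movement geographies; see
#'   [default_geographies()].
#' @return An object of class `track_sim_config`.
#' @export
track_sim_config <- function(n_ep = 80, n_wp = 55,
                             deployment_start = as.Date("1992-01-01"),
                             deployment_end = as.Date("2008-12-31"),
                             duration_meanlog = log(157),
                             duration_sdlog = 0.9,
                             duration_min = 4, duration_max = 948,
                             gap_start_prob = 0.01,
                             gap_mean_length = 8,
                             gap_max_length = 60,
                             deploy_jitter = 1.5,
                             geographies = default_geographies()) {
  stopifnot(n_ep >= 0, n_wp >= 0, n_ep + n_wp >= 1,
            deployment_end > deployment_start,
            duration_min >= 1, duration_max >= duration_min,
            gap_start_prob >= 0, gap_start_prob < 1,
            gap_mean_length >= 1, gap_max_length >= 1, deploy_jitter >= 0)
  validate_geographies(geographies)
  structure(
    list(n_ep = n_ep, n_wp = n_wp,
         deployment_start = deployment_start, deployment_end = deployment_end,
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         duration_min = duration_min, duration_max = duration_max,
         gap_start_prob = gap_start_prob, gap_mean_length = gap_mean_length,
         gap_max_length = gap_max_length, deploy_jitter = deploy_jitter,
         geographies = geographies),
    class = "track_sim_config"
  )
}

#' Default population movement geographies
#'
#' EP turtles deploy off Central America (about 10N, 275E), transit a
#' corridor toward the Galapagos region and forage across the South Pacific
#' Gyre (0--30S, 230--280E). WP turtles deploy off the Bird's Head region
#' (about 0S, 133E) and split between a South China Sea branch and a
#' central/north Pacific branch. Each population is confined to a bounding
#' envelope; the EP and WP envelopes do not share any 5-degree cell, so the
#' two populations' occupancies are disjoint at the grid level.
#'
#' @return A named list (one entry per population) of envelopes and movement
#'   branches (deployment point, transit waypoints, foraging box, branch
#'   probability).
#' @export
default_geographies <- function() {
  list(
    EP = list(
      envelope = list(lat = c(-35, 15), lon = c(225, 290)),
      branches = list(
        gyre = list(prob = 1,
                    deploy = c(10, 275),
                    waypoints = list(c(0, 265)),
                    box = list(lat = c(-30, 0), lon = c(230, 280)))
      )
    ),
    WP = list(
      envelope = list(lat = c(-10, 45), lon = c(105, 215)),
      branches = list(
        scs = list(prob = 0.5,
                   deploy = c(0, 133),
                   waypoints = list(c(5, 127), c(10, 118)),
                   box = list(lat = c(5, 20), lon = c(108, 120))),
        npac = list(prob = 0.5,
                    deploy = c(0, 133),
                    waypoints = list(c(8, 145), c(15, 165)),
                    box = list(lat = c(10, 40), lon = c(150, 210)))
      )
    )
  )
}

validate_geographies <- function(geo) {
  for (pop in names(geo)) {
    g <- geo[[pop]]
    rng <- c(g$envelope$lat,
             unlist(lapply(g$branches, function(b) b$box$lat)))
    if (any(rng < -90 | rng > 90)) {
      stop(sprintf("geography for '%s' has latitudes outside [-90, 90]", pop),
           call. = FALSE)
    }
    for (b in g$branches) {
      if (b$box$lat[1] < g$envelope$lat[1] || b$box$lat[2] > g$envelope$lat[2] ||
          b$box$lon[1] < g$envelope$lon[1] || b$box$lon[2] > g$envelope$lon[2]) {
        stop(sprintf("foraging box outside envelope for '%s'", pop),
             call. = FALSE)
      }
    }
    probs <- vapply(g$branches, function(b) b$prob, numeric(1))
    if (abs(sum(probs) - 1) > 1e-9) {
      stop(sprintf("branch probabilities for '%s' must sum to 1", pop),
           call. = FALSE)
    }
  }
  invisible(geo)
}

# truncated-lognormal duration in whole days
sample_duration <- function(cfg) {
  repeat {
    d <- round(stats::rlnorm(1, cfg$duration_meanlog, cfg$duration_sdlog))
    if (d >= cfg$duration_min && d <= cfg$duration_max) return(as.integer(d))
  }
}

reflect_into <- function(x, lo, hi) {
  # reflect once; values can only step a fraction of a degree past the edge
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo), hi)
}

simulate_one_track <- function(id, population, geo, cfg) {
  dur <- sample_duration(cfg)
  window_days <- as.integer(cfg$deployment_end - cfg$deployment_start) + 1L
  latest <- max(1L, window_days - dur + 1L)
  start <- cfg$deployment_start + sample.int(latest, 1L) - 1L

  probs <- vapply(geo$branches, function(b) b$prob, numeric(1))
  branch <- geo$branches[[sample.int(length(probs), 1L, prob = probs)]]
  env <- geo$envelope
  box <- branch$box

  lat <- reflect_into(branch$deploy[1] + stats::rnorm(1, 0, cfg$deploy_jitter),
                      env$lat[1], env$lat[2])
  lon <- reflect_into(branch$deploy[2] + stats::rnorm(1, 0, cfg$deploy_jitter),
                      env$lon[1], env$lon[2])

  # waypoint queue ends with points resampled inside the foraging box
  wps <- branch$waypoints
  sample_box_point <- function() c(stats::runif(1, box$lat[1], box$lat[2]),
                                   stats::runif(1, box$lon[1], box$lon[2]))
  target_i <- 1L
  target <- if (length(wps)) wps[[1L]] else sample_box_point()

  lat_out <- numeric(dur)
  lon_out <- numeric(dur)
  lat_out[1] <- lat
  lon_out[1] <- lon
  heading <- atan2(target[2] - lon, target[1] - lat)
  ars <- FALSE

  for (day in seq_len(dur)[-1]) {
    in_box <- lat >= box$lat[1] && lat <= box$lat[2] &&
      lon >= box$lon[1] && lon <= box$lon[2]
    p_ars <- if (in_box) {
      if (ars) 0.95 else 0.6
    } else {
      if (ars) 0.7 else 0.05
    }
    ars <- stats::runif(1) < p_ars
    if (ars) {
      heading <- heading + stats::rnorm(1, 0, 1.8)
      speed <- abs(stats::rnorm(1, 0.12, 0.06))
    } else {
      bearing <- atan2(target[2] - lon, target[1] - lat)
      heading <- bearing + stats::rnorm(1, 0, 0.35)
      speed <- max(0.05, stats::rnorm(1, 0.6, 0.15))
    }
    lat <- lat + speed * cos(heading)
    lon <- lon + speed * sin(heading) / max(cos(lat * pi / 180), 0.2)
    lat <- reflect_into(lat, env$lat[1], env$lat[2])
    lon <- reflect_into(lon, env$lon[1], env$lon[2])
    if (sqrt((target[1] - lat)^2 + (target[2] - lon)^2) < 3) {
      target_i <- target_i + 1L
      target <- if (target_i <= length(wps)) wps[[target_i]] else sample_box_point()
    }
    lat_out[day] <- lat
    lon_out[day] <- lon
  }

  observed <- rep(TRUE, dur)
  day <- 2L
  while (day < dur) {
    if (stats::runif(1) < cfg$gap_start_prob) {
      len <- min(1L + stats::rgeom(1, 1 / cfg$gap_mean_length),
                 cfg$gap_max_length)
      observed[day:min(day + len - 1L, dur - 1L)] <- FALSE
      day <- day + len + 1L
    } else {
      day <- day + 1L
    }
  }

  data.frame(turtle_id = id, population = population,
             date = start + 0:(dur - 1L),
             lat = lat_out, lon = lon_out, observed = observed)
}

#' Simulate daily turtle tracks
#'
#' Generates one daily position per turtle per deployment day (the analogue
#' of state-space-filtered satellite tracks), with an `observed` flag marking
#' days on which the tag actually transmitted. Deterministic for a fixed
#' seed.
#'
#' @param cfg A [track_sim_config()].
#' @param seed Integer RNG seed.
#' @return A track data frame: `turtle_id`, `population`, `date`, `lat`,
#'   `lon`, `observed`.
#' @export
simulate_tracks <- function(cfg = track_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "track_sim_config"))
  set.seed(seed)
  out <- list()
  plan <- rbind(
    if (cfg$n_ep > 0) data.frame(population = "EP", i = seq_len(cfg$n_ep)),
    if (cfg$n_wp > 0) data.frame(population = "WP", i = seq_len(cfg$n_wp))
  )
  for (r in seq_len(nrow(plan))) {
    pop <- plan$population[r]
    geo <- cfg$geographies[[pop]]
    if (is.null(geo)) stop(sprintf("no geography for population '%s'", pop),
                           call. = FALSE)
    id <- sprintf("%s%03d", tolower(pop), plan$i[r])
    out[[r]] <- simulate_one_track(id, pop, geo, cfg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configuration for the synthetic effort and catch generator
#'
#' Generates quarterly 5-degree fields of longline hooks with gamma
#' dispersion around a spatial intensity surface, and a matching catch table
#' whose billfish/tuna split follows a configurable billfish-fraction
#' surface with beta sampling noise. An optional coverage fraction leaves
#' some cell-quarters unreported (masked), and an optional planted hotspot
#' raises one cell-quarter's hooks to `multiplier` times the field's
#' pre-planting maximum so it is the maximum by construction.
#'
#' @param spec A [grid_spec()].
#' @param lat_range,lon_range Extent of reported effort, degrees (`lon` on
#'   \[0, 360)).
#' @param base_hooks Mean hooks per cell-quarter before the intensity
#'   multiplier. Must be non-negative.
#' @param hooks_shape Gamma shape of hook-count dispersion.
#' @param intensity `function(lat_c, lon_c, quarter)` returning a
#'   non-negative multiplier on `base_hooks`; default constant 1.
#' @param billfish_fraction_fn `function(lat_c, lon_c, quarter)` returning
#'   the target billfish fraction in \[0, 1\]; the default increases toward
#'   northern latitudes where shallow-set billfish effort concentrates.
#' @param catch_per_hook Mean catch (tonnes) per hook.
#' @param catch_cv Lognormal CV of total catch around its mean.
#' @param composition_conc Beta concentration of the realized billfish
#'   fraction around its target.
#' @param coverage Fraction of cell-quarters with reported data.
#' @param hotspot Optional `list(lat_lo, lon_lo, quarter, multiplier)`.
#' @return An object of class `effort_sim_config`.
#' @export
effort_sim_config <- function(spec = grid_spec(),
                              lat_range = c(-40, 45),
                              lon_range = c(110, 290),
                              base_hooks = 5e4,
                              hooks_shape = 2,
                              intensity = NULL,
                              billfish_fraction_fn = NULL,
                              catch_per_hook = 5e-4,
                              catch_cv = 0.3,
                              composition_conc = 50,
                              coverage = 1,
                              hotspot = NULL) {
  stopifnot(inherits(spec, "grid_spec"),
            hooks_shape > 0, catch_per_hook > 0, catch_cv >= 0,
            composition_conc > 0, coverage > 0, coverage <= 1)
  if (!is.finite(base_hooks) || base_hooks < 0) {
    stop("`base_hooks` must be non-negative", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- function(lat_c, lon_c, quarter) 1
  if (is.null(billfish_fraction_fn)) {
    billfish_fraction_fn <- function(lat_c, lon_c, quarter) {
      stats::plogis(-1.5 + 0.05 * lat_c)
    }
  }
  structure(
    list(spec = spec, lat_range = lat_range, lon_range = lon_range,
         base_hooks = base_hooks, hooks_shape = hooks_shape,
         intensity = intensity, billfish_fraction_fn = billfish_fraction_fn,
         catch_per_hook = catch_per_hook, catch_cv = catch_cv,
         composition_conc = composition_conc, coverage = coverage,
         hotspot = hotspot),
    class = "effort_sim_config"
  )
}

#' Simulate gridded longline effort and catch
#'
#' @param cfg An [effort_sim_config()].
#' @param seed Integer RNG seed.
#' @return A list with `hooks` (a `quarterly_field`) and `catch` (a data
#'   frame `lat_lo`, `lon_lo`, `quarter`, `species_group`, `tonnes`); masked
#'   (unreported) cell-quarters are absent from both.
#' @export
simulate_effort <- function(cfg = effort_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "effort_sim_config"))
  set.seed(seed)
  cs <- cfg$spec$cell_size
  cells <- expand.grid(
    lat_lo = seq(cfg$lat_range[1], cfg$lat_range[2] - cs, by = cs),
    lon_lo = seq(cfg$lon_range[1], cfg$lon_range[2] - cs, by = cs),
    quarter = 1:4
  )
  keep <- stats::runif(nrow(cells)) < cfg$coverage
  cells <- cells[keep, , drop = FALSE]
  lat_c <- cells$lat_lo + cs / 2
  lon_c <- cells$lon_lo + cs / 2
  mu <- cfg$base_hooks * mapply(cfg$intensity, lat_c, lon_c, cells$quarter)
  if (any(mu < 0)) stop("intensity surface returned negative values",
                        call. = FALSE)
  hooks_val <- ifelse(mu > 0,
                      stats::rgamma(nrow(cells), shape = cfg$hooks_shape,
                                    rate = cfg$hooks_shape / pmax(mu, 1e-12)),
                      0)
  if (!is.null(cfg$hotspot)) {
    h <- cfg$hotspot
    idx <- which(cells$lat_lo == h$lat_lo & cells$lon_lo == h$lon_lo &
                   cells$quarter == h$quarter)
    if (!length(idx)) {
      # planted cell must be reported even under partial coverage
      cells <- rbind(cells, data.frame(lat_lo = h$lat_lo, lon_lo = h$lon_lo,
                                       quarter = h$quarter))
      lat_c <- c(lat_c, h$lat_lo + cs / 2)
      lon_c <- c(lon_c, h$lon_lo + cs / 2)
      hooks_val <- c(hooks_val, 0)
      idx <- nrow(cells)
    }
    hooks_val[idx] <- h$multiplier * max(hooks_val)
  }
  hooks <- as_quarterly_field(
    data.frame(lat_lo = cells$lat_lo, lon_lo = cells$lon_lo,
               quarter = cells$quarter, value = hooks_val),
    cfg$spec
  )

  total_t <- hooks_val * cfg$catch_per_hook *
    stats::rlnorm(nrow(cells), -cfg$catch_cv^2 / 2, cfg$catch_cv)
  p_target <- pmin(pmax(
    mapply(cfg$billfish_fraction_fn, lat_c, lon_c, cells$quarter), 0), 1)
  conc <- cfg$composition_conc
  p_real <- ifelse(
    p_target <= 0, 0,
    ifelse(p_target >= 1, 1,
           stats::rbeta(nrow(cells), conc * p_target, conc * (1 - p_target))))
  billfish_t <- total_t * p_real
  tuna_t <- total_t - billfish_t

  split_rows <- function(tonnes, sp1, sp2) {
    share <- stats::runif(length(tonnes), 0.3, 0.7)
    data.frame(
      lat_lo = rep(cells$lat_lo, 2), lon_lo = rep(cells$lon_lo, 2),
      quarter = rep(cells$quarter, 2),
      species_group = rep(c(sp1, sp2), each = length(tonnes)),
      tonnes = c(tonnes * share, tonnes * (1 - share))
    )
  }
  catch <- rbind(split_rows(tuna_t, "albacore", "bigeye"),
                 split_rows(billfish_t, "swordfish", "marlin"))
  catch <- catch[catch$tonnes > 0, , drop = FALSE]
  catch <- catch[order(catch$quarter, catch$lat_lo, catch$lon_lo,
                       catch$species_group), , drop = FALSE]
  rownames(catch) <- NULL
  list(hooks = hooks, catch = catch)
}

#' Construct a named synthetic scenario
#'
#' Three seeded synthetic worlds used as ground truth in tests:
#' \describe{
#'   \item{null_overlap}{One population wandering its default geography over
#'     a spatially uniform effort field, so turtle occupancy and effort are
#'     independent.}
#'   \item{planted_hotspot}{A single population whose foraging box is exactly
#'     one 5-degree cell, with effort at that cell in one quarter raised to
#'     10 times the field maximum. The planted (cell, quarter) is recorded in
#'     `$truth` and should be recovered as the top-ranked hotspot.}
#'   \item{paper_like}{Two populations (EP and WP, 80 and 55 turtles) with
#'     disjoint geographies over an effort field concentrated in the
#'     Indo-Pacific, the central Pacific and the South Pacific Gyre, with a
#'     northward-increasing billfish fraction.}
#' }
#'
#' @param name One of `"null_overlap"`, `"planted_hotspot"`, `"paper_like"`.
#' @param seed Integer seed; all randomness in [simulate_scenario()] flows
#'   from it.
#' @return An object of class `scenario`: `name`, `seed`, `tracks`
#'   (a `track_sim_config`), `effort` (an `effort_sim_config`), and `truth`
#'   (the planted cell-quarter, or `NULL`).
#' @export
make_scenario <- function(name = c("null_overlap", "planted_hotspot",
                                   "paper_like"), seed = 1) {
  name <- match.arg(name)
  truth <- NULL
  if (name == "null_overlap") {
    tcfg <- track_sim_config(n_ep = 12, n_wp = 0)
    ecfg <- effort_sim_config(lat_range = c(-40, 20), lon_range = c(220, 295),
                              coverage = 1)
  } else if (name == "planted_hotspot") {
    geo <- list(EP = list(
      envelope = list(lat = c(-10, 15), lon = c(165, 200)),
      branches = list(main = list(
        prob = 1, deploy = c(10, 176), waypoints = list(c(6, 178)),
        box = list(lat = c(0, 5), lon = c(180, 185))))
    ))
    tcfg <- track_sim_config(n_ep = 18, n_wp = 0, geographies = geo)
    truth <- list(lat_lo = 0, lon_lo = 180, quarter = 3L)
    ecfg <- effort_sim_config(lat_range = c(-15, 20), lon_range = c(160, 200),
                              hotspot = c(truth, list(multiplier = 10)))
  } else {
    bump <- function(lat, lon, lat_rng, lon_rng, height) {
      ifelse(lat >= lat_rng[1] & lat <= lat_rng[2] &
               lon >= lon_rng[1] & lon <= lon_rng[2], height, 0)
    }
    intensity <- function(lat_c, lon_c, quarter) {
      0.3 +
        bump(lat_c, lon_c, c(-10, 20), c(110, 160), 2.0) +  # Indo-Pacific
        bump(lat_c, lon_c, c(0, 25), c(175, 235), 1.2) +    # central Pacific
        bump(lat_c, lon_c, c(-30, 0), c(230, 285), 1.0) +   # SPG
        bump(lat_c, lon_c, c(25, 40), c(160, 230), 0.8)     # NPTZ
    }
    tcfg <- track_sim_config()  # 80 EP + 55 WP, defaults
    ecfg <- effort_sim_config(intensity = intensity, coverage = 0.9)
  }
  structure(list(name = name, seed = as.integer(seed), tracks = tcfg,
                 effort = ecfg, truth = truth),
            class = "scenario")
}

#' Generate the data for a scenario
#'
#' @param scn A [make_scenario()] object.
#' @return A list: `tracks` (daily positions with `observed` flags), `hooks`
#'   (a `quarterly_field`), `catch` (catch table), `truth` (planted
#'   cell-quarter or `NULL`), and `scenario` (the input).
#' @export
simulate_scenario <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  tracks <- simulate_tracks(scn$tracks, seed = scn$seed)
  eff <- simulate_effort(scn$effort, seed = scn$seed + 1L)
  list(tracks = tracks, hooks = eff$hooks, catch = eff$catch,
       truth = scn$truth, scenario = scn)
}
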