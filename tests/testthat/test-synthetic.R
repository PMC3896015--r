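test_that("generators are deterministic under a fixed seed", {
  cfg <- track_sim_config(n_ep = 4, n_wp = 3)
  expect_identical(simulate_tracks(cfg, seed = 5), simulate_tracks(cfg, seed = 5))
  expect_false(identical(simulate_tracks(cfg, seed = 5),
                         simulate_tracks(cfg, seed = 6)))
  ecfg <- effort_sim_config(lat_range = c(-10, 10), lon_range = c(180, 200))
  expect_identical(simulate_effort(ecfg, seed = 5), simulate_effort(ecfg, seed = 5))
  w1 <- simulate_scenario(make_scenario("null_overlap", 1))
  w1b <- simulate_scenario(make_scenario("null_overlap", 1))
  w2 <- simulate_scenario(make_scenario("null_overlap", 2))
  expect_identical(w1$tracks, w1b$tracks)
  expect_false(identical(w1$tracks, w2$tracks))
})

test_that("tracks have one position per day within the deployment window", {
  cfg <- track_sim_config(n_ep = 6, n_wp = 5)
  tracks <- simulate_tracks(cfg, seed = 9)
  expect_setequal(unique(tracks$population), c("EP", "WP"))
  for (id in unique(tracks$turtle_id)) {
    tr <- tracks[tracks$turtle_id == id, ]
    expect_identical(tr$date, seq(min(tr$date), max(tr$date), by = "day"))
    expect_gte(nrow(tr), cfg$duration_min)
    expect_lte(nrow(tr), cfg$duration_max)
  }
  expect_gte(min(tracks$date), cfg$deployment_start)
  expect_lte(max(tracks$date), cfg$deployment_end)
})

test_that("duration sampler hits its configured mean and truncation bounds", {
  tracks <- simulate_tracks(track_sim_config(n_ep = 80, n_wp = 55), seed = 17)
  durations <- tapply(tracks$date, tracks$turtle_id, length)
  expect_true(all(durations >= 4 & durations <= 948))
  # Monte-Carlo check against the configured truncated-lognormal mean (~209 d)
  expect_gt(mean(durations), 209 * 0.75)
  expect_lt(mean(durations), 209 * 1.25)
})

test_that("a no-gap config yields consecutive fully observed days", {
  cfg <- track_sim_config(n_ep = 1, n_wp = 0, gap_start_prob = 0,
                          duration_meanlog = log(10), duration_sdlog = 1e-9,
                          duration_min = 10, duration_max = 10)
  tr <- simulate_tracks(cfg, seed = 1)
  expect_equal(nrow(tr), 10L)
  expect_true(all(tr$observed))
  expect_identical(tr$date, seq(min(tr$date), by = "day", length.out = 10))
})

test_that("gap model produces unobserved spells including some beyond 20 days", {
  cfg <- track_sim_config(n_ep = 30, n_wp = 0, gap_start_prob = 0.03,
                          gap_mean_length = 12)
  tracks <- simulate_tracks(cfg, seed = 23)
  expect_true(any(!tracks$observed))
  run_lengths <- unlist(tapply(tracks$observed, tracks$turtle_id, function(o) {
    r <- rle(o); r$lengths[!r$values]
  }))
  expect_gt(max(run_lengths), 20)  # the long-gap removal rule is exercised
})

test_that("infeasible geographies are rejected", {
  geo <- default_geographies()
  geo$EP$branches$gyre$box$lat <- c(-120, -100)
  expect_error(track_sim_config(geographies = geo), "latitudes")
  geo2 <- default_geographies()
  geo2$EP$branches$gyre$box$lon <- c(10, 20)  # outside the envelope
  expect_error(track_sim_config(geographies = geo2), "envelope")
})

test_that("effort fields honour composition, masking and planted maxima", {
  spec <- grid_spec()
  # billfish fraction identically zero -> only tuna-group rows
  ecfg0 <- effort_sim_config(lat_range = c(0, 10), lon_range = c(180, 190),
                             billfish_fraction_fn = function(la, lo, q) 0)
  eff0 <- simulate_effort(ecfg0, seed = 3)
  grp <- default_species_lookup()[tolower(eff0$catch$species_group)]
  expect_true(all(grp == "tuna"))
  # full coverage: support is n_cells x 4
  expect_equal(nrow(eff0$hooks), 2 * 2 * 4)
  # coverage < 1 masks cell-quarters from hooks and catch alike
  ecfg_m <- effort_sim_config(lat_range = c(-20, 20), lon_range = c(160, 200),
                              coverage = 0.5)
  eff_m <- simulate_effort(ecfg_m, seed = 4)
  expect_lt(nrow(eff_m$hooks), 8 * 8 * 4)
  hooks_keys <- paste(eff_m$hooks$lat_lo, eff_m$hooks$lon_lo, eff_m$hooks$quarter)
  catch_keys <- paste(eff_m$catch$lat_lo, eff_m$catch$lon_lo, eff_m$catch$quarter)
  expect_true(all(catch_keys %in% hooks_keys))
  # realized billfish fraction tracks the configured surface
  ecfg_p <- effort_sim_config(lat_range = c(0, 20), lon_range = c(180, 220),
                              billfish_fraction_fn = function(la, lo, q) 0.3,
                              composition_conc = 200)
  eff_p <- simulate_effort(ecfg_p, seed = 5)
  comp <- billfish_fraction(eff_p$catch)
  expect_equal(mean(comp$p), 0.3, tolerance = 0.05)
  # planted hotspot is the maximum by construction
  hot <- list(lat_lo = 5, lon_lo = 185, quarter = 2L, multiplier = 10)
  ecfg_h <- effort_sim_config(lat_range = c(0, 20), lon_range = c(180, 200),
                              hotspot = hot)
  eff_h <- simulate_effort(ecfg_h, seed = 6)
  top <- eff_h$hooks[which.max(eff_h$hooks$value), ]
  expect_equal(list(top$lat_lo, top$lon_lo, as.integer(top$quarter)),
               list(5, 185, 2L))
  expect_error(effort_sim_config(base_hooks = -1), "non-negative")
})

test_that("scenario worlds match their stated structure", {
  scn <- make_scenario("planted_hotspot", 7)
  expect_equal(scn$truth, list(lat_lo = 0, lon_lo = 180, quarter = 3L))
  # paper_like: EP and WP occupancy disjoint at the 5-degree cell level
  world <- simulate_scenario(make_scenario("paper_like", 3))
  tracks <- preprocess_tracks(world$tracks)
  cells <- bin_position(tracks$lat, tracks$lon)
  key <- paste(cells$lat_lo, cells$lon_lo)
  expect_length(intersect(unique(key[tracks$population == "EP"]),
                          unique(key[tracks$population == "WP"])), 0)
  expect_error(make_scenario("nope", 1))
})
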