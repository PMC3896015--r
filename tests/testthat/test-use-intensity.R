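# The two-turtle example used throughout: turtles tracked for 5 and 10 days,
# giving per-day sample sizes 2,2,2,2,2,1,1,1,1,1 over relative days 1..10.

test_that("per-day sample sizes come from direct enumeration", {
  tracks <- assign_relative_days(two_turtle_tracks())
  counts <- count_individuals_per_day(tracks)
  expect_identical(counts$n[counts$relative_day <= 5], rep(2L, 5))
  expect_identical(counts$n[counts$relative_day > 5], rep(1L, 5))
  # a single turtle counts 1 on all its days
  one <- count_individuals_per_day(
    assign_relative_days(make_track("solo", "WP", 0:6)))
  expect_identical(one$n, rep(1L, 7))
  # a hole at day 3 excludes the turtle from that day's count
  holed <- assign_relative_days(make_track("h", "EP", c(0, 1, 3, 4)))
  counts <- count_individuals_per_day(rbind(
    holed, assign_relative_days(make_track("full", "EP", 0:4))))
  expect_identical(counts$n[counts$relative_day == 3], 1L)
  expect_identical(counts$n[counts$relative_day == 2], 2L)
})

test_that("threshold day is the smallest day reaching the cumulative fraction", {
  tracks <- assign_relative_days(two_turtle_tracks())
  counts <- count_individuals_per_day(tracks)
  # cumulative counts 2,4,...,10,11,...,15; 13/15 = 0.867 >= 0.85 first at day 8
  expect_identical(threshold_day(counts, "EP", 0.85), 8L)
  expect_identical(threshold_day(counts, "EP", 1.0), 10L)
  single <- count_individuals_per_day(
    assign_relative_days(make_track("s", "EP", 0)))
  expect_identical(threshold_day(single, "EP", 0.85), 1L)
  expect_error(threshold_day(counts, "WP"), "no positions")
})

test_that("daily weights follow the inverse-sample-size rule with threshold", {
  tracks <- assign_relative_days(two_turtle_tracks())
  counts <- count_individuals_per_day(tracks)
  expect_identical(daily_weight(counts, "EP", 3, 8L), 0.5)
  # beyond the threshold the weight freezes at the threshold-day value
  expect_identical(daily_weight(counts, "EP", 9, 8L), 1.0)
  expect_identical(daily_weight(counts, "EP", 6, 8L), 1.0)  # n = 1
  expect_error(daily_weight(counts, "EP", 99, 99L), "no sample-size entry")
})

test_that("weights conserve one unit per population-day up to the threshold", {
  set.seed(13)
  tracks <- preprocess_tracks(
    simulate_tracks(track_sim_config(n_ep = 9, n_wp = 7), seed = 13))
  pos <- weight_positions(tracks)
  thr <- attr(pos, "threshold_days")
  counts <- count_individuals_per_day(tracks)
  for (p in thr$population) {
    T_j <- thr$threshold_day[thr$population == p]
    sub <- pos[pos$population == p, ]
    for (t in unique(sub$relative_day)) {
      day <- sub[sub$relative_day == t, ]
      n_jt <- counts$n[counts$population == p & counts$relative_day == t]
      if (t <= T_j) {
        # exact as rationals: n_jt identical copies of 1/n_jt
        expect_identical(unique(day$omega), 1 / n_jt)
        expect_identical(nrow(day), as.integer(n_jt))
        expect_equal(sum(day$omega), 1, tolerance = 1e-12)
      } else {
        n_T <- counts$n[counts$population == p & counts$relative_day == T_j]
        expect_equal(sum(day$omega), n_jt / n_T, tolerance = 1e-12)
      }
    }
  }
})

test_that("identical gap-free tracks give every position identical weight", {
  tracks <- assign_relative_days(rbind(
    make_track("u1", "EP", 0:19), make_track("u2", "EP", 0:19),
    make_track("u3", "EP", 0:19)))
  pos <- weight_positions(tracks)
  expect_identical(unique(pos$omega), 1 / 3)
})

test_that("quarterly inflation equalizes raw position counts", {
  # Q1: EP 200 positions, WP 100 -> WP inflated by 2
  d0 <- as.Date("2003-01-01")  # Q1
  tracks <- assign_relative_days(rbind(
    make_track("e1", "EP", 0:89), make_track("e2", "EP", 0:89),
    make_track("e3", "EP", 0:19),
    make_track("w1", "WP", 0:49), make_track("w2", "WP", 0:49)))
  tracks$date <- d0 + (tracks$relative_day - 1L) %% 85  # keep inside Q1
  pos <- weight_positions(assign_relative_days(
    tracks[!duplicated(tracks[c("turtle_id", "date")]), ]))
  infl <- quarter_inflation(pos)
  q1 <- infl[infl$quarter == 1, ]
  x <- max(q1$n_positions); y <- min(q1$n_positions)
  expect_equal(q1$inflation[q1$n_positions == y], x / y)
  expect_equal(q1$inflation[q1$n_positions == x], 1)
  # inflated counts are equal
  expect_equal(length(unique(q1$n_positions * q1$inflation)), 1L)
  # equal counts -> both factors 1
  bal <- data.frame(population = c("EP", "WP"), quarter = 1L)
  bal <- bal[rep(1:2, each = 10), ]
  infl2 <- quarter_inflation(bal)
  expect_identical(infl2$inflation, c(1, 1))
  # lone population in a quarter -> factor 1
  lone <- data.frame(population = "EP", quarter = 2L)[rep(1, 5), , drop = FALSE]
  expect_identical(quarter_inflation(lone)$inflation, 1)
})

test_that("accumulation conserves the total weighted contribution", {
  # one position with omega 0.5 and inflation 2 contributes 1.0
  pos <- data.frame(turtle_id = "a", population = "EP",
                    quarter = 1L, lat_lo = 0, lon_lo = 180, omega = 0.5)
  infl <- data.frame(population = "EP", quarter = 1L, n_positions = 1L,
                     inflation = 2)
  f <- accumulate_use(pos, inflation = infl)$EP
  expect_equal(field_sum(f), 1.0)

  # two-turtle example, no inflation, T = 8: exhaustive sum over all
  # 15 position-weights is 5 x (2 x 0.5) + 3 x 1 + 2 x 1 = 10
  tracks <- assign_relative_days(two_turtle_tracks())
  pos <- weight_positions(tracks)
  no_infl <- data.frame(population = "EP", quarter = unique(pos$quarter),
                        n_positions = NA_integer_, inflation = 1)
  f <- accumulate_use(pos, inflation = no_infl)$EP
  expect_equal(field_sum(f), 10)
  expect_equal(field_sum(f), sum(pos$omega))

  # binning loses nothing on scattered synthetic positions either
  set.seed(3)
  tracks <- preprocess_tracks(
    simulate_tracks(track_sim_config(n_ep = 5, n_wp = 5), seed = 3))
  use <- use_intensity_fields(tracks)
  key <- paste(use$positions$population, use$positions$quarter)
  ikey <- paste(use$inflation$population, use$inflation$quarter)
  contrib <- use$positions$omega * use$inflation$inflation[match(key, ikey)]
  expect_equal(sum(vapply(use$fields, field_sum, numeric(1))), sum(contrib),
               tolerance = 1e-12)
})

test_that("cells never visited are masked, not zero", {
  tracks <- assign_relative_days(two_turtle_tracks())
  f <- use_intensity_fields(tracks)$fields$EP
  expect_identical(nrow(f), 1L)  # all positions share one cell-quarter
})
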