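test_that("run-length dive detection extracts the three dive statistics", {
  t0 <- utc("2015-05-01 12:00:00")
  b <- dive_bout("w4", t0 + (0:7) * 75, c(3, 15, 40, 15, 3, 2, 20, 3))
  d <- detect_dives(b, threshold = 10)
  expect_equal(nrow(d), 2L)
  expect_equal(d$max_depth_m, c(40, 20))
  expect_equal(d$duration_s, c(225, 75))
  expect_equal(d$post_dive_interval_s, c(150, NA))
  expect_equal(d$start, t0 + c(1, 6) * 75)
  # the shortest reportable dive is one sample
  expect_equal(min(d$duration_s), 75)
  # never exceeding the threshold yields no dives
  shallow <- dive_bout("w4", t0 + (0:3) * 75, c(2, 5, 8, 3))
  expect_equal(nrow(detect_dives(shallow, 10)), 0L)
})

test_that("irregular sample spacing is rejected", {
  t0 <- utc("2015-05-01 12:00:00")
  expect_error(dive_bout("w4", t0 + c(0, 75, 200), c(1, 20, 1)),
               "irregular")
})

test_that("raising the threshold never increases dive count or durations", {
  sc <- sim_scenario(seed = 41)
  sim <- simulate_track(sc)
  dv <- simulate_dives(sc, sim$truth, n_days = 2)
  for (bout in dv$bouts) {
    d5 <- detect_dives(bout, 5)
    d10 <- detect_dives(bout, 10)
    d20 <- detect_dives(bout, 20)
    expect_gte(nrow(d5), nrow(d10))
    expect_gte(nrow(d10), nrow(d20))
    expect_gte(sum(d5$duration_s), sum(d10$duration_s))
    # extreme thresholds
    expect_equal(nrow(detect_dives(bout, 1e6)), 0L)
    d0 <- detect_dives(bout, 1e-9)
    expect_equal(sum(d0$duration_s) / 75,
                 sum(bout$samples$depth > 1e-9))
  }
})

test_that("dive and surface time partition each bout exactly", {
  sc <- sim_scenario(seed = 42)
  sim <- simulate_track(sc)
  dv <- simulate_dives(sc, sim$truth, n_days = 3)
  for (bout in dv$bouts) {
    d <- detect_dives(bout, 10)
    span <- nrow(bout$samples) * bout$resolution_s
    if (nrow(d) == 0L) next
    lead <- as.numeric(d$start[1] - bout$samples$time[1], units = "secs")
    trail <- as.numeric(bout$samples$time[nrow(bout$samples)] + 75 -
                          d$end[nrow(d)], units = "secs")
    expect_equal(sum(d$duration_s) + sum(d$post_dive_interval_s, na.rm = TRUE) +
                   lead + trail, span)
  }
})

test_that("solar geometry separates day from night", {
  # equinox, Greenwich meridian on the equator: local noon vs midnight
  expect_equal(diel_tag(utc("2015-03-20 12:00:00"), 0, 0), "day")
  expect_equal(diel_tag(utc("2015-03-20 00:00:00"), 0, 0), "night")
  expect_gt(solar_elevation(utc("2015-03-20 12:05:00"), 0, 0), 85)
  # mid-June austral winter evening at 42 S, 73.5 W (17:30 UTC-4)
  expect_equal(diel_tag(utc("2015-06-15 21:30:00"), -73.5, -42), "night")
  # same clock time in mid-summer is daylight
  expect_equal(diel_tag(utc("2015-12-15 21:30:00"), -73.5, -42), "day")
  # polar winter: no sun at 80 N in January at any hour
  hrs <- utc("2015-01-10 00:00:00") + seq(0, 23) * 3600
  expect_true(all(diel_tag(hrs, 15, 80) == "night"))
})

test_that("diel-structured dive regimes are recovered from the generated bouts", {
  sc <- sim_scenario(seed = 43)
  sim <- simulate_track(sc)
  dv <- simulate_dives(sc, sim$truth, n_days = 6)
  dives <- do.call(rbind, lapply(dv$bouts, detect_dives, threshold = 10))
  path <- data.frame(time = sim$truth$times, lon = sim$truth$x[, 1],
                     lat = sim$truth$x[, 2])
  dives <- add_diel(dives, path)
  # detection recovers every generated dive exactly (flat-bottom profiles)
  expect_equal(nrow(dives), nrow(dv$truth))
  expect_equal(dives$max_depth_m, dv$truth$depth_m, tolerance = 1e-12)
  expect_equal(dives$duration_s, dv$truth$duration_s)
  expect_equal(dives$diel, dv$truth$diel)

  grid <- build_grid(sim$track, sc$step_hours)
  binned <- bin_dive_stats(dives, grid)
  expect_true(all(c("day", "night") %in% binned$diel))
  # generated day depths (mean 150 m) dominate night depths (mean 25 m)
  # in every bin holding both classes
  both <- names(which(table(binned$bin) == 2))
  for (bn in both) {
    day <- binned$depth_mean[binned$bin == bn & binned$diel == "day"]
    night <- binned$depth_mean[binned$bin == bn & binned$diel == "night"]
    expect_gt(day, night)
  }
  # bin means equal generator truth restricted to the same bins
  h <- as.numeric(difftime(dv$truth$start, grid$times[1], units = "hours"))
  tb <- floor(h / grid$step_hours) + 1
  truth_means <- tapply(dv$truth$depth_m, list(tb, dv$truth$diel), mean)
  for (r in seq_len(nrow(binned))) {
    expect_equal(binned$depth_mean[r],
                 truth_means[as.character(binned$bin[r]), binned$diel[r]],
                 tolerance = 1e-12)
  }
  # single-dive bins have zero SD
  singles <- binned[binned$n_dives == 1, ]
  if (nrow(singles)) expect_true(all(singles$depth_sd == 0))
})

test_that("depth series round-trip through CSV and split at gaps", {
  sc <- sim_scenario(seed = 44)
  sim <- simulate_track(sc)
  dv <- simulate_dives(sc, sim$truth, n_days = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_depth_csv(dv$bouts, f)
  back <- read_depth_series(f)
  expect_length(back, length(dv$bouts))
  expect_equal(back[[1]]$samples$depth, dv$bouts[[1]]$samples$depth,
               tolerance = 1e-9)
  # a missing sample splits a bout in two
  b1 <- dv$bouts[[1]]
  cut <- b1$samples[-10, ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(tag_id = b1$tag_id,
                              time = format(cut$time, "%Y-%m-%d %H:%M:%S",
                                            tz = "UTC"),
                              depth = cut$depth), f2, row.names = FALSE)
  halves <- read_depth_series(f2)
  expect_length(halves, 2L)
  expect_equal(nrow(halves[[1]]$samples) + nrow(halves[[2]]$samples),
               nrow(cut))
})

test_that("per-tag day/night summaries aggregate the whole deployment", {
  sc <- sim_scenario(seed = 45)
  sim <- simulate_track(sc)
  dv <- simulate_dives(sc, sim$truth, n_days = 4)
  dives <- do.call(rbind, lapply(dv$bouts, detect_dives, threshold = 10))
  path <- data.frame(time = sim$truth$times, lon = sim$truth$x[, 1],
                     lat = sim$truth$x[, 2])
  dives <- add_diel(dives, path)
  s <- summarize_dives(dives)
  expect_true(all(s$tag_id == dives$tag_id[1]))
  expect_equal(sum(s$n_dives), nrow(dives))
  for (dl in unique(s$diel))
    expect_equal(s$depth_mean[s$diel == dl],
                 mean(dives$max_depth_m[dives$diel == dl]),
                 tolerance = 1e-12)
})
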