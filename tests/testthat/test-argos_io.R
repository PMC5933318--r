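test_that("read_argos returns time-sorted tracks and collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag_id,time,lon,lat,lc",
               "w1,2015-04-01 12:00:00,-74.0,-41.0,1",
               "w1,2015-04-01 00:00:00,-74.2,-41.2,3",
               "w1,2015-04-01 06:00:00,-74.1,-41.1,B"), f)
  tr <- read_argos(f)
  expect_length(tr, 1L)
  expect_equal(nrow(tr$w1$fixes), 3L)
  expect_true(!is.unsorted(tr$w1$fixes$time))
  expect_equal(tr$w1$fixes$lc, c("3", "B", "1"))

  # duplicate timestamp: the better location class wins
  writeLines(c("tag_id,time,lon,lat,lc",
               "w1,2015-04-01 00:00:00,-74.0,-41.0,B",
               "w1,2015-04-01 00:00:00,-74.5,-41.5,2",
               "w1,2015-04-02 00:00:00,-74.1,-41.1,1"), f)
  tr <- read_argos(f)
  expect_equal(nrow(tr$w1$fixes), 2L)
  expect_equal(tr$w1$fixes$lc[1L], "2")
  expect_equal(tr$w1$fixes$lon[1L], -74.5)
})

test_that("read_argos handles degenerate and malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("tag_id,time,lon,lat,lc", f)
  expect_warning(tr <- read_argos(f), "no data rows")
  expect_length(tr, 0L)

  writeLines(c("tag_id,when,lon,lat,lc",
               "w1,2015-04-01,-74,-41,3"), f)
  expect_error(read_argos(f), "time")

  writeLines(c("tag_id,time,lon,lat,lc",
               "w1,2015-04-01 00:00:00,-74.0,-41.0,3",
               "w1,not-a-time,-74.1,-41.1,3",
               "w1,2015-04-02 00:00:00,bad,-41.2,3",
               "w1,2015-04-03 00:00:00,-74.3,-41.3,Z",
               "w1,2015-04-04 00:00:00,-74.4,-41.4,A"), f)
  expect_message(tr <- read_argos(f), "3 unparseable")
  expect_equal(attr(tr, "skipped"), 3L)
  expect_equal(nrow(tr$w1$fixes), 2L)
})

test_that("synthetic tracks round-trip through the Argos CSV dialect", {
  sims <- lapply(1:2, function(s)
    simulate_track(sim_scenario(n_steps = 20, fixes_per_day = 5, seed = s)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(lapply(sims, `[[`, "track"), f)
  back <- read_argos(f)
  expect_length(back, 2L)
  expect_equal(sum(vapply(back, function(tr) nrow(tr$fixes), 0L)),
               sum(vapply(sims, function(s) nrow(s$track$fixes), 0L)))
  expect_equal(back$sim1$fixes$lon, sims[[1]]$track$fixes$lon,
               tolerance = 1e-8)
})

test_that("implausible-speed filter removes a displaced fix and is idempotent", {
  # middle fix ~2 deg of latitude off course within 30 min: ~445 km/h legs
  tr <- mk_track(hours = c(0, 0.5, 1),
                 lon = c(-75, -75, -75),
                 lat = c(-40, -38, -40.01))
  v1 <- hav_km(-75, -40, -75, -38) / 0.5
  expect_gt(v1, 400)
  flt <- filter_implausible(tr, max_speed = 30, max_fraction_removed = 0.5)
  expect_equal(nrow(flt$fixes), 2L)
  expect_equal(flt$fixes$lat, c(-40, -40.01))
  expect_equal(attr(flt, "removed_fraction"), 1 / 3)

  # all implied speeds below threshold: identity
  slow <- mk_track(hours = c(0, 12, 24), lon = c(-75, -75.1, -75.2),
                   lat = c(-40, -40.1, -40.2))
  expect_equal(filter_implausible(slow)$fixes, slow$fixes)

  # idempotency on a noisy simulated track
  sim <- simulate_track(sim_scenario(n_steps = 60, seed = 3))
  once <- suppressWarnings(filter_implausible(sim$track, max_speed = 20))
  twice <- suppressWarnings(filter_implausible(once, max_speed = 20))
  expect_identical(once$fixes, twice$fixes)
})

test_that("excess removal triggers a data-quality warning, not failure", {
  tr <- mk_track(hours = c(0, 0.5, 1), lon = c(-75, -75, -75),
                 lat = c(-40, -38, -40.01))
  expect_warning(flt <- filter_implausible(tr, max_speed = 30,
                                           max_fraction_removed = 0.01),
                 "removed")
  expect_equal(nrow(flt$fixes), 2L)
})

test_that("tracks split at transmission gaps with alphabetic suffixes", {
  tr <- mk_track(hours = c(0, 1, 2, 35, 36) * 24,
                 lon = -75 + 0:4 * 0.1, lat = -40 + 0:4 * 0.1, tag = "2")
  segs <- split_on_gap(tr, gap_days = 28)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) s$track_id, ""), c("2a", "2b"))
  expect_equal(vapply(segs, function(s) nrow(s$fixes), 0L), c(3L, 2L))
  # conservation of fixes
  expect_equal(sum(vapply(segs, function(s) nrow(s$fixes), 0L)),
               nrow(tr$fixes))

  # no gap: single unsuffixed track
  one <- split_on_gap(tr, gap_days = 40)
  expect_length(one, 1L)
  expect_equal(one[[1]]$track_id, "2")

  # trailing singleton dropped with a warning
  tr2 <- mk_track(hours = c(0, 24, 48, 2000), lon = rep(-75, 4),
                  lat = rep(-40, 4))
  expect_warning(segs2 <- split_on_gap(tr2, gap_days = 28), "dropped")
  expect_length(segs2, 1L)
})

test_that("track duration counts both endpoint dates", {
  expect_equal(track_duration(start = as.Date("2013-04-01"),
                              end = as.Date("2013-05-15")), 45L)
  expect_equal(track_duration(start = as.Date("2015-04-14"),
                              end = as.Date("2015-07-05")), 83L)
  expect_equal(track_duration(start = as.Date("2016-04-05"),
                              end = as.Date("2016-10-22")), 201L)
  expect_equal(track_duration(start = as.Date("2015-06-01"),
                              end = as.Date("2015-06-01")), 1L)
  expect_error(track_duration(start = as.Date("2015-06-02"),
                              end = as.Date("2015-06-01")), "precedes")
})

test_that("published deployment dates reproduce printed durations (whale 9 prints 23 where its dates give 22)", {
  t1 <- table1_deployments()
  computed <- mapply(function(s, e) track_duration(start = s, end = e),
                     t1$start, t1$end)
  consistent <- t1$id != "9"
  expect_equal(computed[consistent], t1$duration_days[consistent])
  expect_equal(computed[t1$id == "9"], 22L)   # printed value is 23
})
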