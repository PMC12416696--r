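test_that("minimal canonical files round-trip exactly", {
  an <- animal_table(0)
  pos <- array(NA_real_, c(2, 2, 2))
  pos[, 1, ] <- c(10, 11, 5, 6)
  pos[, 2, ] <- c(20, 21, 7, 8)
  ts <- trackset(c(0, 0.2), pos, an, fps = 5, anchor_pnd = 16)
  expect_length(ts$time_s, 2)

  csv <- tempfile(fileext = ".csv")
  write_trackset(ts, csv, "wide-csv")
  back <- load_trackset(csv, "wide-csv")
  expect_equal(back$pos, ts$pos, tolerance = 1e-9)
  expect_identical(back$animals, ts$animals)
  expect_equal(back$fps, ts$fps)

  h5 <- tempfile(fileext = ".h5")
  write_trackset(ts, h5, "canonical-h5")
  back2 <- load_trackset(h5, "canonical-h5")
  expect_equal(back2$pos, ts$pos, tolerance = 1e-9)
  expect_equal(back2$time_s, ts$time_s)
  expect_identical(back2$animals, ts$animals)
})

test_that("simulated family round-trips through both dialects", {
  sim <- simulate_family(sim_config(days = 15:16, seconds_per_hour = 30,
                                    seed = 3))
  ts <- sim$tracks
  for (d in c("wide-csv", "canonical-h5")) {
    p <- tempfile(fileext = if (d == "wide-csv") ".csv" else ".h5")
    write_trackset(ts, p, d)
    back <- load_trackset(p, d)
    expect_equal(back$pos, ts$pos, tolerance = 1e-9)
    expect_identical(is.na(back$pos), is.na(ts$pos))
    expect_equal(back$time_s, ts$time_s, tolerance = 1e-9)
    expect_equal(frame_pnd(back), frame_pnd(ts))
  }
})

test_that("malformed or invalid inputs are rejected with informative errors", {
  an <- animal_table(0)
  pos <- array(1, c(2, 2, 2))
  expect_error(trackset(c(1, 0), pos, an), "strictly increasing")
  bad <- pos; bad[2, 1, 1] <- 100
  expect_error(trackset(c(0, 1), bad, an), "bounds")
  expect_error(trackset(c(0, 1), pos, data.frame(name = c("female", "dog"),
                                                 age_class = c("adult", "adult"))),
               "unknown animal")
  expect_error(load_trackset(tempfile(), "wide-csv"), "not found")
  # header-less csv
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1, b = 2), p, row.names = FALSE)
  expect_error(load_trackset(p, "wide-csv"), "time_s")
})

test_that("pose-export adapter converts pixel units and medians nodes", {
  h5 <- tempfile(fileext = ".h5")
  tr <- array(NA_real_, c(3, 2, 6, 2))
  # female: all 6 nodes at (100, 100) px at every frame
  tr[, 1, , 1] <- 100; tr[, 1, , 2] <- 100
  # male: node x-values 10,20,30,40,50,600 px -> median 35 px
  for (f in 1:3) {
    tr[f, 2, , 1] <- c(10, 20, 30, 40, 50, 600)
    tr[f, 2, , 2] <- 50
  }
  rhdf5::h5createFile(h5)
  rhdf5::h5write(tr, h5, "tracks")
  rhdf5::h5write(c("female", "male"), h5, "track_names")
  rhdf5::h5write(0.1, h5, "px_to_cm")
  rhdf5::h5write(5, h5, "fps")
  rhdf5::h5closeAll()
  ts <- load_trackset(h5, "pose-export")
  expect_equal(unname(centroid_series(ts, "female")[1, ]), c(10, 10))
  expect_equal(unname(centroid_series(ts, "male")[1, 1]), 3.5)

  # missing scale is an error
  h5b <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(h5b)
  rhdf5::h5write(tr, h5b, "tracks")
  rhdf5::h5write(c("female", "male"), h5b, "track_names")
  rhdf5::h5closeAll()
  expect_error(load_trackset(h5b, "pose-export"), "px_to_cm")
})

test_that("median centroid is node-order invariant and handles missing nodes", {
  an <- animal_table(0)
  pos <- array(5, c(2, 2, 2))
  poses <- array(NA_real_, c(2, 2, 6, 2))
  xs <- c(1, 2, 3, 4, 5, 100)
  poses[1, 1, , 1] <- xs; poses[1, 1, , 2] <- 10
  poses[2, 1, , 1] <- sample(xs); poses[2, 1, , 2] <- 10
  # male has no nodes at frame 2
  poses[1, 2, , ] <- 7
  ts <- trackset(c(0, 0.2), pos, an, fps = 5, poses = poses)
  cf <- centroid_series(ts, "female")
  expect_equal(unname(cf[1, 1]), 3.5)        # median damps the stray node
  expect_equal(unname(cf[2, 1]), unname(cf[1, 1]))   # invariant to node order
  cm <- centroid_series(ts, "male")
  expect_equal(unname(cm[1, ]), c(7, 7))
  expect_true(all(is.na(cm[2, ])))
  expect_error(centroid_series(ts, "pup1"), "unknown animal")
})

test_that("light phase uses the half-open day convention and partitions time", {
  sch <- light_schedule()
  expect_equal(light_phase(sch, 8 * 3600), "day")
  expect_equal(light_phase(sch, 20 * 3600), "night")
  expect_equal(light_phase(sch, 8 * 3600 - 1), "night")
  secs <- seq(0, 86399, by = 613)
  ph <- light_phase(sch, secs)
  expect_true(all(ph %in% c("day", "night")))
  # wrapped schedule (lights on over midnight) still partitions
  sch2 <- light_schedule(22, 6)
  expect_equal(light_phase(sch2, 23 * 3600), "day")
  expect_equal(light_phase(sch2, 7 * 3600), "night")
})

test_that("bout and daily-matrix CSV round-trips preserve content", {
  b <- bout_series("proximity", "pup1|pup2", c(0, 10), c(5, 12))
  p <- tempfile(fileext = ".csv")
  write_bouts(b, p)
  expect_equal(as.data.frame(read_bouts(p)), as.data.frame(b))
  expect_error(bout_series("x", "a", 5, 5), "end_s > start_s")
  expect_error(bout_series("x", "a", c(0, 3), c(5, 8)), "overlap")

  m <- daily_matrix(matrix(1:6 + 0.5, 2, 3,
                           dimnames = list(c("pup1", "pup2"), 16:18)),
                    "open_exploration", "hrs/day")
  p2 <- tempfile(fileext = ".csv")
  write_daily_matrix(m, p2)
  back <- read_daily_matrix(p2)
  expect_equal(unclass(back), unclass(m))
  expect_equal(attr(back, "units"), "hrs/day")
  expect_error(daily_matrix(matrix(1, 1, 1, dimnames = list("a", 40)),
                            "x", "hrs/day"), "P15-P30")
})

test_that("coverage reflects recorded fraction of each day", {
  sim <- simulate_family(sim_config(days = 15:16, seconds_per_hour = 100,
                                    downtime_frac = 0.1, seed = 5))
  cov <- coverage_by_day(sim$tracks)
  expect_equal(nrow(cov), 2)
  expected <- 24 * floor(100 * 5 * 0.9) / 5 / 86400
  expect_equal(cov$coverage, rep(expected, 2), tolerance = 1e-9)
})
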