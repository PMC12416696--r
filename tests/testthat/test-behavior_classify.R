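test_that("ROI occupancy forms bouts and matches a per-frame oracle", {
  # 50 consecutive frames inside at 25 fps -> one bout of 2.0 s
  xa <- c(rep(30, 10), rep(5, 50), rep(30, 10))
  ts <- toy_trackset(xa, rep(30, 70), fps = 25)
  roi <- c(0, 19.5, 25.1, 35.6)
  out <- roi_occupancy(ts, "female", roi)
  expect_equal(nrow(out$bouts), 1)
  expect_equal(out$bouts$end_s - out$bouts$start_s, 2.0)
  # centroid exactly on the edge is inside (closed rectangle)
  ts_edge <- toy_trackset(19.5, 25.1, fps = 25)
  expect_equal(sum(in_rect(centroid_series(ts_edge, "female"), roi)), 1)
  # random-walk fixture vs brute-force point-in-rectangle scan
  set.seed(11)
  xw <- cumsum(rnorm(2000, 0, 1.5)) %% 57.2
  yw <- cumsum(rnorm(2000, 0, 1.5)) %% 35.6
  tsw <- toy_trackset(xw, yw, fps = 25)
  ow <- roi_occupancy(tsw, "female", roi)
  brute <- sum(xw >= roi[1] & xw <= roi[2] & yw >= roi[3] & yw <= roi[4])
  cov <- coverage_by_day(tsw)$coverage
  expect_equal(ow$daily$hours, brute / 25 / 3600 / cov, tolerance = 1e-9)
})

test_that("distance traveled matches a cumulative-sum oracle and unit checks", {
  ts_fix <- toy_trackset(rep(10, 100), rep(10, 100))
  expect_equal(distance_traveled(ts_fix, "female")$meters, 0)
  # straight 50 cm path -> 0.5 m (undo the coverage rescale)
  xa <- seq(5, 55, length.out = 101)
  ts2 <- toy_trackset(xa, rep(10, 101), fps = 5)
  cov <- coverage_by_day(ts2)$coverage
  expect_equal(distance_traveled(ts2, "female")$meters * cov, 0.5,
               tolerance = 1e-9)
  # seeded random walk vs independent cumulative-sum oracle
  set.seed(3)
  xw <- pmin(pmax(cumsum(rnorm(500, 0, 1)), 0.1), 57)
  yw <- pmin(pmax(cumsum(rnorm(500, 0, 1)), 0.1), 35.5)
  xw[100:120] <- NA                    # missing run is skipped, not bridged
  tsw <- toy_trackset(xw, yw, fps = 5)
  d <- sqrt(diff(xw)^2 + diff(yw)^2)
  oracle <- sum(d, na.rm = TRUE) / 100
  covw <- coverage_by_day(tsw)$coverage
  expect_equal(distance_traveled(tsw, "female")$meters * covw, oracle,
               tolerance = 1e-6)
})

test_that("proximity bouts respect the distance and duration thresholds", {
  mk <- function(d, n, fps = 25) {
    toy_trackset(rep(10, n), rep(10, n), rep(10 + d, n), rep(10, n), fps = fps)
  }
  # 4.9 cm for 8 frames (320 ms) -> one bout
  expect_equal(nrow(pairwise_proximity(mk(4.9, 8), "female", "male")$bouts), 1)
  # 4.9 cm for 4 frames (160 ms) -> none
  expect_equal(nrow(pairwise_proximity(mk(4.9, 4), "female", "male")$bouts), 0)
  # 5.0 cm exactly -> none (strict inequality)
  expect_equal(nrow(pairwise_proximity(mk(5.0, 8), "female", "male")$bouts), 0)
  # symmetric in its arguments
  sim <- default_sim()
  pa <- pairwise_proximity(sim$tracks, "pup1", "pup2")
  pb <- pairwise_proximity(sim$tracks, "pup2", "pup1")
  expect_equal(pa$daily, pb$daily)
  # monotone in the distance threshold
  t4 <- sum(pairwise_proximity(sim$tracks, "pup1", "pup2", dist_cm = 4)$daily$hours)
  t5 <- sum(pairwise_proximity(sim$tracks, "pup1", "pup2", dist_cm = 5)$daily$hours)
  t8 <- sum(pairwise_proximity(sim$tracks, "pup1", "pup2", dist_cm = 8)$daily$hours)
  expect_true(t4 <= t5 && t5 <= t8)
})

test_that("group membership is a partition built from connected components", {
  an <- animal_table(2)
  pos <- array(NA_real_, c(1, 4, 2))
  # A-B 4 cm, B-C 4 cm, A-C 8 cm -> one chained group
  pos[1, 1, ] <- c(10, 10)
  pos[1, 2, ] <- c(14, 10)
  pos[1, 3, ] <- c(18, 10)
  pos[1, 4, ] <- c(40, 30)
  ts <- trackset(0, pos, an, fps = 5, anchor_pnd = 16)
  gm <- group_membership(ts)
  expect_equal(unname(gm$size[1, ]), c(3L, 3L, 3L, 1L))
  # all far apart -> singletons
  pos2 <- pos
  pos2[1, , 1] <- c(5, 15, 30, 50); pos2[1, , 2] <- c(5, 20, 5, 30)
  gm2 <- group_membership(trackset(0, pos2, an, fps = 5, anchor_pnd = 16))
  expect_equal(unname(gm2$size[1, ]), rep(1L, 4))
  # pup1 sits in a group containing both adults
  expect_false(any(gm$pup_only[1, ]))
  expect_true(gm$with_adult[1, "pup1"])
  # a pup pair with no adult is pup-only
  pos3 <- pos
  pos3[1, , 1] <- c(5, 50, 30, 33); pos3[1, , 2] <- c(5, 30, 10, 10)
  gm3 <- group_membership(trackset(0, pos3, an, fps = 5, anchor_pnd = 16))
  expect_true(all(gm3$pup_only[1, c("pup1", "pup2")]))
  expect_false(any(gm3$with_adult[1, ]))
})

test_that("every tracked animal belongs to exactly one group per frame", {
  sim <- default_sim()
  idx <- seq(1, 5000)
  ts <- sim$tracks
  sub <- trackset(ts$time_s[idx], ts$pos[idx, , , drop = FALSE], ts$animals,
                  fps = ts$fps, anchor_pnd = ts$anchor_pnd, cage = ts$cage)
  gm <- group_membership(sub)
  tracked <- !is.na(sub$pos[, , 1])
  expect_identical(!is.na(gm$size), tracked)
  expect_true(all(gm$size[tracked] >= 1))
  # brute-force oracle on a handful of frames with pairs in range
  cand <- which(rowSums(gm$size >= 2, na.rm = TRUE) > 0)[1:20]
  cand <- cand[!is.na(cand)]
  for (f in cand) {
    p <- sub$pos[f, , ]
    present <- which(!is.na(p[, 1]))
    adj <- matrix(FALSE, 6, 6)
    for (i in present) for (j in present) {
      if (i < j && sqrt(sum((p[i, ] - p[j, ])^2)) < 5) adj[i, j] <- adj[j, i] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(adj[present, present, drop = FALSE],
                                             mode = "undirected")
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    expect_equal(unname(gm$size[f, present]), as.integer(sizes))
  }
})

test_that("approach detection follows the kinematic definition", {
  # target fixed; initiator closes 20 -> 2 cm at 5 cm/s then stops
  n <- 100; tm <- (0:(n - 1)) / 5
  xa <- rep(30, n); ya <- rep(17.8, n)
  xb <- pmax(30 + 20 - tm * 5, 32); yb <- rep(17.8, n)
  ts <- toy_trackset(xa, ya, xb, yb)
  ev <- detect_approaches(ts, "male", "female")
  expect_equal(nrow(ev$events), 1)
  expect_lte(ev$events$d_end, 10)
  # stopping more than one gerbil length away does not count
  xb2 <- pmax(30 + 25 - tm * 5, 45)
  ev2 <- detect_approaches(toy_trackset(xa, ya, xb2, yb), "male", "female")
  expect_equal(nrow(ev2$events), 0)
  # moving away from the target does not count
  xb3 <- pmin(32 + tm * 5, 57)
  ev3 <- detect_approaches(toy_trackset(xa, ya, xb3, yb), "male", "female")
  expect_equal(nrow(ev3$events), 0)
})

test_that("huddle attribution counts missing-during-huddle and near-centroid frames", {
  n <- 100
  hud <- huddle_track(0, n / 5, 45, 10)
  # animal missing the whole time while a huddle is active -> fully attributed
  ts <- toy_trackset(rep(NA_real_, n), rep(NA_real_, n),
                     rep(20, n), rep(20, n))
  hf <- huddling_flags(ts, hud)
  expect_true(all(hf[, "female"]))
  expect_false(any(hf[, "male"]))     # tracked 10+ cm away: not huddling
  # tracked within the attribution radius counts
  ts2 <- toy_trackset(rep(44, n), rep(10, n), rep(55, n), rep(10, n))
  hf2 <- huddling_flags(ts2, hud)
  expect_true(all(hf2[, "female"]))
  # missing-track attribution can be disabled
  hf3 <- huddling_flags(ts, hud, attribute_missing = FALSE)
  expect_false(any(hf3[, "female"]))
})

test_that("simulated huddle hours are recovered within 5 percent", {
  sim <- default_sim()
  hud <- huddle_time(sim$tracks, sim$huddles)
  gt <- sim$ground_truth$budgets
  key <- paste(hud$animal, hud$pnd)
  gt_nest <- gt$nest_h[match(key, paste(gt$animal, gt$pnd))]
  rel_err <- abs(hud$hours - gt_nest) / gt_nest
  expect_lt(mean(rel_err), 0.05)
})

test_that("per-day time budget closes to 24 h within one second", {
  sim <- default_sim()
  bud <- daily_time_budget(sim$tracks, sim$huddles)
  tot <- bud$huddle_h + bud$open_h + bud$missing_h
  expect_true(all(abs(tot - 24) * 3600 < 1))
})

test_that("nest-following matches each adult exit to one pup exit in the window", {
  an <- animal_table(2)
  exits <- data.frame(animal = c("pup1", "male"),
                      time_s = c(100, 108), pnd = 16L)
  expect_equal(sum(nest_following(exits, an)$count), 1)   # 8 s < 10 s
  exits2 <- data.frame(animal = c("pup1", "male"),
                       time_s = c(100, 112), pnd = 16L)
  expect_equal(sum(nest_following(exits2, an)$count), 0)  # outside window
  # two pups, one adult: single match to the earliest unmatched pup
  exits3 <- data.frame(animal = c("pup1", "pup2", "male"),
                       time_s = c(100, 101, 105), pnd = 16L)
  expect_equal(sum(nest_following(exits3, an)$count), 1)
})

test_that("recovered daily behaviors track the planted activity budgets", {
  sim <- default_sim()
  etho <- default_ethogram()
  gt <- sim$ground_truth$budgets
  gt <- gt[order(gt$animal, gt$pnd), ]
  map <- c(open_exploration = "active_h", food = "food_h", water = "water_h",
           distance_traveled = "distance_m")
  for (b in names(map)) {
    rec <- as.numeric(t(etho[[b]][sort(rownames(etho[[b]])), ]))
    expect_gt(cor(rec, gt[[map[b]]]), 0.9)
  }
})
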