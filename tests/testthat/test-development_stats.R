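test_that("adult normalization scales by the P29 adult mean and inverts", {
  m <- matrix(1, 6, 16, dimnames = list(animal_table(4)$name, 15:30))
  m["female", "29"] <- 4; m["male", "29"] <- 6
  m["pup1", ] <- 1.0
  dm <- daily_matrix(m, "open_exploration", "hrs/day")
  rel <- normalize_to_adult(dm, animal_table(4))
  expect_equal(rel$reference, 5)
  expect_equal(unname(rel$values["pup1", "20"]), 0.2)
  # a pup at the reference level maps to 1.0
  m2 <- dm; m2["pup2", ] <- 5
  rel2 <- normalize_to_adult(m2, animal_table(4))
  expect_equal(unname(rel2$values["pup2", "16"]), 1.0)
  # multiplying back recovers the input exactly
  expect_equal(rel$values * rel$reference,
               unclass(dm)[animal_table(4)$name[-(1:2)], ])
  # zero reference is an error
  m3 <- dm; m3[c("female", "male"), "29"] <- 0
  expect_error(normalize_to_adult(m3, animal_table(4)), "zero")
})

test_that("rapid-development detection flags a planted step, not a flat series", {
  days <- 15:30
  mk <- function(level_fn, seed) {
    set.seed(seed)
    m <- t(vapply(1:12, function(i)
      level_fn(days) + rnorm(length(days), 0, 0.05), numeric(length(days))))
    dimnames(m) <- list(paste0("p", 1:12), days)
    m
  }
  # flat series with small noise: no flags
  flat <- mk(function(d) rep(1, length(d)), 1)
  expect_length(rapid_development_days(flat)$flags, 0)
  # planted step at P22
  step <- mk(function(d) ifelse(d < 22, 1, 2), 2)
  out <- rapid_development_days(step)
  expect_true(22 %in% out$flags)
  expect_false(any(out$flags < 22))
  # monotone ramp: consecutive flags until the plateau
  ramp <- mk(function(d) pmin((d - 15) * 0.5, 3), 3)
  fr <- rapid_development_days(ramp)$flags
  expect_true(all(17:21 %in% fr))
  expect_false(30 %in% fr)
})

test_that("flag rate under the global null stays near alpha", {
  days <- 15:30
  n_flag <- 0; n_tests <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    m <- matrix(rnorm(12 * length(days), 1, 0.05), 12,
                dimnames = list(NULL, days))
    out <- rapid_development_days(m)
    n_flag <- n_flag + length(out$flags)
    n_tests <- n_tests + nrow(out$table)
  }
  expect_lt(n_flag / n_tests, 0.05 * 1.5)
})

test_that("hull overlap reproduces closed-form and degenerate cases", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  shifted <- sweep(cube, 2, c(0.5, 0, 0), "+")
  # shifted unit cubes: Jaccard = 0.5 / 1.5 = 33.3%
  expect_equal(hull_jaccard(cube, shifted, n_samples = 2e5, seed = 1),
               100 / 3, tolerance = 1)
  # identical sets overlap fully; distant sets not at all
  expect_equal(hull_jaccard(cube, cube, seed = 2), 100)
  far <- sweep(cube, 2, c(200, 0, 0), "+")
  expect_equal(hull_jaccard(cube, far, n_samples = 5e4, seed = 3), 0)
  # symmetry and bounds on random clouds
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30, 0.5), 10, 3)
  ab <- hull_jaccard(a, b, n_samples = 5e4, seed = 5)
  ba <- hull_jaccard(b, a, n_samples = 5e4, seed = 5)
  expect_equal(ab, ba)
  expect_gte(ab, 0); expect_lte(ab, 100)
  expect_error(hull_jaccard(a[1:2, ], b, seed = 1), "3 points")
  # through the PCA route, identical matrices overlap fully
  m <- matrix(rnorm(60), 12, 5)
  expect_equal(hull_overlap(m, m, seed = 6)$percent, 100)
  # rank-deficient 3D sets fall back to 2 components
  flatm <- cbind(matrix(rnorm(24), 12, 2), 0)
  ho <- hull_overlap(flatm, flatm + 0.1, n_pcs = 3, seed = 7,
                     n_samples = 5e4)
  expect_equal(ho$n_pcs_used, 2)
})

test_that("identity shuffling preserves day multisets and is seed-deterministic", {
  set.seed(9)
  m <- matrix(rnorm(48), 6, 8, dimnames = list(animal_table(4)$name, 16:23))
  s1 <- shuffle_identity(m, 5)
  s2 <- shuffle_identity(m, 5)
  expect_identical(s1, s2)
  for (j in seq_len(ncol(m)))
    expect_equal(unname(sort(s1[, j])), unname(sort(m[, j])))
  expect_error(shuffle_identity(m[1, , drop = FALSE], 1), "2 animals")
})

test_that("shuffling identities inflates apparent inter-behavior hull overlap", {
  sim <- default_sim()
  relw <- family_relative_matrix(sim, "water")
  relf <- family_relative_matrix(sim, "food")
  pups <- grepl("pup", rownames(relw))
  real <- hull_overlap(relw[pups, ], relf[pups, ], n_pcs = 2,
                       n_samples = 5e4, seed = 1)$percent
  shuf <- vapply(1:10, function(s) {
    sw <- shuffle_identity(relw, s)[pups, ]
    sf <- shuffle_identity(relf, 100 + s)[pups, ]
    hull_overlap(sw, sf, n_pcs = 2, n_samples = 5e4, seed = s)$percent
  }, 0)
  expect_gte(mean(shuf), real)
})

test_that("trajectory correlations distinguish real from shuffled identity", {
  two <- list(a = rbind(x = 1:10, y = 1:10) * 1.0,
              b = rbind(x = -(1:10), y = 2 * (1:10)) * 1.0)
  tc <- trajectory_correlations(two)
  expect_equal(tc$r[tc$group == "within" & tc$behavior_a == "a"], 1)
  expect_equal(tc$r[tc$behavior_a == "a" & tc$behavior_b == "b" &
                      tc$animal_a == "x" & tc$animal_b == "x"], -1)
  w <- capture_warnings(trajectory_correlations(
    list(a = rbind(x = rep(1, 5), y = 1:5) * 1.0,
         b = rbind(x = 1:5, y = 5:1) * 1.0)))
  expect_true(all(grepl("zero-variance", w)) && length(w) > 0)
  sim <- default_sim()
  relw <- family_relative_matrix(sim, "water")
  relf <- family_relative_matrix(sim, "food")
  pups <- grepl("pup", rownames(relw))
  # a pup that never visits the waterspout has a zero-variance trajectory
  # and is excluded with a warning; that is expected here
  real <- suppressWarnings(
    trajectory_correlations(list(water = relw[pups, ],
                                 food = relf[pups, ])))
  shuf <- suppressWarnings(trajectory_correlations(
    list(water = shuffle_identity(relw, 3)[pups, ],
         food = shuffle_identity(relf, 4)[pups, ])))
  expect_gt(median(real$r[real$group == "within"]),
            median(shuf$r[shuf$group == "within"]))
})

test_that("Monte-Carlo power is calibrated and agrees with t.test", {
  # null case: rejection rate ~ alpha
  p0 <- power_at_n(5, 0, 1, 0, 1, alpha = 0.05, reps = 4000, seed = 1)
  expect_lt(abs(p0 - 0.05), 2 * sqrt(0.05 * 0.95 / 4000) + 0.005)
  # large n, same effect: power -> 1
  expect_gt(power_at_n(100, 0, 0.1, 1, 0.2, reps = 1000, seed = 2), 0.999)
  # vectorized Welch statistic matches stats::t.test rejections
  set.seed(3)
  n <- 4; rejections <- 0
  for (i in 1:200) {
    xa <- rnorm(n, 0, 0.3); xb <- rnorm(n, 0.5, 0.6)
    rejections <- rejections + (t.test(xa, xb)$p.value < 0.05)
  }
  set.seed(3)
  pw <- power_at_n(n, 0, 0.3, 0.5, 0.6, reps = 1000, seed = 33)
  # both estimate the same power; agree within Monte-Carlo error
  expect_lt(abs(pw - rejections / 200), 4 * sqrt(pw * (1 - pw) / 200))
})
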