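# Shared simulated fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full default family: 6 animals, P15-P30, 5 fps, 120 s recorded per hour.
default_sim <- function() {
  cached("default_sim", simulate_family(sim_config(seed = 42)))
}

# Matching ethogram on the default family.
default_ethogram <- function() {
  cached("default_etho", {
    sim <- default_sim()
    nest <- nest_region_by_day(sim$huddles, sort(unique(frame_pnd(sim$tracks))))
    daily_ethogram(sim$tracks, sim$huddles, nest)
  })
}

# Short 3-day family for corruption tests.
short_sim <- function(seed = 7) {
  key <- paste0("short_sim_", seed)
  cached(key, simulate_family(sim_config(days = 15:17, seed = seed)))
}

# Hand-built 2-animal (female, male) trackset from coordinate vectors;
# NA = missing; the second animal is fully missing unless given.
toy_trackset <- function(xa, ya, xb = NA, yb = NA, fps = 5,
                         anchor_pnd = 16, time_s = NULL) {
  an <- animal_table(0)
  Tn <- length(xa)
  pos <- array(NA_real_, c(Tn, 2, 2))
  pos[, 1, 1] <- xa; pos[, 1, 2] <- ya
  pos[, 2, 1] <- xb; pos[, 2, 2] <- yb
  if (is.null(time_s)) time_s <- (0:(Tn - 1)) / fps
  trackset(time_s, pos, an, fps = fps, anchor_pnd = anchor_pnd)
}

# Per-family adult-relative matrices for one ROI behavior, with adults kept
# (adult rows ~ 1.0), used by shuffle-control tests.
family_relative_matrix <- function(sim, behavior) {
  ts <- sim$tracks
  an <- ts$animals
  days <- sort(unique(frame_pnd(ts)))
  m <- matrix(NA_real_, nrow(an), length(days),
              dimnames = list(an$name, days))
  for (a in an$name) m[a, ] <- roi_occupancy(ts, a, behavior)$daily$hours
  ref <- mean(m[an$name[an$age_class == "adult"], "29"])
  m / ref
}
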