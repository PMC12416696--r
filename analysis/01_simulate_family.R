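#!/usr/bin/env Rscript
# Stage 1: simulate three gerbil families (cohorts) across P15-P30 and write
# the canonical track files, huddle tables, and planted ground truth that
# the later stages consume. Three cohorts of 4 pups give the 12 pooled pups
# the developmental statistics expect.

suppressMessages(library(homecagedev))

out <- "results/analysis"
cache <- "scratch/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(cache, showWarnings = FALSE, recursive = TRUE)

seed0 <- 20260901
for (cohort in 1:3) {
  cfg <- sim_config(days = 15:30, seconds_per_hour = 120,
                    seed = seed0 + cohort)
  sim <- simulate_family(cfg)
  write_trackset(sim$tracks, file.path(cache, sprintf("cohort%d_tracks.csv", cohort)),
                 dialect = "wide-csv")
  utils::write.csv(as.data.frame(sim$huddles),
                   file.path(cache, sprintf("cohort%d_huddles.csv", cohort)),
                   row.names = FALSE)
  utils::write.csv(sim$ground_truth$budgets,
                   file.path(out, sprintf("cohort%d_ground_truth.csv", cohort)),
                   row.names = FALSE)
  cov <- coverage_by_day(sim$tracks)
  message(sprintf(
    "cohort %d: %d frames over P%d-P%d, coverage %.3f, %d huddle intervals",
    cohort, length(sim$tracks$time_s), min(cfg$days), max(cfg$days),
    mean(cov$coverage), nrow(sim$huddles)))
}
message("planted ramps: activity P17, food P22, water P23; ",
        "pup circadian onset P26")
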