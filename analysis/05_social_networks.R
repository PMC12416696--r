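#!/usr/bin/env Rscript
# Stage 5: social-state transition graphs per day for the canonical animal
# subsets (singles, pairs, all pups, all animals) and their metrics; prints
# the late/early graph-size ratios that index the growth of social-state
# complexity.

suppressMessages(library(homecagedev))

out <- "results/analysis"
cache <- "scratch/analysis"
met_all <- NULL
for (cohort in 1:3) {
  ts <- load_trackset(file.path(cache, sprintf("cohort%d_tracks_clean.csv", cohort)),
                      "wide-csv")
  met <- daily_network_metrics(ts)
  met_all <- rbind(met_all, cbind(cohort = cohort, met))
}
utils::write.csv(met_all, file.path(out, "network_metrics.csv"),
                 row.names = FALSE)

ratio <- function(subset_pattern, d_late, d_early) {
  sub <- met_all[grepl(subset_pattern, met_all$subset), ]
  late <- mean(sub$size[sub$pnd == d_late])
  early <- mean(sub$size[sub$pnd == d_early])
  late / early
}
message(sprintf("all-pup graph size P29/P16 ratio:    %.2f",
                ratio("^all_pups$", 29, 16)))
message(sprintf("all-animal graph size P29/P16 ratio: %.2f",
                ratio("^all_animals$", 29, 16)))
message(sprintf("adult-pair graph size P29/P16 ratio: %.2f",
                ratio("^adult_pair$", 29, 16)))
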