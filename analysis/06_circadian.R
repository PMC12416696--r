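#!/usr/bin/env Rscript
# Stage 6: circadian analysis: hourly food-hopper profiles per pup and day,
# day/night activity proportions, and the exhaustive (t1, t2) search for the
# developmental periods that maximize the cumulative Bhattacharyya distance
# between period-average circadian profiles.

suppressMessages(library(homecagedev))

out <- "results/analysis"
cache <- "scratch/analysis"
prof_list <- list(); open_list <- list(); dn_all <- NULL
for (cohort in 1:3) {
  ts <- load_trackset(file.path(cache, sprintf("cohort%d_tracks_clean.csv", cohort)),
                      "wide-csv")
  pups <- ts$animals$name[ts$animals$age_class == "pup"]
  bl <- lapply(pups, function(a) roi_occupancy(ts, a, "food")$bouts)
  names(bl) <- paste0("c", cohort, "_", pups)
  prof <- daily_profiles(bl, ts)
  prof_list[[cohort]] <- prof
  # open-field (whole-cage occupancy) bouts: a denser series for the same
  # transition search
  whole <- c(0, ts$cage$length_cm, 0, ts$cage$width_cm)
  ol <- lapply(pups, function(a) roi_occupancy(ts, a, whole)$bouts)
  names(ol) <- paste0("c", cohort, "_", pups)
  open_list[[cohort]] <- daily_profiles(ol, ts)

  # adult day/night split of food-hopper activity, late development
  sch <- ts$schedule
  for (a in c("female", "male")) {
    pr <- hourly_profile(roi_occupancy(ts, a, "food")$bouts, days = 26:29,
                         coverage_s = hourly_coverage_s(ts, 26:29),
                         anchor_pnd = ts$anchor_pnd)
    dn <- day_night_proportions(pr, light_schedule(sch$day_start_h,
                                                   sch$night_start_h))
    dn_all <- rbind(dn_all, data.frame(cohort = cohort, animal = a,
                                       day = dn["day"], night = dn["night"]))
  }
}
utils::write.csv(dn_all, file.path(out, "day_night_proportions.csv"),
                 row.names = FALSE)
message(sprintf("adult food-hopper day fraction (P26-29): %.2f +/- %.2f",
                mean(dn_all$day), stats::sd(dn_all$day)))

# pool the 12 pups and search the transition days, on the food-hopper
# series and on the denser open-field series; window P16-P29
pool <- function(plist) {
  days <- dimnames(plist[[1]])[[2]]
  prof <- array(NA_real_, c(12, length(days), 24),
                dimnames = list(unlist(lapply(plist, function(p)
                  dimnames(p)[[1]])), days, 0:23))
  k <- 0
  for (p in plist) for (a in seq_len(dim(p)[1])) {
    k <- k + 1
    prof[k, , ] <- p[a, , ]
  }
  prof[, as.integer(days) >= 16 & as.integer(days) <= 29, , drop = FALSE]
}
res <- NULL
for (series in c("food", "open_field")) {
  prof <- pool(if (series == "food") prof_list else open_list)
  tr <- find_transitions(prof)
  utils::write.csv(tr$surface,
                   file.path(out, sprintf("circadian_surface_%s.csv", series)),
                   row.names = FALSE)
  res <- rbind(res, data.frame(series = series, t1 = tr$t1, t2 = tr$t2,
                               J = tr$J, degenerate = tr$degenerate))
  message(sprintf(
    "%s: developmental periods D1 = P16-P%d, D2 = P%d-P%d, D3 = P%d-P29 (J = %.2f)",
    series, tr$t1, tr$t1 + 1, tr$t2, tr$t2 + 1, tr$J))
}
utils::write.csv(res, file.path(out, "circadian_transitions.csv"),
                 row.names = FALSE)
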