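#!/usr/bin/env Rscript
# Stage 4: developmental statistics over the pooled 12 pups: adult-relative
# trajectories, rapid-development days (K-S + Benjamini-Hochberg), convex
# hull overlaps in PC space, identity-shuffle controls, pairwise trajectory
# correlations, and the sample-size power table.

suppressMessages(library(homecagedev))

out <- "results/analysis"
cache <- "scratch/analysis"
etho <- utils::read.csv(file.path(out, "daily_ethograms.csv"))
days <- sort(unique(etho$pnd))
behaviors <- c("open_exploration", "distance_traveled", "food", "water")

# adult-relative matrices (adults kept at ~1.0), cohort-wise reference,
# rows pooled; pup-only views for the developmental statistics
rel_full <- list(); rel <- list(); abs_pup <- list()
for (b in behaviors) {
  rows_full <- NULL; rows_abs <- NULL
  for (cohort in sort(unique(etho$cohort))) {
    sub <- etho[etho$behavior == b & etho$cohort == cohort, ]
    m <- matrix(NA_real_, length(unique(sub$animal)), length(days),
                dimnames = list(unique(sub$animal), days))
    m[cbind(match(sub$animal, rownames(m)), match(sub$pnd, days))] <- sub$value
    ref <- mean(m[c("female", "male"), "29"])
    v <- m / ref
    rownames(v) <- paste0("c", cohort, "_", rownames(v))
    rows_full <- rbind(rows_full, v)
    ma <- m[grepl("pup", rownames(m)), ]
    rownames(ma) <- paste0("c", cohort, "_", rownames(ma))
    rows_abs <- rbind(rows_abs, ma)
  }
  rel_full[[b]] <- rows_full
  rel[[b]] <- rows_full[grepl("pup", rownames(rows_full)), ]
  abs_pup[[b]] <- rows_abs
}

# rapid development days per behavior over the pooled pups
flags <- NULL
for (b in behaviors) {
  rd <- rapid_development_days(abs_pup[[b]])
  if (nrow(rd$table) > 0)
    flags <- rbind(flags, cbind(behavior = b, rd$table))
  message(sprintf("%s: rapid-development days %s", b,
                  paste(rd$flags, collapse = ", ")))
}
utils::write.csv(flags, file.path(out, "rapid_development.csv"),
                 row.names = FALSE)

# convex hull overlaps of the pup trajectories, real vs identity-shuffled.
# The shuffle permutes all six animals of a family within each day before
# extracting the pup rows: it emulates what losing identity tracking would
# do, mixing adult-level days into pup trajectories.
shuffled_pups <- function(b, seed) {
  v <- shuffle_identity(rel_full[[b]], seed)
  v[grepl("pup", rownames(v)), ]
}
ov <- NULL
for (i in seq_along(behaviors)) for (j in seq_along(behaviors)) {
  if (j <= i) next
  a <- behaviors[i]; b <- behaviors[j]
  real <- hull_overlap(rel[[a]], rel[[b]], seed = 1)
  sh <- hull_overlap(shuffled_pups(a, 11), shuffled_pups(b, 12), seed = 2)
  ov <- rbind(ov,
              data.frame(behavior_a = a, behavior_b = b, condition = "real",
                         n_pcs = real$n_pcs_used, percent = real$percent),
              data.frame(behavior_a = a, behavior_b = b, condition = "shuffled",
                         n_pcs = sh$n_pcs_used, percent = sh$percent))
}
utils::write.csv(ov, file.path(out, "hull_overlaps.csv"), row.names = FALSE)
message("hull overlap (real): median ",
        sprintf("%.2f%%", stats::median(ov$percent[ov$condition == "real"])),
        "; (shuffled): ",
        sprintf("%.2f%%", stats::median(ov$percent[ov$condition == "shuffled"])))

# pairwise trajectory correlations, real vs shuffled
tc_real <- cbind(condition = "real", trajectory_correlations(rel))
rel_sh <- lapply(seq_along(behaviors), function(k)
  shuffled_pups(behaviors[k], 100 + k))
names(rel_sh) <- behaviors
tc_sh <- cbind(condition = "shuffled", trajectory_correlations(rel_sh))
utils::write.csv(rbind(tc_real, tc_sh),
                 file.path(out, "trajectory_correlations.csv"),
                 row.names = FALSE)

# power analysis table: sample sizes for the P16 pup-vs-adult contrast
pow <- do.call(rbind, lapply(c(3, 4, 6, 12), function(n) {
  data.frame(n_per_group = n,
             power = power_at_n(n, 0, 0.10, 1, 0.20, alpha = 0.05,
                                reps = 10000, seed = 400 + n))
}))
utils::write.csv(pow, file.path(out, "power_table.csv"), row.names = FALSE)
print(pow)
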