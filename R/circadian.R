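# Circadian analysis: hourly ethogram profiles, day/night partition of
# activity, Bhattacharyya distance between hourly profiles, and exhaustive
# detection of the two developmental breakpoints that best separate the
# circadian structure of early, middle, and late postnatal periods.

#' Recorded seconds per clock hour
#'
#' @param ts A [trackset()].
#' @param days Postnatal days to include (default: all in the set).
#' @return `length(days) x 24` matrix of recorded seconds.
#' @export
hourly_coverage_s <- function(ts, days = NULL) {
  pnd <- frame_pnd(ts)
  if (is.null(days)) days <- sort(unique(pnd))
  hour <- floor(frame_clock_s(ts) / 3600)
  out <- matrix(0, length(days), 24, dimnames = list(days, 0:23))
  for (i in seq_along(days)) {
    sel <- pnd == days[i]
    tab <- table(factor(hour[sel], levels = 0:23))
    out[i, ] <- as.numeric(tab) / ts$fps
  }
  out
}

# Distribute bout seconds of one day into 24 wall-clock hour bins,
# splitting bouts proportionally across hour boundaries.
bin_bouts_hourly <- function(start_s, end_s) {
  v <- numeric(24)
  for (i in seq_along(start_s)) {
    s <- start_s[i] %% 86400
    dur <- end_s[i] - start_s[i]
    e <- s + dur
    h0 <- floor(s / 3600); h1 <- floor((e - 1e-9) / 3600)
    for (h in h0:h1) {
      lo <- max(s, h * 3600); hi <- min(e, (h + 1) * 3600)
      v[(h %% 24) + 1] <- v[(h %% 24) + 1] + (hi - lo)
    }
  }
  v
}

#' Hourly behavior profile
#'
#' Accumulates bout seconds into 24 wall-clock hour bins over a day range,
#' then divides each bin by its recorded coverage (seconds of recording in
#' that bin over the same days). The result is behavior time per unit
#' recorded time, per hour of the day. Bins with zero coverage are `NA`.
#'
#' @param bouts A [bout_series()] (one subject).
#' @param days Postnatal days to average over.
#' @param coverage_s `days x 24` matrix from [hourly_coverage_s()], or
#'   `NULL` for no rescale (uniform coverage assumed).
#' @param anchor_pnd Postnatal day containing `start_s = 0`.
#' @return Numeric vector of 24 hour-bin values (class `circadian_profile`).
#' @export
hourly_profile <- function(bouts, days, coverage_s = NULL, anchor_pnd = 15) {
  acc <- numeric(24)
  pnd <- anchor_pnd + floor(bouts$start_s / 86400)
  for (d in days) {
    sel <- pnd == d
    if (any(sel)) acc <- acc + bin_bouts_hourly(bouts$start_s[sel], bouts$end_s[sel])
  }
  if (is.null(coverage_s)) {
    out <- acc / (length(days) * 3600)
  } else {
    cov <- colSums(coverage_s[as.character(days), , drop = FALSE])
    out <- ifelse(cov > 0, acc / cov, NA_real_)
  }
  structure(out, class = "circadian_profile")
}

#' Normalize a profile to a probability distribution
#'
#' @param profile 24-bin profile (missing bins treated as zero).
#' @return Profile summing to 1, or all-zero if the total is zero.
#' @export
normalize_profile <- function(profile) {
  v <- as.numeric(profile)
  v[is.na(v)] <- 0
  tot <- sum(v)
  if (tot > 0) v / tot else v
}

#' Day/night split of an hourly profile
#'
#' @param profile 24-bin profile.
#' @param schedule A [light_schedule()].
#' @return c(day = fraction, night = fraction); sums to 1.
#' @export
day_night_proportions <- function(profile, schedule) {
  v <- as.numeric(profile)
  v[is.na(v)] <- 0
  tot <- sum(v)
  if (tot == 0) stop("profile total is zero: day/night split undefined")
  phase <- light_phase(schedule, (0:23) * 3600)
  c(day = sum(v[phase == "day"]) / tot,
    night = sum(v[phase == "night"]) / tot)
}

#' Bhattacharyya distance between two normalized profiles
#'
#' `D = -ln sum_i sqrt(p_i q_i)`; zero iff the distributions are identical,
#' `+Inf` for disjoint supports. An `eps` regularization
#' (`-ln(BC + eps)`) is available for robustness to disjoint supports.
#'
#' @param p,q Non-negative vectors of equal length, each summing to 1
#'   (tolerance 1e-6).
#' @param eps Regularizer added to the Bhattacharyya coefficient (default 0).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
bhattacharyya_distance <- function(p, q, eps = 0) {
  if (length(p) != length(q)) stop("profiles must have equal length")
  if (any(p < 0) || any(q < 0)) stop("profiles must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("profiles must be normalized (sum to 1)")
  bc <- sum(sqrt(p * q))
  -log(bc + eps)
}

#' Detect circadian developmental transitions
#'
#' Exhaustively searches the two postnatal-day breakpoints (t1, t2) that
#' partition the day range into three periods D1 = [first, t1],
#' D2 = (t1, t2], D3 = (t2, last] (each at least `min_days` long) and
#' maximize the cumulative Bhattacharyya distance
#' `J(t1, t2) = sum over animals, sum over unordered period pairs, of
#' D(mean profile_i, mean profile_j)`, where an animal's period profile is
#' the mean of its daily normalized profiles. Ties are broken by the
#' lexicographically earliest (t1, t2).
#'
#' @param profiles 3-D array `animals x days x 24` of daily hourly profiles
#'   (need not be normalized; days as dimnames of dim 2).
#' @param min_days Minimum days per period (default 2).
#' @param eps Bhattacharyya regularizer (default 1e-12), keeps the objective
#'   finite when supports are disjoint.
#' @param pairs `"all"` (default) sums over all period pairs; `"adjacent"`
#'   only over (D1,D2) and (D2,D3).
#' @return list: `t1`, `t2`, `J`, `surface` (data.frame t1, t2, J),
#'   `degenerate` (TRUE when the objective is flat).
#' @export
find_transitions <- function(profiles, min_days = 2, eps = 1e-12,
                             pairs = c("all", "adjacent")) {
  pairs <- match.arg(pairs)
  stopifnot(length(dim(profiles)) == 3, dim(profiles)[3] == 24)
  days <- as.integer(dimnames(profiles)[[2]])
  if (length(days) < 3 * min_days) stop("insufficient days for 3 periods")
  n_animals <- dim(profiles)[1]
  norm_daily <- array(NA_real_, dim(profiles))
  for (a in seq_len(n_animals)) {
    for (d in seq_along(days)) {
      norm_daily[a, d, ] <- normalize_profile(profiles[a, d, ])
    }
  }
  period_profile <- function(a, sel) {
    m <- norm_daily[a, sel, , drop = FALSE]
    dim(m) <- c(sum(sel), 24)
    keep <- rowSums(m) > 0
    if (!any(keep)) return(NULL)
    normalize_profile(colMeans(m[keep, , drop = FALSE]))
  }
  first <- days[1]; last <- days[length(days)]
  grid <- list()
  best <- list(J = -Inf)
  for (t1 in days) {
    for (t2 in days) {
      n1 <- sum(days <= t1)
      n2 <- sum(days > t1 & days <= t2)
      n3 <- sum(days > t2)
      if (n1 < min_days || n2 < min_days || n3 < min_days) next
      J <- 0
      for (a in seq_len(n_animals)) {
        p1 <- period_profile(a, days <= t1)
        p2 <- period_profile(a, days > t1 & days <= t2)
        p3 <- period_profile(a, days > t2)
        if (is.null(p1) || is.null(p2) || is.null(p3)) next
        pp <- if (pairs == "all") list(c(1, 2), c(1, 3), c(2, 3))
        else list(c(1, 2), c(2, 3))
        ps <- list(p1, p2, p3)
        for (ij in pp) {
          J <- J + bhattacharyya_distance(ps[[ij[1]]], ps[[ij[2]]], eps = eps)
        }
      }
      grid[[length(grid) + 1]] <- data.frame(t1 = t1, t2 = t2, J = J)
      if (J > best$J + 1e-12) best <- list(t1 = t1, t2 = t2, J = J)
    }
  }
  if (length(grid) == 0) stop("no valid (t1, t2) partition")
  surface <- do.call(rbind, grid)
  degenerate <- (max(surface$J) - min(surface$J)) < 1e-9
  list(t1 = best$t1, t2 = best$t2, J = best$J, surface = surface,
       degenerate = degenerate)
}

#' Daily hourly profiles for one behavior across animals
#'
#' Convenience builder: computes per-animal, per-day 24-bin profiles from a
#' per-animal bout list, coverage-rescaled from the track set.
#'
#' @param bout_list Named list (by animal) of [bout_series()].
#' @param ts The originating [trackset()] (for coverage and day range).
#' @return `animals x days x 24` array suitable for [find_transitions()].
#' @export
daily_profiles <- function(bout_list, ts) {
  days <- sort(unique(frame_pnd(ts)))
  cov <- hourly_coverage_s(ts, days)
  out <- array(NA_real_, c(length(bout_list), length(days), 24),
               dimnames = list(names(bout_list), days, 0:23))
  for (a in names(bout_list)) {
    for (i in seq_along(days)) {
      out[a, i, ] <- as.numeric(
        hourly_profile(bout_list[[a]], days[i],
                       coverage_s = cov[i, , drop = FALSE],
                       anchor_pnd = ts$anchor_pnd))
    }
  }
  out
}
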