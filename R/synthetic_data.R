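# Stochastic family simulator: generates multi-animal home-cage trajectories
# with the statistical structure the downstream analysis assumes — logistic
# developmental ramps in pup activity budgets, circadian modulation with a
# switchable onset day, nest/huddle episodes during which open-field tracks
# lapse, scripted food/water ROI visits, recording downtime — plus
# corruption injectors and the planted ground truth for recovery tests.

#' Simulator configuration
#'
#' Defaults encode the recording regime being emulated: 6 animals (2 adults,
#' 4 pups) in a 57.2 x 35.6 cm cage, postnatal days P15-P30, lights on
#' 08:00-20:00, ~10% recording downtime. `seconds_per_hour` sets how much of
#' each hour is simulated (the problem-size knob: full scale is 3600).
#'
#' @param n_pups Pups in the family (default 4).
#' @param fps Frames per second (default 5 for analysis-scale runs; the
#'   emulated recordings are 25).
#' @param days Postnatal day range (default 15:30).
#' @param seconds_per_hour Recorded seconds simulated per hour (default 120).
#' @param downtime_frac Fraction of each session lost to saving (default 0.10).
#' @param adult_active_frac Adult fraction of time out of the nest (0.45).
#' @param adult_food_frac,adult_water_frac Adult fractions of total time at
#'   the food hopper / waterspout (0.10, 0.05).
#' @param ramps data.frame(behavior, onset_day, slope, plateau_frac,
#'   floor_frac): pup logistic ramps toward `plateau_frac` of the adult
#'   level, flat at `floor_frac * plateau` before the onset day. Behaviors
#'   `activity`, `food`, `water`; onsets default 17 / 22 / 23; food and
#'   water floors are 0 (pups do not visit the hopper or spout before
#'   weaning onset).
#' @param pup_circadian_onset Postnatal day pups switch from uniform to
#'   diurnal-crepuscular activity (default 26).
#' @param onset_sd Per-pup, per-behavior jitter (SD, days) on the ramp
#'   onset (default 0.5) — individual pups develop at slightly different
#'   times.
#' @param plateau_cv Per-pup, per-behavior lognormal CV on the ramp plateau
#'   (default 0.15) — individual pups settle at different adult-relative
#'   levels, which is what gives each pup an identifiable trajectory.
#' @param day_cv Day-level multiplicative noise CV on budgets (default 0.05).
#' @param speed_cms Locomotion speed scale (default 9 cm/s).
#' @param nest Nest center `c(x, y)` (default c(45, 10)).
#' @param swap_rate_per_day Identity-swap injection rate used by
#'   [inject_id_swaps()] callers (default 0 here).
#' @param seed Integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pups = 4, fps = 5, days = 15:30,
                       seconds_per_hour = 120, downtime_frac = 0.10,
                       adult_active_frac = 0.45,
                       adult_food_frac = 0.10, adult_water_frac = 0.05,
                       ramps = data.frame(
                         behavior = c("activity", "food", "water"),
                         onset_day = c(17, 22, 23),
                         slope = 1.5,
                         plateau_frac = 0.85,
                         floor_frac = c(0.05, 0, 0)),
                       pup_circadian_onset = 26,
                       onset_sd = 0.5, plateau_cv = 0.15,
                       day_cv = 0.05, speed_cms = 9,
                       nest = c(45, 10), swap_rate_per_day = 0, seed = 1) {
  stopifnot(all(days >= 15), all(days <= 30), fps > 0,
            downtime_frac >= 0, downtime_frac < 1,
            seconds_per_hour > 0, seconds_per_hour <= 3600)
  if (adult_active_frac + 0.02 >= 1 ||
      adult_food_frac + adult_water_frac > adult_active_frac)
    stop("infeasible activity budget: ROI time exceeds active time")
  structure(list(n_pups = n_pups, fps = fps, days = days,
                 seconds_per_hour = seconds_per_hour,
                 downtime_frac = downtime_frac,
                 adult_active_frac = adult_active_frac,
                 adult_food_frac = adult_food_frac,
                 adult_water_frac = adult_water_frac,
                 ramps = ramps, pup_circadian_onset = pup_circadian_onset,
                 onset_sd = onset_sd, plateau_cv = plateau_cv,
                 day_cv = day_cv, speed_cms = speed_cms, nest = nest,
                 swap_rate_per_day = swap_rate_per_day, seed = seed),
            class = "sim_config")
}

# Pup logistic ramp: flat floor before onset, logistic rise after. The
# planted onset is the first day above the floor.
ramp_value <- function(day, onset, slope, plateau, floor_frac) {
  base <- floor_frac * plateau
  ifelse(day < onset,
         base,
         base + (plateau - base) / (1 + exp(-slope * (day - onset - 2))))
}

# Circadian hour weights, normalized to mean 1 over the 24 h.
circ_weights <- function(type = c("uniform", "adult", "pup_late")) {
  type <- match.arg(type)
  h <- 0:23
  w <- switch(type,
              uniform = rep(1, 24),
              adult = 1 + 1.0 * (h >= 8 & h < 20) +
                2.5 * exp(-((h - 19)^2) / 2),
              pup_late = 1 + 0.8 * (h >= 8 & h < 20) +
                2.5 * exp(-((h - 19)^2) / 2) +
                1.5 * exp(-((h - 7)^2) / 2))
  w / mean(w)
}

# Polyline waypoint path with positional jitter; returns an n x 2 matrix:
# the animal advances at cruise speed along p0 -> waypoints, dwelling at the
# final waypoint once it arrives (frame-to-frame steps stay bounded by the
# speed scale; it stops short if the phase is too brief to arrive).
path_phase <- function(p0, waypoints, n, speed_per_frame, jitter, cage) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  if (!is.matrix(waypoints)) waypoints <- matrix(waypoints, 1, 2)
  verts <- rbind(p0, waypoints)
  seg_d <- sqrt(rowSums((verts[-1, , drop = FALSE] -
                           verts[-nrow(verts), , drop = FALSE])^2))
  cum_d <- c(0, cumsum(seg_d))
  d_tot <- cum_d[length(cum_d)]
  adv <- pmin(seq_len(n) * speed_per_frame, d_tot)
  out <- matrix(0, n, 2)
  if (d_tot > 0) {
    seg_i <- findInterval(adv, cum_d, rightmost.closed = TRUE)
    seg_i <- pmin(seg_i, length(seg_d))
    local_f <- (adv - cum_d[seg_i]) / pmax(seg_d[seg_i], 1e-12)
    out[, 1] <- verts[seg_i, 1] + local_f * (verts[seg_i + 1, 1] - verts[seg_i, 1])
    out[, 2] <- verts[seg_i, 2] + local_f * (verts[seg_i + 1, 2] - verts[seg_i, 2])
  } else {
    out[, 1] <- p0[1]; out[, 2] <- p0[2]
  }
  out <- out + matrix(stats::rnorm(2 * n, 0, jitter), n, 2)
  out[, 1] <- pmin(pmax(out[, 1], 0.1), cage$length_cm - 0.1)
  out[, 2] <- pmin(pmax(out[, 2], 0.1), cage$width_cm - 0.1)
  attr(out, "at_target") <- adv >= d_tot - 1e-9
  out
}

# Does the open segment p -> q cross the rectangle r = c(x0,x1,y0,y1)?
# (Liang-Barsky clip: true if any parameter interval survives.)
seg_hits_rect <- function(p, q, r) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- r[2 * k - 1]; hi <- r[2 * k]
    if (abs(d[k]) < 1e-12) {
      if (p[k] < lo || p[k] > hi) return(FALSE)
    } else {
      ta <- (lo - p[k]) / d[k]; tb <- (hi - p[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# Waypoints from p to target that avoid the given rectangles (animals do
# not cut through feeding stations unless visiting them): if the straight
# leg crosses a rect, detour via an expanded rect corner.
route_around <- function(p, target, avoid, cage, margin = 3) {
  for (r in avoid) {
    if (!seg_hits_rect(p, target, r)) next
    cx <- c(r[1] - margin, r[2] + margin)
    cy <- c(r[3] - margin, r[4] + margin)
    corners <- as.matrix(expand.grid(x = cx, y = cy))
    corners[, 1] <- pmin(pmax(corners[, 1], 0.5), cage$length_cm - 0.5)
    corners[, 2] <- pmin(pmax(corners[, 2], 0.5), cage$width_cm - 0.5)
    extra <- sqrt(rowSums(sweep(corners, 2, p)^2)) +
      sqrt(rowSums(sweep(corners, 2, target)^2))
    for (i in order(extra)) {
      w <- corners[i, ]
      if (!seg_hits_rect(p, w, r) && !seg_hits_rect(w, target, r))
        return(rbind(w, target))
    }
  }
  matrix(target, 1, 2)
}

#' Simulate one family's home-cage recordings
#'
#' Each animal alternates nest/huddle episodes (stationary at the nest and
#' absent from open-field tracking) with active bouts (waypoint locomotion
#' inside the cage with scripted visits to the food and water ROIs). Pup
#' active-time and ROI budgets follow planted logistic ramps; adults are
#' stationary in development. Within-day activity is modulated by a
#' circadian template that switches structure at the planted pup onset day.
#' Each hourly session loses its final `downtime_frac` to saving.
#'
#' @param config A [sim_config()].
#' @return list: `tracks` ([trackset()]), `huddles` ([huddle_track()]),
#'   `ground_truth` (list: `budgets` long data.frame, `ramps`,
#'   `circadian_onset`, `nest`, `config`).
#' @export
simulate_family <- function(config = sim_config()) {
  set.seed(config$seed)
  animals <- animal_table(config$n_pups)
  cage <- cage_geometry(rois = default_rois())
  A <- nrow(animals)
  fps <- config$fps
  n_plan <- round(config$seconds_per_hour * fps)
  n_rec <- floor(n_plan * (1 - config$downtime_frac))
  days <- config$days
  nest <- config$nest
  spf <- config$speed_cms / fps             # cm per frame at cruise speed
  jitter <- 0.15
  rp <- function(b) config$ramps[config$ramps$behavior == b, ]
  # Per-animal, per-day budget fractions (of total time).
  frac_tab <- list()
  for (a in seq_len(A)) {
    is_pup <- animals$age_class[a] == "pup"
    ramped <- function(b, adult_level) {
      r <- rp(b)
      onset_a <- r$onset_day +
        if (is_pup) stats::rnorm(1, 0, config$onset_sd) else 0
      plateau_a <- r$plateau_frac *
        if (is_pup) exp(stats::rnorm(1, 0, config$plateau_cv)) else 1
      vapply(days, function(d) {
        v <- if (is_pup) {
          adult_level * ramp_value(d, onset_a, r$slope, plateau_a,
                                   r$floor_frac)
        } else adult_level
        v * exp(stats::rnorm(1, 0, config$day_cv))
      }, 0)
    }
    act <- ramped("activity", config$adult_active_frac)
    foo <- ramped("food", config$adult_food_frac)
    wat <- ramped("water", config$adult_water_frac)
    frac_tab[[a]] <- data.frame(pnd = days, active = pmin(act, 0.9),
                                food = foo, water = wat)
  }
  T_day <- 24 * n_rec
  T_ <- length(days) * T_day
  time_s <- numeric(T_)
  pos <- array(NA_real_, c(T_, A, 2))
  # schedule bookkeeping for huddles and ground truth
  act_int <- vector("list", A)              # active intervals in seconds
  gt_rows <- list()
  phase_food <- matrix(FALSE, T_, A)
  phase_water <- matrix(FALSE, T_, A)
  # ROI dwell budget accumulators (frames): fractional per-hour ROI budgets
  # accrue until a full visit of min_visit frames can be emitted, so small
  # pup budgets still realize as genuine (arrivable) visits
  min_visit <- max(2L, round(3 * fps))
  acc_food <- numeric(A); acc_water <- numeric(A)
  roi_point <- function(r) c(stats::runif(1, r[1] + 1, r[2] - 1),
                             stats::runif(1, r[3] + 1, r[4] - 1))
  for (di in seq_along(days)) {
    d <- days[di]
    day_off_s <- (d - days[1]) * 86400
    for (h in 0:23) {
      blk0 <- (di - 1) * T_day + h * n_rec
      t0_s <- day_off_s + h * 3600
      time_s[blk0 + seq_len(n_rec)] <- t0_s + (seq_len(n_rec) - 1) / fps
      for (a in seq_len(A)) {
        fr <- frac_tab[[a]][di, ]
        is_pup <- animals$age_class[a] == "pup"
        wtype <- if (!is_pup) "adult"
        else if (d >= config$pup_circadian_onset) "pup_late" else "uniform"
        w <- circ_weights(wtype)[h + 1]
        La <- round(min(0.95, fr$active * w) * n_rec)
        acc_food[a] <- acc_food[a] + fr$food * w * n_rec
        acc_water[a] <- acc_water[a] + fr$water * w * n_rec
        Lf <- 0L; Lw <- 0L
        if (La >= 2 && acc_food[a] >= min_visit) {
          Lf <- round(acc_food[a]); acc_food[a] <- 0
        }
        if (La >= 2 && acc_water[a] >= min_visit) {
          Lw <- round(acc_water[a]); acc_water[a] <- 0
        }
        L_out <- La + Lf + Lw
        cap <- floor(0.97 * n_rec)
        if (L_out > cap) { La <- max(La - (L_out - cap), 0L); L_out <- La + Lf + Lw }
        if (L_out < 2) next
        off <- sample.int(n_rec - L_out + 1, 1) - 1L
        act_int[[a]] <- c(act_int[[a]],
                          list(c(t0_s + off / fps, t0_s + (off + L_out) / fps)))
        p <- nest + stats::runif(2, -2, 2)
        rows <- blk0 + off
        rem_w <- La                           # wander + travel budget
        rects <- cage$rois[c("food", "water")]
        emit <- function(type, target, n_ph, avoid = list()) {
          if (n_ph <= 0) return(invisible(NULL))
          wp <- if (length(avoid) > 0) route_around(p, target, avoid, cage)
          else matrix(target, 1, 2)
          pp <- path_phase(p, wp, n_ph, spf, jitter, cage)
          idx <- rows + seq_len(n_ph)
          pos[idx, a, ] <<- pp
          at_tgt <- attr(pp, "at_target")
          if (type == "food") phase_food[idx[at_tgt], a] <<- TRUE
          if (type == "water") phase_water[idx[at_tgt], a] <<- TRUE
          p <<- pp[n_ph, ]
          rows <<- rows + n_ph
          invisible(NULL)
        }
        wander_tgt <- function() {
          repeat {
            tg <- c(stats::runif(1, 2, cage$length_cm - 2),
                    stats::runif(1, 2, cage$width_cm - 2))
            inside <- vapply(rects, function(r)
              tg[1] >= r[1] - 1.5 && tg[1] <= r[2] + 1.5 &&
                tg[2] >= r[3] - 1.5 && tg[2] <= r[4] + 1.5, TRUE)
            if (!any(inside)) return(tg)
          }
        }
        n1 <- round(0.4 * rem_w)
        emit("wander", wander_tgt(), n1, avoid = rects); rem_w <- rem_w - n1
        if (Lf > 0) {
          tgt <- roi_point(cage$rois$food)
          nt <- min(ceiling(sqrt(sum((tgt - p)^2)) / spf), rem_w)
          emit("wander", tgt, nt, avoid = rects["water"]); rem_w <- rem_w - nt
          emit("food", tgt, Lf)                          # dwell at hopper
        }
        n2 <- round(0.5 * rem_w)
        emit("wander", wander_tgt(), n2, avoid = rects); rem_w <- rem_w - n2
        if (Lw > 0) {
          tgt <- roi_point(cage$rois$water)
          nt <- min(ceiling(sqrt(sum((tgt - p)^2)) / spf), rem_w)
          emit("wander", tgt, nt, avoid = rects["food"]); rem_w <- rem_w - nt
          emit("water", tgt, Lw)
        }
        emit("wander", wander_tgt(), rem_w, avoid = rects)
      }
    }
  }
  ts <- trackset(time_s, pos, animals, fps = fps, anchor_pnd = days[1],
                 cage = cage, schedule = light_schedule())
  # Huddle intervals: maximal spans with >= 2 animals at the nest, computed
  # from the scheduled active intervals within each recorded session.
  huddles <- derive_huddles(act_int, days, n_rec, fps, A, nest)
  # Ground truth budgets (per recorded time, rescaled to 24 h equivalents)
  pnd <- frame_pnd(ts)
  for (a in seq_len(A)) {
    tracked <- !is.na(pos[, a, 1])
    step <- c(NA, sqrt(diff(pos[, a, 1])^2 + diff(pos[, a, 2])^2))
    step[c(TRUE, diff(time_s) > 1.5 / fps)] <- NA
    same_day <- c(FALSE, diff(pnd) == 0)
    for (di in seq_along(days)) {
      sel <- pnd == days[di]
      nsel <- sum(sel)
      gt_rows[[length(gt_rows) + 1]] <- data.frame(
        animal = animals$name[a], pnd = days[di],
        active_h = 24 * sum(tracked[sel]) / nsel,
        nest_h = 24 * sum(!tracked[sel]) / nsel,
        food_h = 24 * sum(phase_food[sel, a]) / nsel,
        water_h = 24 * sum(phase_water[sel, a]) / nsel,
        distance_m = sum(step[sel & same_day], na.rm = TRUE) / 100 /
          (nsel / (86400 * fps)))
    }
  }
  budgets <- do.call(rbind, gt_rows)
  list(tracks = ts, huddles = huddles,
       ground_truth = list(budgets = budgets, ramps = config$ramps,
                           circadian_onset = config$pup_circadian_onset,
                           nest = nest, config = config))
}

# Maximal intervals with >= 2 animals at the nest, per recorded session.
derive_huddles <- function(act_int, days, n_rec, fps, A, nest) {
  sess_len <- n_rec / fps
  starts <- numeric(0); ends <- numeric(0)
  for (di in seq_along(days)) {
    for (h in 0:23) {
      t0 <- (di - 1) * 86400 + h * 3600
      t1 <- t0 + sess_len
      # breakpoints: session bounds plus active-interval edges inside it
      brk <- c(t0, t1)
      for (a in seq_len(A)) {
        for (iv in act_int[[a]]) {
          if (iv[2] > t0 && iv[1] < t1)
            brk <- c(brk, max(iv[1], t0), min(iv[2], t1))
        }
      }
      brk <- sort(unique(brk))
      if (length(brk) < 2) next
      mid <- (brk[-length(brk)] + brk[-1]) / 2
      n_nest <- vapply(mid, function(tm) {
        away <- 0
        for (a in seq_len(A)) {
          for (iv in act_int[[a]]) {
            if (tm >= iv[1] && tm < iv[2]) { away <- away + 1; break }
          }
        }
        A - away
      }, 0)
      on <- n_nest >= 2
      r <- rle(on)
      e <- cumsum(r$lengths); s <- e - r$lengths + 1
      for (k in which(r$values)) {
        starts <- c(starts, brk[s[k]])
        ends <- c(ends, brk[e[k] + 1])
      }
    }
  }
  if (length(starts) == 0)
    return(huddle_track(numeric(0), numeric(0), numeric(0), numeric(0)))
  keep <- ends > starts + 1e-9
  huddle_track(starts[keep], ends[keep],
               rep(nest[1], sum(keep)), rep(nest[2], sum(keep)))
}

#' Inject identity-swap corruption
#'
#' At Poisson-sampled frames, exchanges two randomly chosen animals' tracks
#' from that frame onward (sequential application, matching the error model
#' of segment-level identity switches). Swaps are drawn among frames where
#' both animals are tracked and at least `min_sep_cm` apart — the
#' large-jump error class the downstream detector targets.
#'
#' @param ts A [trackset()] with >= 2 animals.
#' @param rate_per_day Expected swaps per day.
#' @param seed Integer seed.
#' @param min_sep_cm Minimum pair separation at the swap frame (default 15).
#' @return list: `tracks` (corrupted trackset), `log` ([swap_events()],
#'   kind `"injected"`).
#' @export
inject_id_swaps <- function(ts, rate_per_day, seed, min_sep_cm = 15) {
  stopifnot(nrow(ts$animals) >= 2)
  set.seed(seed)
  n_days <- length(unique(frame_pnd(ts)))
  k <- stats::rpois(1, rate_per_day * n_days)
  empty <- swap_events(integer(0), character(0), character(0), "injected")
  if (k == 0) return(list(tracks = ts, log = empty))
  nm <- ts$animals$name
  A <- length(nm)
  T_ <- dim(ts$pos)[1]
  # frames eligible regardless of identity permutation: consecutive in time
  # with at least two animals tracked at both f-1 and f
  tracked <- !is.na(ts$pos[, , 1])
  both2 <- rowSums(tracked[-1, , drop = FALSE] &
                     tracked[-T_, , drop = FALSE]) >= 2
  contiguous <- diff(ts$time_s) <= 1.5 / ts$fps
  frames <- which(both2 & contiguous) + 1L
  if (length(frames) == 0) return(list(tracks = ts, log = empty))
  frames <- sort(sample(frames, min(k, length(frames))))
  out <- ts
  log_f <- integer(0); log_a <- character(0); log_b <- character(0)
  for (f in frames) {
    # pairs valid on the current (already corrupted) tracks: both members
    # tracked through the transition and well separated
    ok_an <- which(!is.na(out$pos[f, , 1]) & !is.na(out$pos[f - 1L, , 1]))
    if (length(ok_an) < 2) next
    cand <- utils::combn(ok_an, 2)
    d <- sqrt((out$pos[f, cand[1, ], 1] - out$pos[f, cand[2, ], 1])^2 +
                (out$pos[f, cand[1, ], 2] - out$pos[f, cand[2, ], 2])^2)
    sel <- which(d >= min_sep_cm)
    if (length(sel) == 0) next
    p <- cand[, sel[sample.int(length(sel), 1)]]
    out <- swap_from_frame(out, f, nm[p[1]], nm[p[2]])
    log_f <- c(log_f, f)
    log_a <- c(log_a, nm[min(p)]); log_b <- c(log_b, nm[max(p)])
  }
  if (length(log_f) == 0) return(list(tracks = ts, log = empty))
  list(tracks = out,
       log = swap_events(log_f, log_a, log_b, "injected"))
}

#' Simulated daily circadian profiles with planted breakpoints
#'
#' Generates per-animal, per-day 24-bin hourly profiles with three planted
#' regimes: uniform up to `t1`, evening-peaked in `(t1, t2]`, dawn-peaked
#' after `t2` — the structure used to validate [find_transitions()].
#'
#' @param n_animals Number of animals (default 12).
#' @param days Day range (default 16:29).
#' @param t1,t2 Planted breakpoints (defaults 19, 27).
#' @param sigma Additive noise SD relative to bin mass (default 0.05).
#' @param seed Integer seed.
#' @return `animals x days x 24` array.
#' @export
simulate_circadian_profiles <- function(n_animals = 12, days = 16:29,
                                        t1 = 19, t2 = 27, sigma = 0.05,
                                        seed = 1) {
  set.seed(seed)
  h <- 0:23
  tpl <- list(
    uniform = rep(1 / 24, 24),
    evening = normalize_profile(0.3 + 3 * exp(-((h - 20)^2) / 4)),
    dawn = normalize_profile(0.3 + 3 * exp(-((h - 5)^2) / 4)))
  out <- array(0, c(n_animals, length(days), 24),
               dimnames = list(paste0("a", seq_len(n_animals)), days, h))
  for (a in seq_len(n_animals)) {
    for (di in seq_along(days)) {
      d <- days[di]
      base <- if (d <= t1) tpl$uniform else if (d <= t2) tpl$evening else tpl$dawn
      v <- pmax(base + stats::rnorm(24, 0, sigma * mean(base)), 0)
      out[a, di, ] <- v
    }
  }
  out
}

#' Write a small simulated fixture to disk
#'
#' `tiny`: 2 adults, 2 days; `default`: the full family over P15-P30. Both
#' at 5 fps with short hourly sessions, written as canonical-h5 plus
#' ground-truth CSV sidecars.
#'
#' @param dir Output directory.
#' @param profile `"tiny"` or `"default"`.
#' @param seed Integer seed (default 1).
#' @return Invisible list of written paths.
#' @export
make_test_fixture <- function(dir, profile = c("tiny", "default"), seed = 1) {
  profile <- match.arg(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (profile == "tiny") {
    sim_config(n_pups = 0, days = 15:16, seconds_per_hour = 60, seed = seed)
  } else {
    sim_config(days = 15:30, seconds_per_hour = 60, seed = seed)
  }
  sim <- simulate_family(cfg)
  h5 <- file.path(dir, paste0(profile, "_family.h5"))
  write_trackset(sim$tracks, h5, dialect = "canonical-h5")
  bud <- file.path(dir, paste0(profile, "_ground_truth.csv"))
  utils::write.csv(sim$ground_truth$budgets, bud, row.names = FALSE)
  hud <- file.path(dir, paste0(profile, "_huddles.csv"))
  utils::write.csv(as.data.frame(sim$huddles), hud, row.names = FALSE)
  invisible(list(tracks = h5, ground_truth = bud, huddles = hud))
}
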