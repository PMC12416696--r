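# Heuristic behavior classification from cleaned centroid tracks: ROI
# occupancy, open exploration, distance traveled, pairwise proximity, group
# socialization, approach detection, huddle attribution, nest following.

frames_by_day <- function(ts) split(seq_along(ts$time_s), frame_pnd(ts))

coverage_lookup <- function(ts) {
  cov <- coverage_by_day(ts)
  stats::setNames(cov$coverage, cov$pnd)
}

# Break a logical run at recording gaps so bouts never span downtime.
run_bouts <- function(flags, time_s, fps, gap_tol = 1.5) {
  flags[is.na(flags)] <- FALSE
  if (!any(flags)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                     n_frames = integer(0)))
  brk <- c(FALSE, diff(time_s) > gap_tol / fps)
  grp <- cumsum(!flags | brk)
  idx <- which(flags)
  sp <- split(idx, grp[idx])
  data.frame(
    start_s = vapply(sp, function(i) time_s[i[1]], 0),
    end_s = vapply(sp, function(i) time_s[i[length(i)]] + 1 / fps, 0),
    n_frames = vapply(sp, length, 0L), row.names = NULL)
}

daily_hours <- function(flags, ts, rescale = TRUE) {
  pnd <- frame_pnd(ts)
  cov <- coverage_lookup(ts)
  days <- sort(unique(pnd))
  hrs <- vapply(days, function(d) {
    h <- sum(flags[pnd == d], na.rm = TRUE) / ts$fps / 3600
    if (rescale) h / cov[as.character(d)] else h
  }, 0)
  data.frame(pnd = days, hours = hrs)
}

#' Point-in-rectangle test (closed rectangle)
#'
#' @param xy `T x 2` matrix of positions.
#' @param rect ROI rectangle `c(x0, x1, y0, y1)`.
#' @return Logical vector; `NA` positions give `FALSE`.
#' @export
in_rect <- function(xy, rect) {
  ok <- xy[, 1] >= rect[1] & xy[, 1] <= rect[2] &
    xy[, 2] >= rect[3] & xy[, 2] <= rect[4]
  ok & !is.na(ok)
}

#' ROI occupancy bouts and daily hours
#'
#' Frames with the animal's median centroid inside the closed ROI rectangle
#' form occupancy bouts; the daily total is the inside-frame count divided by
#' fps, rescaled by recording coverage.
#'
#' @param ts A [trackset()].
#' @param animal Animal name.
#' @param roi ROI name (looked up in the cage geometry) or rectangle
#'   `c(x0, x1, y0, y1)`.
#' @return list(bouts = [bout_series()], daily = data.frame(pnd, hours)).
#' @export
roi_occupancy <- function(ts, animal, roi) {
  rect <- if (is.character(roi)) {
    if (!roi %in% names(ts$cage$rois)) stop("unknown ROI: ", roi)
    ts$cage$rois[[roi]]
  } else roi
  label <- if (is.character(roi)) roi else "roi"
  cent <- centroid_series(ts, animal)
  inside <- in_rect(cent, rect)
  b <- run_bouts(inside, ts$time_s, ts$fps)
  bouts <- if (nrow(b) > 0)
    bout_series(label, animal, b$start_s, b$end_s)
  else bout_series(character(0), character(0), numeric(0), numeric(0))
  list(bouts = bouts, daily = daily_hours(inside, ts))
}

#' Seeded random control ROI
#'
#' Places a rectangle of the given size uniformly at random inside the cage
#' (control for food/water ROI placement).
#'
#' @param cage A [cage_geometry()].
#' @param size_cm `c(width_along_x, height_along_y)`.
#' @param seed Integer seed.
#' @return Rectangle `c(x0, x1, y0, y1)`.
#' @export
random_roi <- function(cage, size_cm, seed) {
  set.seed(seed)
  x0 <- stats::runif(1, 0, cage$length_cm - size_cm[1])
  y0 <- stats::runif(1, 0, cage$width_cm - size_cm[2])
  c(x0, x0 + size_cm[1], y0, y0 + size_cm[2])
}

#' Daily nest region from huddle locations
#'
#' The nest region for each day is the modal (most-visited, on a 1 cm grid)
#' huddle centroid location, dilated to a disc.
#'
#' @param huddles A [huddle_track()].
#' @param days Postnatal days to cover.
#' @param radius_cm Disc radius (default 12).
#' @param anchor_pnd Postnatal day containing `start_s = 0`.
#' @return data.frame(pnd, x, y, radius_cm).
#' @export
nest_region_by_day <- function(huddles, days, radius_cm = 12, anchor_pnd = 15) {
  h <- as.data.frame(huddles)
  h$pnd <- anchor_pnd + floor(h$start_s / 86400)
  modal <- function(hh) {
    if (nrow(hh) == 0) return(c(NA_real_, NA_real_))
    key <- paste(round(hh$x), round(hh$y))
    w <- tapply(hh$end_s - hh$start_s, key, sum)
    top <- names(w)[which.max(w)]
    i <- which(key == top)[1]
    c(round(hh$x[i]), round(hh$y[i]))
  }
  all_mod <- modal(h)
  out <- do.call(rbind, lapply(days, function(d) {
    m <- modal(h[h$pnd == d, , drop = FALSE])
    if (anyNA(m)) m <- all_mod
    data.frame(pnd = d, x = m[1], y = m[2], radius_cm = radius_cm)
  }))
  out
}

in_nest <- function(cent, ts, nest) {
  pnd <- frame_pnd(ts)
  out <- rep(FALSE, nrow(cent))
  for (i in seq_len(nrow(nest))) {
    sel <- pnd == nest$pnd[i]
    d <- sqrt((cent[sel, 1] - nest$x[i])^2 + (cent[sel, 2] - nest$y[i])^2)
    out[sel] <- !is.na(d) & d <= nest$radius_cm[i]
  }
  out
}

#' Open exploration time
#'
#' Hours per day the animal is tracked outside the nest region,
#' coverage-rescaled.
#'
#' @param ts A [trackset()].
#' @param animal Animal name.
#' @param nest Nest-region table from [nest_region_by_day()].
#' @return data.frame(pnd, hours).
#' @export
open_exploration <- function(ts, animal, nest) {
  cent <- centroid_series(ts, animal)
  tracked <- !is.na(cent[, 1])
  open <- tracked & !in_nest(cent, ts, nest)
  daily_hours(open, ts)
}

#' Distance traveled per day
#'
#' Sum of consecutive-frame centroid displacements in meters per day,
#' skipping frame pairs that span missing data or recording gaps;
#' coverage-rescaled.
#'
#' @param ts A [trackset()].
#' @param animal Animal name.
#' @return data.frame(pnd, meters).
#' @export
distance_traveled <- function(ts, animal) {
  cent <- centroid_series(ts, animal)
  T_ <- nrow(cent)
  if (T_ < 2) return(data.frame(pnd = unique(frame_pnd(ts)), meters = 0))
  d <- sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)
  gap <- diff(ts$time_s) > 1.5 / ts$fps
  d[gap] <- NA
  pnd <- frame_pnd(ts)[-1]
  same_day <- diff(frame_pnd(ts)) == 0
  d[!same_day] <- NA
  cov <- coverage_lookup(ts)
  days <- sort(unique(frame_pnd(ts)))
  m <- vapply(days, function(day) {
    sum(d[pnd == day], na.rm = TRUE) / 100 / cov[as.character(day)]
  }, 0)
  data.frame(pnd = days, meters = m)
}

#' Pairwise proximity bouts
#'
#' Maximal runs with inter-animal distance strictly below `dist_cm` lasting
#' strictly longer than `min_dur_ms` become proximity bouts.
#'
#' @param ts A [trackset()].
#' @param a,b Animal names.
#' @param dist_cm Proximity radius (default 5 cm).
#' @param min_dur_ms Minimum bout duration (default 200 ms).
#' @return list(bouts, daily = data.frame(pnd, hours)).
#' @export
pairwise_proximity <- function(ts, a, b, dist_cm = 5, min_dur_ms = 200) {
  ca <- centroid_series(ts, a); cb <- centroid_series(ts, b)
  d <- sqrt((ca[, 1] - cb[, 1])^2 + (ca[, 2] - cb[, 2])^2)
  close <- !is.na(d) & d < dist_cm
  runs <- run_bouts(close, ts$time_s, ts$fps)
  keep <- runs$n_frames / ts$fps > min_dur_ms / 1000
  runs <- runs[keep, , drop = FALSE]
  flags <- rep(FALSE, length(ts$time_s))
  for (i in seq_len(nrow(runs)))
    flags[ts$time_s >= runs$start_s[i] & ts$time_s < runs$end_s[i]] <- TRUE
  subj <- paste(sort(c(a, b)), collapse = "|")
  bouts <- if (nrow(runs) > 0)
    bout_series("proximity", subj, runs$start_s, runs$end_s)
  else bout_series(character(0), character(0), numeric(0), numeric(0))
  list(bouts = bouts, daily = daily_hours(flags, ts))
}

# Connected components of a small undirected adjacency matrix (animals
# within dist_cm join one group).
components_small <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Per-frame social group membership
#'
#' Groups are connected components of the graph joining animal pairs closer
#' than `dist_cm`. Missing animals belong to no group.
#'
#' @param ts A [trackset()].
#' @param dist_cm Socialization radius (default 5 cm).
#' @return list with `size` (`T x A` group-size matrix, `NA` when missing),
#'   `pup_only` and `with_adult` (`T x A` logicals, for groups of size >= 2).
#' @export
group_membership <- function(ts, dist_cm = 5) {
  nm <- ts$animals$name
  A <- length(nm)
  cent <- centroid_array(ts)
  T_ <- dim(cent)[1]
  pairs <- utils::combn(A, 2)
  P <- ncol(pairs)
  adj <- matrix(FALSE, T_, P)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- sqrt((cent[, i, 1] - cent[, j, 1])^2 + (cent[, i, 2] - cent[, j, 2])^2)
    adj[, p] <- !is.na(d) & d < dist_cm
  }
  present <- !is.na(cent[, , 1, drop = FALSE][, , 1])
  if (is.null(dim(present))) present <- matrix(present, T_, A)
  is_pup <- ts$animals$age_class == "pup"
  size <- matrix(NA_integer_, T_, A, dimnames = list(NULL, nm))
  pup_only <- matrix(FALSE, T_, A, dimnames = list(NULL, nm))
  with_adult <- matrix(FALSE, T_, A, dimnames = list(NULL, nm))
  # Memoize on the (presence, adjacency) pattern: few distinct patterns occur.
  key <- apply(cbind(present, adj), 1, function(r) paste(as.integer(r), collapse = ""))
  cache <- new.env(parent = emptyenv())
  for (k in unique(key)) {
    rows <- which(key == k)
    f <- rows[1]
    am <- matrix(FALSE, A, A)
    on <- which(adj[f, ])
    for (p in on) am[pairs[1, p], pairs[2, p]] <- am[pairs[2, p], pairs[1, p]] <- TRUE
    pr <- present[f, ]
    am[!pr, ] <- FALSE; am[, !pr] <- FALSE
    comp <- components_small(am)
    sz <- rep(NA_integer_, A); po <- rep(FALSE, A); wa <- rep(FALSE, A)
    for (a in which(pr)) {
      members <- which(comp == comp[a] & pr)
      sz[a] <- length(members)
      if (length(members) >= 2) {
        po[a] <- all(is_pup[members])
        wa[a] <- any(!is_pup[members])
      }
    }
    size[rows, ] <- matrix(sz, length(rows), A, byrow = TRUE)
    pup_only[rows, ] <- matrix(po, length(rows), A, byrow = TRUE)
    with_adult[rows, ] <- matrix(wa, length(rows), A, byrow = TRUE)
  }
  list(size = size, pup_only = pup_only, with_adult = with_adult)
}

#' Daily group-socialization time
#'
#' Per animal and day, coverage-rescaled hours spent in groups of size 1, 2,
#' and 3+, and (for groups of 2+) in pup-only vs any-adult groups.
#'
#' @param ts A [trackset()].
#' @param dist_cm Socialization radius (default 5 cm).
#' @return Long data.frame(animal, pnd, category, hours).
#' @export
group_time_by_day <- function(ts, dist_cm = 5) {
  gm <- group_membership(ts, dist_cm)
  nm <- ts$animals$name
  out <- list()
  for (a in nm) {
    s <- gm$size[, a]
    cats <- list(solo = !is.na(s) & s == 1,
                 pair = !is.na(s) & s == 2,
                 group3plus = !is.na(s) & s >= 3,
                 pup_only = gm$pup_only[, a],
                 with_adult = gm$with_adult[, a])
    for (cn in names(cats)) {
      dh <- daily_hours(cats[[cn]], ts)
      out[[length(out) + 1]] <- data.frame(animal = a, pnd = dh$pnd,
                                           category = cn, hours = dh$hours)
    }
  }
  do.call(rbind, out)
}

#' Approach detection parameters
#' @param gerbil_length_cm Body length defining "arrived" (default 10 cm
#'   adult; ~6 cm for pups).
#' @param move_speed_cms Speed that starts an approach (default 2 cm/s).
#' @param stop_speed_cms Speed that ends it (default 1 cm/s).
#' @param min_closing_frac Required fractional decrease of inter-animal
#'   distance over the bout (default 0.5).
#' @param contact_cm Physical-contact distance (default 2 cm).
#' @export
approach_params <- function(gerbil_length_cm = 10, move_speed_cms = 2,
                            stop_speed_cms = 1, min_closing_frac = 0.5,
                            contact_cm = 2) {
  stopifnot(stop_speed_cms < move_speed_cms, gerbil_length_cm > 0)
  list(gerbil_length_cm = gerbil_length_cm, move_speed_cms = move_speed_cms,
       stop_speed_cms = stop_speed_cms, min_closing_frac = min_closing_frac,
       contact_cm = contact_cm)
}

smoothed_speed <- function(cent, time_s, fps, k = 5) {
  T_ <- nrow(cent)
  if (T_ < 2) return(rep(NA_real_, T_))
  step <- sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)
  dt <- diff(time_s)
  v <- c(step / dt, NA)
  v[c(dt > 1.5 / fps, TRUE)] <- NA
  # centered moving average over k frames to suppress tracking jitter
  sm <- stats::filter(v, rep(1 / k, k), sides = 2)
  out <- as.numeric(sm)
  out[is.na(out)] <- v[is.na(out)]
  out
}

#' Detect approach events
#'
#' An approach is a movement bout of the initiator toward the target:
#' it begins when the initiator's (smoothed) speed reaches
#' `move_speed_cms`, persists while speed stays above `stop_speed_cms`, must
#' close at least `min_closing_frac` of the initial inter-animal distance,
#' and ends with the initiator stopping within one gerbil length of the
#' target, or on contact.
#'
#' @param ts A [trackset()].
#' @param initiator,target Animal names.
#' @param params An [approach_params()] list.
#' @return list(events = data.frame(start_s, end_s, d_start, d_end),
#'   daily = data.frame(pnd, count)).
#' @export
detect_approaches <- function(ts, initiator, target, params = approach_params()) {
  ci <- centroid_series(ts, initiator)
  ct <- centroid_series(ts, target)
  v <- smoothed_speed(ci, ts$time_s, ts$fps)
  d <- sqrt((ci[, 1] - ct[, 1])^2 + (ci[, 2] - ct[, 2])^2)
  T_ <- length(ts$time_s)
  moving <- !is.na(v) & v >= params$move_speed_cms
  not_stopped <- !is.na(v) & v >= params$stop_speed_cms
  events <- list()
  f <- 1L
  while (f <= T_) {
    if (!moving[f] || is.na(d[f])) { f <- f + 1L; next }
    g <- f
    while (g < T_ && not_stopped[g + 1L] && !is.na(d[g + 1L]) &&
           (ts$time_s[g + 1L] - ts$time_s[g]) <= 1.5 / ts$fps) g <- g + 1L
    d0 <- d[f]; d1 <- d[g]
    closed <- (d0 - d1) >= params$min_closing_frac * d0
    arrived <- d1 <= params$gerbil_length_cm || d1 <= params$contact_cm
    if (g > f && closed && arrived) {
      events[[length(events) + 1]] <- data.frame(
        start_s = ts$time_s[f], end_s = ts$time_s[g] + 1 / ts$fps,
        d_start = d0, d_end = d1)
    }
    f <- g + 1L
  }
  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               d_start = numeric(0), d_end = numeric(0))
  pnd0 <- ts$anchor_pnd
  days <- sort(unique(frame_pnd(ts)))
  cov <- coverage_lookup(ts)
  cnt <- vapply(days, function(day) {
    sum(pnd0 + floor(ev$start_s / 86400) == day) / cov[as.character(day)]
  }, 0)
  list(events = ev, daily = data.frame(pnd = days, count = cnt))
}

#' Per-frame huddling flags
#'
#' An animal is huddling at a frame iff a huddle interval is active and
#' either its centroid lies within `attribution_radius_cm` of the huddle
#' centroid, or its track is missing (animals lapse from open-field tracking
#' while huddled). Missing-track attribution can be disabled.
#'
#' @param ts A [trackset()].
#' @param huddles A [huddle_track()].
#' @param attribution_radius_cm Radius around the huddle centroid (default 6).
#' @param attribute_missing Count missing-track frames during an active
#'   huddle as huddling (default TRUE).
#' @return `T x A` logical matrix.
#' @export
huddling_flags <- function(ts, huddles, attribution_radius_cm = 6,
                           attribute_missing = TRUE) {
  nm <- ts$animals$name
  T_ <- length(ts$time_s)
  out <- matrix(FALSE, T_, length(nm), dimnames = list(NULL, nm))
  if (is.null(huddles) || nrow(huddles) == 0) return(out)
  active <- rep(FALSE, T_)
  hx <- rep(NA_real_, T_); hy <- rep(NA_real_, T_)
  for (i in seq_len(nrow(huddles))) {
    sel <- ts$time_s >= huddles$start_s[i] & ts$time_s < huddles$end_s[i]
    active[sel] <- TRUE
    hx[sel] <- huddles$x[i]; hy[sel] <- huddles$y[i]
  }
  for (a in nm) {
    cent <- centroid_series(ts, a)
    miss <- is.na(cent[, 1])
    near <- !miss & active &
      sqrt((cent[, 1] - hx)^2 + (cent[, 2] - hy)^2) <= attribution_radius_cm
    near[is.na(near)] <- FALSE
    out[, a] <- near | (if (attribute_missing) miss & active else FALSE)
  }
  out
}

#' Daily huddle time
#'
#' @inheritParams huddling_flags
#' @return Long data.frame(animal, pnd, hours), coverage-rescaled.
#' @export
huddle_time <- function(ts, huddles, attribution_radius_cm = 6,
                        attribute_missing = TRUE) {
  hf <- huddling_flags(ts, huddles, attribution_radius_cm, attribute_missing)
  out <- lapply(colnames(hf), function(a) {
    dh <- daily_hours(hf[, a], ts)
    data.frame(animal = a, pnd = dh$pnd, hours = dh$hours)
  })
  do.call(rbind, out)
}

#' Daily time budget per animal
#'
#' Splits each recorded frame into exactly one of: huddling, open (tracked,
#' not huddling), or missing-unattributed; returns coverage-rescaled hours.
#' The three components sum to 24 h per animal-day by construction.
#'
#' @inheritParams huddling_flags
#' @return Long data.frame(animal, pnd, huddle_h, open_h, missing_h).
#' @export
daily_time_budget <- function(ts, huddles, attribution_radius_cm = 6,
                              attribute_missing = TRUE) {
  hf <- huddling_flags(ts, huddles, attribution_radius_cm, attribute_missing)
  out <- list()
  for (a in ts$animals$name) {
    cent <- centroid_series(ts, a)
    tracked <- !is.na(cent[, 1])
    hud <- hf[, a]
    open <- tracked & !hud
    miss <- !tracked & !hud
    dh_h <- daily_hours(hud, ts); dh_o <- daily_hours(open, ts)
    dh_m <- daily_hours(miss, ts)
    out[[a]] <- data.frame(animal = a, pnd = dh_h$pnd, huddle_h = dh_h$hours,
                           open_h = dh_o$hours, missing_h = dh_m$hours)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Nest-exit events
#'
#' An exit is a transition from huddling to tracked, non-huddling.
#'
#' @param ts A [trackset()].
#' @param hflags Output of [huddling_flags()].
#' @return data.frame(animal, time_s, pnd).
#' @export
nest_exits <- function(ts, hflags) {
  out <- list()
  pnd <- frame_pnd(ts)
  for (a in colnames(hflags)) {
    h <- hflags[, a]
    tracked <- !is.na(centroid_series(ts, a)[, 1])
    ex <- which(h[-length(h)] & !h[-1] & tracked[-1]) + 1L
    if (length(ex) > 0)
      out[[a]] <- data.frame(animal = a, time_s = ts$time_s[ex], pnd = pnd[ex])
  }
  if (length(out) == 0)
    return(data.frame(animal = character(0), time_s = numeric(0), pnd = integer(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Adults following pups out of the nest
#'
#' Counts (pup exit at t, adult exit in (t, t + window_s]) pairs; each adult
#' exit is matched to at most one pup exit, the earliest unmatched one.
#'
#' @param exits Exit table from [nest_exits()] for all animals.
#' @param animals Animal roster (for age classes).
#' @param window_s Follow window (default 10 s).
#' @return data.frame(pnd, count).
#' @export
nest_following <- function(exits, animals, window_s = 10) {
  is_adult <- exits$animal %in% animals$name[animals$age_class == "adult"]
  pup_ex <- exits[!is_adult, , drop = FALSE]
  ad_ex <- exits[is_adult, , drop = FALSE]
  pup_ex <- pup_ex[order(pup_ex$time_s), , drop = FALSE]
  ad_ex <- ad_ex[order(ad_ex$time_s), , drop = FALSE]
  matched <- rep(FALSE, nrow(pup_ex))
  hits <- integer(0)
  for (i in seq_len(nrow(ad_ex))) {
    t_a <- ad_ex$time_s[i]
    cand <- which(!matched & pup_ex$time_s < t_a &
                    t_a <= pup_ex$time_s + window_s)
    if (length(cand) > 0) {
      j <- cand[1]
      matched[j] <- TRUE
      hits <- c(hits, pup_ex$pnd[j])
    }
  }
  days <- sort(unique(exits$pnd))
  data.frame(pnd = days,
             count = vapply(days, function(d) sum(hits == d), 0L))
}

#' Full daily ethogram for a track set
#'
#' Runs the heuristic classifiers over all animals and returns one
#' [daily_matrix()] per behavior: `open_exploration` (hrs/day),
#' `distance_traveled` (m/day), `food` and `water` ROI occupancy (hrs/day),
#' and `huddle` (hrs/day).
#'
#' @param ts A [trackset()] whose cage geometry carries `food`/`water` ROIs.
#' @param huddles A [huddle_track()].
#' @param nest Optional nest-region table; computed from huddles if `NULL`.
#' @return Named list of [daily_matrix()] objects.
#' @export
daily_ethogram <- function(ts, huddles, nest = NULL) {
  days <- sort(unique(frame_pnd(ts)))
  if (is.null(nest))
    nest <- nest_region_by_day(huddles, days, anchor_pnd = ts$anchor_pnd)
  nm <- ts$animals$name
  grab <- function(f) {
    m <- matrix(NA_real_, length(nm), length(days), dimnames = list(nm, days))
    for (a in nm) {
      df <- f(a)
      m[a, as.character(df$pnd)] <- df[[2]]
    }
    m
  }
  hud <- huddle_time(ts, huddles)
  hud_m <- matrix(NA_real_, length(nm), length(days), dimnames = list(nm, days))
  for (a in nm) {
    sel <- hud$animal == a
    hud_m[a, as.character(hud$pnd[sel])] <- hud$hours[sel]
  }
  list(
    open_exploration = daily_matrix(grab(function(a) open_exploration(ts, a, nest)),
                                    "open_exploration", "hrs/day"),
    distance_traveled = daily_matrix(grab(function(a) distance_traveled(ts, a)),
                                     "distance_traveled", "m/day"),
    food = daily_matrix(grab(function(a) roi_occupancy(ts, a, "food")$daily),
                        "food", "hrs/day"),
    water = daily_matrix(grab(function(a) roi_occupancy(ts, a, "water")$daily),
                         "water", "hrs/day"),
    huddle = daily_matrix(hud_m, "huddle", "hrs/day")
  )
}
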