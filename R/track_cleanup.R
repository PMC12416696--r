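# Identity-switch repair, gap interpolation, and cage-cleaning-day
# substitution for multi-animal centroid tracks.

#' Detect identity switches between animal tracks
#'
#' An identity switch is flagged at frame `f` for the pair (A, B) when A's
#' frame-to-frame displacement exceeds `jump_cm` (a jump no real animal makes
#' between consecutive frames) and B's position at `f` lies within `refit_cm`
#' of A's position at `f - 1` — i.e., B's track continues A's. The test is
#' applied symmetrically; a pair satisfying it in both directions yields one
#' event, not two.
#'
#' @param ts A [trackset()] with at least 2 animals.
#' @param jump_cm Displacement threshold in cm per frame (default 10; about
#'   2.5 m/s at 25 fps, beyond gerbil locomotion).
#' @param refit_cm Refit radius in cm. The default (`NULL`) scales with the
#'   frame period as `speed_cms / fps + 1.2`, covering ordinary per-frame
#'   motion plus tracking jitter.
#' @param speed_cms Locomotion speed scale used for the default refit
#'   radius (default 9 cm/s).
#' @param symmetric Require the refit in both directions — each animal's
#'   new position continues the other's track (default TRUE; much more
#'   specific when animals are close together).
#' @param gap_tol Frame pairs further apart than `gap_tol / fps` seconds
#'   span recording downtime and are never flagged (default 1.5).
#' @return data.frame of class `swap_events` with columns
#'   `frame, animal_a, animal_b, kind`, sorted by frame.
#' @export
detect_id_switches <- function(ts, jump_cm = 10, refit_cm = NULL,
                               speed_cms = 9, symmetric = TRUE,
                               gap_tol = 1.5) {
  nm <- ts$animals$name
  if (is.null(refit_cm)) refit_cm <- speed_cms / ts$fps + 1.2
  if (length(nm) < 2) {
    warning("single-animal trackset: no identity switches possible")
    return(swap_events(integer(0), character(0), character(0), "detected"))
  }
  pos <- ts$pos
  T_ <- dim(pos)[1]
  if (T_ < 2)
    return(swap_events(integer(0), character(0), character(0), "detected"))
  dx <- pos[-1, , 1] - pos[-T_, , 1]
  dy <- pos[-1, , 2] - pos[-T_, , 2]
  disp <- sqrt(dx^2 + dy^2)                 # (T-1) x A
  contiguous <- diff(ts$time_s) <= gap_tol / ts$fps
  disp[!contiguous, ] <- NA
  jumpers <- which(!is.na(disp) & disp > jump_cm, arr.ind = TRUE)
  ev <- list()
  for (k in seq_len(nrow(jumpers))) {
    f <- jumpers[k, 1] + 1L                  # frame index of arrival
    a <- jumpers[k, 2]
    prev_a <- pos[f - 1L, a, ]
    for (b in seq_along(nm)) {
      if (b == a) next
      pb <- pos[f, b, ]
      if (anyNA(pb)) next
      if (sqrt(sum((pb - prev_a)^2)) >= refit_cm) next
      if (symmetric) {
        prev_b <- pos[f - 1L, b, ]
        pa <- pos[f, a, ]
        if (anyNA(prev_b) || anyNA(pa)) next
        if (sqrt(sum((pa - prev_b)^2)) >= refit_cm) next
        if (disp[f - 1L, b] <= jump_cm || is.na(disp[f - 1L, b])) next
      }
      pr <- sort(c(nm[a], nm[b]))
      ev[[length(ev) + 1L]] <- data.frame(frame = f, animal_a = pr[1],
                                          animal_b = pr[2])
    }
  }
  if (length(ev) == 0)
    return(swap_events(integer(0), character(0), character(0), "detected"))
  df <- unique(do.call(rbind, ev))
  df <- df[order(df$frame, df$animal_a), , drop = FALSE]
  swap_events(df$frame, df$animal_a, df$animal_b, "detected")
}

#' Swap-event table constructor
#'
#' @param frame Frame indices (1-based).
#' @param animal_a,animal_b The swapped pair (distinct).
#' @param kind `"detected"` or `"injected"`.
#' @return data.frame of class `swap_events`.
#' @export
swap_events <- function(frame, animal_a, animal_b, kind = "detected") {
  if (any(animal_a == animal_b)) stop("swap pair members must be distinct")
  df <- data.frame(frame = as.integer(frame), animal_a = animal_a,
                   animal_b = animal_b,
                   kind = rep(kind, length.out = length(frame)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("swap_events", "data.frame")
  df
}

# Exchange two animals' tracks from `frame` to the end of the session.
swap_from_frame <- function(ts, frame, a, b) {
  idx <- frame:dim(ts$pos)[1]
  tmp <- ts$pos[idx, a, ]
  ts$pos[idx, a, ] <- ts$pos[idx, b, ]
  ts$pos[idx, b, ] <- tmp
  if (!is.null(ts$poses)) {
    ia <- match(a, ts$animals$name); ib <- match(b, ts$animals$name)
    tmp <- ts$poses[idx, ia, , ]
    ts$poses[idx, ia, , ] <- ts$poses[idx, ib, , ]
    ts$poses[idx, ib, , ] <- tmp
  }
  ts
}

#' Correct identity switches
#'
#' Each event exchanges the two animals' tracks from its frame onward.
#' Identity errors accumulate forward in time (each switch permutes the
#' labels of the already-switched state), so the repair applies the events
#' in reverse chronological order, undoing the most recent switch first —
#' the exact inverse of the accumulation. A later event on the same pair
#' closes the earlier event's segment, which realizes segment-scoped swaps;
#' applying the same event list to a clean track set and then correcting
#' restores the original.
#'
#' @param ts A [trackset()].
#' @param events A [swap_events()] table.
#' @return The corrected [trackset()].
#' @export
correct_id_switches <- function(ts, events) {
  if (nrow(events) == 0) return(ts)
  if (any(events$frame < 1 | events$frame > dim(ts$pos)[1]))
    stop("swap event frame outside trackset range")
  key <- paste(events$frame, events$animal_a, events$animal_b)
  if (anyDuplicated(key))
    stop("contradictory swap events: duplicated ",
         key[duplicated(key)][1])
  same_frame <- split(seq_len(nrow(events)), events$frame)
  for (grp in same_frame) {
    if (length(grp) > 1) {
      an <- c(events$animal_a[grp], events$animal_b[grp])
      if (anyDuplicated(an))
        stop("contradictory swap events at frame ", events$frame[grp[1]],
             ": one animal in two pairs")
    }
  }
  events <- events[order(events$frame, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ts <- swap_from_frame(ts, events$frame[i],
                          events$animal_a[i], events$animal_b[i])
  }
  ts
}

#' Per-frame identity accuracy against ground truth
#'
#' Fraction of (frame, animal) entries whose position matches the reference
#' tracks (both missing counts as a match; a value against a missing entry
#' counts as a mismatch).
#'
#' @param ts,ref Tracksets on the same frames and animals.
#' @param tol_cm Position tolerance in cm.
#' @return Accuracy in `[0, 1]`.
#' @export
identity_accuracy <- function(ts, ref, tol_cm = 1e-6) {
  stopifnot(identical(dim(ts$pos), dim(ref$pos)))
  d <- sqrt((ts$pos[, , 1] - ref$pos[, , 1])^2 +
              (ts$pos[, , 2] - ref$pos[, , 2])^2)
  both_na <- is.na(ts$pos[, , 1]) & is.na(ref$pos[, , 1])
  ok <- both_na | (!is.na(d) & d <= tol_cm)
  mean(ok)
}

#' Bridge short gaps in tracks and merge split huddles
#'
#' A missing run for one animal is linearly interpolated (in time) iff the
#' Euclidean distance between its flanking tracked positions is below
#' `max_gap_cm` — short occlusions, not nest entries. Huddle intervals
#' separated by less than `max_huddle_gap_s` whose centroids lie within
#' `same_huddle_cm` are merged into one interval (duration-weighted
#' centroid).
#'
#' @param ts A [trackset()] with cleaned identities.
#' @param huddles A [huddle_track()] or `NULL`.
#' @param max_gap_cm Flank-distance threshold (default 3 cm).
#' @param max_huddle_gap_s Huddle merge gap (default 30 s).
#' @param same_huddle_cm Centroid radius for "same huddle" (default 6 cm).
#' @return list(tracks = trackset, huddles = huddle_track).
#' @export
interpolate_gaps <- function(ts, huddles = NULL, max_gap_cm = 3,
                             max_huddle_gap_s = 30, same_huddle_cm = 6) {
  T_ <- dim(ts$pos)[1]
  for (a in seq_len(dim(ts$pos)[2])) {
    miss <- is.na(ts$pos[, a, 1])
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
      if (i0 < 1 || i1 > T_) next
      p0 <- ts$pos[i0, a, ]; p1 <- ts$pos[i1, a, ]
      if (anyNA(p0) || anyNA(p1)) next
      if (sqrt(sum((p1 - p0)^2)) < max_gap_cm) {
        idx <- starts[k]:ends[k]
        w <- (ts$time_s[idx] - ts$time_s[i0]) / (ts$time_s[i1] - ts$time_s[i0])
        ts$pos[idx, a, 1] <- p0[1] + w * (p1[1] - p0[1])
        ts$pos[idx, a, 2] <- p0[2] + w * (p1[2] - p0[2])
      }
    }
  }
  if (!is.null(huddles) && nrow(huddles) > 1) {
    h <- as.data.frame(huddles)
    out <- h[1, , drop = FALSE]
    for (i in 2:nrow(h)) {
      last <- nrow(out)
      gap <- h$start_s[i] - out$end_s[last]
      dcen <- sqrt((h$x[i] - out$x[last])^2 + (h$y[i] - out$y[last])^2)
      if (gap < max_huddle_gap_s && dcen < same_huddle_cm) {
        w1 <- out$end_s[last] - out$start_s[last]
        w2 <- h$end_s[i] - h$start_s[i]
        out$x[last] <- (out$x[last] * w1 + h$x[i] * w2) / (w1 + w2)
        out$y[last] <- (out$y[last] * w1 + h$y[i] * w2) / (w1 + w2)
        out$end_s[last] <- h$end_s[i]
      } else {
        out <- rbind(out, h[i, ])
      }
    }
    huddles <- huddle_track(out$start_s, out$end_s, out$x, out$y)
  }
  list(tracks = ts, huddles = huddles)
}

#' Substitute a cage-cleaning day by its neighbors' mean
#'
#' Replaces each animal's value on `day` by the mean of its values on
#' `day - 1` and `day + 1` (the disturbance-day interpolation used for
#' bedding changes).
#'
#' @param mat A [daily_matrix()].
#' @param day Postnatal day to substitute.
#' @return The modified [daily_matrix()].
#' @export
substitute_day <- function(mat, day) {
  days <- as.integer(colnames(mat))
  need <- as.character(c(day - 1, day, day + 1))
  if (!all(c(day - 1, day + 1) %in% days))
    stop("substitute_day needs both flanking days P", day - 1, " and P", day + 1)
  lo <- mat[, need[1]]; hi <- mat[, need[3]]
  if (anyNA(lo) || anyNA(hi))
    stop("flanking day value missing for: ",
         paste(rownames(mat)[is.na(lo) | is.na(hi)], collapse = ", "))
  mat[, need[2]] <- (lo + hi) / 2
  mat
}
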