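# Cage defaults: floor is 57.2 cm (x, "length") by 35.6 cm (y, "width"),
# origin at one corner. ROI rectangles are stored as c(x0, x1, y0, y1) in cm.
CAGE_LENGTH_CM <- 57.2
CAGE_WIDTH_CM <- 35.6

#' Animal roster for one family
#'
#' Builds the canonical animal table: two adults (`female`, `male`) and up to
#' four pups (`pup1` ... `pup4`).
#'
#' @param n_pups Number of pups in the family (0 to 4).
#' @return A data.frame with columns `name` and `age_class`.
#' @export
animal_table <- function(n_pups = 4) {
  stopifnot(n_pups >= 0, n_pups <= 4)
  pups <- if (n_pups > 0) paste0("pup", seq_len(n_pups)) else character(0)
  data.frame(
    name = c("female", "male", pups),
    age_class = c("adult", "adult", rep("pup", n_pups)),
    stringsAsFactors = FALSE
  )
}

#' Cage geometry
#'
#' @param length_cm Cage extent along x (default 57.2 cm).
#' @param width_cm Cage extent along y (default 35.6 cm).
#' @param rois Named list of ROI rectangles `c(x0, x1, y0, y1)` in cm; all
#'   must lie within the cage.
#' @return A list of class `cage_geometry`.
#' @export
cage_geometry <- function(length_cm = CAGE_LENGTH_CM, width_cm = CAGE_WIDTH_CM,
                          rois = list()) {
  stopifnot(length_cm > 0, width_cm > 0)
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (length(r) != 4 || r[1] > r[2] || r[3] > r[4] ||
        r[1] < 0 || r[2] > length_cm || r[3] < 0 || r[4] > width_cm) {
      stop("ROI '", nm, "' does not lie within the cage bounds")
    }
  }
  structure(list(length_cm = length_cm, width_cm = width_cm, rois = rois),
            class = "cage_geometry")
}

#' Default food-hopper and waterspout ROIs
#'
#' ROI sizes are fixed (food hopper 19.50 x 10.50 cm, waterspout
#' 8.50 x 8.00 cm); their placement along the cage walls is configurable.
#'
#' @param food_corner,water_corner Lower-left `c(x, y)` corner of each ROI.
#' @return Named list of ROI rectangles.
#' @export
default_rois <- function(food_corner = c(0, 25.1), water_corner = c(48.7, 0)) {
  list(
    food = c(food_corner[1], food_corner[1] + 19.5,
             food_corner[2], food_corner[2] + 10.5),
    water = c(water_corner[1], water_corner[1] + 8.5,
              water_corner[2], water_corner[2] + 8.0)
  )
}

#' Light schedule
#'
#' @param day_start_h Clock hour at which the light phase begins (default 8).
#' @param night_start_h Clock hour at which the dark phase begins (default 20).
#' @return A list of class `light_schedule`.
#' @export
light_schedule <- function(day_start_h = 8, night_start_h = 20) {
  stopifnot(day_start_h >= 0, day_start_h < 24,
            night_start_h >= 0, night_start_h < 24,
            day_start_h != night_start_h)
  structure(list(day_start_h = day_start_h, night_start_h = night_start_h),
            class = "light_schedule")
}

#' Light phase of a clock time
#'
#' Half-open convention: day is `[day_start, night_start)`; every clock time
#' belongs to exactly one phase.
#'
#' @param schedule A [light_schedule()].
#' @param clock_s Seconds since midnight (vectorised), in `[0, 86400)`.
#' @return Character vector of `"day"` / `"night"`.
#' @export
light_phase <- function(schedule, clock_s) {
  h <- (clock_s / 3600) %% 24
  d0 <- schedule$day_start_h
  n0 <- schedule$night_start_h
  if (d0 < n0) {
    ifelse(h >= d0 & h < n0, "day", "night")
  } else {
    ifelse(h >= d0 | h < n0, "day", "night")
  }
}

#' Construct a track set
#'
#' The container for multi-animal centroid (and optionally 6-node pose)
#' trajectories over postnatal days. Time is kept as seconds since midnight
#' of the anchor postnatal day, so wall-clock hour and postnatal day are both
#' derivable per frame.
#'
#' @param time_s Strictly increasing numeric vector, seconds since 00:00 of
#'   postnatal day `anchor_pnd`.
#' @param pos Array `T x A x 2` of (x, y) positions in cm; `NA` = missing.
#'   Column names of the animal axis must match `animals$name`.
#' @param animals Roster from [animal_table()] (or same shape).
#' @param fps Nominal frame rate (frames per second).
#' @param anchor_pnd Postnatal day containing `time_s = 0`.
#' @param cage A [cage_geometry()].
#' @param schedule A [light_schedule()].
#' @param poses Optional array `T x A x 6 x 2` of node coordinates in cm.
#' @return An object of class `trackset`.
#' @export
trackset <- function(time_s, pos, animals, fps = 25, anchor_pnd = 15,
                     cage = cage_geometry(), schedule = light_schedule(),
                     poses = NULL) {
  stopifnot(fps > 0)
  time_s <- as.numeric(time_s)
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    k <- which(diff(time_s) <= 0)[1]
    stop("timestamps must be strictly increasing (violation at frame ", k + 1, ")")
  }
  if (length(dim(pos)) != 3 || dim(pos)[3] != 2)
    stop("pos must be a T x A x 2 array")
  if (dim(pos)[1] != length(time_s))
    stop("pos has ", dim(pos)[1], " frames but time_s has ", length(time_s))
  if (dim(pos)[2] != nrow(animals))
    stop("pos animal axis does not match the animal table")
  known <- animal_table(4)$name
  if (!all(animals$name %in% known))
    stop("unknown animal name(s): ",
         paste(setdiff(animals$name, known), collapse = ", "))
  if (anyDuplicated(animals$name)) stop("animal names must be unique")
  if (sum(animals$age_class == "adult") != 2)
    stop("a family must have exactly 2 adults")
  dimnames(pos) <- list(NULL, animals$name, c("x", "y"))
  x <- pos[, , 1]; y <- pos[, , 2]
  bad <- which(!is.na(x) & (x < 0 | x > cage$length_cm), arr.ind = TRUE)
  if (length(bad) == 0)
    bad <- which(!is.na(y) & (y < 0 | y > cage$width_cm), arr.ind = TRUE)
  if (length(bad) > 0)
    stop("position out of cage bounds at frame ",
         if (is.matrix(bad)) bad[1, 1] else bad[1])
  if (!is.null(poses)) {
    if (length(dim(poses)) != 4 || any(dim(poses)[c(1, 2, 4)] != c(dim(pos)[1:2], 2)))
      stop("poses must be a T x A x n_nodes x 2 array matching pos")
  }
  structure(list(time_s = time_s, pos = pos, poses = poses,
                 animals = animals, fps = fps, anchor_pnd = anchor_pnd,
                 cage = cage, schedule = schedule),
            class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  cat("<trackset> ", length(x$time_s), " frames, ", nrow(x$animals),
      " animals (", paste(x$animals$name, collapse = ", "), "), ",
      x$fps, " fps\n", sep = "")
  cat("  days P", min(frame_pnd(x)), "-P", max(frame_pnd(x)),
      ", cage ", x$cage$length_cm, " x ", x$cage$width_cm, " cm\n", sep = "")
  invisible(x)
}

#' Per-frame postnatal day and clock time
#'
#' Postnatal-day boundaries are at wall-clock midnight.
#'
#' @param ts A [trackset()].
#' @return Integer vector (for `frame_pnd`) or numeric seconds since
#'   midnight (for `frame_clock_s`).
#' @export
frame_pnd <- function(ts) as.integer(ts$anchor_pnd + floor(ts$time_s / 86400))

#' @rdname frame_pnd
#' @export
frame_clock_s <- function(ts) ts$time_s %% 86400

#' Recording coverage per postnatal day
#'
#' Fraction of each calendar day covered by recorded frames, estimated as
#' recorded frame count / (fps * 86400). Daily rates elsewhere are divided by
#' this coverage so that days with recording downtime remain comparable.
#'
#' @param ts A [trackset()].
#' @return data.frame with columns `pnd`, `coverage`.
#' @export
coverage_by_day <- function(ts) {
  pnd <- frame_pnd(ts)
  tab <- table(pnd)
  data.frame(pnd = as.integer(names(tab)),
             coverage = pmin(1, as.numeric(tab) / (ts$fps * 86400)))
}

#' Median-centroid series for one animal
#'
#' When 6-node poses are present the per-frame coordinate is the per-axis
#' median over the available nodes (robust to a single stray node); otherwise
#' the stored centroid positions pass through. A frame with no available node
#' is missing.
#'
#' @param ts A [trackset()].
#' @param animal Animal name.
#' @return A `T x 2` matrix (columns `x`, `y`), `NA` where missing.
#' @export
centroid_series <- function(ts, animal) {
  if (!animal %in% ts$animals$name)
    stop("unknown animal: ", animal)
  if (is.null(ts$poses)) {
    out <- ts$pos[, animal, , drop = FALSE]
    dim(out) <- c(dim(ts$pos)[1], 2)
  } else {
    a <- match(animal, ts$animals$name)
    nodes <- ts$poses[, a, , , drop = FALSE]
    dim(nodes) <- dim(nodes)[c(1, 3, 4)]      # T x n_nodes x 2
    med <- function(v) if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
    out <- cbind(apply(nodes[, , 1, drop = FALSE], 1, med),
                 apply(nodes[, , 2, drop = FALSE], 1, med))
  }
  colnames(out) <- c("x", "y")
  out
}

#' Centroid matrix for several animals
#'
#' @param ts A [trackset()].
#' @param animals Animal names (default: all).
#' @return A `T x A x 2` array of median centroids.
#' @export
centroid_array <- function(ts, animals = ts$animals$name) {
  out <- array(NA_real_, c(length(ts$time_s), length(animals), 2),
               dimnames = list(NULL, animals, c("x", "y")))
  for (a in animals) out[, a, ] <- centroid_series(ts, a)
  out
}

# ---------------------------------------------------------------------------
# On-disk formats

write_meta_json <- function(ts, path) {
  meta <- list(
    fps = ts$fps, anchor_pnd = ts$anchor_pnd, units = "cm", px_to_cm = 1.0,
    cage = list(length_cm = ts$cage$length_cm, width_cm = ts$cage$width_cm,
                rois = ts$cage$rois),
    schedule = list(day_start_h = ts$schedule$day_start_h,
                    night_start_h = ts$schedule$night_start_h),
    animals = ts$animals
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
}

meta_sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), "_meta.json")

read_meta_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$px_to_cm) && identical(m$units, "px"))
    stop("pixel-unit file lacks the mandatory px_to_cm scale in metadata")
  m
}

rois_from_meta <- function(m) {
  rois <- m$cage$rois
  if (is.null(rois) || length(rois) == 0) return(list())
  lapply(rois, as.numeric)
}

#' Write a track set to disk
#'
#' Two dialects: `canonical-h5` (HDF5 groups `/meta`, `/animals`, `/tracks`,
#' `/timestamps`, optional `/poses`) and `wide-csv` (columns `time_s`, `pnd`,
#' then `<animal>_x`, `<animal>_y`; metadata in a `*_meta.json` sidecar).
#'
#' @param ts A [trackset()].
#' @param path Output file path.
#' @param dialect `"canonical-h5"` or `"wide-csv"`.
#' @return `path`, invisibly.
#' @export
write_trackset <- function(ts, path, dialect = c("canonical-h5", "wide-csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide-csv") {
    df <- data.frame(time_s = ts$time_s, pnd = frame_pnd(ts))
    for (a in ts$animals$name) {
      df[[paste0(a, "_x")]] <- ts$pos[, a, 1]
      df[[paste0(a, "_y")]] <- ts$pos[, a, 2]
    }
    utils::write.csv(df, path, row.names = FALSE)
    write_meta_json(ts, meta_sidecar_path(path))
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "meta")
    rhdf5::h5write(ts$fps, path, "meta/fps")
    rhdf5::h5write(1.0, path, "meta/px_to_cm")
    rhdf5::h5write(c(ts$cage$length_cm, ts$cage$width_cm), path, "meta/cage_cm")
    rhdf5::h5write(c(ts$schedule$day_start_h, ts$schedule$night_start_h),
                   path, "meta/light_schedule_h")
    if (length(ts$cage$rois) > 0) {
      rhdf5::h5write(names(ts$cage$rois), path, "meta/roi_names")
      rhdf5::h5write(do.call(rbind, ts$cage$rois), path, "meta/roi_rects")
    }
    rhdf5::h5createGroup(path, "animals")
    rhdf5::h5write(ts$animals$name, path, "animals/name")
    rhdf5::h5write(ts$animals$age_class, path, "animals/age_class")
    rhdf5::h5write(ts$pos, path, "tracks")
    if (!is.null(ts$poses)) rhdf5::h5write(ts$poses, path, "poses")
    rhdf5::h5createGroup(path, "timestamps")
    rhdf5::h5write(ts$time_s, path, "timestamps/time_s")
    rhdf5::h5write(frame_pnd(ts), path, "timestamps/pnd")
    rhdf5::h5write(as.integer(ts$anchor_pnd), path, "timestamps/anchor_pnd")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Load a track set from disk
#'
#' @param path Input file.
#' @param dialect `"canonical-h5"`, `"wide-csv"`, or `"pose-export"` (a
#'   best-effort adapter for generic pose-analysis HDF5 exports; requires the
#'   px-to-cm scale as file metadata).
#' @return A validated [trackset()].
#' @export
load_trackset <- function(path, dialect = c("canonical-h5", "wide-csv", "pose-export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         "wide-csv" = load_trackset_csv(path),
         "canonical-h5" = load_trackset_h5(path),
         "pose-export" = load_trackset_pose_export(path))
}

load_trackset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "pnd") %in% names(df)))
    stop("malformed wide-csv: missing 'time_s'/'pnd' header columns")
  coord_cols <- setdiff(names(df), c("time_s", "pnd"))
  nm <- unique(sub("_[xy]$", "", coord_cols))
  for (a in nm) {
    if (!all(paste0(a, c("_x", "_y")) %in% coord_cols))
      stop("malformed wide-csv: animal '", a, "' lacks paired _x/_y columns")
  }
  mpath <- meta_sidecar_path(path)
  if (!file.exists(mpath)) stop("metadata sidecar not found: ", mpath)
  m <- read_meta_json(mpath)
  animals <- as.data.frame(m$animals)
  if (!setequal(animals$name, nm))
    stop("malformed wide-csv: columns do not match the animal table")
  scale <- if (identical(m$units, "px")) m$px_to_cm else 1.0
  pos <- array(NA_real_, c(nrow(df), nrow(animals), 2))
  for (i in seq_len(nrow(animals))) {
    pos[, i, 1] <- df[[paste0(animals$name[i], "_x")]] * scale
    pos[, i, 2] <- df[[paste0(animals$name[i], "_y")]] * scale
  }
  trackset(df$time_s, pos, animals, fps = m$fps, anchor_pnd = m$anchor_pnd,
           cage = cage_geometry(m$cage$length_cm, m$cage$width_cm,
                                rois = rois_from_meta(m)),
           schedule = light_schedule(m$schedule$day_start_h, m$schedule$night_start_h))
}

load_trackset_h5 <- function(path) {
  ls <- rhdf5::h5ls(path)
  need <- c("tracks", "meta", "animals", "timestamps")
  miss <- setdiff(need, ls$name)
  if (length(miss) > 0)
    stop("malformed canonical-h5: missing '", miss[1], "'")
  fps <- as.numeric(rhdf5::h5read(path, "meta/fps"))
  cage_cm <- as.numeric(rhdf5::h5read(path, "meta/cage_cm"))
  sched <- as.numeric(rhdf5::h5read(path, "meta/light_schedule_h"))
  rois <- list()
  if ("roi_names" %in% ls$name) {
    rn <- as.character(rhdf5::h5read(path, "meta/roi_names"))
    rr <- rhdf5::h5read(path, "meta/roi_rects")
    rois <- stats::setNames(lapply(seq_along(rn), function(i) as.numeric(rr[i, ])), rn)
  }
  animals <- data.frame(
    name = as.character(rhdf5::h5read(path, "animals/name")),
    age_class = as.character(rhdf5::h5read(path, "animals/age_class")),
    stringsAsFactors = FALSE)
  pos <- rhdf5::h5read(path, "tracks")
  poses <- if ("poses" %in% ls$name) rhdf5::h5read(path, "poses") else NULL
  time_s <- as.numeric(rhdf5::h5read(path, "timestamps/time_s"))
  anchor <- as.integer(rhdf5::h5read(path, "timestamps/anchor_pnd"))
  px <- as.numeric(rhdf5::h5read(path, "meta/px_to_cm"))
  rhdf5::h5closeAll()
  if (px != 1) { pos <- pos * px; if (!is.null(poses)) poses <- poses * px }
  trackset(time_s, pos, animals, fps = fps, anchor_pnd = anchor,
           cage = cage_geometry(cage_cm[1], cage_cm[2], rois = rois),
           schedule = light_schedule(sched[1], sched[2]), poses = poses)
}

# Best-effort adapter for generic pose-analysis HDF5 exports: expects a
# `tracks` dataset of shape T x A x 2 (centroids) or T x A x n_nodes x 2
# (poses), a `track_names` vector, `fps`, and a mandatory `px_to_cm` scale.
load_trackset_pose_export <- function(path) {
  ls <- rhdf5::h5ls(path)
  if (!"tracks" %in% ls$name) stop("pose export lacks a 'tracks' dataset")
  if (!"px_to_cm" %in% ls$name)
    stop("pose export lacks the mandatory px_to_cm scale")
  tr <- rhdf5::h5read(path, "tracks")
  nm <- as.character(rhdf5::h5read(path, "track_names"))
  fps <- if ("fps" %in% ls$name) as.numeric(rhdf5::h5read(path, "fps")) else 25
  px <- as.numeric(rhdf5::h5read(path, "px_to_cm"))
  anchor <- if ("anchor_pnd" %in% ls$name)
    as.integer(rhdf5::h5read(path, "anchor_pnd")) else 15L
  rhdf5::h5closeAll()
  known <- animal_table(4)
  animals <- known[match(nm, known$name), ]
  if (anyNA(animals$name)) stop("unknown animal name(s) in pose export")
  tr <- tr * px
  nd <- length(dim(tr))
  if (nd == 4) {
    poses <- tr
    pos <- apply(poses, c(1, 2, 4), function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  } else if (nd == 3) {
    poses <- NULL; pos <- tr
  } else stop("pose export 'tracks' must have 3 or 4 dimensions")
  t_s <- (seq_len(dim(pos)[1]) - 1) / fps
  trackset(t_s, pos, animals, fps = fps, anchor_pnd = anchor, poses = poses)
}

# ---------------------------------------------------------------------------
# Bout series and daily matrices

#' Construct a bout series
#'
#' Labeled, non-overlapping time intervals for one behavior: each row is one
#' bout `[start_s, end_s)` for a subject (an animal or an ordered pair
#' written `"a>b"` / unordered `"a|b"`).
#'
#' @param label Behavior name.
#' @param subject Subject identifier (recycled).
#' @param start_s,end_s Bout boundaries in seconds (same time base as the
#'   originating track set).
#' @return A data.frame of class `bouts`, sorted, with `end_s > start_s`.
#' @export
bout_series <- function(label, subject, start_s, end_s) {
  df <- data.frame(label = label, subject = subject,
                   start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  if (any(df$end_s <= df$start_s)) stop("bouts must satisfy end_s > start_s")
  df <- df[order(df$subject, df$start_s), , drop = FALSE]
  for (s in unique(df$subject)) {
    b <- df[df$subject == s, ]
    if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)]))
      stop("bouts for subject '", s, "' overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("bouts", "data.frame")
  df
}

#' Read/write bout series CSV
#'
#' Columns: `label, subject, start_s, end_s`.
#' @param bouts A `bouts` data.frame.
#' @param path CSV path.
#' @export
write_bouts <- function(bouts, path) {
  utils::write.csv(as.data.frame(bouts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bout_series(df$label, df$subject, df$start_s, df$end_s)
}

#' Daily behavior matrix
#'
#' An animals x postnatal-days grid of daily behavior amounts in absolute
#' units (`hrs/day`, `m/day`, `count/day`, or `min/day`).
#'
#' @param values Numeric matrix, rownames = animal names, colnames =
#'   postnatal days (contiguous, within P15-P30). `NA` allowed.
#' @param behavior Behavior name.
#' @param units One of `"hrs/day"`, `"m/day"`, `"count/day"`, `"min/day"`.
#' @return The matrix with class `daily_matrix` and attributes set.
#' @export
daily_matrix <- function(values, behavior,
                         units = c("hrs/day", "m/day", "count/day", "min/day")) {
  units <- match.arg(units)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  days <- as.integer(colnames(values))
  if (any(days < 15 | days > 30)) stop("days must lie within P15-P30")
  if (length(days) > 1 && any(diff(days) != 1)) stop("days must be contiguous")
  if (any(values < 0, na.rm = TRUE)) stop("daily values must be >= 0")
  structure(values, behavior = behavior, units = units,
            class = c("daily_matrix", "matrix", "array"))
}

#' @export
print.daily_matrix <- function(x, ...) {
  cat("<daily_matrix> ", attr(x, "behavior"), " [", attr(x, "units"), "], ",
      nrow(x), " animals x P", colnames(x)[1], "-P",
      colnames(x)[ncol(x)], "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read/write daily behavior matrices as long CSV
#'
#' Columns: `behavior, animal, pnd, value, units`.
#' @param mat A [daily_matrix()].
#' @param path CSV path.
#' @export
write_daily_matrix <- function(mat, path) {
  df <- data.frame(behavior = attr(mat, "behavior"),
                   animal = rep(rownames(mat), ncol(mat)),
                   pnd = rep(as.integer(colnames(mat)), each = nrow(mat)),
                   value = as.vector(mat),
                   units = attr(mat, "units"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_matrix
#' @export
read_daily_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  animals <- unique(df$animal)
  days <- sort(unique(df$pnd))
  m <- matrix(NA_real_, length(animals), length(days),
              dimnames = list(animals, days))
  m[cbind(match(df$animal, animals), match(df$pnd, days))] <- df$value
  daily_matrix(m, behavior = df$behavior[1], units = df$units[1])
}

#' Huddle track
#'
#' Non-overlapping intervals during which a huddle (2+ animals clustered at a
#' stable location) is active, with the huddle centroid.
#'
#' @param start_s,end_s Interval bounds in seconds.
#' @param x,y Huddle centroid (cm).
#' @return data.frame of class `huddle_track`, sorted by start.
#' @export
huddle_track <- function(start_s, end_s, x, y) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   x = as.numeric(x), y = as.numeric(y))
  if (any(df$end_s <= df$start_s)) stop("huddle intervals must satisfy end > start")
  df <- df[order(df$start_s), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)]))
    stop("huddle intervals overlap")
  rownames(df) <- NULL
  class(df) <- c("huddle_track", "data.frame")
  df
}
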