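# Developmental-trajectory statistics: adult-normalized trajectories,
# Kolmogorov-Smirnov rapid-development detection with Benjamini-Hochberg
# adjustment, convex-hull overlap in principal-component space, identity
# shuffles, trajectory correlations, and a Monte-Carlo power utility.

#' Normalize pup trajectories to the adult reference
#'
#' Divides every pup's daily value by the mean of the two adults' values on
#' the reference day, so 1.0 means "at adult level".
#'
#' @param mat A [daily_matrix()] containing both adults and the pups.
#' @param animals Animal roster (for age classes).
#' @param reference_day Postnatal day of the adult reference (default 29).
#' @return list of class `relative_trajectory`: `values` (pup x day matrix,
#'   adult mean = 1.0), `reference` (adult mean in absolute units),
#'   `behavior`.
#' @export
normalize_to_adult <- function(mat, animals, reference_day = 29) {
  adults <- animals$name[animals$age_class == "adult"]
  pups <- animals$name[animals$age_class == "pup"]
  if (!as.character(reference_day) %in% colnames(mat))
    stop("reference day P", reference_day, " not present")
  ref_vals <- mat[adults, as.character(reference_day)]
  if (anyNA(ref_vals))
    stop("adult value missing at reference day for behavior ",
         attr(mat, "behavior"))
  reference <- mean(ref_vals)
  if (reference == 0)
    stop("adult reference is zero for behavior ", attr(mat, "behavior"))
  structure(list(values = mat[pups, , drop = FALSE] / reference,
                 reference = reference,
                 behavior = attr(mat, "behavior")),
            class = "relative_trajectory")
}

#' Detect rapid-development days
#'
#' For each day `d`, the cross-animal value distribution is compared by
#' two-sample Kolmogorov-Smirnov test against the pooled values of the
#' previous two days (and, optionally, also against the following day).
#' p-values are Benjamini-Hochberg adjusted within the behavior; a day is
#' flagged when its test(s) reject at `alpha`.
#'
#' @param mat A [daily_matrix()] or plain animal x day matrix (pups are
#'   typically pooled across cohorts).
#' @param alpha Significance level after adjustment (default 0.05).
#' @param comparison `"previous_only"` (default): flag on the
#'   previous-two-days test; `"both"`: additionally require rejection
#'   against the following day.
#' @param min_n Minimum sample size per side (default 3); days with fewer
#'   values are skipped with a warning.
#' @return list: `flags` (integer days), `table` (pnd, p_prev, p_next,
#'   p_prev_adj, p_next_adj, flagged).
#' @export
rapid_development_days <- function(mat, alpha = 0.05,
                                   comparison = c("previous_only", "both"),
                                   min_n = 3) {
  comparison <- match.arg(comparison)
  days <- as.integer(colnames(mat))
  rows <- list()
  for (d in days) {
    if (!all(c(d - 2, d - 1) %in% days)) next
    cur <- mat[, as.character(d)]
    prev <- c(mat[, as.character(d - 2)], mat[, as.character(d - 1)])
    cur <- cur[!is.na(cur)]; prev <- prev[!is.na(prev)]
    if (length(cur) < min_n || length(prev) < min_n) {
      warning("P", d, ": fewer than ", min_n, " values, day skipped")
      next
    }
    p_prev <- suppressWarnings(stats::ks.test(cur, prev)$p.value)
    p_next <- NA_real_
    if (comparison == "both") {
      if (!(d + 1) %in% days) next
      nxt <- mat[, as.character(d + 1)]
      nxt <- nxt[!is.na(nxt)]
      if (length(nxt) < min_n) {
        warning("P", d, ": fewer than ", min_n, " next-day values, day skipped")
        next
      }
      p_next <- suppressWarnings(stats::ks.test(cur, nxt)$p.value)
    }
    rows[[length(rows) + 1]] <- data.frame(pnd = d, p_prev = p_prev,
                                           p_next = p_next)
  }
  if (length(rows) == 0)
    return(list(flags = integer(0),
                table = data.frame(pnd = integer(0), p_prev = numeric(0),
                                   p_next = numeric(0), p_prev_adj = numeric(0),
                                   p_next_adj = numeric(0), flagged = logical(0))))
  tab <- do.call(rbind, rows)
  pooled <- c(tab$p_prev, tab$p_next)
  keep <- !is.na(pooled)
  adj <- rep(NA_real_, length(pooled))
  adj[keep] <- stats::p.adjust(pooled[keep], method = "BH")
  tab$p_prev_adj <- adj[seq_len(nrow(tab))]
  tab$p_next_adj <- adj[nrow(tab) + seq_len(nrow(tab))]
  tab$flagged <- tab$p_prev_adj < alpha &
    (comparison == "previous_only" | (!is.na(tab$p_next_adj) & tab$p_next_adj < alpha))
  list(flags = tab$pnd[tab$flagged], table = tab)
}

# ---------------------------------------------------------------------------
# Convex hulls in 2-3 dimensions: half-space representation by facet
# enumeration (point sets here are small: one point per animal).

hull_rank <- function(pts, tol = 1e-9) {
  c0 <- sweep(pts, 2, colMeans(pts))
  sum(svd(c0, nu = 0, nv = 0)$d > tol * max(1, max(abs(c0))))
}

# Half-space representation A x <= b of conv(pts), d = 2 or 3.
# Enumerates d-subsets; a subset spans a facet plane iff all points lie on
# one side. Returns NULL when the point set is not full-dimensional.
hull_facets <- function(pts, tol = 1e-9) {
  d <- ncol(pts)
  n <- nrow(pts)
  if (n < d + 1 || hull_rank(pts, tol) < d) return(NULL)
  idx <- utils::combn(n, d)
  A <- list(); b <- numeric(0)
  scale <- max(abs(pts), 1)
  for (k in seq_len(ncol(idx))) {
    S <- pts[idx[, k], , drop = FALSE]
    if (d == 2) {
      v <- S[2, ] - S[1, ]
      nrm <- c(-v[2], v[1])
    } else {
      u <- S[2, ] - S[1, ]; v <- S[3, ] - S[1, ]
      nrm <- c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
    }
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale) next
    nrm <- nrm / nn
    s <- as.vector(pts %*% nrm) - sum(nrm * S[1, ])
    eps <- tol * scale
    if (all(s <= eps)) {
      A[[length(A) + 1]] <- nrm; b <- c(b, sum(nrm * S[1, ]))
    }
    if (all(s >= -eps)) {
      A[[length(A) + 1]] <- -nrm; b <- c(b, -sum(nrm * S[1, ]))
    }
  }
  if (length(A) == 0) return(NULL)
  list(A = do.call(rbind, A), b = b)
}

in_hull <- function(pts, facets, tol = 1e-9) {
  s <- pts %*% t(facets$A)
  rowSums(s > matrix(facets$b + tol * max(1, max(abs(facets$b))),
                     nrow(pts), length(facets$b), byrow = TRUE)) == 0
}

#' Monte-Carlo Jaccard overlap of two convex hulls
#'
#' Estimates `100 * vol(A intersect B) / vol(A union B)` for the convex
#' hulls of two point sets by uniform rejection sampling over the union
#' bounding box.
#'
#' @param pts_a,pts_b Point matrices (same dimension, 2 or 3 columns).
#' @param n_samples Number of Monte-Carlo samples (default 2e5).
#' @param seed Integer seed.
#' @return Overlap percentage in `[0, 100]`.
#' @export
hull_jaccard <- function(pts_a, pts_b, n_samples = 2e5, seed = 1) {
  stopifnot(ncol(pts_a) == ncol(pts_b))
  if (nrow(pts_a) < 3 || nrow(pts_b) < 3)
    stop("need at least 3 points per set")
  fa <- hull_facets(pts_a)
  fb <- hull_facets(pts_b)
  if (is.null(fa) || is.null(fb))
    stop("point set is not full-dimensional; project to fewer components")
  d <- ncol(pts_a)
  lo <- pmin(apply(pts_a, 2, min), apply(pts_b, 2, min))
  hi <- pmax(apply(pts_a, 2, max), apply(pts_b, 2, max))
  set.seed(seed)
  smp <- matrix(stats::runif(n_samples * d), n_samples, d)
  smp <- sweep(sweep(smp, 2, hi - lo, "*"), 2, lo, "+")
  ina <- in_hull(smp, fa)
  inb <- in_hull(smp, fb)
  uni <- sum(ina | inb)
  if (uni == 0) return(0)
  100 * sum(ina & inb) / uni
}

#' Convex-hull overlap of two behaviors' developmental trajectories
#'
#' Each animal contributes one point: its multi-day trajectory for a
#' behavior. Both behaviors' animal x day matrices are stacked, a common
#' principal-component projection is fitted on the concatenation, each
#' behavior's points are taken in the first `n_pcs` components, and the
#' Jaccard overlap of the two convex hulls is returned as a percentage.
#' Falls back to 2 components when either projected point set cannot form a
#' full-dimensional hull in `n_pcs` dimensions.
#'
#' @param traj_a,traj_b Animal x day matrices on a shared day axis
#'   (typically adult-normalized pup trajectories).
#' @param n_pcs Number of principal components (default 3).
#' @param n_samples,seed Monte-Carlo settings for [hull_jaccard()].
#' @return list: `percent`, `n_pcs_used`.
#' @export
hull_overlap <- function(traj_a, traj_b, n_pcs = 3, n_samples = 2e5, seed = 1) {
  stopifnot(ncol(traj_a) == ncol(traj_b))
  if (nrow(traj_a) < 3 || nrow(traj_b) < 3)
    stop("need at least 3 animals per behavior")
  stacked <- rbind(traj_a, traj_b)
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  repeat {
    sa <- pc$x[seq_len(nrow(traj_a)), seq_len(k), drop = FALSE]
    sb <- pc$x[nrow(traj_a) + seq_len(nrow(traj_b)), seq_len(k), drop = FALSE]
    ok <- !is.null(hull_facets(sa)) && !is.null(hull_facets(sb))
    if (ok || k <= 2) break
    k <- k - 1
  }
  if (!ok) stop("point sets degenerate even in 2 components")
  list(percent = hull_jaccard(sa, sb, n_samples = n_samples, seed = seed),
       n_pcs_used = k)
}

#' Shuffle animal identity within each day
#'
#' Independently permutes the animal labels on every day, preserving each
#' day's value multiset while destroying cross-day individual identity.
#'
#' @param mat Animal x day matrix.
#' @param seed Integer seed.
#' @return Shuffled matrix of the same shape.
#' @export
shuffle_identity <- function(mat, seed) {
  if (nrow(mat) < 2) stop("need at least 2 animals to shuffle")
  set.seed(seed)
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- mat[sample(nrow(mat)), j]
  out
}

#' Pairwise trajectory correlations, within and between behaviors
#'
#' Pearson correlation over the day axis for every pair of animal
#' trajectories, grouped as within-behavior vs between-behavior. Zero-variance
#' trajectories are excluded with a warning.
#'
#' @param mats Named list of animal x day matrices on a common day axis.
#' @return Long data.frame(group, behavior_a, behavior_b, animal_a,
#'   animal_b, r).
#' @export
trajectory_correlations <- function(mats) {
  stopifnot(length(mats) >= 2)
  rows <- list()
  nb <- names(mats)
  flat_ok <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    !is.na(s) && s > 0
  }
  for (i in seq_along(mats)) {
    for (j in i:length(mats)) {
      ma <- mats[[i]]; mb <- mats[[j]]
      group <- if (i == j) "within" else "between"
      for (a in seq_len(nrow(ma))) {
        bs <- if (i == j) seq_len(nrow(mb))[-seq_len(a)] else seq_len(nrow(mb))
        for (b in bs) {
          va <- ma[a, ]; vb <- mb[b, ]
          if (!flat_ok(va) || !flat_ok(vb)) {
            warning("zero-variance trajectory excluded (",
                    nb[i], " animal ", a, " / ", nb[j], " animal ", b, ")")
            next
          }
          rows[[length(rows) + 1]] <- data.frame(
            group = group, behavior_a = nb[i], behavior_b = nb[j],
            animal_a = rownames(ma)[a], animal_b = rownames(mb)[b],
            r = stats::cor(va, vb, use = "complete.obs"))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Monte-Carlo power of a two-sample comparison
#'
#' Estimates the power of a two-sided unequal-variance (Welch) two-sample
#' t-test by simulation from two normal populations.
#'
#' @param n_per_group Animals per group.
#' @param mean_a,sd_a,mean_b,sd_b Group means and standard deviations (on
#'   the adult-relative scale in the developmental use case).
#' @param alpha Significance level (default 0.05).
#' @param reps Monte-Carlo replicates (>= 1000; default 10000).
#' @param seed Integer seed.
#' @return Estimated power in `[0, 1]`.
#' @export
power_at_n <- function(n_per_group, mean_a, sd_a, mean_b, sd_b,
                       alpha = 0.05, reps = 10000, seed = 1) {
  stopifnot(sd_a > 0, sd_b > 0, reps >= 1000)
  set.seed(seed)
  xa <- matrix(stats::rnorm(n_per_group * reps, mean_a, sd_a), n_per_group)
  xb <- matrix(stats::rnorm(n_per_group * reps, mean_b, sd_b), n_per_group)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  se2a <- va / n_per_group; se2b <- vb / n_per_group
  tstat <- (ma - mb) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (n_per_group - 1) + se2b^2 / (n_per_group - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  mean(p < alpha)
}
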