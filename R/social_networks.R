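# Social-state vectors on a discretized cage floor and their transition
# graphs: the cage is partitioned into a 5 x 4 grid (5 columns along the
# 57.2 cm axis, 4 rows along the 35.6 cm axis, ~11.4 x 8.9 cm cells) and a
# frame's social state is the 20-vector of per-cell animal counts.

#' Grid-cell index of positions
#'
#' Cells are half-open on their low edges; the last row/column is closed so
#' the far cage walls belong to the final cells. Row-major numbering:
#' cell = row * 5 + col + 1.
#'
#' @param xy `T x 2` positions in cm.
#' @param cage A [cage_geometry()].
#' @param ncol_grid,nrow_grid Grid shape (default 5 x 4).
#' @return Integer vector in `1..(ncol_grid*nrow_grid)`; `NA` when missing.
#' @export
grid_cell <- function(xy, cage, ncol_grid = 5, nrow_grid = 4) {
  cw <- cage$length_cm / ncol_grid
  ch <- cage$width_cm / nrow_grid
  # small epsilon so exact multiples of the cell size land in the upper cell
  col <- pmin(floor(xy[, 1] / cw + 1e-9), ncol_grid - 1)
  row <- pmin(floor(xy[, 2] / ch + 1e-9), nrow_grid - 1)
  as.integer(row * ncol_grid + col + 1L)
}

#' Per-frame social-state vectors
#'
#' For the chosen animal subset, counts animals per grid cell at every
#' frame. Missing animals are omitted, so the vector sum equals the number
#' of tracked subset animals at that frame.
#'
#' @param ts A [trackset()].
#' @param subset Animal names (default: all). The canonical subset families
#'   are singles, pairs, all pups, and all animals.
#' @param ncol_grid,nrow_grid Grid shape (default 5 x 4 = 20 states).
#' @return `T x 20` integer matrix of cell counts.
#' @export
state_sequence <- function(ts, subset = ts$animals$name,
                           ncol_grid = 5, nrow_grid = 4) {
  stopifnot(length(subset) >= 1)
  ncell <- ncol_grid * nrow_grid
  T_ <- length(ts$time_s)
  counts <- matrix(0L, T_, ncell)
  for (a in subset) {
    cell <- grid_cell(centroid_series(ts, a), ts$cage, ncol_grid, nrow_grid)
    ok <- which(!is.na(cell))
    idx <- cbind(ok, cell[ok])
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

state_keys <- function(counts) {
  apply(counts, 1, paste, collapse = ",")
}

#' Build a social-state transition graph
#'
#' Consecutive identical state vectors are collapsed; each ordered pair of
#' distinct states ever observed consecutively contributes one unweighted
#' directed edge (repeated transitions deduplicated, no self-loops). Frame
#' pairs that span recording downtime do not create edges.
#'
#' @param counts `T x 20` state matrix from [state_sequence()].
#' @param time_s Frame timestamps (to detect recording gaps); `NULL`
#'   disables gap handling.
#' @param fps Frame rate used for the gap test.
#' @param gap_tol Gap threshold in multiples of the frame period.
#' @return An [igraph::graph] (directed); vertex names are the
#'   comma-separated 20-vectors.
#' @export
build_state_graph <- function(counts, time_s = NULL, fps = 25, gap_tol = 1.5) {
  stopifnot(nrow(counts) >= 2)
  keys <- state_keys(counts)
  T_ <- length(keys)
  from <- keys[-T_]; to <- keys[-1]
  keep <- from != to
  if (!is.null(time_s))
    keep <- keep & (diff(time_s) <= gap_tol / fps)
  edges <- unique(data.frame(from = from[keep], to = to[keep],
                             stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = unique(keys)))
}

#' Metrics of a social-state graph
#'
#' `size` = number of distinct states; `n_cycles` = circuit rank of the
#' undirected simple projection (edges - nodes + components, the number of
#' independent cycles, counting no cycle twice); `transitivity` = global
#' clustering, 3 x triangles / connected triples (0 when no triples);
#' `mean_path_length` = mean shortest-path length within the largest
#' connected component of the undirected projection.
#'
#' @param g Graph from [build_state_graph()].
#' @return list(size, n_cycles, transitivity, mean_path_length).
#' @export
graph_metrics <- function(g) {
  stopifnot(igraph::vcount(g) > 0)
  u <- igraph::as_undirected(g, mode = "collapse")
  u <- igraph::simplify(u, remove.loops = TRUE, remove.multiple = TRUE)
  n <- igraph::vcount(u)
  m <- igraph::ecount(u)
  ncomp <- igraph::components(u)$no
  trans <- igraph::transitivity(u, type = "global")
  if (is.na(trans) || is.nan(trans)) trans <- 0
  comp <- igraph::components(u)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(u, which(comp$membership == big))
  mpl <- if (igraph::vcount(sub) > 1)
    igraph::mean_distance(sub, directed = FALSE) else 0
  list(size = n, n_cycles = m - n + ncomp, transitivity = trans,
       mean_path_length = mpl)
}

#' Enumerate directed simple cycles (small graphs only)
#'
#' Exhaustive count of distinct directed simple cycles, intended as an
#' alternative cycle reading for small graphs and as a cross-check.
#'
#' @param g Directed igraph.
#' @param max_nodes Refuse graphs larger than this (default 12).
#' @return Integer cycle count.
#' @export
count_directed_cycles <- function(g, max_nodes = 12) {
  n <- igraph::vcount(g)
  if (n > max_nodes) stop("graph too large for exhaustive cycle enumeration")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  count <- 0L
  # Johnson-style: only cycles whose smallest vertex is the start are counted.
  dfs <- function(start, v, visited) {
    for (w in which(adj[v, ])) {
      if (w == start) count <<- count + 1L
      else if (w > start && !visited[w]) {
        visited[w] <- TRUE
        dfs(start, w, visited)
        visited[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    dfs(s, s, visited)
  }
  count
}

#' Daily social-state network metrics for the canonical subset families
#'
#' Builds one graph per day for each requested subset (singles, pairs,
#' all pups, all animals) and tabulates the four metrics.
#'
#' @param ts A [trackset()].
#' @param subsets Named list of animal-name vectors; default: every single
#'   animal, the adult pair, all pup pairs, all pups, all animals.
#' @return data.frame(subset, pnd, size, n_cycles, transitivity,
#'   mean_path_length).
#' @export
daily_network_metrics <- function(ts, subsets = NULL) {
  if (is.null(subsets)) {
    nm <- ts$animals$name
    pups <- ts$animals$name[ts$animals$age_class == "pup"]
    adults <- ts$animals$name[ts$animals$age_class == "adult"]
    subsets <- c(
      stats::setNames(lapply(nm, identity), paste0("single_", nm)),
      list(adult_pair = adults),
      if (length(pups) >= 2) {
        pp <- utils::combn(pups, 2, simplify = FALSE)
        stats::setNames(pp, vapply(pp, paste, "", collapse = "_"))
      },
      list(all_pups = pups, all_animals = nm)
    )
  }
  fb <- split(seq_along(ts$time_s), frame_pnd(ts))
  rows <- list()
  for (sn in names(subsets)) {
    counts <- state_sequence(ts, subsets[[sn]])
    for (d in names(fb)) {
      idx <- fb[[d]]
      if (length(idx) < 2) next
      g <- build_state_graph(counts[idx, , drop = FALSE],
                             time_s = ts$time_s[idx], fps = ts$fps)
      met <- graph_metrics(g)
      rows[[length(rows) + 1]] <- data.frame(
        subset = sn, pnd = as.integer(d), size = met$size,
        n_cycles = met$n_cycles, transitivity = met$transitivity,
        mean_path_length = met$mean_path_length)
    }
  }
  do.call(rbind, rows)
}

#' Write a state graph as edge-list CSV
#'
#' @param g Graph from [build_state_graph()].
#' @param path CSV path (columns `src_state`, `dst_state`).
#' @export
write_state_graph <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.csv(data.frame(src_state = el[, 1], dst_state = el[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
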