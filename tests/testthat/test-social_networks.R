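test_that("grid cells follow the half-open convention with closed far edges", {
  cage <- cage_geometry()
  # cell widths: 57.2/5 = 11.44 cm; heights: 35.6/4 = 8.9 cm
  expect_equal(grid_cell(cbind(0, 0), cage), 1L)
  expect_equal(grid_cell(cbind(11.44, 0), cage), 2L)   # boundary -> higher cell
  expect_equal(grid_cell(cbind(0, 8.9), cage), 6L)
  expect_equal(grid_cell(cbind(57.2, 35.6), cage), 20L) # far corner stays in grid
  expect_true(is.na(grid_cell(cbind(NA, 5), cage)))
})

test_that("state vectors count present animals and conserve their number", {
  sim <- default_sim()
  ts <- sim$tracks
  idx <- 1:4000
  sub <- trackset(ts$time_s[idx], ts$pos[idx, , , drop = FALSE], ts$animals,
                  fps = ts$fps, anchor_pnd = ts$anchor_pnd, cage = ts$cage)
  counts <- state_sequence(sub)
  present <- rowSums(!is.na(sub$pos[, , 1]))
  expect_equal(rowSums(counts), present)
  expect_true(all(counts >= 0) && all(counts <= 6))
  # all animals in one cell -> a single entry equal to the subset size
  an <- animal_table(4)
  pos <- array(NA_real_, c(1, 6, 2))
  pos[1, , 1] <- 5; pos[1, , 2] <- 5
  one <- state_sequence(trackset(0, pos, an, fps = 5, anchor_pnd = 16))
  expect_equal(max(one), 6)
  expect_equal(sum(one > 0), 1)
})

test_that("state graphs collapse repeats, deduplicate edges, and skip gaps", {
  A <- c(rep(0L, 19), 1L); B <- c(rep(0L, 18), 1L, 0L)
  counts <- rbind(A, A, B, A)
  g <- build_state_graph(counts)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 2)       # A->B and B->A
  gc <- build_state_graph(rbind(A, A, A))
  expect_equal(igraph::vcount(gc), 1)
  expect_equal(igraph::ecount(gc), 0)
  # a transition spanning a recording gap does not create an edge
  g2 <- build_state_graph(rbind(A, B), time_s = c(0, 100), fps = 5)
  expect_equal(igraph::ecount(g2), 0)
  # random sequences: edge set equals a brute-force consecutive-pair scan
  set.seed(21)
  for (rep in 1:5) {
    seq_states <- sample(1:6, 300, replace = TRUE)
    counts_r <- matrix(0L, 300, 20)
    counts_r[cbind(1:300, seq_states)] <- 1L
    g3 <- build_state_graph(counts_r)
    keys <- apply(counts_r, 1, paste, collapse = ",")
    brute <- unique(data.frame(from = keys[-300], to = keys[-1]))
    brute <- brute[brute$from != brute$to, ]
    el <- igraph::as_edgelist(g3)
    expect_setequal(paste(el[, 1], el[, 2]),
                    paste(brute$from, brute$to))
  }
})

test_that("graph metrics match closed forms", {
  tri <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A)
  m <- graph_metrics(tri)
  expect_equal(m$size, 3)
  expect_equal(m$n_cycles, 1)
  expect_equal(m$transitivity, 1.0)
  path <- igraph::graph_from_literal(A -+ B, B -+ C)
  mp <- graph_metrics(path)
  expect_equal(mp$size, 3)
  expect_equal(mp$n_cycles, 0)
  expect_equal(mp$transitivity, 0)
  expect_equal(mp$mean_path_length, 4 / 3)
  # star h-a, h-b, h-c plus edge a-b: transitivity 3*1/5
  star <- igraph::graph_from_literal(h -+ a, h -+ b, h -+ c, a -+ b)
  expect_equal(graph_metrics(star)$transitivity, 0.6)
  expect_equal(count_directed_cycles(tri), 1)
  expect_equal(count_directed_cycles(path), 0)
})

test_that("metrics agree with brute-force counts on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    m_edges <- sample(n:(2 * n), 1)
    el <- cbind(sample(n, m_edges, replace = TRUE),
                sample(n, m_edges, replace = TRUE))
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    if (nrow(el) == 0) next
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    met <- graph_metrics(g)
    # brute force on the undirected simple projection
    adj <- (igraph::as_adjacency_matrix(g, sparse = FALSE) +
              t(igraph::as_adjacency_matrix(g, sparse = FALSE))) > 0
    diag(adj) <- FALSE
    nv <- nrow(adj)
    tri <- 0; triples <- 0
    for (i in 1:nv) {
      nb <- which(adj[i, ])
      k <- length(nb)
      triples <- triples + k * (k - 1) / 2
      if (k >= 2) {
        cmb <- utils::combn(nb, 2)
        tri <- tri + sum(adj[t(cmb)])
      }
    }
    expect_equal(met$transitivity, if (triples > 0) tri / triples else 0)
    ne <- sum(adj) / 2
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))$no
    expect_equal(met$n_cycles, ne - nv + comp)
    expect_equal(met$size, nv)
  }
})

test_that("cycle count and transitivity are invariant to sequence reversal", {
  set.seed(41)
  seq_states <- sample(1:8, 400, replace = TRUE)
  counts <- matrix(0L, 400, 20)
  counts[cbind(1:400, seq_states)] <- 1L
  g_f <- build_state_graph(counts)
  g_r <- build_state_graph(counts[400:1, , drop = FALSE])
  mf <- graph_metrics(g_f); mr <- graph_metrics(g_r)
  expect_equal(mf$n_cycles, mr$n_cycles)
  expect_equal(mf$transitivity, mr$transitivity)
  # adding an edge never decreases the circuit rank
  el <- igraph::as_edgelist(g_f)
  nodes <- igraph::V(g_f)$name
  extra <- setdiff(as.vector(outer(nodes, nodes, paste, sep = "->")),
                   paste(el[, 1], el[, 2], sep = "->"))
  pick <- strsplit(extra[1], "->")[[1]]
  if (pick[1] != pick[2]) {
    g_plus <- igraph::add_edges(g_f, pick)
    expect_gte(graph_metrics(g_plus)$n_cycles, mf$n_cycles)
  }
})

test_that("all-pup graph size grows along the planted developmental ramp", {
  sim <- default_sim()
  ts <- sim$tracks
  counts <- state_sequence(ts, paste0("pup", 1:4))
  fb <- split(seq_along(ts$time_s), frame_pnd(ts))
  sizes <- vapply(names(fb), function(d) {
    idx <- fb[[d]]
    graph_metrics(build_state_graph(counts[idx, , drop = FALSE],
                                    ts$time_s[idx], ts$fps))$size
  }, 0)
  expect_gt(cor(as.integer(names(sizes)), sizes, method = "spearman"), 0.8)
  met <- daily_network_metrics(ts, subsets = list(all_pups = paste0("pup", 1:4)))
  expect_equal(met$size, unname(sizes))
  expect_true(all(met$transitivity >= 0 & met$transitivity <= 1))
  expect_true(all(met$n_cycles >= 0))
})
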