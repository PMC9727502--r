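# Independent oracles used across the test suite. These never call the
# package's own MDP machinery: graph distances come from igraph on an
# independently constructed grid graph, and absorbing-chain quantities are
# hand-built from first principles.

# igraph-based shortest-path distance matrix for an empty grid with full-stop
# wall bumps (bumps never shorten paths, so plain grid adjacency suffices)
bfs_distance_matrix <- function(width, height, neighborhood) {
  n <- width * height
  moves <- list(c(-1L, 0L), c(0L, -1L), c(1L, 0L), c(0L, 1L))
  if (neighborhood == "moore")
    moves <- c(moves, list(c(-1L, -1L), c(1L, -1L), c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (s in seq_len(n) - 1L) {
    r <- s %/% width; c <- s %% width
    for (mv in moves) {
      r2 <- r + mv[1L]; c2 <- c + mv[2L]
      if (r2 >= 0L && r2 < height && c2 >= 0L && c2 < width)
        edges <- c(edges, s + 1L, r2 * width + c2 + 1L)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::distances(g)
}

# brute-force epsilon-infodesic triples directly from a distance matrix
brute_force_triples <- function(Dm, start, goal, epsilon) {
  n <- nrow(Dm)
  hits <- list()
  for (m in seq_len(n) - 1L) {
    if (m == start || m == goal) next
    nd <- (Dm[start + 1L, m + 1L] + Dm[m + 1L, goal + 1L] -
             Dm[start + 1L, goal + 1L]) / Dm[start + 1L, goal + 1L]
    if (abs(nd) < epsilon) hits[[length(hits) + 1L]] <- c(start, m, goal)
  }
  hits
}

# brute-force interim-state counts over all ordered distinct triples
brute_force_interim_counts <- function(Dm, epsilon) {
  n <- nrow(Dm)
  counts <- integer(n)
  for (s in seq_len(n)) for (m in seq_len(n)) for (g in seq_len(n)) {
    if (s == m || m == g || s == g) next
    nd <- (Dm[s, m] + Dm[m, g] - Dm[s, g]) / Dm[s, g]
    if (abs(nd) < epsilon) counts[m] <- counts[m] + 1L
  }
  counts
}

fe_defaults <- list(outer_tol = 1e-9, inner_tol = 1e-9)
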