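test_that("value geodesic test accepts exact decompositions and rejects detours", {
  Vd <- pairwise_value_distance(grid_spec(5, 5))
  # any single leg is trivially geodesic
  expect_true(value_geodesic_test(c(3, 17), Vd))
  # 0 -> 6 -> 12: both legs lie on a shortest path to the centre
  expect_true(value_geodesic_test(c(0, 6, 12), Vd))
  # corner detour 0 -> 20 -> 4: 4 + 8 > 4
  expect_false(value_geodesic_test(c(0, 20, 4), Vd))
  expect_error(value_geodesic_test(c(0, 6, 0), Vd), "repeat")
  expect_error(value_geodesic_test(7, Vd), "at least")
})

test_that("all contiguous shortest paths are geodesics; off-path detours are not", {
  skip_if_not_installed("igraph")
  spec <- grid_spec(5, 5)
  Vd <- pairwise_value_distance(spec)
  oracle <- bfs_distance_matrix(5, 5, "manhattan")
  set.seed(21)
  for (rep in 1:25) {
    s <- sample(0:24, 1); g <- sample(setdiff(0:24, s), 1)
    # build one contiguous shortest path greedily from the oracle
    path <- s
    cur <- s
    while (cur != g) {
      nbrs <- which(oracle[cur + 1L, ] == 1) - 1L
      cur <- nbrs[which.min(oracle[nbrs + 1L, g + 1L])]
      path <- c(path, cur)
    }
    expect_true(value_geodesic_test(path, Vd))
    # inserting a state strictly off every shortest path breaks it
    off <- setdiff(0:24, c(path, which(oracle[s + 1L, ] + oracle[, g + 1L] ==
                                         oracle[s + 1L, g + 1L]) - 1L))
    if (length(off) > 0)
      expect_false(value_geodesic_test(c(s, off[1], g), Vd))
  }
})

test_that("chained free energy is consistent for trivial routes", {
  spec <- grid_spec(4, 4)
  route <- chain_free_energy(spec, beta = 100, c(0, 15))
  expect_equal(route$chained_F, route$direct_F)
  expect_equal(route$normalized_diff, 0)
  route2 <- chain_free_energy(spec, beta = 100, c(0, 5, 15))
  expect_true(all(route2$segment_F >= 0))
  expect_gte(route2$chained_F, max(route2$segment_F))
})

test_that("normalized differences are non-negative in the shortest-path regime", {
  spec <- grid_spec(4, 4)
  D <- pairwise_free_energy(spec, beta = 1e7)
  set.seed(33)
  for (rep in 1:40) {
    states <- sample(0:15, sample(3:5, 1))
    expect_gte(normalized_difference(spec, 1e7, states, D = D), -1e-6)
  }
})

test_that("epsilon-infodesic search matches the brute-force oracle", {
  spec <- grid_spec(3, 3)
  D <- pairwise_free_energy(spec, beta = 1e7)
  # exact triangle equalities at near-zero epsilon
  routes <- epsilon_infodesic_search(spec, 1e7, start = 0, goal = 8,
                                     max_len = 3, epsilon = 1e-9, D = D)
  oracle <- brute_force_triples(D$D, 0, 8, 1e-9)
  got <- lapply(routes, function(r) r$states)
  expect_setequal(lapply(got, paste, collapse = "-"),
                  lapply(oracle, paste, collapse = "-"))
  # a 5x5 grid at a moderate band
  spec5 <- grid_spec(5, 5)
  D5 <- pairwise_free_energy(spec5, beta = 100)
  routes5 <- epsilon_infodesic_search(spec5, 100, start = 0, goal = 24,
                                      max_len = 3, epsilon = 0.02, D = D5)
  oracle5 <- brute_force_triples(D5$D, 0, 24, 0.02)
  expect_setequal(lapply(routes5, function(r) paste(r$states, collapse = "-")),
                  lapply(oracle5, paste, collapse = "-"))
  # epsilon = Inf returns every candidate sequence
  all3 <- epsilon_infodesic_search(spec, 1e7, 0, 8, max_len = 3,
                                   epsilon = Inf, D = D)
  expect_length(all3, 7)
  # results come sorted by |normalized difference|
  nd <- vapply(all3, function(r) abs(r$normalized_diff), numeric(1))
  expect_true(!is.unsorted(nd))
})

test_that("interim histogram equals brute-force counts and respects trivial bands", {
  spec <- grid_spec(3, 3)
  D <- pairwise_free_energy(spec, beta = 1e7)
  h <- interim_histogram(spec, 1e7, epsilon = 1e-9, D = D)
  expect_identical(unname(h$counts), brute_force_interim_counts(D$D, 1e-9))
  expect_identical(h$total, sum(h$counts))
  h0 <- interim_histogram(spec, 1e7, epsilon = 0, D = D)
  expect_identical(sum(h0$counts), 0L)
})

test_that("trajectory sampling is exact for deterministic policies and matches visit predictions", {
  m <- build_gridworld(grid_spec(3, 1), goals = 2)
  probs <- matrix(0, 3, 4, dimnames = list(NULL, m$actions$action))
  probs[, "right"] <- 1
  ts <- sample_trajectories(m, new_policy(probs), start = 0, n_episodes = 50, seed = 4)
  expect_equal(unname(ts$proportion), c(1, 1, 1))
  # stochastic policy: visit proportions correlate with fundamental-matrix visits
  m5 <- build_gridworld(grid_spec(5, 5), goals = 12)
  sol <- free_energy_solve(m5, beta = 1)
  ts5 <- sample_trajectories(m5, sol$policy, start = 24, n_episodes = 10000, seed = 8)
  tr <- m5$transient
  Tm <- matrix(0, 25, 25)
  pol <- unclass(sol$policy)
  for (a in seq_len(4)) Tm <- Tm + pol[, a] * as.matrix(m5$P[[a]])
  N <- solve(diag(24) - Tm[tr, tr])
  visits <- numeric(25); visits[tr] <- N[which(tr == 25), ]
  expect_gt(cor(ts5$proportion[tr], visits[tr], method = "spearman"), 0.9)
})

test_that("sequence validation rejects malformed routes", {
  spec <- grid_spec(3, 3)
  expect_error(chain_free_energy(spec, 100, c(0, 9)), "out of range")
  expect_error(normalized_difference(spec, 100, c(4, 4)), "differ|repeat")
  expect_error(epsilon_infodesic_search(spec, 100, 0, 8, max_len = 6), "3, 4 or 5")
})
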