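test_that("value iteration recovers exact step distances and uniform ties", {
  m <- build_gridworld(grid_spec(5, 5), goals = 12)
  vs <- value_iteration(m)
  expect_equal(-vs$V[25], 4)          # corner 24 -> centre
  expect_equal(vs$V[13], 0)           # absorbing goal
  m7 <- build_gridworld(grid_spec(7, 7, "moore"), goals = 6)
  expect_equal(-value_iteration(m7)$V[43], 6)  # state 42, Chebyshev distance
  # co-optimal actions share mass equally: corner 24 can go up or left
  expect_equal(unname(vs$policy[25, "up"]), 0.5)
  expect_equal(unname(vs$policy[25, "left"]), 0.5)
  expect_equal(sum(vs$policy[25, ]), 1)
})

test_that("live distribution matches hand-computed fundamental-matrix results on a 1x3 chain", {
  m <- build_gridworld(grid_spec(3, 1), goals = 2)
  probs <- matrix(0, 3, 4, dimnames = list(NULL, m$actions$action))
  probs[, "right"] <- 1
  pol <- new_policy(probs)
  # start at 0: profile (1/2, 1/2); start at 1: (0, 1); average (1/4, 3/4)
  expect_equal(live_distribution(m, pol), c(1, 3, 0) / 4)
  # pooled expected visits: state 0 visited 0.5 times, state 1 visited 1.0
  expect_equal(live_distribution(m, pol, method = "expected-visits"), c(1, 2, 0) / 3)
  expect_equal(sum(live_distribution(m, pol)), 1)
})

test_that("action prior is the live-weighted policy marginal", {
  m <- build_gridworld(grid_spec(3, 1), goals = 2)
  pol <- uniform_policy(m)
  live <- live_distribution(m, pol)
  expect_equal(unname(action_prior(pol, live)), rep(0.25, 4))
  det <- matrix(0, 3, 4, dimnames = list(NULL, m$actions$action))
  det[, "right"] <- 1
  pr <- action_prior(new_policy(det), live_distribution(m, new_policy(det)))
  expect_equal(unname(pr), c(0, 0, 0, 1))
})

test_that("decision information is zero when the policy equals the prior", {
  m <- build_gridworld(grid_spec(5, 5), goals = 12)
  pol <- uniform_policy(m)
  info <- decision_information(m, pol, rep(0.25, 4))
  expect_equal(info, numeric(25))
})

test_that("policy evaluation of free energy matches hand computation on a 1x3 chain", {
  m <- build_gridworld(grid_spec(3, 1), goals = 2)
  probs <- matrix(0, 3, 4, dimnames = list(NULL, m$actions$action))
  probs[, "right"] <- 1
  pol <- new_policy(probs)
  # 2 steps from state 0, each charging log2(1/0.25) = 2 bits at beta = 1
  Fv <- evaluate_free_energy(m, pol, rep(0.25, 4), beta = 1)
  expect_equal(Fv[1], 6)
  expect_equal(Fv[2], 3)
  expect_equal(Fv[3], 0)
})

test_that("free-energy solve satisfies its contract at beta = 100", {
  m <- build_gridworld(grid_spec(5, 5), goals = 12)
  sol <- free_energy_solve(m, beta = 100)
  expect_true(sol$diagnostics$converged)
  expect_true(all(sol$F >= 0))
  expect_equal(sol$F[13], 0)
  expect_true(all(sol$decision_info >= -1e-12))
  expect_equal(sol$decision_info[13], 0)
  expect_equal(sum(sol$prior), 1)
  expect_equal(sum(sol$live), 1)
  expect_equal(sol$live[13], 0)
  expect_error(free_energy_solve(m, beta = 0), "strictly positive")
  # fixed-point consistency: evaluating the converged policy reproduces F
  Fv <- evaluate_free_energy(m, sol$policy, sol$prior, beta = 100)
  expect_equal(Fv, sol$F, tolerance = 1e-6)
})

test_that("large beta recovers shortest-path distances on both neighbourhoods", {
  skip_if_not_installed("igraph")
  for (nb in c("manhattan", "moore")) {
    spec <- grid_spec(5, 5, nb)
    oracle <- bfs_distance_matrix(5, 5, nb)
    for (g in c(0L, 12L)) {
      sol <- free_energy_solve(build_gridworld(spec, g), beta = 1e7)
      expect_lt(max(abs(sol$F - oracle[, g + 1L])), 1e-3)
      # the information term vanishes: F equals -V under the greedy policy
      vs <- value_iteration(build_gridworld(spec, g))
      Fv <- evaluate_free_energy(build_gridworld(spec, g), vs$policy,
                                 action_prior(vs$policy,
                                              live_distribution(build_gridworld(spec, g), vs$policy)),
                                 beta = 1e12)
      expect_equal(Fv, -vs$V, tolerance = 1e-9)
    }
  }
})

test_that("small beta drives the policy towards the marginal action distribution", {
  m <- build_gridworld(grid_spec(5, 5), goals = 12)
  sol <- free_energy_solve(m, beta = 1e-3)
  dev <- abs(unclass(sol$policy) - rep(sol$prior, each = 25))
  expect_lt(max(dev[m$transient, ]), 0.05)
})

test_that("free energy descends by at least one unit per expected step", {
  for (case in list(list(grid_spec(5, 5), 12, 100),
                    list(grid_spec(7, 7, "moore"), 6, 100),
                    list(grid_spec(5, 5), 18, 0.5))) {
    m <- build_gridworld(case[[1]], case[[2]])
    sol <- free_energy_solve(m, case[[3]])
    EF <- matrix(as.numeric(m$P_stack %*% sol$F), m$n_states, m$n_actions)
    drop_per_state <- sol$F - rowSums(unclass(sol$policy) * EF)
    expect_true(all(drop_per_state[m$transient] >= 1 - 1e-9))
  }
})

test_that("Monte-Carlo rollouts reproduce the linear-solve decision information", {
  m <- build_gridworld(grid_spec(5, 5), goals = 12)
  sol <- free_energy_solve(m, beta = 100)
  mc <- mc_decision_information(m, sol$policy, sol$prior, start = 24,
                                n_episodes = 10000, seed = 99)
  expect_identical(mc$n_capped, 0L)
  expect_lt(abs(mc$mean - sol$decision_info[25]), 3 * max(mc$se, 1e-12))
})

test_that("negative optimal value is a quasi-metric (exhaustive audit)", {
  for (nb in c("manhattan", "moore")) {
    spec <- grid_spec(5, 5, nb)
    rep <- quasimetric_audit(pairwise_value_distance(spec))
    expect_true(rep$d1); expect_true(rep$d2); expect_true(rep$d3)
    expect_identical(rep$n_violations, 0L)
  }
})
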