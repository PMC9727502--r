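#' All-pairs shortest-path distance matrix from the value function
#'
#' Runs [value_iteration()] once per goal and collects `-V*` columns:
#' entry `(i, j)` is the number of steps on a shortest path from state `i`
#' to state `j`. On empty grids this equals the Manhattan (4-action) or
#' Chebyshev (8-action) distance between the cells.
#'
#' @param spec A [grid_spec()].
#' @return A square numeric matrix with 0-based state-index dimnames.
#' @export
pairwise_value_distance <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- spec$n_states
  D <- matrix(0, n, n, dimnames = list(seq_len(n) - 1L, seq_len(n) - 1L))
  for (g in seq_len(n) - 1L) {
    vs <- value_iteration(build_gridworld(spec, g))
    D[, g + 1L] <- -vs$V
  }
  D
}

check_sequence <- function(states, n_states) {
  states <- as.integer(states)
  if (length(states) < 2L) stop("a state sequence needs at least start and goal", call. = FALSE)
  if (anyDuplicated(states)) stop("state sequence must not repeat states", call. = FALSE)
  if (any(states < 0L | states >= n_states)) stop("state index out of range", call. = FALSE)
  states
}

#' Test whether a state sequence is a value geodesic
#'
#' A sequence `s_0, ..., s_N` is a value geodesic when its leg distances
#' under the shortest-path quasi-metric sum exactly to the direct
#' distance, so every interim state is visited at optimal cost from the
#' start. On deterministic grids the distances are integers and the test
#' is exact.
#'
#' @param states Ordered 0-based state indices (start ... goal), no repeats.
#' @param Vstar_matrix All-pairs `-V*` matrix from
#'   [pairwise_value_distance()].
#' @param tol Numeric slack for the equality.
#' @return `TRUE` iff the summed leg distances equal the direct distance.
#' @export
#' @examples
#' Vd <- pairwise_value_distance(grid_spec(5, 5))
#' value_geodesic_test(c(0, 6, 12), Vd)   # TRUE: both legs on a shortest path
#' value_geodesic_test(c(0, 20, 4), Vd)   # FALSE: corner detour
value_geodesic_test <- function(states, Vstar_matrix, tol = 1e-9) {
  states <- check_sequence(states, nrow(Vstar_matrix))
  i <- states[-length(states)] + 1L
  j <- states[-1L] + 1L
  legs <- sum(Vstar_matrix[cbind(i, j)])
  direct <- Vstar_matrix[states[1L] + 1L, states[length(states)] + 1L]
  abs(legs - direct) <= tol
}

# legs and direct free energies for a route, solving only the goals needed
# (or reading them from a precomputed all-pairs matrix)
route_free_energies <- function(spec, beta, states, D = NULL, ...) {
  states <- check_sequence(states, spec$n_states)
  legs_from <- states[-length(states)]
  legs_to <- states[-1L]
  if (!is.null(D)) {
    Dm <- if (inherits(D, "fe_distance")) D$D else as.matrix(D)
    if (inherits(D, "fe_distance") && D$symmetrized)
      stop("route free energies need the raw (directed) matrix, not the symmetrized one",
           call. = FALSE)
    cols <- match(as.character(legs_to), colnames(Dm))
    if (anyNA(cols)) stop("distance matrix lacks a required goal column", call. = FALSE)
    segment_F <- Dm[cbind(legs_from + 1L, cols)]
    direct_F <- Dm[states[1L] + 1L, match(as.character(states[length(states)]), colnames(Dm))]
  } else {
    sols <- lapply(unique(legs_to), function(g)
      free_energy_solve(build_gridworld(spec, g), beta, ...))
    names(sols) <- unique(legs_to)
    segment_F <- vapply(seq_along(legs_to), function(k)
      sols[[as.character(legs_to[k])]]$F[legs_from[k] + 1L], numeric(1))
    direct_F <- sols[[as.character(states[length(states)])]]$F[states[1L] + 1L]
  }
  list(states = states, segment_F = segment_F, direct_F = direct_F)
}

#' Chain per-segment optimal policies along a subgoal sequence
#'
#' Scores a route `s_0 -> s_1 -> ... -> s_T` where each leg is travelled
#' under its own free-energy-optimal policy (one solve per distinct leg
#' goal), and compares the summed per-segment free energies with the
#' direct free energy of going `s_0 -> s_T` under a single policy. At
#' small `beta` the chained cost can undercut the direct one — a triangle
#' inequality violation impossible for the value quasi-metric.
#'
#' @param spec A [grid_spec()].
#' @param beta Strictly positive trade-off parameter.
#' @param states Ordered 0-based state indices (start ... goal), no repeats.
#' @param D Optional precomputed raw [pairwise_free_energy()] matrix for
#'   this `beta`; legs are then read off instead of re-solved.
#' @param ... Passed to [free_energy_solve()].
#'
#' @return An object of class `segmented_route`: `states`, `segment_F`
#'   (per-leg free energies), `chained_F` (their sum), `direct_F`,
#'   `normalized_diff` = `(sum(segment_F) - direct_F) / direct_F`
#'   (negative when segmentation is cheaper), and `beta`.
#' @export
#' @examples
#' \donttest{
#' chain_free_energy(grid_spec(7, 7, "moore"), beta = 100, c(0, 12, 6))
#' }
chain_free_energy <- function(spec, beta, states, D = NULL, ...) {
  r <- route_free_energies(spec, beta, states, D = D, ...)
  structure(
    list(states = r$states, segment_F = r$segment_F,
         chained_F = sum(r$segment_F), direct_F = r$direct_F,
         normalized_diff = (sum(r$segment_F) - r$direct_F) / r$direct_F,
         beta = beta),
    class = "segmented_route"
  )
}

#' @export
print.segmented_route <- function(x, ...) {
  cat(sprintf("<segmented_route> <%s> beta=%g: legs %s = %.4g vs direct %.4g (normalized diff %+.4g)\n",
              paste(x$states, collapse = ", "), x$beta,
              paste(sprintf("%.4g", x$segment_F), collapse = " + "),
              x$chained_F, x$direct_F, x$normalized_diff))
  invisible(x)
}

#' Normalized free-energy difference of a segmented route
#'
#' `(sum of per-segment optimal free energies - direct free energy) /
#' direct free energy`; negative when splitting the route at the interim
#' states is cheaper than the single direct policy. A route whose
#' magnitude stays within `epsilon` is an epsilon-infodesic.
#'
#' @inheritParams chain_free_energy
#' @return A single number.
#' @export
normalized_difference <- function(spec, beta, states, D = NULL, ...) {
  if (states[1L] == states[length(states)])
    stop("start and goal must differ", call. = FALSE)
  chain_free_energy(spec, beta, states, D = D, ...)$normalized_diff
}

#' Exhaustive search for epsilon-infodesics between fixed endpoints
#'
#' Enumerates every non-repeating state sequence of length 3 up to
#' `max_len` between `start` and `goal`, scores each from the all-pairs
#' free-energy matrix (every leg under its own optimal policy), and
#' returns the sequences whose normalized free-energy difference lies in
#' the band `(-epsilon, epsilon)`, sorted by magnitude.
#'
#' @inheritParams chain_free_energy
#' @param start,goal 0-based endpoint states.
#' @param max_len Maximum sequence length including the endpoints (3-5).
#' @param epsilon Relaxation band of the triangle equality.
#' @param D Optional precomputed raw [pairwise_free_energy()] for `beta`;
#'   computed once here if missing.
#' @param budget Cap on the number of candidate sequences enumerated.
#' @return List of [chain_free_energy()] `segmented_route` objects sorted
#'   by `abs(normalized_diff)`.
#' @export
epsilon_infodesic_search <- function(spec, beta, start, goal, max_len = 3L,
                                     epsilon = 0.05, D = NULL,
                                     budget = 5e6, ...) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!max_len %in% 3:5) stop("`max_len` must be 3, 4 or 5", call. = FALSE)
  n <- spec$n_states
  check_sequence(c(start, goal), n)
  if (is.null(D)) D <- pairwise_free_energy(spec, beta, ...)
  Dm <- if (inherits(D, "fe_distance")) D$D else as.matrix(D)

  interior <- setdiff(seq_len(n) - 1L, c(start, goal))
  n_cand <- sum(vapply(3:max_len, function(L)
    prod(length(interior) - seq_len(L - 2L) + 1L), numeric(1)))
  if (n_cand > budget)
    stop(sprintf("infodesic search would enumerate %.3g sequences (budget %.3g); reduce max_len",
                 n_cand, budget), call. = FALSE)

  direct_F <- Dm[start + 1L, goal + 1L]
  routes <- list()
  for (L in 3:max_len) {
    k <- L - 2L
    mids <- as.matrix(do.call(expand.grid, rep(list(interior), k)))
    if (k > 1L) {
      keep <- rowSums(vapply(seq_len(k - 1L), function(a)
        rowSums(mids[, a, drop = FALSE] == mids[, (a + 1L):k, drop = FALSE]) > 0,
        logical(nrow(mids)))) == 0
      mids <- mids[keep, , drop = FALSE]
    }
    if (nrow(mids) == 0L) next
    seqs <- cbind(start, mids, goal)
    legsum <- numeric(nrow(seqs))
    for (leg in seq_len(L - 1L))
      legsum <- legsum + Dm[cbind(seqs[, leg] + 1L, seqs[, leg + 1L] + 1L)]
    nd <- (legsum - direct_F) / direct_F
    hit <- which(abs(nd) < epsilon)
    for (h in hit) {
      st <- as.integer(seqs[h, ])
      seg <- Dm[cbind(st[-L] + 1L, st[-1L] + 1L)]
      routes[[length(routes) + 1L]] <- structure(
        list(states = st, segment_F = seg, chained_F = sum(seg),
             direct_F = direct_F, normalized_diff = nd[h], beta = beta),
        class = "segmented_route")
    }
  }
  routes[order(vapply(routes, function(r) abs(r$normalized_diff), numeric(1)))]
}

#' Interim-state histogram over three-state epsilon-infodesics
#'
#' For every ordered triple of distinct states `(s, m, g)`, checks whether
#' `<s, m, g>` is an epsilon-infodesic (normalized free-energy difference
#' within the band), and counts for each state `m` how often it serves as
#' the interim state. At small `beta`, corner and edge states dominate:
#' they are the informationally cheap waypoints of the distorted geometry.
#'
#' @inheritParams epsilon_infodesic_search
#' @return An object of class `interim_histogram`: integer `counts` (one
#'   per state), `epsilon`, `beta`, and the total number of qualifying
#'   triples.
#' @export
interim_histogram <- function(spec, beta, epsilon = 0.05, D = NULL, ...) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(D)) D <- pairwise_free_energy(spec, beta, ...)
  Dm <- if (inherits(D, "fe_distance")) D$D else as.matrix(D)
  n <- nrow(Dm)
  counts <- integer(n)
  for (m in seq_len(n)) {
    two_leg <- outer(Dm[, m], Dm[m, ], "+")
    nd <- (two_leg - Dm) / Dm
    nd[!is.finite(nd)] <- Inf
    nd[m, ] <- Inf; nd[, m] <- Inf          # s, g distinct from m
    diag(nd) <- Inf                          # s distinct from g
    counts[m] <- sum(abs(nd) < epsilon)
  }
  names(counts) <- seq_len(n) - 1L
  structure(list(counts = counts, epsilon = epsilon, beta = beta,
                 total = sum(counts)),
            class = "interim_histogram")
}

#' @export
print.interim_histogram <- function(x, ...) {
  cat(sprintf("<interim_histogram> beta=%g, epsilon=%g: %d qualifying triples; top states: %s\n",
              x$beta, x$epsilon, x$total,
              paste(names(sort(x$counts, decreasing = TRUE))[1:4], collapse = ", ")))
  invisible(x)
}

#' Sample trajectories and report per-state visit proportions
#'
#' Simulates episodes from a fixed start under a policy until absorption
#' (capped at `max_steps`), and reports for each state the fraction of
#' episodes that visit it at least once.
#'
#' @param mdp A [build_gridworld()] MDP.
#' @param policy A [new_policy()].
#' @param start 0-based start state.
#' @param n_episodes Number of episodes.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param max_steps Per-episode step cap; episodes still unabsorbed are
#'   counted in `n_capped` and a warning is recorded when more than 1%
#'   are cut off.
#' @return An object of class `trajectory_sample`: `proportion` (per-state
#'   visit fraction), `n_episodes`, `n_capped`, `warnings`.
#' @export
sample_trajectories <- function(mdp, policy, start, n_episodes = 10000L,
                                seed, max_steps = 1e5) {
  stopifnot(inherits(mdp, "tabular_mdp"), n_episodes >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  n <- mdp$n_states
  pol <- unclass(policy)
  cum <- t(apply(pol, 1L, cumsum))
  goalset <- mdp$goals + 1L
  cur <- rep(sidx(start), n_episodes)
  visited <- matrix(FALSE, n_episodes, n)
  visited[, sidx(start)] <- TRUE
  active <- !(cur %in% goalset)
  step <- 0L
  while (any(active) && step < max_steps) {
    idx <- which(active)
    u <- stats::runif(length(idx))
    a <- rowSums(u > cum[cur[idx], , drop = FALSE]) + 1L
    nxt <- mdp$succ[cbind(cur[idx], a)]
    cur[idx] <- nxt
    visited[cbind(idx, nxt)] <- TRUE
    active[idx] <- !(nxt %in% goalset)
    step <- step + 1L
  }
  n_capped <- sum(active)
  warnings <- character(0)
  if (n_capped > 0.01 * n_episodes)
    warnings <- sprintf("%d of %d episodes hit the %g-step cap before absorption",
                        n_capped, n_episodes, max_steps)
  prop <- colMeans(visited)
  names(prop) <- seq_len(n) - 1L
  structure(list(proportion = prop, n_episodes = as.integer(n_episodes),
                 n_capped = as.integer(n_capped), warnings = warnings,
                 start = as.integer(start), seed = as.integer(seed)),
            class = "trajectory_sample")
}

#' Monte-Carlo estimate of decision information
#'
#' Estimates the decision information at a start state as the empirical
#' mean, over sampled absorbing rollouts, of the cumulative per-step
#' information cost `log2(pi(a|s) / prior(a))`. Serves as an independent
#' stochastic cross-check of the exact linear-solve value returned by
#' [decision_information()].
#'
#' @inheritParams sample_trajectories
#' @param prior Action prior used for the information charge.
#' @return List with `mean`, `se` (standard error), `n_episodes`,
#'   `n_capped`.
#' @export
mc_decision_information <- function(mdp, policy, prior, start,
                                    n_episodes = 10000L, seed, max_steps = 1e5) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  pol <- unclass(policy)
  cum <- t(apply(pol, 1L, cumsum))
  lratio <- log2(pmax(pol, 1e-300)) - rep(log2(pmax(prior, 1e-300)), each = nrow(pol))
  goalset <- mdp$goals + 1L
  cur <- rep(sidx(start), n_episodes)
  cost <- numeric(n_episodes)
  active <- !(cur %in% goalset)
  step <- 0L
  while (any(active) && step < max_steps) {
    idx <- which(active)
    u <- stats::runif(length(idx))
    a <- rowSums(u > cum[cur[idx], , drop = FALSE]) + 1L
    cost[idx] <- cost[idx] + lratio[cbind(cur[idx], a)]
    nxt <- mdp$succ[cbind(cur[idx], a)]
    cur[idx] <- nxt
    active[idx] <- !(nxt %in% goalset)
    step <- step + 1L
  }
  list(mean = mean(cost), se = stats::sd(cost) / sqrt(n_episodes),
       n_episodes = as.integer(n_episodes), n_capped = sum(active))
}
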