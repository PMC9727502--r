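#' Construct a policy object
#'
#' A policy is a per-state probability distribution over actions,
#' `probs[s, a]` = probability of taking action `a` in state `s` (rows are
#' states in index order, 0-based state `s` in row `s + 1`).
#'
#' @param probs Numeric matrix, one row per state, one column per action;
#'   rows must be non-negative and sum to 1.
#' @return An object of class `policy` (the validated matrix).
#' @export
new_policy <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < -1e-12)) stop("policy probabilities must be non-negative", call. = FALSE)
  if (max(abs(rowSums(probs) - 1)) > 1e-8)
    stop("each state's action distribution must sum to 1", call. = FALSE)
  structure(probs, class = c("policy", "matrix"))
}

#' @export
print.policy <- function(x, ...) {
  cat(sprintf("<policy> %d states x %d actions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Uniform policy over the action set
#'
#' @param mdp A [build_gridworld()] MDP.
#' @return A [new_policy()] assigning equal mass to every action in every
#'   state.
#' @export
uniform_policy <- function(mdp) {
  new_policy(matrix(1 / mdp$n_actions, mdp$n_states, mdp$n_actions,
                    dimnames = list(NULL, mdp$actions$action)))
}

# E[f(S') | s, a] for all (s, a) at once: (n x n_actions) matrix
expect_successor <- function(mdp, f) {
  matrix(as.numeric(mdp$P_stack %*% f), mdp$n_states, mdp$n_actions)
}

# row-wise maximum of a small matrix without apply() overhead
row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# dense state-to-state transition matrix under a policy; deterministic MDPs
# scatter policy mass straight onto the successor table
policy_transition <- function(mdp, policy) {
  n <- mdp$n_states
  Tm <- matrix(0, n, n)
  if (isTRUE(mdp$deterministic)) {
    for (a in seq_len(mdp$n_actions)) {
      idx <- cbind(seq_len(n), mdp$succ[, a])
      Tm[idx] <- Tm[idx] + policy[, a]
    }
  } else {
    for (a in seq_len(mdp$n_actions))
      Tm <- Tm + policy[, a] * as.matrix(mdp$P[[a]])
  }
  Tm
}

#' Optimal value function by value iteration
#'
#' Solves the undiscounted Bellman optimality equation for a cost-only MDP.
#' Because every transient step costs one, the negative optimal value
#' `-V*(s)` is the graph distance (number of steps) from `s` to the nearest
#' goal. The returned greedy policy spreads probability uniformly over all
#' co-optimal actions.
#'
#' @param mdp A [build_gridworld()] MDP.
#' @param tol Convergence threshold on the sup-norm value change.
#' @param max_iter Iteration cap.
#'
#' @return An object of class `value_solution`: `V` (per-state value, <= 0),
#'   `policy` (uniform over argmax actions), `iterations`.
#' @export
#' @examples
#' m <- build_gridworld(grid_spec(5, 5), goals = 12)
#' vs <- value_iteration(m)
#' -vs$V[25]  # state 24: Manhattan distance corner -> centre is 4
value_iteration <- function(mdp, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(mdp, "tabular_mdp"), tol > 0)
  n <- mdp$n_states
  V <- numeric(n)
  gl <- mdp$goals + 1L
  for (it in seq_len(max_iter)) {
    Q <- mdp$reward + expect_successor(mdp, V)
    Vnew <- row_max(Q)
    Vnew[gl] <- 0
    resid <- max(abs(Vnew - V))
    V <- Vnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("value iteration did not converge in %d iterations (residual %.3g)",
                 max_iter, resid), call. = FALSE)
  Q <- mdp$reward + expect_successor(mdp, V)
  best <- Q >= row_max(Q) - 1e-9
  probs <- best / rowSums(best)
  colnames(probs) <- mdp$actions$action
  structure(list(V = V, policy = new_policy(probs), iterations = it),
            class = "value_solution")
}

#' Live (visitation) state distribution of an absorbing chain
#'
#' The live distribution is the probability of finding the agent at a given
#' transient state at a random time while its policy is still running, for
#' a trajectory started uniformly over the transient states. Both variants
#' are built from the absorbing-chain fundamental matrix
#' `N = (I - T)^-1`, where `T` is the transient-to-transient transition
#' matrix under the policy and `N[i, j]` the expected number of visits to
#' `j` for a trajectory started at `i`. Goal states carry zero mass.
#'
#' With `method = "time-fraction"` (the default) each start's visit profile
#' is first normalized by that trajectory's own expected duration
#' (`N[i, ] / sum(N[i, ])`, the expected fraction of its lifetime the
#' chain spends in each state) and the profiles are then averaged over the
#' uniform start: a random start followed by a random time within that run.
#' With `method = "expected-visits"` raw expected visit counts are pooled
#' across starts (`u' N`) and normalized, which weights long-lived starts
#' more heavily.
#'
#' @param mdp A [build_gridworld()] MDP.
#' @param policy A [new_policy()] under which the chain is absorbing.
#' @param method Visit aggregation across starting states; see Details.
#'
#' @return Numeric vector over all states summing to 1, zero at goals.
#' @export
live_distribution <- function(mdp, policy,
                              method = c("time-fraction", "expected-visits")) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  method <- match.arg(method)
  tr <- mdp$transient
  n_tr <- length(tr)
  if (n_tr == 0L) return(numeric(mdp$n_states))
  Tm <- policy_transition(mdp, policy)[tr, tr, drop = FALSE]
  xi <- tryCatch({
    if (method == "time-fraction") {
      N <- solve(diag(n_tr) - Tm)
      colMeans(N / rowSums(N))
    } else {
      solve(diag(n_tr) - t(Tm), rep(1 / n_tr, n_tr))
    }
  }, error = function(e) stop("live distribution: absorbing-chain system is singular ",
                              "(policy may not reach the goal set): ", conditionMessage(e),
                              call. = FALSE))
  if (any(!is.finite(xi)) || any(xi < -1e-8))
    stop("live distribution: absorption time numerically unbounded for this policy",
         call. = FALSE)
  out <- numeric(mdp$n_states)
  out[tr] <- pmax(xi, 0) / sum(pmax(xi, 0))
  out
}

#' Marginal action prior under the live distribution
#'
#' The action prior is the policy marginalized over the live state
#' distribution: `p(a) = sum_s pi(a|s) p_live(s)`. It is the "default"
#' action distribution against which per-state decisions are
#' informationally charged.
#'
#' @param policy A [new_policy()].
#' @param live Live state distribution (zero at goals, sums to 1).
#' @return Named numeric action distribution summing to 1.
#' @export
action_prior <- function(policy, live) {
  if (abs(sum(live) - 1) > 1e-8) stop("`live` must sum to 1", call. = FALSE)
  pr <- as.numeric(crossprod(unclass(policy), live))
  names(pr) <- colnames(policy)
  pr
}

#' Decision information per state
#'
#' Decision information is the expected cumulative Kullback-Leibler
#' divergence (in bits) between the per-state policy and the fixed marginal
#' action prior, accumulated over the remaining trajectory until
#' absorption. It satisfies the linear fixed point
#' `I(s) = sum_a pi(a|s) log2(pi(a|s)/p(a)) + sum_s' P_pi(s'|s) I(s')`
#' with `I(g) = 0` at goals, solved here exactly over the transient states.
#'
#' @param mdp A [build_gridworld()] MDP.
#' @param policy A [new_policy()].
#' @param prior Action distribution; must be positive wherever the policy is.
#' @param log_base Base of the logarithm (2 for bits, the default, or
#'   `exp(1)` for nats).
#' @return Numeric vector of per-state information costs, zero at goals.
#' @export
decision_information <- function(mdp, policy, prior, log_base = 2) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  pol <- unclass(policy)
  bad <- pol > 1e-15 & rep(prior, each = nrow(pol)) <= 0
  if (any(bad[mdp$transient, ]))   # goal-state action choice never matters
    stop("policy has support where the prior is zero: divergence undefined",
         call. = FALSE)
  lp <- log(pmax(rep(prior, each = nrow(pol)), 1e-300))
  term <- pol * (log(pmax(pol, 1e-300)) - lp)
  term[pol <= 0] <- 0  # 0 * log 0 := 0
  cost <- rowSums(term) / log(log_base)
  tr <- mdp$transient
  out <- numeric(mdp$n_states)
  if (length(tr) > 0L) {
    Tm <- policy_transition(mdp, policy)[tr, tr, drop = FALSE]
    out[tr] <- solve(diag(length(tr)) - Tm, cost[tr])
  }
  out
}

#' Free-energy-optimal policy by double Bellman/Blahut-Arimoto iteration
#'
#' Minimizes the free energy `F(s) = (1/beta) I_D(s) - V(s)` over policies,
#' where `I_D` is the decision information relative to the live-distribution
#' action prior and `-V` the expected number of steps to the goal. The
#' trade-off parameter `beta` weights path cost against information
#' processing: large `beta` recovers shortest-path behaviour, small `beta`
#' drives the policy towards a state-independent (open-loop) action
#' distribution.
#'
#' The solver alternates two loops. The inner loop, for a fixed prior
#' `p(a)`, iterates the soft Bellman recursion
#' `F(s) = -(1/beta) log_b sum_a p(a) b^(beta * Q(s,a))` with
#' `Q(s,a) = E[r - F(S') | s, a]` and the Boltzmann policy
#' `pi(a|s) propto p(a) b^(beta Q(s,a))` (log-sum-exp shifted against
#' overflow) until `F` is stationary. The outer loop then recomputes the
#' live distribution and the marginal prior from the current policy and
#' repeats until the prior is stationary.
#'
#' @param mdp A [build_gridworld()] MDP.
#' @param beta Strictly positive trade-off parameter.
#' @param log_base Base used for information terms inside the objective
#'   (2 = bits, the default; information is traded against step costs, so
#'   the base changes `F` at a given `beta`).
#' @param inner_tol,outer_tol Sup-norm convergence thresholds for the inner
#'   free-energy loop and the outer prior loop.
#' @param max_inner,max_outer Iteration caps.
#' @param damping Optional prior damping in `[0, 1)`: the new prior is
#'   `(1 - damping) * updated + damping * previous`. 0 (undamped) by default.
#'
#' @return An object of class `fe_solution`: `F` (non-negative free energy,
#'   0 at goals), `policy`, `decision_info` (bits), `prior`, `live`, `V`
#'   (value of the converged policy), `beta`, `log_base`, and `diagnostics`
#'   (iteration counts and final residuals).
#' @export
#' @examples
#' m <- build_gridworld(grid_spec(5, 5), goals = 12)
#' sol <- free_energy_solve(m, beta = 100)
#' sol$decision_info[25]  # information cost from corner state 24, in bits
free_energy_solve <- function(mdp, beta, log_base = 2,
                              inner_tol = 1e-9, outer_tol = 1e-9,
                              max_inner = 10000L, max_outer = 20000L,
                              damping = 0) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be strictly positive", call. = FALSE)
  n <- mdp$n_states
  n_a <- mdp$n_actions
  gl <- mdp$goals + 1L
  kappa <- beta * log(log_base)  # exponent scale in natural-log units

  # deterministic start: uniform policy -> live -> prior
  pol <- uniform_policy(mdp)
  live <- live_distribution(mdp, pol)
  prior <- action_prior(pol, live)

  Fv <- numeric(n)
  inner_total <- 0L
  outer_resid <- Inf
  inner_resid <- Inf
  for (outer in seq_len(max_outer)) {
    lp <- rep(log(pmax(prior, 1e-300)), each = n)
    for (inner in seq_len(max_inner)) {
      Q <- mdp$reward - expect_successor(mdp, Fv)   # E[r - F(S') | s, a]
      L <- lp + kappa * Q
      M <- row_max(L)
      Z <- M + log(rowSums(exp(L - M)))
      Fnew <- -Z / kappa
      Fnew[gl] <- 0
      inner_resid <- max(abs(Fnew - Fv))
      Fv <- Fnew
      if (inner_resid < inner_tol) break
    }
    inner_total <- inner_total + inner
    Q <- mdp$reward - expect_successor(mdp, Fv)
    L <- lp + kappa * Q
    M <- row_max(L)
    probs <- exp(L - (M + log(rowSums(exp(L - M)))))
    probs <- probs / rowSums(probs)
    # goal-state action choice never matters (absorbing); display the prior
    probs[gl, ] <- rep(prior, each = length(gl))
    colnames(probs) <- mdp$actions$action
    pol <- new_policy(probs)

    live <- live_distribution(mdp, pol)
    upd <- action_prior(pol, live)
    newprior <- (1 - damping) * upd + damping * prior
    outer_resid <- max(abs(newprior - prior))
    prior <- newprior
    if (outer_resid < outer_tol && inner_resid < inner_tol) break
  }
  converged <- outer_resid < outer_tol && inner_resid < inner_tol
  if (!converged)
    warning(sprintf(paste0("free_energy_solve: not fully converged at beta=%g ",
                           "(outer residual %.3g, inner residual %.3g)"),
                    beta, outer_resid, inner_resid))

  info <- decision_information(mdp, pol, prior, log_base = 2)
  tr <- mdp$transient
  V <- numeric(n)
  if (length(tr) > 0L) {
    Tm <- policy_transition(mdp, pol)[tr, tr, drop = FALSE]
    V[tr] <- solve(diag(length(tr)) - Tm, mdp$reward[tr])
  }
  structure(
    list(F = Fv, policy = pol, decision_info = info, prior = prior,
         live = live, V = V, beta = beta, log_base = log_base,
         diagnostics = list(outer_iterations = outer,
                            inner_iterations = inner_total,
                            inner_residual = inner_resid,
                            outer_residual = outer_resid,
                            converged = converged)),
    class = "fe_solution"
  )
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> beta=%g, %d states; F in [%.4g, %.4g]; %d outer / %d inner iterations\n",
              x$beta, length(x$F), min(x$F), max(x$F),
              x$diagnostics$outer_iterations, x$diagnostics$inner_iterations))
  invisible(x)
}

#' Evaluate the free energy of a fixed policy
#'
#' Policy-evaluation counterpart of [free_energy_solve()]: for a fixed
#' policy and a fixed action prior, `F = (1/beta) I_D - V`, with both the
#' decision information `I_D` and the value `V` obtained by exact linear
#' solves over the transient states.
#'
#' @inheritParams free_energy_solve
#' @param policy A [new_policy()] whose induced chain is absorbing.
#' @param prior Action distribution used in the information term.
#' @return Numeric per-state free energy, zero at goals.
#' @export
evaluate_free_energy <- function(mdp, policy, prior, beta, log_base = 2) {
  stopifnot(inherits(mdp, "tabular_mdp"), beta > 0)
  info <- decision_information(mdp, policy, prior, log_base = log_base)
  tr <- mdp$transient
  V <- numeric(mdp$n_states)
  if (length(tr) > 0L) {
    Tm <- policy_transition(mdp, policy)[tr, tr, drop = FALSE]
    V[tr] <- solve(diag(length(tr)) - Tm, mdp$reward[tr])
  }
  info / beta - V
}
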