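---
title: "Cognitive geometry of information-bounded agents: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive geometry of information-bounded agents: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`cognigeo` studies how the geometry of a navigation task deforms when the
navigating agent pays not only for time but for *information processing*.
The environment is a cost-only, undiscounted, episodic Markov decision
process on an empty rectangular gridworld: every action from a transient
state costs one step (reward −1), goal states are absorbing with reward 0,
and transitions are deterministic. Under the Manhattan neighbourhood the
agent has the four cardinal moves; under the Moore neighbourhood also the
four diagonals. A move whose target cell lies outside the grid is a *wall
bump*: the agent stays exactly where it is and still pays the step. This
full-stop rule matters: a blocked diagonal move does not slide along the
wall. It makes edges and corners "buffer" imprecise action choices — a
repeated diagonal action pressed against a wall wastes time but cannot
push the agent off course — which is the mechanism behind most of the
geometry distortions the package exhibits.

With this reward structure, the negative optimal value −V\*(s) is exactly
the number of steps on a shortest path from s to the goal, and it
satisfies the three quasi-metric axioms (non-negativity, identity of
indiscernibles, directed triangle inequality) on the state space. The
package verifies this by exhaustive enumeration rather than by argument
(`quasimetric_audit()`).

## Decision information

The information cost of *executing* a policy π is measured per state as
the expected cumulative Kullback–Leibler divergence, in bits, between the
per-state action distribution and a fixed marginal action prior:

ℑ_D(s) = Σ_a π(a|s) log₂ [π(a|s) / p̂(a)] + Σ_{s′} P_π(s′|s) ℑ_D(s′),  ℑ_D(goal) = 0.

The prior p̂(a) is not free: it is the policy marginalized over the *live*
(visitation) state distribution, p̂(a) = Σ_s π(a|s) p̂(s). The live
distribution answers: "if the agent started uniformly at random somewhere
in the transient states and we look at a random time while the policy is
still running, where is it?" It is computed exactly from the
absorbing-chain fundamental matrix N = (I − T)⁻¹, where T is the
transient-to-transient transition matrix under π: each start's visit
profile N[i, ] is normalized by that trajectory's own expected duration
(rowsum), and the profiles are averaged over the uniform start
(`live_distribution()`, method `"time-fraction"`).

Two remarks on this construction. First, the per-start normalization is a
deliberate reading of "a random time of carrying out the policy": a start
far from the goal contributes the *shape* of its visiting behaviour, not
more total mass because its trajectories are longer. The alternative —
pooling raw expected visit counts over starts — is available as method
`"expected-visits"`, but it over-weights long-lived starts, and the
worked-example values shipped in the test suite single out the
time-fraction reading. Second, mass on goal states is identically zero:
decisions taken where no decision is pending are never charged.

## Free energy and the solver

The trade-off objective is the free energy

F(s; β) = (1/β) ℑ_D(s) − V(s),

minimized over policies for a single global trade-off parameter β > 0
(per-state information thresholds are conceptually possible but are not
used). β → ∞ recovers shortest-path behaviour; β → 0 forces the policy
toward a single state-independent action distribution — an *open-loop*
policy, the discrete analogue of walking on a compass bearing.

`free_energy_solve()` computes the optimizing policy πF with a double
iteration. The inner loop, for a fixed prior, is a soft Bellman recursion:

- Q(s, a) = E[r − F(S′) | s, a]
- F(s) ← −(1/β) log₂ Σ_a p̂(a) 2^(β Q(s,a)), with F(goal) = 0
- π(a|s) ∝ p̂(a) 2^(β Q(s,a)),

iterated until the sup-norm change of F falls below `inner_tol` (default
1e−9, cap 10⁴ sweeps). The outer loop then recomputes the live
distribution and the marginal prior from the current policy and repeats
until the prior is stationary (`outer_tol` 1e−9, cap 2·10⁴ updates —
thousands of prior updates are genuinely needed at small β). The
exponentials are log-sum-exp shifted, so β = 10⁷ runs without overflow;
prior entries are floored at 1e−300 inside logarithms only; and terms with
π(a|s) = 0 contribute 0·log 0 := 0 to divergences. Initialization is
deterministic and unbiased: uniform policy → its live distribution → its
marginal prior.

All information quantities are kept in **bits** (base-2 logarithms), also
inside the optimization, where (1/β) ℑ_D is traded against step costs so
the base genuinely changes F at a given β. A `log_base` switch to natural
logarithms is provided; the shipped defaults and all reference values use
base 2, which is the base that reproduces the package's worked examples.

## Fixed points are not unique

The coupled (policy, prior) system is not jointly convex, and at both
large and small β its fixed points are genuinely non-unique:

- At large β, every deterministic shortest-path policy together with its
  own marginal is (nearly) a fixed point; the Boltzmann weighting selects
  among co-optimal actions by the prior, which the prior update then
  reinforces.
- At small β, the outer prior map becomes nearly the identity along a
  "slow manifold" of near-open-loop priors, and distinct basins exist
  whose priors put mass on different action subsets.

The package's deterministic initialization makes the computed solution
reproducible: the same grid, goal, β and tolerances always give the same
fixed point. Users probing the landscape can pass a different initial
prior through the solver's internals, but all shipped values refer to the
uniform start. Convergence diagnostics (outer/inner iteration counts and
final residuals) are returned with every solution; non-convergence warns
rather than fails, and an optional prior `damping` is available should
the outer iteration oscillate (the shipped examples do not need it).

# Distance geometry

`pairwise_free_energy()` assembles D with d_ij = F_{goal j}(s_i), one
solve per goal column. D is a directed (asymmetric) cost table; its
symmetrization D_sym = (D + Dᵀ)/2 (`symmetrize()`) feeds metric MDS.
`mds_embed()` minimizes normalized stress-1 by SMACOF majorization,
initialized from the classical (Torgerson) solution plus random restarts
(default 4) under an explicit seed; the implementation is in-package
because the installed toolchain offers classical and non-metric scaling
but not stress-majorizing metric MDS. Embedded coordinates are defined
only up to rigid motion — comparisons must go through stress or
Procrustes alignment, and no numeric reference value in the package
depends on raw coordinates.

`quasimetric_audit()` checks D1–D3 by exhaustive enumeration of all
ordered triples (exact, not sampled, for the grid sizes involved) and
reports violations with the normalized magnitude
(d_ij + d_jk − d_ik)/d_ik. For free-energy distances the audit is of the
"re-optimized segments" kind: each matrix entry already carries its own
per-goal optimal policy, which is exactly the regime in which the
triangle inequality can fail.

# Geodesics and infodesics

A *value geodesic* is a state sequence whose leg distances under −V\* sum
exactly to the direct distance (`value_geodesic_test()`, exact integer
arithmetic on these grids). The free-energy analogue relaxes the equality
to a band: a sequence is an ε-*infodesic* when the normalized difference

(Σ_i F_{s_{i+1}}(s_i) − F_{s_T}(s_0)) / F_{s_T}(s_0)

lies in (−ε, ε), each leg scored under its own optimal policy
(`normalized_difference()`, `chain_free_energy()`). The sign convention
makes the value negative when segmentation is cheaper — the direction in
which the triangle inequality breaks. Negative values are impossible in
the shortest-path regime but become large as β shrinks, because switching
to a fresh policy at a subgoal lets each segment use a prior tailored to
its own leg. No switching penalty is charged for changing policies at a
subgoal; pricing that switch is explicitly outside the package's scope.

`epsilon_infodesic_search()` enumerates every non-repeating sequence of
length 3–5 between fixed endpoints against a precomputed all-pairs matrix
(the per-segment policies are implicit in the matrix). The full
unconstrained enumeration is restricted to length-3 sequences
(`interim_histogram()`), which counts how often each state serves as the
interim state across all ordered triples; longer sequences are available
only with both endpoints fixed to bound the combinatorics.
`sample_trajectories()` complements the exact computations with
synchronized vectorized rollouts (default 10,000 episodes, 10⁵-step cap,
mandatory seed).

# Problem sizes and test design

All reference computations are desk-scale and chosen to mirror the worked
examples the package documents: 5×5 Manhattan grids for the
decision-information examples, 7×7 Moore grids for the infodesic and
open-loop examples (β = 100, 0.07, 0.01), and 11×11 Moore grids for the
corner-contraction trend (β ∈ {100, 5, 0.3, 0.1}, where only the two
corner-goal solves are needed rather than the full 121-column matrix).
Oracles in the test suite are independent of the implementation: graph
distances come from `igraph` on an independently built grid graph,
embedding recovery is checked through `vegan`'s Procrustes rotation,
infodesic searches are compared against a direct brute-force scan of the
distance matrix, and decision information is cross-checked by Monte-Carlo
rollouts (agreement within three standard errors at 10,000 episodes).

Because the gridworlds are generated programmatically from first
principles (width, height, neighbourhood, goal), passing tests certify
the solver and geometry machinery on exactly the deterministic,
obstacle-free, unit-cost worlds described above. They say nothing about
stochastic transitions (the data structures permit them; the shipped
dynamics never produce them), penalized walls, obstacles, or continuous
state spaces.

# Known limitations

- Fixed-point multiplicity (above) means solutions at small β are
  schedule- and initialization-dependent in principle; the package fixes
  both and documents the convention rather than claiming a global
  optimum.
- The outer iteration can need thousands of prior updates in the
  near-open-loop regime (β ≈ 0.01 on a 7×7 Moore grid converges after
  roughly 2,500 updates); budget accordingly when building all-pairs
  matrices at small β.
- MDS stress is reported but never compared against an external
  reference; embeddings are qualitative instruments.
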