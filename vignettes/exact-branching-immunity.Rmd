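---
title: "Exact branching-process models of within-host immunity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact branching-process models of within-host immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwimmune)
```

## The model

Every population in `gwimmune` is a *Darwinian entity*: a clonal population
of indistinguishable individuals that advances in discrete, non-overlapping
generations, each generation being a multiplication phase followed by a
selection phase. The state of an entity is not a count but a probability
distribution `W(N)` over counts `0 <= N <= N_max`; both phases are linear
maps on that distribution and are evaluated exactly.

**Multiplication.** From `N` parents the capacity is
`mu = min(rho * N, N_max)`: the multiplication factor `rho` (a positive
integer — each individual offers `rho - 1` copy slots) sets the demand, and
the nutrient ceiling `N_max` caps it. Each of the `mu - N` available slots
fills independently with copy probability `alpha`, so the count after
multiplication is `N` plus a binomial. When a second (or third, fourth)
type is present, each *realized* copy of type X further mutates into type Y
with per-copy probability `eps_XY`; a slot is therefore a trinomial —
empty, faithful copy, mutated copy — and the joint update is the
convolution of per-type trinomial kernels.

**Selection.** Every individual survives independently with probability
`beta`: binomial thinning, independent across types.

**Extinction.** Zero is absorbing. Because the full distribution is
propagated, the extinction probability `W(0)` (for joint states,
`W(0, ..., 0)`) is read off the recursion rather than estimated; all
reported means and standard deviations are *unconditional*, i.e. they
include the mass at zero. This is the quantity deterministic ODE models
cannot represent, and it is why the package propagates distributions
rather than sampling.

**Shared capacity and the cut-off geometry.** Types that live in one
compartment share one simplex `sum(N_i) <= N_max`. When the total demand
`sum(rho_i * N_i)` exceeds `N_max`, capacity is allocated along the ray
from the origin through the demand vector: the capacities are the integer
point(s) on the hyperplane `sum(mu_i) = N_max` nearest (Euclidean) to the
ray's intersection with it, constrained to `N_i <= mu_i <= rho_i * N_i`.
The lower bound says the cut-off starves growth but never removes existing
individuals; the upper bound — our addition, active only in the four-type
generalization — says a type whose `rho` is 1 cannot be handed copy slots
it has no way to use. When two lattice points are exactly equidistant from
the intersection the parent state's mass is split equally between them
(and the Monte-Carlo sampler flips a fair coin), a literal reading of the
published tie rule; distances are compared with a 1e-9 absolute guard so
the tie set is stable under floating-point noise.

## The coupled immune models

The infection models interlock two entities through their *means*: at each
generation the pathogen's `(rho_P, beta_P)` are a step function of the
previous generation's effector mean (set point `T_E`), and the immune
bundle `(rho_E, rho_M, eps_EM, eps_ME, beta_E, beta_M)` is a step function
of the previous pathogen mean (set point `T_P`). Three conventions were
genuinely open and are fixed as follows:

* **Simultaneous update.** Both entities advance from the *previous*
  generation's post-selection means; neither sees the other's
  within-generation update. No update order is implied by the two-state
  control-loop description, and simultaneity is the only symmetric
  reading.
* **Set-point equality resolves to the below branch.** Arbitrary, but
  fixed, logged in the trajectory's branch flags, and asserted by a test
  that replays the flags from the logged means.
* **The coupling reads the effector marginal.** The immune mean entering
  the pathogen's rule is the effector-axis marginal mean of the joint
  effector/memory distribution, exactly as the printed average is defined.

The clearance caption prints its two pathogen-threshold conditions with
the same inequality sign; the parentheticals ("below …", "above …") are
taken as governing. The chronic and two-strain scenarios state only
overrides; everything unlisted inherits the clearance parameter set, the
only published set that is complete.

Other modelling conventions: the initial immune state is one effector and
no memory (mirroring the single pathogen ancestor; the source text says an
immune cell "is singled out" but gives no count), configurable in the
scenario; reinfection is modelled as an explicit event schedule that
shifts the pathogen distribution up by one individual (mass already at
`N_max` stays), default none, since no mechanism or timing is published.
In the two-strain model each strain is gated only by its cognate arm and
each arm only by its cognate strain (lock-and-key, no cross-reactivity),
the two strains share one capacity simplex, and the two arms each have
their own — nothing couples the arms' nutrient supplies, and they never
exchange individuals.

## T-cell maturation

The four-type process (naive, self-reactive, matured-inactivated,
matured-activated) adds differentiation: each realized naive copy runs a
sequential cascade — take the first fate with its `eps`, else the second
with its `eps`, else the third, else stay naive — and the multiplication
operator averages the 3! fate orderings with weight 1/6. The three
published `eps` values are 0.7 each and sum to 2.1, so they cannot be
multinomial fractions; the sequential reading is the only consistent one,
and at equal `eps` the operator is invariant under fate relabelling (a
property the tests assert). Equivalently, per ordering the fates of one
copy are `eps_1`, `(1-eps_1) eps_2`, `(1-eps_1)(1-eps_2) eps_3`, which is
how the kernel is built. The published schedule switches the bundle at
generations 50 and 100; the same multiplication operator is used in every
phase (no alternative operator is published for later phases), only the
parameters change. Differentiated types never de-differentiate or
transdifferentiate — the recursion gives them self-copy terms only.

## Numerical organization

Both phases are linear operators on the distribution vector, so each
parameter bundle yields a *transition matrix* over simplex states
(`(N_max+1)` states for one type, 561 for two types at `N_max = 32`, 4845
for four types at `N_max = 16`), built once and cached per bundle; a
generation is then a matrix–vector product. The coupled models switch
between at most two bundles per entity, so at most a handful of matrices
is ever built per run. Selection factorizes per type and is applied as a
thinning matrix along each axis of the dense array. The per-type
trinomial kernel organization is mathematically identical to the printed
nested convolution sums (binomial-compounded-with-binomial equals the
trinomial split); the test suite keeps the literal nested sums, with
out-of-range binomial terms masked to zero, as an independent brute-force
oracle and pins the equivalence at 1e-12.

Mass conservation is enforced, not assumed: after every phase the total
mass must be within 1e-9 of one (then renormalized); a defect beyond 1e-6
aborts, because round-off cannot produce it — only an indexing bug can.
Dense arrays are used throughout (`N_max <= 128` in every shipped
scenario, so sparsity buys nothing). Binomial factors come from
`stats::dbinom`, which works in log space, so no explicit big-coefficient
handling is needed.

Degenerate inputs have defined behaviour: `alpha = 0` multiplication and
`beta = 1` selection are identities; the empty state is absorbing in every
model; a zero-pathogen start keeps the immune system on its dormant branch
forever; a maturation run from the empty state reports extinction
probability one at every generation.

## Deterministic comparators

`logistic_solution()` evaluates the closed-form logistic curve in the
overflow-stable form `K / (1 + (K - N0)/N0 * exp(-R t))`;
`two_species_ode()` integrates the two-species extension with `lsoda` at
relative tolerance 1e-8 (a smooth two-dimensional system; stiffness is
not an issue). `fit_logistic_R()` fits `R` and `K` by Levenberg–Marquardt
least squares with `N0` fixed and a documented deterministic
initialization: `R` from the log-slope of the first ten positive means,
`K` from the final mean. Conventions the source leaves open, fixed here:
the fit uses the **post-selection, unconditional** means over the **full**
window, generation 0 included, with `N0 = 1` and `K` free (the plateau is
an emergent property of the stochastic cut-off, not a configured value).
A constant trajectory equal to `N0` is reported with a
`non_identifiable` flag (any `R` fits it); a constant-zero trajectory is
an error.

## The Monte-Carlo oracle

`mc_ensemble()` samples the identical rules at the agent level —
Bernoulli per slot, Bernoulli per copy for mutation/differentiation, one
fate-ordering draw per replicate and generation, Bernoulli per individual
for survival — using the same capacity-allocation function as the exact
recursion, with equidistant ties resolved by a fair coin so the two
semantics coincide. Replicates are advanced in vectorized batches from a
single seeded RNG stream (replicate-indexed seeding would forfeit
vectorization and buys nothing for a convergence check). The expected
total-variation distance between the empirical and exact distributions
scales like `sqrt(support size / replicates)`; at 1e5 replicates and the
shipped scenarios' support sizes that is well below the 0.01–0.02 bands
the tests assert at generation 10. For the coupled models the threshold
switching is a deterministic function of the exact means, so the sampler
replays the same per-generation bundles and must converge to the same
joint distributions — an end-to-end check of the coupling logic, not just
of the kernels.

## What the canned scenarios emulate — and what they do not

The shipped configurations are the published study conditions: capacities
of 32 (coupled models), 128 (single type) and 16 (maturation), one
ancestor per entity, copy probability 0.1 in every coupled model, and the
published threshold/branch tables. They emulate the *structure* of an
infection — flare, detection, clearance or escape, memory — at deliberately
small carrying capacities where stochasticity is strong and exact
propagation is cheap. They do not emulate real titers (no units of cells
or virions — one "individual" is an abstraction), real generation times,
genotypes or receptor sequences (mutation is a type switch, not an edit),
host compartments, or cross-reactive recognition. A passing suite
therefore shows the recursions and couplings are exact and the published
regimes reproduce; it says nothing about quantitative fit to any real
infection.

## Problem sizes

The test suite runs the brute-force equivalences at `N_max <= 8` (where
exhaustive enumeration is exact and fast), the Monte-Carlo comparisons at
1e5 replicates over 10 generations, and the scenario runs at their
published horizons (200, 100, 100 and 150 generations; the 600-generation
two-strain takeover run is checked at 120 generations, by which point the
mutant dominates). The full suite completes in a few minutes on one CPU.

## Known limitations

* Coupling acts through means only; fluctuations of one entity do not
  reach the other except through its mean. That is the published model,
  but it makes the coupled system a mean-field hybrid: the joint
  pathogen-immune distribution is never formed.
* Unconditional means under substantial extinction mass are bimodal
  summaries: "mean 1.4" can be "extinct with probability 0.93, saturated
  otherwise". The distributions themselves (keep = "all") are the honest
  output; branch switching on such means is sensitive to this compression.
* `rho` is restricted to positive integers, as in every published
  configuration; fractional multiplication factors would need a different
  slot model.
* Dense transition matrices scale as the square of the simplex size; the
  four-type matrix at `N_max = 16` (4845 states) is the practical
  ceiling of this organization.
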