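---
title: "Linked amino-acid substitutions on a branch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked amino-acid substitutions on a branch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranlink)
```

## The problem

Phylogenetic substitution models — including mutation–selection models that
parameterize sitewise amino-acid fitnesses — almost universally assume that
sites evolve independently. In regions of low recombination this is wrong in
a specific, population-genetic way: mutations arising in the same lineage
stay linked forever, so a weakly deleterious change can ride to fixation
with an advantageous neighbour (hitchhiking) and an advantageous change can
be purged with a deleterious background (background selection). Both
distort fitness estimates made under independence.

`moranlink` models a single phylogenetic branch as a Moran population of
`N` haploid individuals evolving for `t_b` time units, conditions on the
`K` substitutions observed on that branch, and computes the probability of
every *fixation history* — which consecutive substitutions fixed together
on one haplotype and which fixed sequentially. The headline quantity for a
pair of substitutions is the probability that they fixed together given
that both fixed, which is also the relative error an independent-sites
model incurs on that branch (it accounts only for the sequential history).

## The processes

**Finite-sites model.** The reference process is an `N x M` population
matrix of amino-acid characters. Each replacement event copies individual
`j` over individual `i` at rate `f(X_j) / (N * sum_k f(X_k))` per ordered
pair — fecundity-weighted birth, uniform death — and character mutations
`A -> B` occur at rate `mu(A, B)` per site per individual. Individual
fitness is multiplicative over sites. The state space has order `20^(MN)`,
far too large for transient analysis, so this model is provided as an exact
Gillespie simulator (`simulate_finite_sites()`) and serves as the package's
end-to-end oracle.

**k-allele (tracked) process.** Between mutation arrivals the conditioned
model is a k-allele continuous-time Moran process tracking the counts
`x = (x_1, ..., x_k)` of the nested mutant haplotypes; the wild type is
implicit with count `N - sum(x)`. A convention used throughout the
package: **`k` counts tracked mutant haplotypes**, so what the
population-genetics literature calls an m-allele model corresponds to
`k = m - 1` here; `enumerate_states(k = 1, N)` is the classical two-allele
model. The state space has `choose(N + k, k)` states; generators are
sparse with at most `k*(k+1)` off-diagonals per row (`build_generator()`),
and dense conversions are refused above `1e4` states.

Time units: rates are scaled so that one birth/death event is expected per
unit time, *counting* self-replacements (an individual replaced by a copy
of its own type). Self-replacements change no state, so they do not appear
in the generator; `N` time units correspond roughly to one generation.

Under complete linkage with multiplicative effects, the i-th nested
haplotype has fitness `f*_i = prod(f[1:i])` relative to the wild type
(`haplotype_fitnesses()`), where `f_i` is the relative fitness of the i-th
mutation at its own site.

## Two-allele machinery

All quantities reduce to sparse linear algebra on the tridiagonal
transient block `Q*`:

* `transient_distribution()` propagates a distribution by `v exp(Qt)`
  using uniformization (Poisson-weighted powers of `I + Q/Lambda`); all
  terms are non-negative, so the long horizons fixation needs are stable.
  The truncation tolerance is `1e-14` of Poisson tail mass. A dense
  `Matrix::expm()` path exists only inside the test suite, as an oracle.
* `longrun_fixation_probability()` solves `r Q* = e_{x0}` once
  (tridiagonal, O(N)) and returns `-r . v_N`; it matches the birth–death
  closed form `(1 - f^-x0) / (1 - f^-N)` to `1e-10` and remains practical
  to `N` near `1e6`.
* `conditional_fixation_time_moments()` computes the mean and SD of the
  fixation time given fixation from the sojourn matrix `G = -(Q*)^{-1}`:
  `mu = [G h]_x0 / h_x0` and `E[T^2|fix] = 2 [G^2 h]_x0 / h_x0`, where
  `h` solves `Q* h = -v_N`. Each row of `G` and `G^2` comes from one
  triangular solve, the second reusing the first solution as its
  right-hand side.

### The Gumbel finite-time approximation

For large `N` the standardized conditional fixation time converges to a
weighted convolution of two Gumbel variables, `W = G1 + f * G2`, one from
each slow boundary layer of the conditioned sweep (the factor `f` is the
ratio of the boundary time scales). `gumbel_fixation_cdf()` approximates
`P(fixed by t)` as `F_G((t - mu)/sigma) * pfix_inf`, tabulating `F_G` once
per fitness by Simpson-rule convolution on a 4096-point grid spanning
about 12 standard deviations and interpolating monotonically.

Because the argument `(t - mu)/sigma` is standardized, `F_G` must be the
CDF of a zero-mean, unit-variance variable. Printed forms of this limit
normalize `W` variously by `1 + f^2`, `1 + f`, or `sqrt(1 + f^2)` without
recentring; applied literally to raw standard Gumbels, every one of those
variants misses the exact transient CDF by about 0.03 in sup norm at
`N = 100`, `f = 1.1`, while the standardized mixture (centre `gamma*(1+f)`,
scale `(pi/sqrt(6)) * sqrt(1+f^2)`) agrees to about 0.002 — the comparison
is recomputed by the test suite and the acceptance script. The
standardized form is therefore the default (`variant = "standardized"`),
and the literal variants remain available for comparison.

```{r gumbel, eval = FALSE}
m <- conditional_fixation_time_moments(100, 1.1)
tg <- seq(0, m$mu + 6 * m$sigma, length.out = 150)
max(abs(gumbel_fixation_cdf(100, 1.1, tg) - fixation_cdf_exact(100, 1.1, tg)))
```

## Pairs of substitutions

With fixed arrival times `t1 <= t2` on a branch of length `tb`:

* `p_independent()`: the first mutation fixes in `[t1, t2)` and the second
  (a fresh two-allele sweep against the redefined wild type) fixes in
  `[t2, tb]` — a product of two fixation-by-time probabilities.
* `p_together()`: the first is still segregating with `i` copies at `t2`,
  the second arises in a carrier (probability `i/N`), and the double
  mutant (haplotype fitness `f1*f2`) reaches count `N` by `tb` in the
  three-allele process started from `(i-1, 1)`. The three-allele factor
  for *all* `i` comes from a single backward action `exp(Qt) e_target`
  (or one absorption solve when `tb = Inf`), never `N - 1` separate
  exponentials.

Mass in which the second mutation lands on a wild-type background is
counted toward neither probability: under complete linkage two non-nested
haplotypes cannot both reach frequency 1, so that mass cannot produce the
conditioned outcome. The same argument disposes of the hypothetical
variant in which new tracked mutations are introduced on
non-most-derived backgrounds in the general-K recursion — such mass can
never contribute to a history in which *all* tracked mutations fix, so no
behavioural flag is needed; the nested update is the only one with
non-zero conditioned probability.

For random times, mutations arrive as a Poisson process; conditional on
two arrivals the times are iid uniform. `p_together_random_times()`
returns the conditional probability as a ratio of integrated
probabilities,

    P(together | both fix) = Int p_T / Int (p_T + p_I),

summed over both arrival orders (hence exactly symmetric in `f1`, `f2`).
The ratio-of-integrals form weights each time configuration by its
probability of producing the conditioning event, and is what conditioned
simulation estimates; the simpler average of `p_T/(p_T+p_I)` under the
prior time density — which weights times where fixation is nearly
impossible equally with times where it is likely — is also returned, as
the `mean_conditional` attribute. The integral uses tensor Gauss–Legendre
quadrature (default 24 x 24 nodes) on the triangle parameterized by the
time between mutations and the time remaining; the suite checks 24- vs
32-node agreement to `1e-4` relative.

## General K: fixation histories

A branch with `K` substitutions has `2^(K-1)` fixation histories, encoded
as binary strings of length `K - 1`: digit `i` is 1 when a fixation
separates mutations `i` and `i + 1` (the final fixation is implied).
`history_probabilities()` propagates the tracked sub-probability mass
through the `K` intervals; during the interval after mutation `i` the
active process tracks mutations `kappa..i` (where `kappa` restarts after
each intervening fixation, because the wild type is redefined) with
haplotype fitnesses `cumprod(f[kappa:i])`. At each arrival the mass is
remapped: digit 1 keeps only the fully-fixed component and restarts at
one copy; digit 0 grows the dimension, moving mass `y_k/N` from each
state with `y_k` most-derived carriers. The fully fixed state is excluded
from the digit-0 remap — a mutation arriving there belongs to the digit-1
branch; including it would double-count and break the partition property
(the histories are disjoint and together exhaust the event that all `K`
mutations fix).

Histories sharing a prefix share their tracked mass until the prefix
diverges, so all `2^(K-1)` histories are computed in one depth-first pass
with cached state spaces and generators. Random arrival times are
integrated by Monte Carlo over sorted uniform draws (default `1e4`,
seeded and recorded); deterministic grids over the K-dimensional ordered
simplex grow too fast to be worthwhile beyond `K = 2`. The default cap
`K <= 5` keeps the largest state space at `choose(N + 5, 5)`; raise
`k_cap` deliberately if you accept the memory.

## Simulators

`simulate_finite_sites()` is an exact Gillespie realization of the
finite-sites generator with an event log and a substitution log (a site
becoming monomorphic for a character differing from its current
reference). Replacement pairs are drawn jointly — parent with probability
proportional to fitness, victim uniformly — which reproduces the
generator's off-diagonals exactly; self-replacements advance time but not
state, keeping the total replacement rate at 1 per unit time so logged
inter-event times are exponential with rate `1 + total mutation rate`.

`tracked_pair_replicates()` / `tracked_k_replicates()` simulate the
conditioned tracked model directly (sorted-uniform arrivals, nested
k-allele jump chains, lineage assignment `x_k/N`) and classify each
replicate into the history it realizes or "failed". Conditioning is by
rejection; for neutral pairs the acceptance rate is about `1/N^2`, so
failure counts dominate and are reported. The jump chains are implemented
in C++; a fixed seed replays bit-identical outcomes.

What the simulators emulate — and what they do not: they realize exactly
the processes the analytic modules model, so agreement validates the
implementation, not the model's fidelity to real proteins. Real data add
standing variation at branch ends, background ("ghost") mutations that
segregate without fixing, non-multiplicative (epistatic) fitness
interactions, and recombination; none of these is represented here.

## Branch likelihood and its identifiability limit

`branch_likelihood()` evaluates the likelihood of a fitness vector given
an observed substitution history as the total probability of all fixation
histories consistent with it, with arrival times integrated out
(deterministic quadrature for `K <= 2`, seeded Monte Carlo beyond).
`estimate_fitnesses()` maximizes the pooled log-likelihood over branches
with bounded quasi-Newton search on the log scale, using common random
numbers so the Monte-Carlo surface is smooth, and reports per-coordinate
profile-likelihood intervals.

This likelihood is deliberately unnormalized — it is the probability that
the recorded mutations fixed, not the probability of the record among all
possible outcomes — and that has a hard consequence: it is non-decreasing
in every fitness. Records consisting only of completed substitutions
(site, from, to, branch length) cannot bound fitnesses from above, so
point estimates sit on the upper search bound, and the `bounds_hit` flags
report exactly that. Informative estimation requires data that penalize
high fitness — failed mutations, segregation times, or normalization by
the probability of observing `K` substitutions (which reintroduces the
mutation process). The machinery is exposed because the likelihood itself
and its per-history decomposition are useful (e.g. for weighting
fixation histories when post-processing fitness profiles), with this
caveat documented rather than hidden.

## Numerical choices and problem sizes

* Uniformization truncation: `1e-14` Poisson tail mass; generator row
  sums are zero to `1e-12` by construction.
* Quadrature: Gauss–Legendre, 24 nodes per dimension by default
  (convergence checked at 32); the quantity is a model output, so `1e-4`
  relative accuracy is ample.
* Gumbel CDF tabulation: Simpson convolution, 4097-point inner grid on
  the second component, 4096-point monotone (Hyman) spline on the result.
* Monte-Carlo defaults: `1e4` time draws for random-times histories,
  `4e3` for the likelihood; every stochastic entry point takes and
  records a seed.
* The test suite exercises exact oracles at `N <= 30` (dense matrix
  exponentials), closed forms to `N = 1000`, the Gumbel regime at
  `N = 100`, and simulation bridges at `1e5`–`4e5` replicates — sizes
  chosen so the full suite runs on a laptop-class single core in a few
  minutes while leaving every comparison statistically sharp (3
  standard-error bands).

## Limitations

* Transient analysis is desk-scale: the three-allele (two-tracked)
  quantities are routine to `N` of a few hundred; only the long-run
  solves extend to very large `N`. Diffusion approximations are the
  natural next step and are not implemented.
* One branch at a time: applying the calculus across a tree (and mapping
  substitutions onto branches) is the caller's concern.
* The wild type is assumed homogeneous at the branch start and fitness 1
  throughout; segregating background mutations, which would effectively
  raise every tracked mutation's relative fitness, are ignored.
* Fitness ratios are per-site relative fitnesses under multiplicative
  interaction; structural/functional epistasis is out of scope.
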