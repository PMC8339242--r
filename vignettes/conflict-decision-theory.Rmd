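---
title: "A size-based decision theory of animal conflict: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A size-based decision theory of animal conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkdove)
```

## The model

`hawkdove` treats a two-player animal encounter as a one-shot game whose
payoffs are functions of body size alone. For a dyad with trait values
`x > y > 0` (X the larger, Y the smaller player), four descriptors quantify
the strength each interaction type would have:

* mutualism `z_mu = x·y/(x − y)` — the product of sizes, scale-adjusted by
  their difference. Similar-sized animals (fixed sum, maximal product,
  minimal difference) score high, reflecting the observation that near-equal
  individuals school and cooperate;
* antagonism `z_an = 1/(x·y·(x − y))` — the inverse product, same
  adjustment: mutual conflict is most attractive where mutualism is least;
* aggression `z_ag = x/y` — the dominance of the larger player;
* altruism `z_al = (x − y)/x` — the relative size surplus the larger player
  can cede.

All four diverge as `x → y`; a dyad with (numerically) equal traits has no
defined geometry, so construction of a `size_pair` enforces a relative
degeneracy guard `(x − y)/x ≥ eps`, default `1e-9`, configurable. Ties are
rejected, never jittered: silent perturbation would contaminate every ratio
statistic downstream.

Dividing every descriptor by the antagonism strength (the hawk/hawk cell)
removes the common singular factor and yields the relativized reward matrix

```
              Y dove        Y hawk
  X dove    x² y²         y (x − y)²
  X hawk    x² (x − y)        1
```

with X choosing rows and Y columns. `e_hh = 1` holds exactly by
construction, and each entry equals descriptor/`z_an` to machine precision —
both are tested properties.

## Break-even thresholds and the strategy rule

Decisions are assumed to depend on relative, not absolute, size: all
comparisons are made at the normalization `x = 1`, writing `ρ = y/x`. The
four pairwise payoff comparisons give four analytic thresholds
(`conflict_thresholds()`):

* larger vs dove: `ρ²` vs `1 − ρ` break even at the positive root of
  `y² + y − 1 = 0`, the golden section `φ ≈ 0.618` (note the reciprocal
  convention: this is `1/1.618…`, the golden *section*, though the model
  family calls it the golden ratio);
* larger vs hawk: `ρ(1 − ρ)²` vs `1` break even only at `y ≈ 1.755 > 1`
  (real root of `y(1 − y)² = 1`, found by bracketed Brent root-finding with
  a sign-change-expanded bracket, tolerance `1e-12`; the quadratics and the
  linear case use closed forms) — inside the admissible range `(0, 1)`
  aggression always wins;
* smaller vs dove: `ρ²` vs `ρ(1 − ρ)²` break even at the root of
  `y² − 3y + 1 = 0` in `(0, 1)`, the Fibonacci mark `1 − φ ≈ 0.382`;
* smaller vs hawk: `1 − ρ` vs `1` break even at `ρ = 0` — surrender is
  dominated by resistance everywhere in `(0, 1)`.

`predict_strategy()` is defined as the argmax over the two competing matrix
entries, the same comparison the threshold derivations solve; a dedicated
test checks the two routes agree on 10,000 random ratios. One direction
deserves comment because it is easy to state backwards: for the smaller
player facing a dove, the cooperation payoff `ρ²` exceeds the cheating
payoff `ρ(1 − ρ)²` *above* the Fibonacci mark, i.e. a relatively large
subordinate does best by cooperating and a very small one by free-riding on
the larger dove's surplus. Informal summaries of this hypothesis sometimes
state the opposite direction; the package follows the matrix argmax, which
is the only reading consistent with the break-even algebra and with the
larger player's analogous rule.

Exact payoff ties (a ratio numerically at a threshold) resolve to the
cooperative branch, implemented as a relative tolerance of `1e-12` in the
payoff comparison. A documented deterministic rule beats platform-dependent
floating-point comparison; random ratios are unaffected.

## Growth curves and phase partitioning

The co-culture validation needs each trajectory segmented into lag, linear
and asymptotic phases. Trajectories are fitted with the three classical
sigmoids in the Zwietering parameterization, whose parameters are the
quantities the analysis needs directly — asymptote `A` (abundance units),
maximum slope `mu_m` (abundance/hour) and lag `lam` (hours):

* logistic `N(t) = A / (1 + exp(4·mu_m/A·(lam − t) + 2))`
* Gompertz `N(t) = A · exp(−exp(mu_m·e/A·(lam − t) + 1))`
* Richards adds a shape `nu`, recovering the logistic exactly at `nu = 1`
  (a tested closed-form identity) and the Gompertz as `nu → 0`.

Fitting is unweighted least squares on the raw abundance scale
(Levenberg–Marquardt, `minpack.lm`), the simplest defensible default for
qPCR-scale data with roughly proportional noise over the dynamic range used
here; a `log_scale` option exists. Initialization is the classical tangent
construction (`A₀` = max value, `mu₀` = max finite-difference slope, `lam₀`
= the tangent's baseline intercept) plus five fixed rescalings of
`(mu₀, lam₀)` — a deterministic multi-start, so fits involve no randomness.

Model selection mirrors standard growth-curve practice: the two
three-parameter models are compared by AICc (they are not nested), the
winner against Richards by an extra-sum-of-squares F-test at `α = 0.05`
(both are its limiting cases); exact RSS ties go to the fewer-parameter
model. Both criteria are recorded on the returned fit so either can be
audited.

Phases: lag is `[t_min, lam]`; linear `(lam, t95]`; asymptotic beyond, where
`t95` is the closed-form time at which the fitted curve reaches 95% of `A`.
The 95% cutoff is a convention, not a law; it is exposed as `p` in
`partition_phases()` and recorded in results. A curve that does not reach
`p·A` inside the observation window yields an empty asymptotic phase with a
warning.

## Empirical strengths and the validation arm

With `x(t), y(t)` the co-culture abundances of the more/less abundant strain
and `x0(t), y0(t)` their monoculture counterparts:

* `Mu(t) = (x/x0 + y/y0)/2` — above 1, socialization benefited both
  partners (cooperation region); below 1, competition;
* `Ag(t) = (x/y)/(x0/y0)` and `Al(t) = (y/y0)/(x/x0) = 1/Ag(t)` — the
  relative gain of the dominant and subordinate strain (the product
  `Al·Ag = 1` is an exact identity and a standing test).

Which strain plays X is decided by co-culture abundance. Because strains can
swap rank over time, the default re-orders per time point; a `per_pair`
option fixes the assignment by mean co-culture abundance. The choice only
matters for pairs that actually cross, and both conventions are exposed.

`coculture_validation()` pools all pairs × time points within each phase (as
a cross-sectional scatter, not per-pair correlations), computing the
descriptors `z_mu, z_ag, z_al` from the co-culture abundances at each time
point, and reports per-phase Pearson `r` and `p` (Spearman optional) for
each descriptor against its empirical counterpart. Cells with fewer than 3
points or zero variance are skipped with a warning. Curve smoothing in
published scatter plots of this kind is presentation, not statistics, and is
deliberately not implemented in the correlation path.

The empirical antagonism strength is deliberately absent: no defensible
formula pairs with `z_an` the way the other three strengths pair with their
descriptors, and inventing one would not be validation.

## Synthetic data: what it emulates and what it does not

All three generators are pure functions of their parameters and a mandatory
seed.

**Co-culture trajectories** use coupled logistic (generalized
Lotka–Volterra) dynamics, `dN_x/dt = r_x N_x (1 − N_x/A_x + a_xy N_y/A_y)`
and symmetrically for Y, integrated with `deSolve`; the monoculture is the
exact zero-coupling limit (closed-form logistic), which doubles as an
independent check on the integrator. This mechanism was chosen because the
validation only requires that co-culture/monoculture ratios encode the sign
and strength of interaction — it is a data-generating stand-in, not a
mechanistic claim. Defaults: 100 pairs (the scale of the validation
experiments); carrying capacities `A_x ∈ (0.8, 1.5)`, `A_y ∈ (0.3, 0.6)` in
relative abundance units so the dominant strain is unambiguous; rates
`r ∈ (0.3, 0.4) h⁻¹` and initial abundance `A/50`, which place the lag,
linear and asymptotic phases all inside the sampling window; multiplicative
log-normal noise with `sd = 0.05`, a qPCR-like error magnitude. The sampling
schedule is every 2 h to 24 h, then every 4 h to 36 h (16 points); the
"every four" step is read as every four *hours*, and the schedule is
configurable. For symmetric coupling `a`, both strains equilibrate at
`A/(1 − a)`, so `Mu → 1/(1 − a)`: graded positive couplings produce graded
mutualism, which is why the descriptor–strength correlation is recoverable
downstream — a property the acceptance suite checks with 100 pairs graded
over `a ∈ (0.05, 0.6)`.

What the generator does *not* emulate: death phases, lag-phase mechanisms
beyond a small inoculum, strain-specific noise, or rank crossings driven by
opposing growth rates. Passing tests therefore show the pipeline recovers
planted interaction structure under sigmoid growth with multiplicative
noise — not that any particular real community behaves this way.

**Trait cohorts** are log-normal (median 500 units, log-sd 0.35 — adult
fish-mass-like numbers; the analysis is scale-free where it matters).
Planted tier structure draws each lower tier at per-individual target ratios
uniform in the requested band times the upper tier's mean, with the upper
tier tightly dispersed (log-sd 0.05) so dyad-level ratios track the band;
realization is rejection-sampled (≤ 500 attempts) on the dyad-mean ratio
falling inside the band with all cross-tier ratios below 1, and infeasible
bands error out.

**Genotypes** follow Mendelian segregation in a full-sib family: per SNP a
cross type (`AB×AB` with probability 0.5, `AB×AA`/`AA×AB` 0.25 each —
segregating configurations only), offspring alleles drawn independently.
Expected identity-by-state is 0.625 per intercross SNP and 0.75 per
single-heterozygote SNP, 0.6875 under the default mix — the band the
relatedness tests check.

## Networks, roles and tier tests

`build_networks()` computes all `n(n−1)/2` dyad descriptors per type, ranks
them, and retains the top fraction `q` as weighted edges. The retention
fraction is genuinely unknown territory — results depend on it, so the
default `q = 0.1` is deliberately conservative, exposed everywhere, and
recorded in output metadata; rank ties break lexicographically by dyad id so
retention is deterministic. Aggression and altruism edges are directed from
the larger member (actor to recipient: hawk upon dove, altruist benefiting
egoist); mutualism, antagonism and relatedness are undirected.

Hierarchy in the mutualism network: hubs ("links much more than average")
are read parametrically as degree > mean + `k`·sd, `k = 1` by default and
configurable. Secondary leaders are the hubs' other neighbours. Tertiary
leaders are non-assigned nodes adjacent to a secondary whose every route to
a primary passes through a secondary (checked by deleting the secondaries
and testing reachability); followers are the remaining nodes adjacent to a
tertiary but not to a secondary. A regular graph has no hubs and warns. The
same hub rule serves the relatedness network's core/periphery split — no
reason to maintain two notions of "hub" in one package.

`tier_mass_ratio()` averages lower/upper trait ratios over *dyads* (not
tier means), restricted to network-connected dyads when a graph is given,
and applies a one-sample one-sided t-test against `φ` or `1 − φ`. Dyads
sharing an individual are not independent; the naive t-test is reported
because it is the convention this analysis style uses, and an optional
seeded node-permutation p-value is emitted alongside for the cautious
reader. If every ratio is numerically identical the t statistic degenerates
and is reported as 0 (at the threshold) or ±∞.

Between-network correlation uses the full pre-culling dyad vectors, so it
does not depend on `q`. Genetic similarity is the allele-sharing IBS
fraction — assumption-light and requiring no allele-frequency estimation
inside a full-sib family, where frequencies are not estimable in the usual
sense anyway.

## Numerical choices and degenerate inputs

* Degeneracy guard `eps = 1e-9` (relative) on all dyads; degenerate dyads
  error in scalar paths and are dropped with a warning (and reported) in
  vectorized paths.
* Root-finding: closed forms wherever they exist; Brent on an expanding
  bracket for the hawk-shift cubic; no randomness anywhere in the analysis
  path.
* Growth fits require more points than parameters, reject constant series
  as degenerate, and carry a structured error class (`hawkdove_fit_error`)
  so pipelines can skip unfittable series deliberately.
* All generators take a mandatory seed and restore the RNG state
  (`withr::with_seed`), so library calls never perturb a user's session
  RNG.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make sampling error
negligible relative to the tested effects while keeping the default run
fast: 10,000 random ratios for the strategy-oracle equivalence; 200 noise
replicates per growth model at 2% multiplicative noise; 100 co-culture
pairs with graded couplings for the validation-arm property; cohorts of
~20–71 for network properties; 10,000 sibs for the segregation calibration.

## Known limitations

* The model is one-shot: no iterated play, mixed strategies, or replicator
  dynamics.
* Descriptors are size-only; other interaction-relevant traits (age,
  condition, signalling) need different descriptors.
* Network results are conditional on the retention fraction `q`; there is
  no principled default, only a transparent one.
* The tier t-tests inherit the dyad-dependence caveat above.
* Phase labels come from a single fitted trajectory per pair (the dominant
  strain's co-culture series); pairs whose two strains have very different
  kinetics would need per-strain phases.
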