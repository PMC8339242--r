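# hawkdove

Size-based decision theory of animal conflict, as a tested R package.

When two animals interact, body size is a dominant driver of whether the
encounter becomes cooperation, exploitation, or open conflict. `hawkdove`
implements a quantitative decision model for a dyad with trait values
`x > y > 0` (the larger and smaller player): four size-based descriptors
quantify the strength of each interaction type,

| interaction | descriptor |
|---|---|
| mutualism   | `z_mu = x·y / (x − y)` |
| antagonism  | `z_an = 1 / (x·y·(x − y))` |
| aggression  | `z_ag = x / y` |
| altruism    | `z_al = (x − y) / x` |

and, relativized by the antagonism (hawk/hawk) term, they form the
well-behaved hawk–dove reward matrix

```
              Y dove        Y hawk
  X dove    x² y²         y (x − y)²
  X hawk    x² (x − y)        1
```

Solving the break-even equations of this matrix at the normalization `x = 1`
yields four analytic behavioral thresholds on the size ratio `ρ = y/x`:

- **golden-section threshold** `φ = (√5 − 1)/2 ≈ 0.618` (root of
  `y² + y − 1 = 0`): a larger player exploits a dove below 62% of its size
  and cooperates above it;
- **hawk shift** `≈ 1.755` (root of `y(1 − y)² = 1`): a larger player always
  meets a smaller hawk with aggression — non-aggression breaks even only if
  the hawk reversely outgrows it by 75%;
- **Fibonacci retracement mark** `1 − φ ≈ 0.382` (root of `y² − 3y + 1 = 0`
  in (0, 1)): the switch point of a smaller player's best response to a
  larger dove;
- **surrender point** `0` (from `x²(x − y) = 1` at `x = 1`): against a larger
  hawk, resistance dominates surrender over the whole ratio range.

Around this core the package provides the two validation arms such a model
needs, exercised end-to-end on synthetic data with known ground truth:

- **co-culture arm** — empirical interaction strengths `Mu`, `Ag`, `Al` from
  paired co-culture/monoculture abundance trajectories; Gompertz, logistic
  and Richards growth-curve fitting (Zwietering parameterization) with
  F-test/AICc model selection and lag/linear/asymptotic phase partitioning;
  per-phase correlation of each descriptor with its empirical counterpart.
- **cohort arm** — the four descriptor networks plus a SNP
  identity-by-state relatedness network over a cohort, hierarchy roles
  (primary/secondary/tertiary leaders, followers; hawks/doves;
  altruists/egoists; core/periphery), tier body-mass ratio tests against
  `φ` and `1 − φ`, and between-network correlations.
- **generators** — seeded trait cohorts with plantable tier-ratio bands,
  coupled-logistic co-culture dynamics with controllable interaction sign
  and strength, and Mendelian full-sib genotype matrices.

## Worked example

```r
library(hawkdove)

p <- size_pair(580, 395, "fish07", "fish23")   # body masses in grams
compute_descriptors(p)
#> interaction descriptors (fish07 vs fish23):
#>   mutualism  z_mu = 1238.38
#>   antagonism z_an = 2.35941e-08
#>   aggression z_ag = 1.46835
#>   altruism   z_al = 0.318966

predict_strategy(p, "larger", "dove")
#> larger player vs dove opponent at ratio 0.6810 -> cooperate
#>   (payoff 0.4638 over 0.3190; threshold 0.6180)
```

The smaller fish is 68.1% of the larger one's mass — above the
golden-section threshold of 61.8% — so the larger player's dove/dove payoff
(`ρ² = 0.464` at the normalization `x = 1`) beats its hawk/dove payoff
(`1 − ρ = 0.319`): cooperation is optimal. Below 61.8% the inequality flips
and exploitation pays.

The threshold constants themselves:

```r
unlist(conflict_thresholds())
#>             phi      hawk_shift        fib_mark surrender_point
#>        0.618034        1.754878        0.381966        0.000000
```

A full synthetic analysis (networks, roles, tier tests, co-culture
validation) is one call:

```r
cohort <- generate_cohort(n = 71, seed = 1)
res <- run_pipeline(traits = cohort[, c("id", "trait")], out_dir = "out")
```

See `vignettes/conflict-decision-theory.Rmd` for the model, its assumptions,
and every tunable default.

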