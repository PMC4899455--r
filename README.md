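# rootforage

Analysis toolkit for split-pot root-foraging experiments: greenhouse designs
in which each plant grows in a pot whose two halves receive different
fertilizer doses (no, shallow, or steep contrast), the pot is bisected at
harvest, and the dry root mass of each half is weighed. The question such
experiments ask is comparative: which plant species actively place their
roots in the nutrient-rich patch, and which life-history traits (clonality,
reproduction potential, leaf economics, stature) predict that behaviour?

The package covers the whole analysis chain — per-pot scores, species-level
nonparametric effect sizes with bootstrap stability, scale-aware trait
correlations, and phylogenetic comparative checks — plus a synthetic-data
generator with known ground truth so every stage can be validated end to end
without any external data.

## The statistics at the core

* **Precision** of root placement in a pot is the size-invariant log ratio

  ```
  p = ln( mass_rich / mass_poor )
  ```

  Zero means indifferent placement; positive means more roots in the rich
  half. For no-contrast control pots the halves are oriented by a seeded
  fair coin flip, so the control distribution is symmetric by construction.
  Balance data like these are typically skewed (checked with the robust
  medcouple), so all downstream summaries are medians and ranks.

* **Foraging** response of a species under one contrast is the centered
  Mann–Whitney effect comparing its treated pots with its control pots:

  ```
  foraging = U / (m · n) − 0.5   ∈ [−0.5, +0.5]
  ```

  with `U` counting treated-over-control pairs (ties ½), `m` control pots
  and `n` treated pots. It equals the tie-aware probability of superiority
  minus ½. **Plasticity** is its absolute value — the directionless amount
  of response, counting rich-patch avoidance too.

* **Stability** of each response is the middle-half width (0.75 − 0.25
  quantile distance) of 1,000 ordinary-bootstrap replicates of the effect.

* Treatment efficacy is tested by **paired Wilcoxon** tests on species
  medians (control vs each contrast, Bonferroni ×2 because the control data
  are used twice), with an exact tie-aware null distribution up to 25 pairs.

* Trait–response association uses **Pearson's r** for continuous traits
  (SLA, log leaf area, height, lateral spread) and **Spearman's ρ** for
  ordinal/binary ones (reproduction potentials, shoot lifespan, clonality),
  with pairwise-complete deletion of missing cells.

* Phylogenetic structure is handled by **Pagel's λ** (profiled ML on
  `[0, 1]`, profile-likelihood CI, boundary-corrected LRTs against 0 and 1)
  and **PGLS** regressions of responses on traits (ML λ, plus λ = 1
  Brownian-motion parallel checks).

## Worked example

Simulate a study at the default conditions — 37 species on a pure-birth
phylogeny, 3 treatments × 10 pots per species, clonal species' foraging
strength lowered by 0.5 — and run the full pipeline:

```r
library(rootforage)

cfg <- run_config(
  synthetic = list(n_species = 37, pots_per_cell = 10),
  n_boot = 1000, seed = 1
)
report <- run_pipeline(cfg)
report
#> Split-pot root foraging analysis
#>   species: 37, pots: 1110
#>   treatment tests (medians, Bonferroni x2):
#>   contrast statistic p.value p.adjusted n_pairs        method
#> 1      low       540 0.00457    0.00913      37 normal-approx
#> 2     high       539 0.00479    0.00957      37 normal-approx
#>   cross-contrast rho = 0.925 (p = 3.04e-16)
#>   stability comparison V = 584.5 (raw p = 9.61e-07)
#>   lambda (foraging) = 0.000, CI 0.00-0.44
```

Both contrasts shift root placement toward the rich half (adjusted p <
0.01); the two contrasts' species responses are strongly rank-correlated
(ρ = 0.925), so trait analyses use the high-contrast estimates; the
high-contrast responses are more stable (narrower bootstrap middle halves,
V = 584.5); and the responses carry no phylogenetic signal (λ̂ = 0, 95% CI
reaching only 0.44), as expected since the generator evolved nothing along
the tree.

```r
tidy(report$lambda$foraging)
#>   term   estimate conf.low conf.high p.vs.zero p.vs.one
#> 1 lambda        0        0     0.436         1 7.53e-17

head(render_table1(report), 3)
#>   block    row   sla    leaf_area height lateral_spread generative_repro ...
#> 1 FORAGING r/rho -0.024 0.252     0.0698 -0.165         -0.151
#> 2 FORAGING n     37     34        37     18             35
#> 3 FORAGING p     0.888  0.15      0.681  0.513          0.385
```

The built-in clonality coupling comes back out of the association table:
`report$association` shows clonality × foraging ρ = −0.65 (p ≈ 1.5e-05)
while the uncoupled traits sit near zero. Each stage is also available as a
plain function on tibbles (`compute_precision()`, `species_responses()`,
`association_table()`, `ml_lambda()`, `pgls_fit()`, ...), and
`plot_precision_by_treatment()`, `plot_response_by_contrast()`,
`plot_response_by_trait()` and `plot_lambda_profile()` draw the standard
diagnostic figures.

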