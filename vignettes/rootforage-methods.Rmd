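---
title: "Methods: split-pot root foraging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-pot root foraging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootforage)
```

This vignette documents the statistical model behind `rootforage`, the
choices made where the methodology was genuinely open, and what the
synthetic-data validation does and does not establish.

## The measurement model

A split-pot experiment bisects each pot at harvest and weighs the dry root
mass of the nutrient-rich and nutrient-poor halves. The per-pot score is the
*precision*

$$p = \ln\frac{m_\text{rich}}{m_\text{poor}},$$

which is invariant to overall plant size (multiplying both halves by any
$c > 0$ leaves $p$ unchanged), so it isolates the size-independent — active —
component of the allocation response from passive growth effects. Pots with
a zero or missing half-mass are excluded with a logged warning, never
imputed: $\ln 0$ has no defensible fill value, and exclusion mirrors the
field practice of dropping individuals whose roots are too small to process
reliably.

Control pots have no gradient, so "rich" and "poor" are meaningless labels.
`assign_control_halves()` orients each control pot by a seeded fair coin
flip, which makes the control precision distribution symmetric *by
construction* regardless of any physical left/right bias. An alternative
reading — fixing the orientation at harvest — would differ only by per-pot
sign flips; the seeded randomization was chosen because it is reproducible
and guarantees the symmetry the downstream null tests rely on.

Balance data of this kind are substantially skewed even in controls; the
package reports the robust medcouple (bounded in $[-1,1]$, computed by the
exact $O(n^2)$ kernel with the standard sign kernel for observations tied at
the median) as a diagnostic. Because per-cell sample sizes are small, no
fast medcouple algorithm is needed. The skewness motivates the use of
medians for species-by-treatment summaries and of rank statistics
throughout; the medcouple itself gates nothing.

## Species-level responses

For one species, the response to one contrast is the centered Mann–Whitney
effect

$$\theta = \frac{U}{m\,n} - \tfrac12 \in [-0.5, +0.5],$$

where $U$ counts treated-over-control pairs with ties scored ½ ("foraging");
its absolute value is "plasticity". The orientation of $U$ is fixed so that
positive values mean allocation toward the rich half — with that convention
figures and tables read directly as foraging intensity. $\theta$ is computed
via the midrank rank-sum identity and is antisymmetric, bounded, and
invariant under strictly monotone transforms of the data; the test suite
checks all three plus exact agreement with brute-force pair counting.

Treatment efficacy is tested by paired Wilcoxon signed-rank tests on the
species' median precisions (control vs low, control vs high). Because the
control medians enter both tests, p-values are Bonferroni-multiplied by 2.
Whether such tests should run on medians or some other per-species summary
is ambiguous in parts of the literature; medians were chosen here for
consistency with the median-based cell summaries. Zero differences are
dropped before ranking and tied absolute differences receive midranks. For
$n \le 25$ pairs the two-sided p is exact, computed from the full null
distribution of $V$ by convolution over doubled midranks (equivalent to
enumerating all $2^n$ sign assignments, but $O(n \cdot \sum r)$); beyond
that a normal approximation with tie and continuity correction is used. The
threshold of 25 matches common practice and is configurable
(`exact_threshold`).

Stability of each response is estimated by the ordinary bootstrap: both
groups are independently resampled with replacement at their original sizes,
$\theta$ recomputed, and the *middle half* — the distance between the 0.25
and 0.75 quantiles of `n_boot = 1000` replicates — reported (large =
unstable). Quantiles use linear interpolation of order statistics
(`stats::quantile` type 7), a rule that had to be fixed somewhere and is
documented here. Input groups are sorted before resampling so the seeded
width is exactly invariant to pot relabeling. Stability widths are compared
across contrasts with the paired Wilcoxon test; that comparison is reported
with its raw p-value since it involves no reuse of a reference sample.

The low- and high-contrast responses are strongly correlated across species,
so only the high-contrast estimates enter trait analyses
(`response_cross_correlation()` quantifies this with Spearman's ρ).

## Trait associations

The correlation method follows the trait's measurement scale, never the
data: Pearson's $r$ for continuous traits (SLA in m²/g, natural-log leaf
area in m², height at maturity in m, lateral spread in m), Spearman's $\rho$
for ordinal and binary ones (generative and vegetative reproduction
potential on the 1..5 garden-expansion scale, shoot lifespan as a two-level
ordinal, clonality 0/1). Shoot lifespan's two-level coding is treated as an
opaque ordinal — its exact semantics (1- vs 2-year shoots) do not matter for
a rank statistic. Missing cells are deleted pairwise per cell, so each
coefficient uses all species complete for *that* pair; lateral spread is
defined only for clonal species, so its rows automatically use the clonal
subset. Spearman p-values use the t approximation on the midrank ρ (the
tie adjustment is inherent in midranks); an exact permutation p is available
for $n \le 10$. Table cells are reported with raw p-values — the
association table is a descriptive screen, not a confirmatory family — but
`association_table(p_adjust = "holm")` adds an adjusted column for users who
want one.

## Phylogenetic comparative checks

Under Brownian motion the tip covariance is $V_{ij} = $ shared root-to-MRCA
path length. Pagel's λ rescales the off-diagonal of $V$; the package
profiles the MVN likelihood of an intercept-only model over $\lambda \in
[0,1]$, with mean and variance maximised analytically at each λ and the
optimum found by bounded scalar search (the optimizer's value is also
checked against a grid). The search is bounded at 1 rather than the
algebraic maximum because values above 1 have no interpretation as signal
and the CI/tests are framed on $[0,1]$. The 95% CI is the profile set
$\{\lambda: \ell(\lambda) \ge \ell(\hat\lambda) - 1.92\}$; LRTs against the
boundaries use the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture. On a star
phylogeny λ does not enter the likelihood and the fit is flagged
unidentifiable with CI $[0,1]$. Zero-length branches are nudged to a tiny
positive value ($10^{-8}\times$ depth, with a logged note) to protect the
Cholesky factorisation; non-ultrametric trees are accepted, with the
diagonal of $V$ taken from actual root-to-tip distances.

PGLS fits use GLS by whitening (Cholesky backsolve); the test suite verifies
the whitening route against the closed-form
$(X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ to $10^{-8}$ and against OLS at
λ = 0. Coefficient tests are t-based with $n - p$ degrees of freedom.
Binary clonality enters PGLS as a 0/1 Gaussian regressor — a known
approximation, flagged here as a caveat. λ is either ML-estimated jointly
with the regression or fixed at 1 as a Brownian-motion parallel check; both
tables are produced by the pipeline, and `phylo_association_check()` flags
any trait whose PGLS slope sign disagrees with the ordinary correlation.

## The synthetic generator

The generator is first-class, tested code: it defines the ground truth
against which the whole pipeline is validated.

* **Design.** Treatments are coded by contrast level 0/1/2 for
  control/low/high — a monotone coding of the dripper ratios (2:2, 3:1,
  4:0); rank statistics are unaffected by the specific values.
* **Precision.** Each pot draws
  $p = \delta \cdot \text{contrast} + \omega\,(z - \tilde z_\gamma)$, with
  $z$ a standard skew-normal of shape $\gamma$ and $\tilde z_\gamma$ its
  median (found numerically), so the *median* of $p$ is exactly
  $\delta \cdot \text{contrast}$ — the natural centering for a pipeline
  built on medians and ranks. Skewness is injected on the log-ratio scale
  because a single interpretable shape knob suffices to emulate the skewed
  balance data such experiments produce.
* **Masses.** Total root mass is lognormal$(\mu_T, \sigma_T)$ and split as
  $m_\text{rich} = T\,\text{logit}^{-1}(p)$, so recomputing $p$ from the
  masses reproduces the latent draw to floating-point accuracy (a round-trip
  the tests assert at $10^{-10}$). Size and allocation are generated
  independently: the analysis is size-invariant by design, so no
  size–allocation coupling is modelled.
* **Traits and tree.** The phylogeny is a Yule tree rescaled to unit depth;
  trait latents are MVN with covariance $V(\lambda_\text{true})$, mapped to
  positive continuous traits (lognormal transforms), 1..5 ordinals (quantile
  bins), a two-level shoot lifespan and binary clonality (median splits).
  Per-species foraging strength is
  $\delta_i = \bar\delta + \sigma_\delta z_i + c \cdot \text{clonality}_i$,
  so a negative $c$ encodes the clonal-plants-forage-less coupling with
  known sign and magnitude.
* **Defaults as study conditions.** 37 species, 10 pots per cell,
  $\bar\delta = 0.5$, $\sigma_\delta = 0.25$, $c = -0.5$, $\omega = 0.5$,
  $\gamma = 2$ (substantial right skew), $\mu_T = 0$, $\sigma_T = 0.5$
  (total root mass around 1 g, a realistic young-plant harvest),
  $\lambda_\text{true} = 0$ (no signal in the latents, matching the absence
  of phylogenetic signal this kind of response typically shows), and a 5%
  missing-cell rate on SLA, leaf area and generative reproduction,
  emulating database gaps (n ≈ 33/31/35 of 37). The replicate count per
  species×treatment is a free parameter (`pots_per_cell`) because real
  designs vary; 10 is the default study condition.
* **Randomness.** One master seed expands into fixed substreams (tree,
  traits, foraging strengths, pots, control orientation, bootstrap), so any
  stage can be regenerated independently and the whole pipeline is
  bit-reproducible given the seed.

What the generator does **not** emulate: greenhouse physics, irrigation
chemistry and temporal root growth; lateral spread as a spatial process;
genotype-level variation in plasticity; any dependence of allocation on
plant size; real measurement error in root washing and weighing. Passing
recovery tests therefore show the *statistical machinery* is correct and
calibrated under a plausible data-generating process — they do not show that
real split-pot data satisfy the generator's assumptions.

## Validation design and problem sizes

The acceptance suite validates each statistic against an independent route
and the pipeline against the generator's ground truth; the sizes below were
chosen to keep Monte-Carlo error far below the tested margins while running
comfortably on a laptop:

* exact-agreement checks: 1,000 random Mann–Whitney instances
  ($m, n \le 12$) vs pair-count enumeration; 200 signed-rank instances
  ($n \le 12$) vs $2^n$ enumeration; 60 medcouple samples ($n \le 50$,
  including forced median ties) vs naive kernel enumeration;
* λ recovery: 20 replicates each at $\lambda_\text{true} \in \{0, 0.5, 1\}$
  on 500-tip Yule trees (mean $\hat\lambda$ within ±0.1, ±0.15 at 0.5; CI
  coverage ≥ 85%);
* GLS two-route equivalence on 100 random instances at $10^{-8}$;
* coupling recovery over 100 seeds and null calibration over 200 seeds at
  the default study conditions;
* bootstrap-width consistency over 20 seeds at 10 vs 40 pots per cell.

## Known limitations

* The Mann–Whitney effect is granular at small $m, n$ (steps of
  $1/(mn)$), so species-level responses from small designs are coarse; the
  bootstrap middle half makes that visible rather than hiding it.
* The skew-normal is one convenient skewed family; real balance data may be
  heavier-tailed. All downstream statistics are rank-based precisely so the
  family choice matters little.
* Spearman p-values for $n$ in the 30s rely on the t approximation;
  deviations at extreme ρ are negligible at that size but the exact option
  exists for very small panels.
* PGLS with a binary regressor treats a 0/1 variable as Gaussian; sign and
  approximate magnitude of slopes are meaningful, exact p-values less so.
* λ estimated on 30–40 tips has wide profile CIs by nature; the package
  reports the CI rather than pretending precision.
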