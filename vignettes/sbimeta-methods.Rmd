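---
title: "Methods: multilevel meta-analysis of intercropping effects on soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel meta-analysis of intercropping effects on soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbimeta)
```

## The problem

Soybean-based intercropping (SBI) — soybean grown in strips with maize or
another companion crop — changes the soil environment that microbial
communities inhabit. Individual paired experiments report the response of
microbial alpha-diversity (Shannon, Chao1, richness), beta-diversity,
community structure, and crop yield to intercropping versus monoculture,
but single studies are small and heterogeneous. `sbimeta` implements the
full quantitative-synthesis pipeline for such paired
monoculture-versus-intercropping databases: effect-size construction,
study-nested random-effects pooling, subgroup and dose-response moderator
analyses, and publication-bias diagnostics, together with a seeded
synthetic database generator so that every stage can be exercised against
known truth.

## Effect sizes

For a trait with treatment (intercropping) mean $\bar{x}_t$ and control
(monoculture) mean $\bar{x}_c$, the effect size is the log response ratio

$$\mathrm{lnRR} = \ln \bar{x}_t - \ln \bar{x}_c,$$

with sampling variance built from the arm standard deviations $s_t, s_c$
and sample sizes $n_t, n_c$:

$$v = \frac{s_t^2}{n_t \bar{x}_t^2} + \frac{s_c^2}{n_c \bar{x}_c^2}.$$

Both arms must have strictly positive means; the variance depends on the
arms only through their coefficients of variation (CVs), so it is invariant
to unit changes.

**SD imputation.** Studies that report means without dispersion are
common. For those rows the missing SD is estimated as the reported mean
times an average CV taken from the rows that do report SDs. The pooling
stratum for that average is a genuine design choice: averaging globally
lets a high-CV trait (e.g. yield in t/ha) contaminate a low-CV index
(Shannon on a log-ish scale). The default therefore pools CVs **per trait
and per arm** (treatment CVs separately from control CVs within each
trait); `pool = "global"` restores a single pooled CV. Imputation never
touches a reported SD and is idempotent; rows in a stratum with *no*
reported SD at all cannot be imputed and are dropped from
variance-weighted fits with a warning rather than given a made-up unit
variance.

**Planting-density standardization.** Density differences between
intercrops and sole crops are expressed with the relative density total,
$\mathrm{RDT} = d_{1,ic}/d_{1,sc} + d_{2,ic}/d_{2,sc}$ (1 = replacement
design, >1 = additive design) and the soybean-specific ratio
$\mathrm{pRDT} = d_{ic}/d_{sc}$. Observations with a *measured* RDT below 1
are excluded by `filter_rdt()`; rows with unknown RDT are retained, since
the exclusion criterion is the measured density, not missingness. When a
study spans several seasons only its final-year rows enter the analysis
(`select_final_year()`); a study with no flagged final-year row keeps all
its rows with a warning instead of silently disappearing.

## Ordination-derived statistics

Published beta-diversity and structure results usually arrive as 2-D
ordination plots (NMDS, PCA, PCoA, RDA). Given sample coordinates on the
first two axes, the package computes mean pairwise Euclidean distances
over three index sets: within control ($D_c$), within treatment ($D_t$),
and between groups ($D_b$). Only the first two axes are used, with no
weighting by explained variance — matching how coordinates are extracted
from published figures.

The beta-diversity response ratio is the dispersion contrast
$\mathrm{lnRR}_b = \ln(D_t/D_c)$.

For community **structure** two conventions are supported, because they
answer different questions:

* `"as_printed"`: $\ln\!\big(D_t/(D_c+D_t)\big)$. This quantity is
  *bounded above by zero* for positive distances — it cannot express a
  positive structure shift, and large reported positive structure effects
  are impossible under it.
* `"between_within"` (default):
  $\ln\!\big(D_b \,/\, \tfrac{1}{2}(D_c+D_t)\big)$ — between-group
  separation relative to mean within-group dispersion. It is
  approximately 0 for coincident groups and grows monotonically with
  centroid separation, so positive values mean "intercropping moved the
  community".

Because the two conventions disagree in sign behaviour, the pipeline's
ordination report emits **both** columns on every row, and the default is
the sign-consistent `between_within` form. Degenerate groups (all samples
coincident) yield a within-distance of exactly 0 and are flagged; log
ratios are refused rather than returning `-Inf`.

## The pooling model

Observations are nested in studies and are not independent. The pooling
model is the minimal structure honouring that nesting:

$$y_{ij} = \mu + b_i + u_{ij} + e_{ij}, \qquad
  b_i \sim N(0, \tau^2_{study}),\;
  u_{ij} \sim N(0, \tau^2_{obs}),\;
  e_{ij} \sim N(0, v_{ij}),$$

with the sampling variances $v_{ij}$ treated as known (the standard
meta-analytic contract). Variance components are estimated by REML.

**Numerics.** The restricted likelihood is maximized by Fisher scoring
with step-halving. Scoring is performed on the $\tau^2$ scale with
projection onto $\tau^2 \ge 0$ (an active-set rule keeps a component at
the boundary when its score points outward); the natural scale is what
makes the projection well defined, and step-halving guarantees monotone
likelihood ascent. Convergence is declared when the restricted
log-likelihood changes by less than $10^{-8}$, with a cap of 200
iterations. A component that ends at the boundary is reported as exactly
0, not an epsilon. Two degeneracies are handled explicitly: a single
effect returns $(\mu, se) = (y, \sqrt{v})$ with zero heterogeneity, and a
database where every study contributes exactly one observation makes the
two components unidentifiable ($ZZ' = I$), so a single heterogeneity
component is estimated and reported as $\tau^2_{study}$.

**Inference** is Wald-type: $\mu \pm z_{1-\alpha/2}\,se$, and an effect is
called significant when its CI does not cross zero — the conventional
default of the standard multilevel meta-analytic tooling. (A t-type
alternative with containment degrees of freedom would widen small-$k$
intervals; Wald is used throughout and stated in every output.)

**Subgroups.** A categorical moderator is fitted as one pooled mean per
level (no intercept), and the omnibus moderator test $Q_M$ is the Wald
chi-square for equality of all level means, with $df = L - 1$. After a
significant $Q_M$, all pairwise level contrasts receive **single-step
adjusted p-values** from the max-$|z|$ distribution of the joint normal of
the contrasts — the Tukey-style family-wise correction. The tail
probability is approximated with 100,000 seeded Monte-Carlo draws from the
contrast correlation; with one contrast the adjusted p equals the raw
two-sided p exactly, adjusted p is clamped to be $\ge$ the raw p (true
analytically, enforced against Monte-Carlo noise), and a singular contrast
covariance falls back to Bonferroni with a warning. The test suite checks
the Monte-Carlo answer against numerical integration
(`multcomp::glht`, single-step) to ~0.01.

## Publication bias

The Rosenthal fail-safe number is the count of hypothetical zero-effect
studies needed to lift the Stouffer-combined one-tailed p above $\alpha$:
$N_{fs} = \lfloor (\sum_i z_i)^2 / z_\alpha^2 - k \rfloor$ with
$z_i = y_i/\sqrt{v_i}$, floored at 0. One-tailed $\alpha = 0.05$ is the
classical convention. The synthesis is called robust when
$N_{fs} > 5k + 10$.

The Begg-type rank test correlates the variance-standardized deviates from
the **fixed-effect** pooled mean (the classical form of the test, not the
multilevel $\mu$) with the sampling variances using Kendall's $\tau_b$.
For $k \le 8$ the two-sided p-value is exact by full enumeration of the
permutation distribution; beyond that, a normal approximation of the
concordance statistic with continuity and tie corrections is used.

## Continuous moderators and the yield-diversity dose-response

Meta-regression is weighted least squares with weights
$1/(v_i + \hat\tau^2)$, where $\hat\tau^2 = \hat\tau^2_{study} +
\hat\tau^2_{obs}$ comes from a preliminary intercept-only multilevel fit
and is **reused across candidate forms** — re-estimating $\tau^2$ per form
would make the information criteria incomparable. Candidates are linear
and quadratic only (the forms the dose-response analyses require); AIC
decides, ties go to lower BIC, then to fewer parameters. AIC/BIC come from
the Gaussian likelihood with known per-observation variances
$v_i + \hat\tau^2$, the weighted $R^2$ is computed about the weighted mean
and clamped to $[0,1]$, and the model p-value is the Wald chi-square on
the slope coefficient(s).

For a selected concave quadratic, `quadratic_summary()` returns the
turning point $x^\* = -b_1/(2b_2)$, the real roots of the fitted curve,
and the open interval where the fitted lnRR is positive — the
"yield-advantage window" of the diversity-yield relationship.

**Mantel tests** between distance matrices use the Pearson correlation of
strictly-lower-triangle entries; the permutation p permutes rows/columns
of the second matrix jointly and uses the add-one estimator
$(1 + \#\{r^{perm} \ge r\})/(1 + n_{perm})$, which can never return an
exact zero. For small $n$ an exhaustive mode enumerates all $n!$
relabelings. The partial Mantel test correlates residuals after linear
regression of both triangles on the conditioning triangle; a matrix fully
explained by the conditioner has partial $r = 0$ by convention.

**Moderator importance** fits a random-forest regressor (`ranger`, seeded,
500 trees) on a 70% training split and scores each predictor by the mean
increase in held-out mean-squared error over 10 seeded permutations of its
column. Permutation importance is used instead of impurity importance
because it is comparable across mixed-type predictors; a held-out split is
used so the baseline error is a genuine out-of-sample quantity.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` fixes the simulated study conditions:

* **Scale**: 89 studies, 4 observations each — the size of a typical
  published SBI synthesis corpus (a few hundred observations from ~90
  articles).
* **True effects** `mu_true`: per-trait lnRRs of a few percent for the
  alpha-diversity indices (0.036 Shannon, 0.034 Chao1, 0.102 richness), a
  weak negative beta-diversity response (-0.098), a large positive
  structure shift (0.741), and a near-zero yield response (-0.020) —
  effect magnitudes representative of this literature.
* **Heterogeneity**: $\tau_{study} = 0.05$, $\sigma_{obs} = 0.03$ —
  between-study spread comparable to the trait effects themselves, as is
  typical for field studies.
* **Measurement**: lognormal control means (all means positive by
  construction), arm CVs of 15% with 4 replicates per arm (field-trial
  replication), CV perturbed by ±10% per arm, and 10% of arm SDs masked
  missing to exercise the imputation path.
* **Moderator structure**: nitrogen-source shifts are deviation-coded
  (mean zero: mixed +0.05, organic 0, mineral -0.03, none -0.02) so that
  subgroup contrasts exist while the trait-level estimand remains
  `mu_true`.
* **Dose-response link**: yield lnRR is a concave quadratic in Shannon
  lnRR with roots at 0.008 and 0.401 — a bounded yield-advantage window —
  plus Gaussian noise (SD 0.02). The implied turning point is the root
  midpoint, 0.2045.
* **Reproducibility**: one RNG stream per (seed, study) pair, so a fixed
  seed yields byte-identical databases and *adding studies never
  reshuffles earlier ones*.

The generator deliberately does **not** emulate: the empirical covariate
distributions of any real article corpus, correlations between moderators
and covariates, selective reporting (its sampling is unbiased by
construction), non-normal effect distributions, or within-study
correlation structures richer than a shared intercept. Passing the
recovery and calibration tests therefore demonstrates that the estimators
are correct under the stated model, not that any particular real-world
database satisfies that model.

## Problem sizes used by the test suite

The suite is sized to run comfortably on a single CPU: parameter recovery
uses 200 replicate databases of 30 studies x 3 observations (true
lnRR 0.05, $\tau_{study} = 0.05$, $\sigma_{obs} = 0.03$, seeds 1-200);
type-I error control uses 500 null replicates each for the $Q_M$ omnibus
test (30 studies x 3) and the Begg-Kendall test ($k = 20$); Monte-Carlo
convergence checks for the ordination statistics use clouds of 200-500
points. These sizes give Monte-Carlo standard errors well inside the
asserted bands.

## Known limitations

* Sampling variances are treated as known; no allowance is made for their
  estimation error in small arms.
* Wald intervals undercover slightly for very small numbers of studies;
  with ~30 studies the measured coverage is 96-98%.
* The `as_printed` structure convention is retained only for audit
  purposes; analyses of positive structure shifts must use
  `between_within`.
* Meta-regression reuses a single $\tau^2$ across forms; a
  full profile-likelihood per form is not implemented.
* The CLI is a thin veneer (`inst/cli/sbimeta.R`); the package functions
  are the primary interface.
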