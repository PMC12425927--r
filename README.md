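# sbimeta

Meta-analysis of soybean-based intercropping (SBI) effects on soil
microbial community traits and crop yield.

## What it is for

Field experiments that pair soybean intercropping against monoculture
report soil microbial responses — alpha-diversity (Shannon, Chao1,
richness), beta-diversity, community structure — and soybean yield, but
individually they are small, heterogeneous, and nested (several
observations per article). `sbimeta` is the synthesis layer for such a
study database: it validates and filters the observation table, builds
effect sizes, pools them with a study-nested multilevel model, and runs
the moderator, dose-response and publication-bias analyses a full
meta-analysis requires. A seeded synthetic database generator with known
truth makes the whole pipeline testable end to end.

## The model in brief

Each paired observation contributes a log response ratio and its sampling
variance,

```
lnRR = ln(x_t) - ln(x_c),      v = s_t^2/(n_t x_t^2) + s_c^2/(n_c x_c^2),
```

and the pooled effect per trait comes from the multilevel random-effects
model

```
y_ij = mu + b_i + u_ij + e_ij,   b_i ~ N(0, tau2_study),
                                 u_ij ~ N(0, tau2_obs),  e_ij ~ N(0, v_ij),
```

fitted by REML (Fisher scoring with step-halving; variance components
projected onto >= 0), with Wald 95% CIs and the CI-crosses-zero
significance rule. Around that core: CV-based SD imputation, RDT/pRDT
planting-density filters, ordination-coordinate conversion into
beta-diversity/structure response ratios, subgroup Q_M omnibus tests with
single-step (Tukey-style) post hoc comparisons, Rosenthal fail-safe N with
the 5n+10 robustness rule, the Begg-Kendall rank test, weighted
linear/quadratic meta-regression with AIC/BIC selection and turning-point
extraction, Mantel / partial Mantel permutation tests, and
permutation-importance ranking of moderators with a random forest.
See `vignettes/sbimeta-methods.Rmd` for the full methods account.

## Worked example

```r
library(sbimeta)

spec <- synthetic_spec(seed = 42)        # 89 studies, known per-trait truth
db   <- generate_observations(spec)      # 356 validated observations

cfg <- run_config(db = db, traits = c("shannon", "structure", "yield"),
                  seed = 42)
run_overall(cfg)
#>       trait  k n_studies       mu  ci_low ci_high significant
#> 1   shannon 70        51  0.04702  0.0223  0.0717        TRUE
#> 2 structure 62        50  0.74200  0.7155  0.7685        TRUE
#> 3     yield 53        40 -0.00453 -0.0330  0.0240       FALSE
```

Each row is a pooled lnRR with its Wald 95% CI: at this seed the synthetic
database (true Shannon effect 0.036, structure 0.741, yield -0.020)
is recovered as a significant ~4.7% Shannon increase, a large significant
structure shift, and a yield response indistinguishable from zero —
the CI-crosses-zero rule drives the `significant` column.

```r
eff <- compute_effect_sizes(impute_sd(db))
fit_multilevel_re(eff[eff$trait == "shannon", ])
#> Multilevel random-effects meta-analysis
#>   k = 70 observations, 51 studies
#>   tau2 (study) = 0.00000, tau2 (obs) = 0.00000
#>   pooled lnRR = 0.0470 (SE 0.0126), 95% CI [0.0223, 0.0717], z = 3.734, p = 0.0001884
#>   Q_total = 28.324 (df = 69)

bias_report(eff[eff$trait == "shannon", ])
#> Publication-bias report
#>   fail-safe N = 283 (threshold 5n+10 = 360) -> not robust
#>   Kendall tau = -0.0932, p = 0.2561
```

A small true effect (0.036) needs only 283 hypothetical null studies to be
overturned — below the 5n+10 threshold of 360 — while the Kendall test
finds no variance-effect association; both diagnostics behave as expected
for a weak, unbiased signal.

A command-line front end over the same functions lives at
`inst/cli/sbimeta.R`:

```sh
Rscript inst/cli/sbimeta.R simulate --out demo --seed 4
Rscript inst/cli/sbimeta.R report --input demo/simulated_observations.csv \
    --ordination demo/simulated_ordination.csv --out demo --seed 4
```

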