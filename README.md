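# dietnet

Dietary pattern networks and cardiometabolic risk factors.

Nutritional epidemiology has a multicollinearity problem: fatty acids travel
together in foods, so high intake of one implies high intake of several
others, and regression adjustment for 31 collinear nutrient intakes is
hopeless. A practical alternative is to cluster *people* by their whole
intake profile and use the cluster labels as exposures. `dietnet` implements
that analysis end to end for dietary fatty acids and fat-spread usage
(butter, margarines, blends), as used in repeat cross-sectional cohort
studies of young adults:

1. **Pattern detection.** Subjects are averaged over their two study visits,
   z-standardized, and linked to their K = 20 nearest neighbours
   (Euclidean). Edges are weighted by the cosine similarity of the two
   subjects' intake vectors, non-positive weights are dropped, and
   communities are found by multi-level Louvain maximization of the weighted
   Newman–Girvan modularity

   Q = (1/2m) Σᵢⱼ [Aᵢⱼ − γ kᵢkⱼ/2m] δ(cᵢ, cⱼ),

   with seeded restarts and a final refinement sweep.

2. **Association models.** Each risk factor (systolic/diastolic blood
   pressure, pulse pressure on the identity scale; triglycerides,
   cholesterol, HDL, non-HDL and HOMA-IR on the natural-log scale, reported
   as geometric-mean ratios) is regressed on the fatty-acid cluster and the
   spread cluster simultaneously, separately by sex, with both visits
   stacked. Standard errors come from the subject-clustered sandwich
   V = (X'X)⁻¹ (Σ_g X_g'û_g û_g'X_g) (X'X)⁻¹ · G/(G−1)·(N−1)/(N−p).
   A familywise Wald gate per exposure factor (Hotelling-style
   F(q, G−q) reference, α = 0.05) must pass before individual
   cluster-versus-reference contrasts are interpreted.

3. **Missing covariates.** Multiple imputation by chained equations
   (predictive mean matching for categorical covariates, Bayesian linear
   regression otherwise; m = 20 completed datasets), pooled with Rubin's
   rules (Barnard–Rubin degrees of freedom) and the D1 statistic for the
   gates.

Because the motivating cohort data are access-restricted, the package ships
a **synthetic cohort generator** (`generate_cohort()`) that plants known
cluster structure and outcome effects: correlated log-normal fatty-acid
profiles, zero-inflated spread usage patterns with structural zeros, two
correlated visits per subject, sex-specific blood-pressure baselines, and
missing-at-random covariates. Every stage of the pipeline is tested against
this known ground truth.

## Worked example

Plant a +8 mmHg systolic effect for males in spread pattern 2, run the full
pipeline, and read off the recovered contrast:

```r
library(dietnet)

effects <- data.frame(exposure = "spread", cluster = 2, outcome = "sbp",
                      effect = 8, sex = "male")
cfg <- cohort_config(n_subjects = 600, seed = 7, effect_table = effects)
run <- run_pipeline(cfg, m_imputations = 5, outcomes = c("sbp", "trig"))
run
#> dietnet_run
#>   fatty acids : 8 clusters, Q = 0.853
#>   fat spreads : 10 clusters, Q = 0.899
#>   cross-tab   : chi-square = 45.3, 63 df, p 0.955
#>   models      : 128 pooled contrasts, 41 under a passing gate
```

Both planted structures are recovered exactly (adjusted Rand index 1.0
against `planted_truth()`), the fatty-acid regime shows strong modularity
(Q = 0.85) and the sparser spread-usage regime even stronger (Q = 0.90).
The planted pattern surfaces as detected label 9; in the adjusted male
systolic model its contrast against the "no spreads" reference is:

```r
subset(as.data.frame(run$results),
       outcome == "sbp" & sex == "male" & model == "model2" &
       exposure == "spread_cluster" & level == "9")
#>  level estimate   se ci_lo ci_hi        p  gate_p
#>      9     8.61 2.32  4.05  13.2 0.000226 0.00991
```

The familywise gate passes (p = 0.0099), so the +8.61 mmHg
(95% CI 4.1–13.2) contrast is interpretable — and covers the planted
+8 mmHg. Per-cluster intake profiles (`run$profiles`), Table-1-style
descriptives (`describe_cohort()`) and plot-ready tidy results are part of
the bundle; `write_bundle()` persists everything as CSV/JSON.

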