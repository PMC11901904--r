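---
title: "Dietary pattern networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary pattern networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dietnet)
```

This vignette is the package's account of the statistics it implements: the
clustering model and its assumptions, the association models, the imputation
machinery, what the synthetic cohort generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## 1. The problem

Fatty acids are consumed together: butter drives up butyric through stearic
acid jointly; oily fish drives the long-chain n-3s. Regressing a risk
factor on 31 collinear intakes, or adjusting for them, fails (the curse of
dimensionality in nutrient space). The approach here replaces the nutrient
axes with *people patterns*: subjects are clustered by their whole intake
profile, and cluster membership becomes a categorical exposure in ordinary
epidemiological models. The same machinery is applied twice — once to 31
fatty-acid intakes and once to fat-spread usage (5 spread types plus a
"no spread" indicator) — and both cluster factors enter every outcome model
simultaneously, so each is estimated net of the other.

## 2. Pattern detection

**Intake matrix.** Per subject, each intake is averaged over the two study
visits (ages 20 and 22), then each column is z-standardized
(`build_intake_matrix()`). Standardization is a deliberate choice the
method's description leaves open: raw g/day ranges differ by three orders
of magnitude (palmitic ≈ 24 g/day vs docosahexaenoic ≈ 0.25 g/day), and
unscaled Euclidean distances would be dominated by the two or three major
fatty acids. `standardize = FALSE` restores raw distances. For the spreads
the default layout keeps the two visits as separate columns (5 intakes +
the no-spread indicator per visit, 12 columns); a visit-averaged 6-column
layout is available via `layout = "averaged"`. The 12-column form is the
default because spread usage is sparse and pattern changes between visits
are themselves informative.

**K-NN graph.** Each subject is linked to its K = 20 nearest neighbours in
the standardized space (exact search; ties broken by smaller subject index
so results are reproducible). Pairs linked in either direction share an
undirected edge (union symmetrization — keeps the graph connected at small
K; `mutual` is available), weighted by the cosine similarity of the two
subjects' standardized intake vectors. Cosine weighting of K-NN pairs is
the most literal reading of "transform the K-NN distances into edge
weights"; a shared-nearest-neighbour Jaccard weighting
(`weighting = "snn_jaccard"`) is provided as a labelled alternative, not
the default. Edges with non-positive weight are dropped
(`min_similarity = 0`): modularity with negative weights is not
well-defined in the standard form below.

**Louvain.** Communities maximize the weighted Newman–Girvan modularity
$$Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \gamma\frac{k_ik_j}{2m}\Big]\,\delta(c_i,c_j),$$
with resolution $\gamma = 1$ by default (the cluster counts are meant to
*emerge*, not be set). The optimizer is the standard two-phase scheme —
greedy single-node moves with incremental gains until no move improves Q by
more than `tol = 1e-7`, then aggregation of communities into super-nodes
(intra-community weight becomes a self-loop) — iterated until a pass adds
nothing. Two additions materially improve solution quality and cost little:

* a **refinement sweep** on the original graph, started from the coarse
  solution, which escapes optima locked in by aggregation; and
* per restart, a second candidate run started from a **random coarse
  partition** rather than singletons.

With the default 5 restarts this attains the exhaustively-enumerated
modularity optimum on essentially every random graph of up to 8 nodes the
test suite throws at it, and never exceeds it (the enumeration oracle is
part of the suite). Sweep order is Louvain's only stochastic element; all
of it is derived from one seed, so a fixed seed gives a byte-identical
partition. Singleton and disconnected components simply remain their own
communities; no post-hoc merging is done (real analyses report clusters as
small as a few dozen subjects). `relabel_by_size()` renames communities in
decreasing size order (ties: earliest member) for stable reporting.

## 3. Association models

Each outcome is modelled on both visits' rows (two per subject). Blood
pressures and pulse pressure stay on the identity scale (coefficients are
mean differences in mmHg); triglycerides, total/HDL/non-HDL cholesterol and
HOMA-IR are natural-log transformed, and coefficients are reported as
geometric-mean ratios, $100(e^\beta - 1)$ percent change. The log-Gaussian
route (rather than, say, a Gamma GLM with log link) is chosen because it
inverts exactly to the percent-change reporting convention. Model 1 is
unadjusted; Model 2 adjusts for age, waist–hip ratio, family history of
hypertension, healthy and Western diet factor scores, fruit and vegetable
frequency, alcohol, sodium, METs/week and physical-activity category. The
adjustment set is configurable because the covariate inventory in such
studies varies. Sexes are analysed separately as hard-wired strata (the
motivating analyses found sex interactions), not via interaction terms.

**Cluster-robust covariance.** Repeated visits violate independence, so the
model-based covariance is replaced by the subject-clustered sandwich
$$V = (X'X)^{-1}\Big(\sum_g X_g'\hat u_g\hat u_g' X_g\Big)(X'X)^{-1}
\cdot \frac{G}{G-1}\cdot\frac{N-1}{N-p},$$
the CR1/Stata-style small-sample factor. With every cluster of size one
this reduces exactly to HC1, which the tests assert. The implementation is
plain matrix algebra; the suite checks it to 1e-8 against both a long-hand
oracle and `sandwich::vcovCL(type = "HC1")`.

**Familywise gate.** For each exposure factor the joint Wald statistic
$W = b'V_{bb}^{-1}b$ over its q non-reference coefficients is tested first;
only if that gate rejects at α = 0.05 are individual cluster contrasts
interpreted (they are still emitted, flagged non-inferential, when it does
not). The reference distribution matters: with q ≈ 7–9 and a few hundred
clusters the χ²(q) reference is visibly anti-conservative (≈7.5–8% null
rejection in simulation). The package therefore uses the Hotelling-style
small-sample reference
$$W\,\frac{G-q}{q(G-1)} \sim F(q,\,G-q),$$
which brings the simulated null rate to ≈6–7%, inside the binomial band
around the nominal 5% that the acceptance suite checks over 500 simulated
null cohorts.

**References.** The spread reference cluster is the detected community with
the highest share of spread-free visits — the "no spreads" pattern — chosen
data-driven because detected labels are arbitrary. The fatty-acid reference
defaults to the largest cluster after size relabelling and is configurable;
substantive analyses would pick the pattern with the most favourable
profile (e.g. low-saturated/high n-3), which is an interpretive judgement
the package deliberately leaves to the analyst, emitting per-cluster
standardized profile summaries (`profile_clusters()`) instead of names.

## 4. Multiple imputation

Covariates (not outcomes: the design restricts to complete-outcome
subjects) are imputed by chained equations, m = 20 completed datasets, 10
cycles each. Family history, smoking and physical-activity category use
predictive mean matching with 5 donors (imputed values are always observed
category values); continuous covariates use Bayesian linear regression
(posterior draw of σ², β, then a normal predictive draw). Covariates are
subject-level, so the chained equations run on a one-row-per-subject table
whose always-complete predictors are sex and both visits' mean systolic and
diastolic pressure. This is the group-mean form of "subject and visit
indicators": one dummy per subject would be degenerate with n ≈ 800
subjects. Because the generator's missingness mechanism depends only on sex
and SBP, the imputation model contains the MAR mechanism — by construction,
not accident.

Scalar pooling follows Rubin's rules with Barnard–Rubin degrees of freedom;
the familywise gates are pooled across imputations with the D1
multivariate Wald statistic. Both are asserted against long-hand
computations in the tests, and a 500-replicate simulation checks that the
pooled 95% CI for a planted +5 mmHg effect under 20% MAR missingness covers
the truth at the nominal rate (observed ≈94–95%) with negligible bias.

## 5. The synthetic cohort generator

The generator is first-class, tested code: every downstream property test
is only as good as the structure planted here.

* **Fatty acids.** Log-normal intakes: log-scale mean vector set to typical
  adult geometric means (palmitic 24, oleic 32, stearic and linoleic 11
  g/day, trace intakes for the long-chain n-3s), common log-SD 0.35, and a
  3-factor loading structure for the correlation matrix — the
  "fatty acids travel together" multicollinearity. Each of the 8 planted
  clusters shifts a fixed random subset of 8 fatty acids by
  ±`cluster_separation` × the log-SD. The separation parameter is defined
  *per distinguishing fatty acid*, not as the norm of the whole mean
  difference: in 31 correlated noise dimensions a 3-SD norm separation
  would be statistically unrecoverable, while a 3-SD per-coordinate shift
  on 8 coordinates is the regime in which K-NN + Louvain plausibly recovers
  8 clusters, which is the regime real analyses report. Separation 0
  disables the signal entirely (the suite checks ARI ≈ 0 there).
* **Spreads.** Ten usage patterns over 5 spread types: the empty pattern
  ("no spreads"), the five singletons and four pairs, with cluster-specific
  intake levels (6/12/25 g/day geometric means — moderate vs high users of
  the same spread are distinct real-world patterns) and log-SD 0.15.
  Unused types are *exactly* 0 g/day — the structural zeros that make the
  spread regime sparser and more modular (Q ≈ 0.9 vs ≈ 0.85). Patterns are
  assigned as a balanced planted partition (equal blocks, permuted). The
  balance is deliberate: a much larger single-type pattern has only ~2
  intrinsic dimensions (its amounts at two visits), its internal K-NN graph
  becomes band-like, and modularity then *genuinely* prefers splitting it —
  we verified the split partition can carry higher Q than the planted one.
  Balanced sizes keep the planted partition the modularity optimum, which
  is what a recovery benchmark needs.
* **Visits.** The two visits share a subject-level component:
  x(v) = μ + σ(√ρ·z + √(1−ρ)·e(v)), giving log-scale visit correlation
  ρ = `within_subject_corr` (default 0.7). The suite checks the empirical
  correlation to ±0.05 at n = 2000.
* **Outcomes.** Six seated BP readings per pressure per visit; the first
  reading carries a +6 mmHg settling-in offset (which the averaging rule
  must discard), the rest scatter around the visit's true pressure.
  Baselines follow the observed panel of such cohorts: male SBP 122.2,
  female 111.7 mmHg at the first visit (≈+1.7 at the second), total SD
  ≈ 11 via a 7-mmHg subject intercept plus visit noise; DBP without a sex
  gap; log-normal triglycerides, glucose, insulin; HDL with a higher and
  more variable female distribution; total cholesterol composed as
  HDL + non-HDL so the derived non-HDL is never negative. Planted effects
  (`effect_table`) add mmHg on the identity scale or log-ratios on the log
  scale, optionally sex-specific, constant across visits.
* **Covariates and missingness.** Subject-level covariates with realistic
  marginals (31% family history, 14% smokers, sex-specific sodium and diet
  scores, Likert fruit/vegetable). Missingness is imposed MAR through a
  logistic model in sex and mean SBP, with the intercept calibrated by
  root-finding so realized rates match the configured ones to ±2 points.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: the FFQ instrument itself (portion-size
discreteness, item grouping, recall bias), nutrient-composition conversion,
true dietary intake covariances (published analyses report cluster sizes
but not covariance matrices, so the factor structure here is a realistic
invention), energy intake, seasonality, attrition, and any
not-at-random missingness. Recovery of planted structure demonstrates that
the pipeline is correct, not that real dietary data contain 8 or 10
clusters.

## 6. Numerical choices and degenerate inputs

* K-NN ties: smaller subject index wins; duplicated rows are legal (cosine
  weight 1) and arise naturally in the all-zero spread pattern.
* Zero-variance columns abort standardization with the column named;
  zero intake vectors abort cosine weighting.
* Louvain: `tol = 1e-7` on modularity gain; candidate communities are
  scanned in ascending id so equal gains resolve deterministically; empty
  graphs and m = 0 are errors, not silent results.
* Imputation: variables are swept in increasing-missingness order; rank
  deficiencies in a conditional model drop the offending columns for that
  draw; a 100%-missing variable is an error.
* Modelling: singular designs error with the collinear columns named;
  fewer clusters than parameters warns; log-scale outcomes must be
  positive.
* Determinism: one master seed feeds named sub-streams (generator, each
  Louvain restart and sweep, each imputation), so stages are independently
  replayable and a fixed seed reproduces the written bundle byte for byte.

## 7. Problem sizes in the test suite

Unit tests run cohorts of 60–800 subjects. The statistical acceptance
checks use the sizes the properties are stated at: n = 800 for
planted-structure recovery (8 + 10 clusters), 100 random ≤8-node graphs
against exhaustive partition enumeration, 500 null cohorts at n = 400 for
the gate's type-I error, and 500 replicates at n = 400 (m = 20 imputations
each) for coverage and bias of a planted effect under 20% MAR missingness —
the replicate counts were chosen so the binomial noise of the estimated
rates is small relative to the acceptance bands. The full suite completes
in a couple of minutes on one CPU.

## 8. Known limitations

* Modularity maximization inherits the resolution limit; very small true
  patterns attached to large ones may not surface at γ = 1. The γ
  parameter is exposed but untuned.
* The sandwich estimator is CR1; with far fewer clusters than here, CR2/CR3
  with Satterthwaite corrections would be preferable and are not
  implemented.
* PMM with 5 donors can propagate sparse-category noise when a categorical
  covariate has very few observed cases in a stratum.
* The pipeline assumes exactly two visits per subject (it errors
  otherwise); generalizing to variable visit counts would touch the intake
  averaging, the generator and the imputation predictors.
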