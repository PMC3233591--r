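---
title: "Glucose tracking and twin-based heritability: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucose tracking and twin-based heritability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotwin)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and what the simulation-backed tests do and do not
demonstrate about real cohorts.

## The scientific setting

Prediabetes — impaired fasting glucose (IFG) and/or impaired glucose
tolerance (IGT) — marks intermediate glucose dysregulation between
euglycemia and diabetes. Two questions drive the analyses here. First,
*tracking*: does a child's rank in the glucose distribution persist
into young adulthood, so that a high-normal glucose in childhood
predicts later prediabetes? Second, *heritability*: how much of the
variation in fasting glucose, post-load glucose, insulin resistance and
prediabetes itself is attributable to genes rather than environment?
Same-sex twin pairs followed over several years let both questions be
answered in one design, because monozygotic (MZ) pairs share all their
segregating genes while dizygotic (DZ) pairs share half on average.

## Glycemic phenotypes

An oral glucose tolerance test yields fasting plasma glucose (FPG,
mmol/L), 2-hour post-load glucose (2hPG, mmol/L) and fasting insulin
(FPI, µU/mL). Insulin resistance is summarized by HOMA-IR =
FPI × FPG / 22.5, analysed on the natural-log scale because its
distribution is strongly right-skewed. (The natural rather than base-10
log is used throughout: typical log-HOMA means of 0.5–0.9 correspond to
HOMA-IR of 1.7–2.5, which is the observed range; base-10 logs would be
0.2–0.4.)

Glycemic status uses the ADA cut-offs: diabetes when FPG ≥ 7.0 or
2hPG ≥ 11.1; IFG when FPG ∈ [5.6, 7.0) with 2hPG < 7.8; IGT when
2hPG ∈ [7.8, 11.1) with FPG < 5.6; prediabetes is IFG and/or IGT. Two
decisions are worth making explicit:

- The conventional printed ranges ("5.6–6.9", "7.8–11.0") are closed at
  one-decimal precision; implementing them as half-open intervals
  [5.6, 7.0) and [7.8, 11.1) makes the categories partition the
  (FPG, 2hPG) plane with no gaps, which a property test verifies on a
  dense grid.
- A subject inside *both* elevated ranges belongs to neither the strict
  IFG nor the strict IGT definition but is unambiguously prediabetic.
  `classify_glycemic()` gives this combination its own `IFG_IGT`
  category by default; a `combined` switch folds it into IFG or IGT for
  tabulations that need a dichotomy, since conventions differ across
  studies.

## The synthetic cohort

No individual-level data ship with the package; `generate_cohort()`
produces cohorts whose correlation structure is known exactly, so every
downstream estimate has a simulation target. The default configuration
is chosen once to represent the study conditions the package is built
around: 218/141 male and 201/81 female MZ/DZ pairs, baseline ages
uniform on 6–21 years with follow-up six years later, trait means and
SDs per sex and visit matching a lean pediatric cohort (e.g. male FPG
4.5 ± 0.5 → 5.4 ± 0.4 mmol/L), an FPG architecture of a² = 0.43,
c² = 0.19, and an IFG liability prevalence of 28.2% (males) / 18.9%
(females) at follow-up.

For each trait, the vector (twin 1 baseline, twin 1 follow-up, twin 2
baseline, twin 2 follow-up) is drawn from a multivariate normal whose
correlation matrix is the Kronecker product of a pair matrix
(off-diagonal a² + c² for MZ, ½a² + c² for DZ) with a visit matrix
(off-diagonal `tracking_r`). Consequences of this separable choice:

- positive definiteness holds exactly when both correlations are inside
  (−1, 1), and is still checked explicitly so that a degenerate request
  fails with the offending (a², c², tracking_r) named;
- the cross-twin cross-visit correlation is the product of the familial
  and tracking correlations — the simplest structure consistent with
  both margins, adopted as a design default since nothing in the study
  design pins it down.

Further choices: insulin is generated log-normally (moment-matched to
the target mean and SD) so HOMA-IR and its log are always defined;
binary traits threshold the *standardized follow-up liability* at the
normal quantile of the configured prevalence, and by default the IFG
liability is coupled to the FPG latent score (an independent liability
with its own ACE structure is available, since a thresholded trait need
not share its continuous trait's latent scale); covariates are
generated independently of glucose except for an optional linear
BMI → FPG effect, so regression recovery tests have a known target; BMI
has a within-pair correlation of 0.5 and cross-visit correlation of 0.7
regardless of zygosity (covariates carry no genetic signal by design);
Tanner stage is a deterministic step function of age; smoking and
physical activity exist only at follow-up (subjects are children at
baseline, and the activity questionnaire is a follow-up instrument),
with a 14–15% "N/A" activity share retained as its own factor level.
The default within-subject `tracking_r` of 0.5 yields middle-or-top
persistence around 75–78%, at the upper end of what child-to-adult
glucose studies report; it is a single configurable dial, and the
tracking tests sweep it rather than rely on the default. `sex_ratio`
accepts per-zygosity values so the default reproduces the four pair
counts above exactly.

What the generator deliberately does *not* emulate: assay measurement
error and OGTT day-to-day non-reproducibility, age trends within a
visit (means shift between visits but not across ages within one),
non-normal glucose tails, sex-linked genetic effects, and any
gene–environment interaction. Tests passing on these cohorts therefore
demonstrate the *estimators* are correct under the stated model, not
that the model captures every feature of a field cohort.

## Tracking

Tertiles are assigned within sex × age-bin strata (2-year bins by
default — "age-specific" leaves the width open, so it is a parameter),
with cut-points at the within-stratum 1/3 and 2/3 empirical quantiles.
Equal values always receive the same tertile: on one-decimal glucose
data, ranking ties arbitrarily would inject label noise. Strata smaller
than 3 merge into the nearest age bin with a warning.

Transition matrices cross-tabulate baseline against follow-up tertile;
the headline statistic is the middle-or-top persistence
P(follow-up ∈ {T2, T3} | baseline ∈ {T2, T3}), whose null value under
independent rankings is 2/3 — a useful calibration point that the test
suite checks to within three binomial standard errors across replicate
null cohorts. Because tertiles are ranks, persistence is invariant
under any strictly monotone transform of the trait. Incidence analysis
restricts to baseline-NGT subjects and reports the proportion
developing prediabetes per baseline tertile, by sex. Tracking curves
use local linear regression with tricube weights (span 0.6, 50-point
grid by default) — a visual device, not an inferential one, and tested
against an independent hand-rolled local-regression oracle.

## Pair-clustered regression

Twins within a pair are correlated, so ordinary regression understates
uncertainty. `gee_fit()` implements generalized estimating equations
with an exchangeable working correlation and robust sandwich standard
errors; with clusters of size ≤ 2 the exchangeable structure is
saturated, so nothing is lost relative to an unstructured working
correlation. Gaussian-identity and binomial-logit families cover the
continuous outcomes and incident prediabetes (odds ratios). Models
adjust for follow-up age, Tanner stage (entered as an ordinal integer),
smoking, BMI and activity (4-level factor including "N/A"). The trend
test recodes tertile as an ordinal score 1/2/3 and reads the robust
Wald p-value — the common epidemiologic "P trend". The sex difference
in tracking strength is implemented as a pair-clustered
baseline × sex interaction on the follow-up value; this is an
interpretation (the originating analyses do not describe their test),
flagged as such here.

## Twin variance components

Twin correlations are double-entry Pearson correlations (each pair
entered in both orders), making them invariant to twin labelling;
at a few hundred pairs the difference from an ANOVA intraclass
correlation is below reporting precision. The ACE fit maximizes the
two-group Wishart likelihood described in the README, on the
standardized scale so a² + c² + e² = 1 exactly. Numerical details:

- Optimization is bounded quasi-Newton (L-BFGS-B) on (a², c²) with
  e² = 1 − a² − c², multi-started from five points of the simplex and
  finished with a feasibility-constrained coordinate polish, because
  the deviance surface flattens near the boundaries. Estimates below
  10⁻⁶ snap to exactly 0 so boundary solutions are reported as such.
- Because the two-parameter model is saturated for two observed
  correlations, any interior optimum reproduces r_MZ and r_DZ exactly
  (equivalently a² = 2(r_MZ − r_DZ), c² = 2r_DZ − r_MZ); the pair
  counts matter only for boundary solutions and for all likelihood-
  based uncertainty. The test suite exploits this as a closed-form
  oracle alongside a brute-force grid search.
- r_MZ < r_DZ is not an error: the fit lands on the a² = 0 boundary.
- Confidence intervals are 95% profile-likelihood intervals: the
  component values where the profiled deviance rises by 3.84, found by
  bisection and truncated to [0, 1]. Boundary-truncated intervals
  report an endpoint of exactly 0.00, the signature seen in published
  twin tables. Profile CIs were preferred to bootstrap intervals
  because they behave correctly at boundary estimates and require no
  resampling of summary-level inputs.

Binary traits use the liability-threshold model: threshold
z = Φ⁻¹(1 − prevalence), and the observed concordance is inverted to a
tetrachoric correlation by root-finding on the bivariate-normal orthant
probability P(X₁ > z, X₂ > z), evaluated by one-dimensional quadrature
of the conditional-normal form to ~10⁻¹² relative tolerance (the
round-trip r → concordance → r is tested to 10⁻⁶). Concordances are
treated as *probandwise* — P(affected | co-twin affected) — by default,
with a pairwise option; the probandwise reading reproduces published
liability heritabilities of the kind this package targets, the pairwise
reading does not. A concordance below its independence value (the
prevalence) implies a negative liability correlation; an optional
`nonnegative` switch clamps it to 0 for designs that exclude negative
familial correlation. Extremely low concordances (e.g. a DZ concordance
of exactly 0 at low prevalence) push the tetrachoric correlation toward
−1, where it is ill-conditioned; such fits are reported as computed,
without claiming a unique interpretation.

Model comparison fits ACE and its nested submodels AE, CE, E on the
same correlations. Dropping one variance component tests a parameter on
the boundary of its space, so likelihood-ratio p-values use the
½χ²₀ + ½χ²₁ mixture (and the corresponding two-component mixture for E
vs ACE); AIC (deviance + 2 × free components) flags a preferred model.

## Problem sizes and verification

The test suite generates all of its data in code. Monte-Carlo checks
use: 20,000 pairs per zygosity for correlation-structure and parameter-
recovery checks (20 random points of the (a², c²) simplex recovered
within ±0.03; liability recovery at prevalence 0.3 within ±0.05), 200
replicate null cohorts for persistence calibration, 500 replicates for
the uniformity of the GEE trend test's null p-values (Kolmogorov–
Smirnov at α = 0.01), and 0.01/0.001-step grid scans as brute-force
oracles for the ML optimum and the profile-CI endpoints. These sizes
keep the full suite under a minute of simulation-heavy work while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

- The GEE implementation covers the twin design (cluster sizes ≤ 2,
  exchangeable correlation, gaussian/logit); it is not a general
  longitudinal GEE.
- ACE fits operate on summary correlations (or raw pairs reduced to
  them); sex-limitation models, covariate regression inside the
  variance model (beyond optional pre-residualization), dominance (ADE)
  and bivariate decompositions are out of scope.
- Liability fits take the prevalence as known rather than estimating it
  jointly with the correlation, matching the summary-statistics entry
  point; with cohort data the empirical prevalence is used.
- The tracking smoother and the tertile machinery assume complete
  pairs of visits per subject; subjects seen once are excluded and
  tallied, with no imputation.
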