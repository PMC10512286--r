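---
title: "Survival biomarker panels from candidate gene lists: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival biomarker panels from candidate gene lists: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingpanel)
```

## The problem

A recurring design in translational transcriptomics starts from a curated
candidate gene list — here, genes implicated in biological aging — and asks
whether a small subset predicts a time-to-event endpoint (biochemical
recurrence after prostatectomy, overall survival in AML) beyond what the
standard clinical covariates already explain. The analysis has a fixed
shape: per-gene covariate-adjusted Cox screening of the candidates on a
training cohort, assembly of the survivors into one additive multivariable
panel, re-evaluation of that panel inside clinically defined strata of the
training and validation cohorts, combination of the per-cohort stratified
p-values across cohorts, and a permutation argument that the panel
outperforms random gene sets of the same size. `agingpanel` implements that
pipeline end to end, with a simulator that generates cohorts under the
model the analysis assumes so that every stage is testable without
access-controlled patient data.

## The Cox engine

Every stage rests on the Cox proportional-hazards model
$h(t \mid x) = h_0(t)\,\exp(\beta^\top x)$, estimated by maximizing the
partial likelihood. The engine is implemented in this package (compiled
kernel, `fit_cox()`):

* **Tie handling.** Efron's approximation by default, Breslow selectable.
  The two coincide exactly when no two events share a time; the simulator's
  continuous times never tie unless the tie-generating flag is set.
* **Optimization.** Newton–Raphson from $\beta = 0$ with step halving,
  declared converged when the largest Newton step falls below $10^{-8}$,
  capped at 50 iterations. A coefficient escaping beyond $\pm 50$ (complete
  separation) or a singular information matrix yields a *flagged* fit
  (`converged = FALSE` with a reason), never a silent answer and never an
  exception: screening loops must survive pathological genes.
* **Inference.** Standard errors from the observed information at the
  maximum; per-term Wald $z$ tests; 95% intervals as
  $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ (Wald-type on the log scale, the
  conventional default when no method is stated); the panel's joint
  significance as the global Wald quadratic form
  $\hat\beta_S^\top [V_{SS}]^{-1} \hat\beta_S$ over the gene terms $S$,
  referred to $\chi^2_{|S|}$. For one term this is exactly the squared
  per-term $z$.
* **Conventions.** A subject censored at an event time remains in that
  event's risk set. Adjustment covariates enter additively and
  untransformed: age in years, histologic grade as the Gleason major+minor
  sum treated as continuous, cytogenetic risk as 0 = favorable /
  1 = unfavorable. No interactions, no time-varying effects, no penalties.

The test suite cross-checks the engine against golden-section maximization
of the partial likelihood on small fixtures, against the log-rank statistic
(score test at $\beta=0$, binary covariate, no ties), and against an
independent implementation on simulated cohorts.

## Screening and panel selection

`screen_genes()` fits, for each candidate present in the cohort, the crude
model (gene alone) and the adjusted model (gene + grade + age), keeping
both hazard ratios and Wald p-values so the two-stage funnel — crude
significance first, adjusted significance among those — can be read from a
single pass. Candidates absent from the expression matrix are reported,
never dropped silently. No multiple-testing correction is applied at this
stage by default: the design defers robustness to external validation and
the random-panel null, and a BH switch exists for users who want it.

`select_panel()` keeps genes with adjusted $p < \alpha$ (default 0.05),
orders them by ascending adjusted p (no ordering is conventional, so the
most significant first), and computes variance inflation factors jointly
over the selected genes' expression: $\mathrm{VIF}_j = 1/(1 - R^2_j)$ from
regressing each gene on the others. Any VIF at or above the threshold
(conventionally 5) rejects the panel by name; in practice the simulator's
weak block correlation ($\rho = 0.1$) keeps panel VIFs below 1.5.

A consequence worth stating plainly: with ~50 candidates screened at raw
$\alpha = 0.05$, about 2–3 null candidates are expected to pass per cohort,
so the selected panel typically *contains* the true signal genes plus a
small number of false discoveries. Exact recovery of the signal set alone
is rare by construction — that is a property of unadjusted screening, not
of this implementation — and it is why the downstream validation and
random-null stages exist.

## Stratified evaluation

`stratify()` partitions a cohort by one of three rules, each disjoint and
exhaustive: Gleason pairs 3+3/3+4 (the clinically favorable group) versus
all other pairs; age at or below a cutoff versus above (60 years for
prostate, 56 for AML — the cohort medians conventionally used);
favorable versus unfavorable cytogenetic risk. `evaluate_strata()` refits
the additive panel model separately per stratum, **without** covariate
adjustment by default: the stratifying variable is controlled by design,
and the stratified analyses this mirrors are described with the panel genes
as the only inputs. A flag re-enables adjustment by the non-stratifying
covariates for sensitivity analysis. Strata with no samples or no events
are marked not-analyzable and the rest proceed — a validation cohort whose
patients are all 60 or younger simply yields a single analyzable age
stratum.

## Cross-cohort integration

For each subgroup, the per-cohort stratified panel Wald p-values
$x, y, z$ are combined with the plain harmonic mean,

$$\mathrm{HM}(p_1,\dots,p_n) = \frac{n}{\sum_i 1/p_i},$$

i.e. $2xy/(x+y)$ for two cohorts and $3xyz/(xy+yz+xz)$ for three. The
combined values are then BH-adjusted across the subgroup family (the four
strata of one cancer analysis, $m = 4$, configurable). A variant with the
constant fixed at 2 for any $n$ — a form that circulates in applied work
with a typographic origin — is implemented behind `variant = "printed"`
for audit; only the standard constant-$n$ form reproduces the published
adjusted values (0.0196 vs printed 0.019, 0.0236 vs 0.023, 0.0356 vs
0.035) from the published per-cohort inputs, so the standard form is the
default. When only part of the family is supplied, `family_size` fixes
$m$; the absent subgroups are assumed to rank above every observed one,
which is the configuration consistent with those published values and is
recorded as an assumption, not an inference. Note this plain
harmonic-mean-plus-BH procedure is deliberately not the asymptotically
calibrated harmonic-mean-p method from the methodological literature.

## The random-panel null

`random_panel_null()` draws $R$ panels of $k$ distinct genes uniformly
from *all* genes in the cohort (the discovered panel is not excluded,
matching the stated sampling frame), fits each as one additive Cox model —
crude by default, and the observed p must then be the crude panel p for a
like-with-like comparison — and reports the nominal empirical p as
`count / R`, the fraction of random panels that reached or outperformed
the observed p. That estimator can be zero; an add-one variant
`(count+1)/(R+1)` is available for users who want a strictly positive
p-value. Repetitions that fail to converge are excluded and counted. The
whole null is a deterministic function of the seed.

## The simulator

`simulate_cohort()` generates cohorts under exactly the data-generating
process the Cox analyses assume, which is what makes the downstream tests
interpretable:

* **Expression**: standard Gaussian per gene, block-equicorrelated via a
  shared factor — blocks of 10 genes at $\rho = 0.1$ by default, enough to
  make the VIF guard non-vacuous without inducing real collinearity.
  $\rho$ is restricted to $[0,1)$, which the factor construction requires.
* **Covariates**: Gleason pairs drawn from the published per-score
  distribution of a 138-patient prostatectomy training cohort (or a
  binary favorable/unfavorable risk split 53:74 for the AML regime); age
  normal with mean 60, SD 8 (prostate) or mean 56, SD 16 (AML).
* **Hazard**: $T \sim \mathrm{Exponential}(\lambda_0 e^\eta)$ with
  $\eta = \sum_g \beta_g x_g + \gamma_\text{grade}\,\text{grade} +
  \gamma_\text{age}\,(\text{age}-\bar a)/s_a$. The exponential baseline is
  the simplest proportional-hazards-compatible choice; a Weibull shape
  parameter power-transforms both event and censoring times, preserving
  the event indicator and the censoring calibration. Grade carries a real
  effect by default ($\gamma_\text{grade} > 0$) so covariate adjustment is
  non-vacuous, mirroring grade's known prognostic role.
* **Censoring**: independent exponential whose rate is tuned by root
  finding — given the realized per-subject event rates — so the expected
  censored fraction equals the target: per subject,
  $P(\text{censored}) = \lambda_C/(\lambda_C + \lambda_T(\eta))$.
* **Presets**: `pc_like` (n = 138, ~25% events, four planted genes at the
  hazard ratios such panels report: 0.49, 0.55, 0.66, 1.30 per unit
  expression), `aml_like` (n = 127, ~36% events, three planted genes at
  1.4887, 1.5161, 1.228), and `null` (`pc_like` with all gene effects
  removed). Baseline rates ($\lambda_0$ = 0.002/month prostate,
  0.03/month AML) put median follow-up on the scale of years and months
  respectively, matching the endpoints' clinical time scales. The default
  universe is 500 genes containing the 52-gene candidate list: large
  enough that random panels are almost never the planted one, small
  enough that a 10,000-repetition null is cheap.

What the simulator does **not** emulate: realistic genome-wide covariance
beyond block equicorrelation, batch or platform effects, non-proportional
hazards, informative censoring, or measurement error in the clinical
covariates. Passing tests therefore certify the pipeline's statistical
machinery under its own assumptions — calibration, power, invariances —
not robustness of the biological claim to violations of those assumptions
in real cohorts.

## Problem sizes and calibration choices in the test suite

The suite verifies parameter recovery (500 replicates at n = 500, single
gene at $\beta = \log 0.5$, 40% censoring: bias below 0.05, CI coverage in
[0.92, 0.97]), screening type-I calibration under the null preset (~1,000
pooled gene fits at the 138-sample regime), uniformity of the random-null
nominal p (200 repeats of R = 200), planted-panel power (100 replicates at
n = 300), and the null-beating rate (50 replicates at R = 1,000). Planted
recovery simulations put the signal at $\beta = \log 0.5$ per unit
expression with 40% censoring at n = 300. The uniformity check of the raw
random-panel p-values runs at n = 600 rather than the 138-sample preset:
at ~35 events the global Wald $\chi^2_4$ test is visibly anticonservative
(a known small-sample property of Wald quadratic forms), which would be
misread as a sampler defect. The nominal-p uniformity check, by contrast,
is valid at any n because observed and random panels share one
distribution there.

## Known limitations

* No proportional-hazards diagnostics, no stratified-baseline Cox
  (stratification here means subgroup refitting), no penalized estimation.
  Models with more terms than events will simply flag non-convergence.
* Wald inference is first-order; in strata with very few events its
  p-values run small. Where that matters, the permutation null is the more
  trustworthy yardstick.
* Listwise deletion of incomplete clinical rows (with reported counts) is
  the only missing-data policy; records with zero follow-up time are
  rejected outright rather than guessed at.
* The BH step with a fixed `family_size` over a partially observed family
  encodes the stated ranking assumption; supplying all family members
  makes it the exact BH adjustment.
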