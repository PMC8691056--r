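---
title: "Methods: building and validating clinical-environmental-genotypic prognostic indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating clinical-environmental-genotypic prognostic indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cegpi)
```

## The problem

In relapsing-onset multiple sclerosis (ROMS) and clinically isolated syndrome
(CIS), the disease course after a first demyelinating event (FDE) is highly
variable and hard to predict from any single data source.  `cegpi`
implements a workflow that combines clinical and environmental predictors
with genetic risk variants into prognostic indices for three recurrent-event
endpoints measured in years since FDE:

* **WoD** — worsening of disability, defined from transitions of the
  Expanded Disability Status Scale (EDSS, ordinal 0–10 in half points);
* **RRE** — relapse and/or recurrence of relapsing events;
* **RWoD** — the union of the two.

The analysis view of the longitudinal data is a counting process: each pair
of consecutive visits contributes a half-open interval `(start, stop]` whose
event status is read off the state observed at its stop visit, with
covariate values taken at its start.  Under this Markov view the WoD status
of an interval is `EDSS_j >= EDSS_{j-1}` (the default `gte` rule — the event
is "not improving"; a strict-increase `gt` rule is available because the
verbal definition "worsening versus not-worsening" admits both readings).
Terminal intervals without an event are right-censored.  Repeated same-day
EDSS measures are collapsed to the last of the day; this choice is a
convention, logged when applied, since clinical practice gives no unique
answer.

## Model components

### Andersen–Gill Cox engine

All fits are stratified Cox partial-likelihood fits on `(start, stop]`
records with Breslow tie handling.  Because the same subject contributes
many correlated intervals, variances are cluster-robust sandwich estimates
with score residuals summed within subject (the Andersen–Gill recurrent
event model).  The engine is backed by `survival::coxph` for unpenalized
fits and `glmnet` (Cox family with start–stop data, `stratifySurv` strata
and `penalty.factor` for forced-in covariates) for L1-penalized fits; the
Breslow baseline cumulative hazard, the Breslow partial log-likelihood at an
arbitrary coefficient vector, and everything built on top of them are
implemented in the package and verified in the test suite against
brute-force evaluation of the hand-written partial likelihood on small
instances.

Breslow ties were chosen over Efron for internal coherence: the same
convention is used by the baseline-hazard estimator that landmark
prediction relies on.  Time-varying coefficient terms `x * ln(t + 0.5)` are
made exact at risk-set evaluation times by episode-splitting records at the
event times before fitting.

### Cross-validated partial likelihood and variable selection

SNP selection follows a Cox-LASSO with the penalty chosen by maximizing the
Verweij–van Houwelingen cross-validated partial log-likelihood
`sum_k [l(beta_(-k)) - l_(-k)(beta_(-k))]`.  Folds always leave out whole
subjects, never single records, because records within a subject are
dependent.  Leave-one-subject-out is the default and is what the small-data
tests verify against a literal LOO loop; for benchmark-scale cohorts the
functions accept an integer `folds` (subject-level k-fold), since a full
LOO path refit is an `O(n)` multiple of the path cost with no practical
gain at those sizes.

Selected SNPs (nonzero penalized coefficients) are refitted unpenalized
("backfitting") and iteratively filtered at Wald `p <= 0.05`; surviving SNPs
are offered interaction terms with the log inter-attack interval (effects
that decay or grow with the gap between events) and with standardized
latitude (gene–environment modulation), retained at the same level.  A
designated HLA-DRB1-tag SNP is always kept, reflecting its established
primary role in MS susceptibility, regardless of its p-value.

The added prognostic value of the whole SNP block given the clinical model
is tested with a permutation score test: the statistic is the
trace-standardized squared norm of the genotype-weighted martingale
residual score, and its null distribution is obtained by permuting genotype
rows across subjects.  This replaces the asymptotic global test used in the
source literature with an exact-under-exchangeability analogue; the two
test the same null hypothesis but their statistics are not numerically
comparable, which is accepted.

Clinical–environmental predictors are chosen by backward elimination at
Wald `p <= 0.05` with a forced adjuster set that is never dropped.  Each
continuous candidate first undergoes a one-term fractional-polynomial (FP1)
scan over powers `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` (log for 0), keeping the
best transform only when it improves the deviance by more than 3.84 (the
5% chi-square point with one degree of freedom).  The full multivariable
fractional-polynomial search is deliberately reduced to this FP1 scan: in
practice only linear and categorical terms tend to survive, and the single
scan keeps the procedure transparent and cheap.  Elimination order is
deterministic (largest p first, ties broken lexically).

### Index synthesis and calibration

The clinical–environmental prognostic index (CEPI) and the genetic
prognostic index (GPI) are per-record linear predictors, cross-validated by
leave-one-subject-out so that no subject's index is computed from
coefficients their own data influenced; a fold that cannot be fitted falls
back to the full-fit coefficients and is logged.  Indices are mean-centered.
Supermodel Cox fits on the index values (stratified by EDSS bin and
dynamic CDMS conversion status, cluster-robust) give:

* `alpha1`, `alpha2` from the joint fit on (CEPI, GPI), defining the
  combined index **CEGPI = alpha1 CEPI + alpha2 GPI** (an exact identity,
  asserted to machine precision in the tests);
* `alpha3` from the super-learner fit on CEGPI alone, which is 1 by
  construction up to numerical tolerance;
* calibration coefficients `psi_i = alpha_i(joint) / alpha_i(single)`,
  measuring how much each component shrinks in combination;
* the model chi-square (likelihood-ratio form, consistent with the
  pseudo-R² formula below), AIC, and the cross-validated Harrell C-index.

Explained variation is summarized as `pseudo-R² = 1 - exp(-chi²/D)` with
`D` the event count, and the genetic contribution to the combined index as
`chi²_GPI / (chi²_GPI + chi²_CEGPI)`.  Both robust and naive standard
errors of the supermodel coefficients are reported, since conventions
differ on which to print.

### Dynamic prediction by landmarking

Landmark datasets are built at `s = 0, 1, 2, 3, 4, 5` years with a
`w = 5`-year prediction window: subjects still under observation at `s`
enter the `s`-slice with covariates (and index values) frozen at `s`
(last observation carried forward), records truncated to `(s, s + w]` and
administratively censored at `s + w`.  One Cox fit on the stacked slices —
cluster-robust on subject, which appears in several slices by construction —
carries the index main effect and linear/quadratic landmark interactions
`f1(s) = s/5`, `f2(s) = (s/5)²`.  The proportional mode shares one baseline
and adds `f1, f2` as baseline-shift covariates; the stratified mode gives
each landmark its own baseline.  The window event probability is

`P(event in (s, s+w] | at risk at s) = 1 - exp(-[H0(s+w) - H0(s)] e^{theta(s) v})`,

with `theta(s) = theta0 + theta1 f1 + theta2 f2`, monotone in the index
value `v` whenever `theta(s) > 0`.  (The source description counts "five"
landmark datasets while listing six time points; the listed set
`{0, ..., 5}` is implemented and configurable.)

### Risk groups, risk scores and validation by calibration

Subjects are split into quartile risk groups IPI1–IPI4 on their baseline
(s = 0) CEGPI value — subject-level, so nobody changes group mid-curve;
ties break by subject id and group sizes differ by at most one (253
subjects split 64/63/63/63).  A Cox fit on the group indicators (IPI1
reference) yields log-hazards `gamma`, hazard ratios `HR = exp(gamma)` and
risk scores `lambda = HR / (1 + HR)` on the probability scale.  Per group,
a maximum-likelihood Weibull model is fitted to the time to first event and
the observed log cumulative hazard is regressed on the predicted one over a
20-point quantile time grid; slope 1 and intercept 0 indicate calibration.
An external reference baseline (a `time`/`cumhaz` table) can replace the
internal baseline by linear interpolation — an interface stub for
recalibration against external cohorts whose data are not shipped.

### Prediction-error curves

Model performance at diagnosis is summarized by Brier and Kullback–Leibler
prediction-error curves with inverse-probability-of-censoring weights from
the Kaplan–Meier estimate of the censoring distribution computed on the
full sample (the standard IPCW choice).  The null model is the marginal
Kaplan–Meier curve and the error-reduction curve is
`(err_null - err_model)/err_null`.  Kullback–Leibler contributions are
clipped at `eps = 1e-12` when a degenerate prediction meets the opposite
outcome.  Static curves default to 40 horizons over `(0, 10]` years;
dynamic curves score the `w`-window probability of each landmark supermodel
at its single horizon `s + w` against the observed window outcome.

## The synthetic cohort generator

No individual-level MS cohort data are shipped or available, so every stage
is exercised on synthetic cohorts with known ground truth.  The generator
emulates a 253-subject, 10-year FDE cohort with roughly 2800 visit
intervals: 77.5% female, age at entry `N(36.6, 9.2²)`, four recruitment
sites, latitude drawn uniformly over a configurable band and standardized
before entering gene–environment terms, 199 independent SNPs with MAF
uniform on a configurable range (first ~8.5% flagged as MHC, the first SNP
as the HLA-DRB1 tag).

Between consecutive visits (gamma-jittered gaps, coefficient of variation
0.25, mean 0.85 years) two processes run on a shared covariate linear
predictor with independent log-normal frailties (sd 0.5 by default, so the
genetic drivers of relapse and worsening can be nearly independent):

* relapses: Poisson counts with intensity
  `h_rel * exp(lp + frailty + genetic terms)`;
* EDSS: a birth–death step on the half-point grid whose upward intensity
  carries the covariate effects and whose downward (improvement) intensity
  is a fixed fraction (0.3) of it.

Causal SNP effects are additive in dosage **centered at the population mean
2·MAF** (so baseline rates keep their typical-subject interpretation), with
optional multipliers on the log inter-attack interval, on standardized
latitude, and on disease duration; the duration slope exists precisely to
generate the "clinical information early, genetic information late" regime
that the dynamic error-reduction analysis is designed to detect.
Time-varying covariates (BMI, HADS, supplement use, income, employment)
follow subject-level random walks — the simplest structure giving
within-subject variation; their distributional forms are stand-ins, flagged
as such in `truth.json`, because no empirical forms are available.  CDMS
conversion is triggered by a second relapse or EDSS ≥ 3 and never reverts.
Independent exponential censoring is applied.  Identical seed and
configuration reproduce the tables bit for bit.

What passing tests on these cohorts do **not** show: linkage disequilibrium
between loci, genotyping error, informative censoring, visit schedules
driven by disease activity, or the true biology of EDSS dynamics.  One
quantitative limitation is worth stating: relapse events are recorded as
per-interval indicators, so for covariates with heavy-tailed effects at
high event rates the interval probability `1 - exp(-lambda dt)` saturates
and attenuates fitted coefficients relative to the generating intensity.
This is a property of visit-grouped data, not of the fitting engine (which
matches a brute-force likelihood oracle to `1e-4` on the same records);
parameter-recovery experiments therefore use binary covariates at moderate
event rates, where the approximation is close.

## Numerical choices

* Cox convergence: relative log-likelihood change `1e-9`, at most 50
  iterations, step-halving on overshoot (the `survival` defaults tightened);
  tie handling Breslow throughout.
* L1 path: log-spaced 12-point grid from the data-derived `lambda_max` down
  to 1% of it unless supplied; coefficients at the chosen penalty come from
  a short path ending at that value, which stabilizes `glmnet` warm starts.
* EDSS strata bin integer floors with 0–1 merged, to avoid empty strata at
  realistic cohort sizes; bin edges configurable.  Strata that contain no
  events are dropped with a warning before fitting.
* Quartile cuts use rank order with ties broken by subject id, making group
  assignment deterministic; an all-equal index degenerates to all-IPI1 with
  a warning rather than an arbitrary split.
* Weibull calibration uses a 20-point quantile time grid per group, which
  stabilizes the slope estimate at a few hundred subjects.
* KL clipping bound `1e-12`; IPCW censoring survival floored at `1e-10`.

## Benchmark scales used by the test suite

Test problem sizes were chosen as the smallest at which each property is
comfortably identifiable: brute-force oracle agreement on n ≤ 8 instances;
Andersen–Gill effect recovery at n = 2000 subjects; Weibull shape recovery
at 500 subjects per risk group; landmark-interaction recovery and the
clinical-early/genetic-late crossover at 350–400 subjects; size calibration
of the permutation global test and of backward elimination over 50
replicates; selection benchmarks at 200–350 subjects with 30–60 SNPs and
subject-level 5–8-fold cross-validation.  The end-to-end pipeline demo runs
110 subjects, 20 SNPs, one endpoint.

## Known limitations

* The generator's covariate dynamics and visit process are stand-ins; no
  claim is made that effect sizes estimated on synthetic cohorts transfer
  to real MS data.
* The permutation global test will not reproduce asymptotic-test statistics
  numerically, only the same accept/reject behaviour under exchangeability.
* External validation is an interpolation interface only; no external
  cohort data are bundled.
* Interactions at the level of the indices (CEPI × GPI) are deliberately
  out of scope — they would make the joint and independent contributions of
  the two sources impossible to disentangle.
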