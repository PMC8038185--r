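---
title: "Deriving a points-based risk index for diabetic retinopathy from EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a points-based risk index for diabetic retinopathy from EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diabetic retinopathy (DR) is a microvascular complication of diabetes and
a leading cause of preventable blindness in working-aged adults. Because
vision loss at late stages is irreversible while adherence to annual eye
examinations is poor, an early-warning signal computable from data that
hospitals already hold — routine laboratory results, diagnosis codes,
encounters — is clinically valuable. **drindex** implements the full
derivation workflow for such a signal: a gradient-boosted predictive
model over a small set of *essential predictors*, and alongside it an
integer, Framingham-style points index that a health worker can apply
with a lookup table and mental arithmetic.

```{r}
library(drindex)
```

# Cohort construction: windows around an event of interest

Patients are diabetic if they carry at least one ICD-9/10-CM code in
`250.x`, `E10.x`, `E11.x`; DR cases additionally carry `362.0x` or
`E10.31x`–`E10.35x` / `E11.31x`–`E11.35x` (see `icd_code_lists()`). Each
patient gets an *event of interest* (EOI): the first DR diagnosis for
cases, and for controls a random draw among eligible encounters after
the diabetes diagnosis. Backwards from the EOI we lay two adjacent,
half-open windows:

* **prediction window** `[eoi − 182, eoi)` — six months of lead time;
  nothing dated here (or later) may feed any feature;
* **observation window** `[eoi − 912, eoi − 182)` — two years over which
  laboratory results are aggregated.

Six months and two years are calendar lengths; we fix them as 182 and
730 days and run all arithmetic on integer day offsets (rendered as
ISO-8601 in files), which makes the window algebra unambiguous under
leap years. Duration of diabetes is `(pred_start − first diabetes
code) / 365.25` years.

Per patient and per lab, in-window values pass an interquartile-range
filter (`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`, quartiles by linear
interpolation — `stats::quantile` type 7) before taking the mean.
Whether the original fences were computed per patient or over the whole
cohort is not documented in the source workflow; both are implemented
(`window_config(outlier_scope =)`), and per-patient is the default
because the filter is applied *before* a per-patient aggregation.
Complication flags (nephropathy, neuropathy) are 1 when a matching code
precedes the prediction window; they and duration can never be missing.
Patients missing any demographic or any lab mean are removed by the
complete-case filter, with a per-patient logged reason.

The minimum record history a control's candidate encounter must have is
also undocumented; it defaults to the full 912 days so that both windows
are covered, and is configurable.

# Bivariate screening

The 26 candidate variables (age group, gender, race, duration group,
two complications, 20 lab means) are screened marginally: Pearson
chi-squared without continuity correction for categorical variables,
two-sample t for labs, with a raw `p < 0.05` gate and no
multiple-testing adjustment — fidelity to the derivation workflow, not a
statistical recommendation. The t-test defaults to Welch's
unequal-variance form (a pooled flag exists); with the group sizes and
spreads involved, either form reproduces the same significance pattern.
Per-level odds ratios use the Woolf (log-scale) interval,
`exp(ln OR ± z·√(1/a+1/b+1/c+1/d))` with `z = qnorm(0.975)`; reference
levels (OR ≡ 1) are the same ones the published bivariate table anchors
on (age ≥85, female, Black, duration 0–1, complication absent).

# Ensemble predictor selection

`select_predictors()` runs the two-step EPS procedure on a stratified
70/30 split (stratification by outcome keeps the ~3.8%-prevalence DR
class present in every partition; the source describes a simple random
split, which at derivation scale is equivalent in expectation):

1. **AUC-weighted importance.** On each of `n_bootstrap` resamples of
   the training split, an XGBoost model is fitted and its per-variable
   gain recorded; importances are aggregated as a weighted mean with the
   resample's AUC as weight. The evaluation rows for that AUC are not
   specified in the source; we use the out-of-bag rows, which avoids
   weighting by optimistic in-bag accuracy. Ties in aggregated
   importance break by variable name for determinism. Gain is the
   default importance measure; cover and split frequency sit behind a
   flag.
2. **Golden-section search.** On the importance-sorted variables,
   `golden_section_min_k()` finds the smallest `k` whose top-`k` model
   stays within `auc_tolerance` (default 0.005) of the full model,
   evaluated on an inner stratified split of the training data so the
   held-out 30% never informs selection. The search assumes the
   AUC-vs-`k` curve is non-decreasing; probes follow golden-ratio
   interval reduction rounded to integers, evaluations are memoised, and
   a terminal linear pass over the final bracket confirms minimality
   there (for monotone curves this equals exhaustive search, which the
   tests verify; for non-monotone curves minimality is only guaranteed
   within the terminal bracket). An undefined (single-class) evaluation
   can never certify the tolerance.

The tolerance default of 0.005 operationalises "close predictive
accuracy"; it is configurable and reported with every result.

# The five-step points system

`fit_logistic()` fits `label ~ essential predictors` by maximum
likelihood, with age and duration as continuous years, complications as
0/1 and labs as their aggregated means. `derive_points()` then:

1. takes the coefficients `β_i`;
2. uses a level scheme: each predictor cut into half-open levels
   `[lower, upper)` with a representative value `M_ij` — the midpoint
   for bounded intervals, small non-negative integers for binary or
   nominal levels, and the *empirical in-level mean* for open-ended
   intervals (the published open-level values, e.g. creatinine >2 →
   2.68, are not midpoints and match this convention; an empty open
   level warns and falls back to a midpoint-style value);
3. measures each level's distance from its predictor's reference level
   in regression risk units, `β_i (M_ij − M_iR)`;
4. sets the unit `B = 5 × |β_age|` — one point equals the risk of five
   years of age. The magnitude is forced by the published footnote,
   which multiplies 0.0187 although the age coefficient is −0.0187.
   Because the unit is defined through age, the pipeline always includes
   age among the index predictors even when the search drops it;
5. rounds `β_i (M_ij − M_iR)/B` to the nearest integer — half *away
   from zero*; no published point value sits on an exact .5 boundary,
   so the choice is test-neutral, but it is fixed and documented.

Reference levels score exactly 0. With the published inputs this
reproduces all 43 printed point values and the 0–160 score range:

```{r}
sys <- published_risk_index()
score_range(sys)
subset(sys$table, predictor == "hba1c")
```

Scoring sums matched level points (`score_patients()`); a value outside
every level is an error naming the predictor, never a silent 0.
`bin_scores()` tabulates observed DR rates over half-open score bins
(published cutoffs 40, 50, …, 100 by default). A system derived on a
*new* cohort has its own scale — `B` depends on that cohort's fitted age
coefficient — so for gradient checks on synthetic data the bins are
taken at octiles of the realised score distribution rather than at the
published cutoffs.

# The synthetic cohort generator

The real derivation and validation sources are restricted EHR
warehouses, so the pipeline is exercised end-to-end on seeded synthetic
cohorts (`generate_cohort()`). Defaults *are* the derivation-like
condition and are not tuned per test: DR prevalence 3.8%; case/control
means and SDs of the 20 labs from the published cohort table
(`lab_reference_stats()`); age, race, gender, duration and complication
mixes from the published per-level counts (`cohort_reference_counts()`).
Per patient the generator draws an EOI day, places the first diabetes
code so the drawn duration is realised (durations uniform within their
group; the open-ended >4-year group is 4 + Exponential(mean 5.2) years,
matching the published 9.2-year mean for that level), guarantees a
registration encounter early enough for full window coverage, dates
complication codes before the prediction window, and draws
`1 + Poisson(1.5)` values per present (patient, lab) pair inside the
observation window, Gaussian around the label-specific mean, plus
occasional prediction-window values that the windowing stage must
ignore. A (patient, lab) pair is absent entirely with probability
`missing_rate` (default 0.02 — modest per-test missingness that still
removes roughly a third of patients under the 20-lab complete-case
rule, echoing real EHR attrition). Ground truth (labels, designed EOI
days, true means, the informative-variable set) is returned for
recovery tests.

What the generator deliberately does **not** emulate: between-lab
correlation (unreported in the source; the labs are independent given
the label, and a correlation hook is exposed but unparameterised),
ICD code co-occurrence structure, medication/procedure tables, and
secular trends in lab values. Two consequences matter for interpreting
green tests. First, independent labs with the published marginal
separations make the cohort *easier* to classify than real data —
synthetic AUCs around 0.95 against the published 0.85 are expected, and
no test asserts the published real-cohort AUCs. Second, independence
makes weak predictors jointly redundant: the true AUC-versus-k curve
saturates around k ≈ 7, so the minimal-subset search honestly returns
5–7 predictors on synthetic cohorts where the real, correlated cohort
needed 10. The recovery suite therefore checks that the *ranking* places
informative variables ahead of pure noise, and the strict
8-of-10-in-the-essential-set acceptance check documents this limitation
when it fails.

# Evaluation

`auc()` is the rank (Mann–Whitney) statistic with ties counted as half —
algebraically the trapezoidal ROC area — verified exactly against
all-pairs concordance counting in the tests and cross-checked against an
independent ROC implementation. Age-group-specific AUCs
(`age_specific_auc()`) report groups with fewer than two classes as
undefined, never zero. No confidence intervals are attached by default
(the derivation workflow reports point AUCs); a percentile-bootstrap
helper `auc_ci()` is available. Validation-style use applies the frozen
derivation-fit system unchanged to new data; refitting on validation
data is deliberately not offered.

# Reproducibility and problem sizes

Every stochastic step (generation, control-EOI draws, splits,
bootstraps) runs under a named seed stream derived from one global seed;
identical configurations give byte-identical tables, and the pipeline
manifest records per-stage attrition counts and output checksums. The
test suite exercises structural properties on cohorts of 400–6,000
patients and the statistical recovery properties at 20,000 patients
with 50 bootstrap resamples and 30 boosting rounds per model — sizes at
which the binomial tolerances quoted in the tests are meaningful while
the whole suite stays fast on a single CPU.

# Known limitations

* The generator's independence assumption (above) limits what synthetic
  recovery tests can say about correlated real-world predictors.
* The complete-case filter reproduces the source workflow; it is not a
  recommendation against imputation.
* Points systems derived on cohorts whose age–outcome association is
  weak inherit a small `B` and hence a stretched score scale; the scale
  is reported (`score_range()`) and serialised with the system.
* ICD matching is by the literal published prefix lists; no general
  ICD-9→10 mapping is attempted.
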