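---
title: "Building and evaluating a Wald-chi-square-weighted risk score for lymph node metastasis"
author: "lnmrisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a Wald-chi-square-weighted risk score for lymph node metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmrisk)
```

## The problem and the model

Lymph node metastasis (LNM) after hepatectomy for hepatocellular
carcinoma is uncommon (on the order of 10–12% of patients over long
follow-up) but carries a poor prognosis, and identifying high-risk
patients early enough for prophylactic regional radiotherapy requires a
prediction made at surgery, not at relapse.  `lnmrisk` implements a
score-based predictor built from binary clinicopathological factors and
in situ hybridization (ISH) calls of tissue microRNAs.

The statistical object is a weighted sum of binary covariates.  With
time-to-LNM $T$, censoring at the end of follow-up, and covariates
$x_1,\dots,x_k \in \{0,1\}$, a Cox proportional-hazards model
$h(t\mid x)=h_0(t)\exp(\sum_i \beta_i x_i)$ is fitted to the screened
factors.  Each covariate's Wald statistic
$\chi^2_i = (\hat\beta_i/\widehat{se}_i)^2$ measures its contribution on
a common scale; dividing by the smallest $\chi^2$ in the model and
rounding to one decimal turns these into interpretable weights
$w_i$ with $\min_i w_i = 1.0$.  A patient's total score is
$S=\sum_i w_i x_i$, and a single cutoff $c$ dichotomizes the cohort into
low risk ($S \le c$) and high risk ($S > c$).

This construction assumes proportional hazards for every retained factor,
binary (already dichotomized) covariates, and enough events for the
multivariate fit to be stable — the pipeline refuses to fit more
covariates than events and flags monotone likelihood (complete
separation) rather than reporting a spuriously finite hazard ratio.

## Marker scoring

Four ISH scoring systems are implemented, matching how each marker is
read in practice:

* **miR-145, miR-31** — additive systems: chromogenic intensity 0–3 plus
  stained-percentage category 0–2 give a final score 0–5.  miR-145 is
  positive above 4 (so only intensity 3 with percentage 2 qualifies);
  miR-31 is positive above 3.
* **miR-92a** — four-tier intensity 0–3 alone; positive above 0.5.
* **miR-10b** — percentage of stained cells 0–100; "high" at **or above**
  20%, the one inclusive boundary.

Two raters score each section independently and their composite final
scores are averaged before the threshold is applied; averaging composite
scores (rather than intensity and percentage separately) is what makes
half-point scores such as 3.5 — and the 0.5 threshold of miR-92a —
meaningful.  Averaged scores are compared to thresholds without rounding.
More than two raters are accepted (the mean is taken over all).  When a
patient contributes multiple tissue cores, all readings for that
patient/marker are pooled into the mean and a message notes the pooling;
no scoring rule for between-core disagreement exists, so pooling is the
least-assuming default.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided screening threshold on the univariate Wald p |
| `horizon_months` | 60 | horizon for confusion metrics and AUC case status |
| `ties` | `"efron"` | Cox tie handling; Efron behaves better with the heavy ties produced by month-resolution times (`"breslow"` available) |
| `expected_min` | 5 | expected-count threshold below which a 2×2 table routes to Fisher's exact test |
| `km_lookup_months` | 12, 24, 60 | Kaplan–Meier cumulative-incidence readouts |

Two boundary conventions are fixed and documented rather than
configurable: a total score exactly at the cutoff is **low** risk, and
the miR-10b 20% threshold is inclusive on the high side.

## Cutoff selection

The cutoff is described only as "best separation by the χ² test for
linear trend" in the literature this design follows; neither the
candidate set nor whether the trend statistic itself is the selection
criterion is specified.  The package makes a deterministic, reproducible
choice: candidates are midpoints between consecutive distinct attained
scores, each candidate is scored by the Pearson χ² of its 2×2
(above/below × event) split, the maximizer wins, and ties break toward
the smaller cutoff (favoring sensitivity).  The Cochran–Armitage trend
χ² across all score levels is computed on the same data and reported
alongside, so users preferring the trend criterion can inspect it.  Score
levels are compared with a 10⁻⁸ tolerance so floating-point noise in sums
of one-decimal weights cannot split a level in two.

## Evaluation conventions

At horizon $t_h$, a *case* has an observed event at or before $t_h$ and a
*control* was followed event-free through $t_h$; patients censored
event-free earlier are excluded from the evaluable set.  This
exclude-early-censored estimand is simple and stated in every report;
inverse-probability-of-censoring weighting and time-dependent ROC methods
are deliberately out of scope.  The AUC is computed on the *continuous*
total score against horizon case status as the Mann–Whitney probability
of correct ranking with half credit for ties — a binary high/low grouping
cannot produce the intermediate AUC values a multi-valued score does.
Cumulative incidence is $1-\hat S_{KM}(t)$ of time-to-LNM with all
non-LNM exits censored, read right-continuously.

## The synthetic cohort generator

No patient-level data are distributed, so the generator stands in for
them with the statistical structure the pipeline assumes:

* **Factors.** 19 binary covariates drawn by thresholding a multivariate
  normal at the prevalence quantiles (Gaussian copula).  Default
  prevalences are the training-cohort marginals (e.g. vascular invasion
  27/192, BCLC B–C 23/192, miR-145 47/192, miR-31 35/192, miR-92a
  55/192).  The five model factors share a latent correlation of 0.4 —
  the markers are reported to co-occur with vascular invasion and BCLC
  stage, but no magnitude is published, so 0.4 is an explicit assumption
  (a config default, not an estimate).
* **Events.** Exponential time-to-event with rate
  $h_0\exp(\sum_i \beta_i x_i)$, $\beta_i$ defaulting to the log of the
  published multivariate hazard ratios (5.151, 2.899, 3.630, 3.506,
  3.449) and 0 for the other 14 factors.  The constant baseline
  $h_0 = 1.6\times10^{-4}$ events/month was calibrated once, by solving
  $E_x[P(T<C)] = 0.12$ under the default covariate distribution, so that
  about 12% of patients — ≈ 23 of 192 — develop LNM before censoring.
* **Censoring.** Administrative, uniform over 36–126 months, matching a
  median follow-up near 53 months with range up to ~126.

`generate_paperlike_pair()` draws independent 192- and 209-patient
cohorts from this default.  `generate_ish_readings()` inverts the marker
scoring: it emits two-rater raw readings whose scored calls reproduce a
cohort's marker columns exactly (miR-145 positives must be intensity 3 /
percentage 2, the only additive cell above 4), with optional one-step
rater disagreement whose induced call flips are counted.

What the generator does **not** emulate: the empirical correlation
structure beyond one pairwise latent value, non-proportional hazards, a
time-varying baseline, covariate measurement error, or the exact
finite-sample configuration behind the published cohort-level numbers
(AUC, sensitivity, group hazard ratios).  Tests passing on synthetic
cohorts therefore demonstrate that the pipeline recovers a known
generating model of the assumed form — not that the published
cohort-specific values would be reproduced on the original data.

## Numerical choices

* Weights are rounded half-away-from-zero to one decimal
  (11.665/4.496 = 2.594 → 2.6; 7.485/4.496 = 1.665 → 1.7); base R's
  round-half-to-even would get the latter wrong.  The published weight
  vector sums to 7.9, conventionally described as a 0–8 score range; the
  package reports 7.9 and treats 8 as that value's printed rounding.
* Wald confidence intervals use $\exp(\hat\beta \pm 1.959964\,se)$.
* The univariate hazard-ratio screen uses Cox fits (hazard-ratio plus CI
  output format implies a proportional-hazards model); contingency-table
  χ²/Fisher tests are available separately.
* 2×2 Pearson χ² in the cutoff scan uses the closed form
  $n(ad-bc)^2/(r_1 r_2 c_1 c_2)$ in double precision.
* Degenerate inputs fail loudly and specifically: zero-margin tables
  return p = 1 with a warning instead of erroring mid-pipeline; constant
  factors, no-event cohorts, collinear covariates and out-of-range marker
  scores raise errors naming the offender.

## Problem sizes used by the test suite

The recovery experiments fit cohorts of n = 2000 over 50 replicates
(all five generating factors re-screened as significant, mean weights
within ±0.5 of the published vector, mean hazard ratios within 15% of
truth); type-I-error calibration of the log-rank test and the univariate
screen uses 1000 null replicates against a binomial confidence band at
α = 0.05; simulator calibration draws 200 cohort pairs.  These sizes
give Monte-Carlo error comfortably below the tolerances they are tested
against while keeping a full run in tens of seconds.

## Known limitations

* Binary covariates only; no multi-level or continuous factors, and no
  penalized or stepwise selection beyond the univariate screen.
* Screening at α = 0.05 across 19 factors admits occasional false
  positives into the multivariate model; when such a factor lands the
  minimum χ², the derived weights inflate relative to the five-factor
  table (the weights remain internally consistent — ratios to the
  weakest retained factor).
* No competing-risks treatment: death before LNM is censoring.
* The exclude-early-censored confusion metrics are biased relative to
  IPCW estimands when censoring is heavy before the horizon; the
  convention is stated in every report.
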