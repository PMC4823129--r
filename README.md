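# lnmrisk

Risk scoring for lymph node metastasis (LNM) after hepatectomy in
hepatocellular carcinoma (HCC), built from clinicopathological factors and
semi-quantitative in situ hybridization (ISH) calls of three microRNAs
(miR-145, miR-31, miR-92a).  The package is aimed at biostatisticians and
clinical researchers who want to construct, inspect or stress-test this
class of Wald-chi-square-weighted survival risk scores; it ships a
synthetic-cohort simulator so every stage runs without patient data.

## The model

Starting from a cohort with 19 binary candidate factors, follow-up time and
an LNM event indicator, the pipeline is:

1. **Univariate screening.** Each factor is tested in a single-covariate
   Cox proportional-hazards model of time-to-LNM; factors with two-sided
   Wald *p* < 0.05 survive.  (2×2 factor-by-event tables are also testable
   with Pearson's χ² or, for sparse tables, Fisher's exact test.)
2. **Multivariate Cox fit.** The survivors are fitted jointly; each
   covariate *i* yields a coefficient βᵢ, standard error seᵢ, hazard ratio
   exp(βᵢ), and Wald statistic χ²ᵢ = (βᵢ/seᵢ)².
3. **Weight derivation.** Every χ²ᵢ is divided by the smallest χ² in the
   model and rounded to one decimal, so the weakest retained factor scores
   1.0: wᵢ = round₁(χ²ᵢ / minⱼ χ²ⱼ).  A patient's total score is the sum
   of weights over the factors they carry.
4. **Cutoff selection.** Candidate cutoffs are the midpoints between
   consecutive attained scores; the cutoff maximizing the 2×2 Pearson χ²
   of (score > cutoff) against the event indicator is chosen, and the
   Cochran–Armitage χ² for linear trend across score levels is reported as
   a diagnostic.  Scores strictly above the cutoff are *high risk*.
5. **Evaluation.** At a stated horizon (default 60 months): sensitivity,
   specificity, PPV and NPV of the high/low grouping (patients censored
   event-free before the horizon are excluded), Mann–Whitney AUC of the
   continuous score, Kaplan–Meier cumulative incidence per group with
   log-rank test, and the high-vs-low Cox hazard ratio.

Raw ISH readings are converted to binary marker calls first: miR-145 and
miR-31 use an additive intensity (0–3) + percentage (0–2) score of 0–5
with positivity above 4 and 3 respectively; miR-92a uses a four-tier
intensity score with positivity above 0.5; miR-10b is "high" at ≥ 20% of
cells stained.  Scores from two raters are averaged before calling.

## Worked example

The score table from the published multivariate Wald chi-squares:

```r
library(lnmrisk)
chi2 <- data.frame(
  factor = c("vascular_invasion", "bclc_b_c", "mir_145_pos",
             "mir_31_pos", "mir_92a_pos"),
  wald_chi2 = c(11.665, 5.632, 6.011, 7.485, 4.496))
derive_weights(chi2)
#> Risk score weights (per-factor Wald chi2 / minimum chi2 = 4.496 ):
#> vascular_invasion          bclc_b_c       mir_145_pos        mir_31_pos
#>               2.6               1.3               1.3               1.7
#>       mir_92a_pos
#>               1.0
#> Maximum attainable total score: 7.9
```

A carrier of all five factors scores 2.6 + 1.3 + 1.3 + 1.7 + 1.0 = 7.9
(reported as a 0–8 scale); a patient positive only for miR-31 scores 1.7.

End to end on synthetic cohorts:

```r
train <- generate_cohort(cohort_spec(n = 2000, seed = 103))
model <- build_risk_model(train)
model
#> Lymph-node-metastasis risk model
#> Risk score weights (per-factor Wald chi2 / minimum chi2 = 65.52755 ):
#> vascular_invasion          bclc_b_c       mir_145_pos        mir_31_pos
#>               2.0               1.0               1.5               1.5
#>       mir_92a_pos
#>               1.1
#> Maximum attainable total score: 7.1
#> Cutoff (score > cutoff = high risk): 3.55  [2x2 chi2 = 715.4 ]

valid <- generate_cohort(cohort_spec(n = 2000, seed = 202), "validation")
evaluate_model(valid, model)
#> Risk-model evaluation (horizon 60 months)
#>   groups: high = 254 , low = 1746
#>   sensitivity 0.700  specificity 0.931  PPV 0.561  NPV 0.961
#>   AUC 0.911  (n evaluable 1521)
#>   high vs low HR 20.674 (95% CI 15.498-27.578), log-rank p 3.06e-186
```

Screening re-found the five generating factors, the weights track the
generating hazard ratios, and the high-risk group carries a twenty-fold
LNM hazard.  A command-line wrapper with `simulate`, `score-markers`,
`build`, `evaluate` and `apply` subcommands lives at
`inst/cli/lnmrisk.R` (installed under `system.file("cli", package =
"lnmrisk")`).

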