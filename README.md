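# mbtcrsr

Acute-phase outcome prediction for disorders of consciousness (DOC) from
CRS-R subscale scores and the ten-item binary Motor Behaviour Tool (MBT).

After severe brain injury, patients in an Unresponsive Wakefulness
Syndrome (UWS) or a Minimally Conscious State (MCS) are graded with the
Coma Recovery Scale-Revised (CRS-R). Its stringent quoting rules score
subtle or motorically blocked signs of consciousness as reflex behaviour,
which makes the first CRS-R assessment a poor outcome predictor in the
acute phase. This package implements, as a tested reusable pipeline, an
analysis design that addresses that gap; it is written for
clinical-research statisticians and methodologists working on DOC
prognosis. Its stages:

* **Scoring and taxonomy** — CRS-R diagnosis (emergence at motor = 6 or
  communication = 2; MCS at auditory ≥ 3, visual ≥ 2, motor ≥ 3,
  oromotor = 3 or communication ≥ 1), the two primary outcome classes
  (emerged vs remaining in DOC) and six subclasses (a–f), and the fixed
  battery of nine group comparisons.
* **Nonparametric prediction** — Mann–Whitney U tests (exact by full
  permutation enumeration with midrank ties for pooled n ≤ 12, else a
  tie- and continuity-corrected normal approximation), Holm–Bonferroni
  family-wise control, and binary-predictor performance: sensitivity
  a/(a+c), specificity d/(b+d), Yule's Q = (ad − bc)/(ad + bc).
* **MBT weighting** — when a subscale sits at its reflex level
  (auditory 1, visual 1, motor 2, oromotor 1, communication 0) and a
  mapped positive MBT item is present, the score is raised by an
  increment δ ∈ {0.1, …, 0.9} (items 1, 3, 5 raise all subscales; item 2
  the auditory/visual; item 4 the motor/oromotor); a sweep over δ locates
  the smallest increment at which the weighted scores discriminate
  outcome groups.
* **Longitudinal modelling** — per-patient OLS fits of each subscale
  trajectory on polynomials of degree 0–3, orthonormalized over the
  analysis window (GLM with identity link); combinatorial degree-subset
  tests (Lilliefors normality check, one-sample t per group, Welch
  between groups, Holm across subscales); group mean ± SEM curves;
  band-separation discrimination times and motor-6 / communication-2
  cutoff-attainment times.
* **Synthetic cohorts** — a seeded generator with a per-patient logistic
  latent recovery L(t) = 1/(1 + exp(−(t − t50)/τ)) shared across
  subscales, ordinal noise, weekly-jittered schedules and
  outcome-conditional MBT items, plus `"null"`, `"paper-like"` and
  `"strong-separation"` reference scenarios.

A transcribed 33-patient acute-neurorehabilitation cohort table ships as
a fixture (`doc_cohort()`).

## Worked example

```r
library(mbtcrsr)

co <- doc_cohort()
d  <- doc_descriptives(co)
d$n
#> # A tibble: 1 x 3
#>   remaining emerged total
#>       <int>   <int> <int>
#> 1        12      21    33
round(d$continuous$remaining_mean[1], 2)
#> [1] 39.83
```

Twelve of the 33 patients (36%) remained in DOC at discharge and 21
(64%) emerged; the remaining group's mean age is 39.83 years. On a
synthetic cohort whose first assessments carry no raw CRS-R signal:

```r
sim  <- run_simulation("strong-separation", seed = 1)
pred <- run_prediction(sim$cohort, sim$assessments)

# raw first-assessment subscores: nothing discriminates
min(pred$raw$p_holm[pred$raw$comparison == "class1 vs class2"])
#> [1] 0.94308

# MBT-weighted subscores: the sweep finds a critical increment
subset(critical_deltas(pred$sweep), comparison == "class1 vs class2")
#> # A tibble: 5 x 3
#>   comparison       subscale      critical_delta
#>   <chr>            <chr>                  <dbl>
#> 1 class1 vs class2 auditory                NA
#> 2 class1 vs class2 communication          0.1
#> 3 class1 vs class2 motor                   NA
#> 4 class1 vs class2 oromotor                NA
#> 5 class1 vs class2 visual                  NA

glm <- run_glm(sim$cohort, sim$assessments)
glm$discrimination$day[glm$discrimination$subscale == "motor"]
#> [1] 8
```

The raw Holm-corrected p-values never approach 0.05. In this scenario
the patients are assessed so early that four subscales still sit below
their reflex levels (where weighting never applies), but the
communication subscale — whose reflex level is score 0 — discriminates
already at the smallest increment (δ = 0.1). The longitudinal group
curves separate persistently from day 8 in this replicate;
`autoplot(glm$curves)` draws the group mean ± SEM trajectories per
subscale.

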