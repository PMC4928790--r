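---
title: "Acute-phase outcome prediction in disorders of consciousness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acute-phase outcome prediction in disorders of consciousness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbtcrsr)
```

## The clinical problem

After severe brain injury, patients with disorders of consciousness (DOC)
are graded on the Coma Recovery Scale-Revised (CRS-R): six ordinal
subscales probing auditory, visual, motor, oromotor, communication and
arousal function. The first five define the diagnostic categories —
Unresponsive Wakefulness Syndrome (UWS), Minimally Conscious State (MCS) —
and emergence from DOC is declared at functional object use (motor score 6)
or functional communication (communication score 2). The arousal subscale
and the total score do not enter the category definitions, so this package
records but never analyses them.

The CRS-R's deliberately stringent quoting rules mean that subtle,
inconsistent, or motorically blocked signs of consciousness (cognitive
motor dissociation) are scored as reflex behaviour. The Motor Behaviour
Tool (MBT) is a ten-item binary bedside instrument capturing exactly those
signs: items 1–5 are *positive* signs (non-reflex movement, isolated ocular
movement, poorly reproducible response to command, facial response to
noxious stimulation, motivational modulation of motor behaviour), items
6–7 are *negative* signs (concomitant conditions masking facial or verbal
output), and items 8–10 are *reflex* signs (abnormal motor reflexes,
roving eyes, increased oral reflex).

`mbtcrsr` implements the full analysis pipeline around these instruments:

1. outcome prediction from the first CRS-R subscale scores (nonparametric),
2. outcome prediction from the MBT items, with binary-predictor
   performance metrics,
3. MBT-based weighting of reflex-level CRS-R subscores with a
   progressive-increment critical-point search,
4. longitudinal modelling of the CRS-R trajectories on an orthonormal
   polynomial basis, with group mean ± SEM curves, band-separation
   discrimination times, and cutoff-attainment times,
5. a seeded synthetic cohort generator so that every stage is testable
   end to end.

## Diagnosis and the outcome taxonomy

`crsr_diagnose()` implements the standard conventions: emergence at motor
6 or communication 2; otherwise MCS as soon as any subscale reaches its
MCS threshold (auditory ≥ 3, visual ≥ 2, motor ≥ 3, oromotor = 3,
communication ≥ 1); otherwise UWS. The threshold table is an explicit,
overridable argument because the category boundaries — not the arithmetic
— carry the clinical content. Profiles with no conscious sign are simply
UWS; a pre-UWS coma stage is out of scope (cohort inclusion requires UWS
or MCS at entry).

Patients are classified by `classify_outcome()` into two primary classes
(emerged from DOC vs remaining in DOC at discharge) and six subclasses
crossing the initial diagnosis with the discharge state (a: UWS→non-DOC,
b: MCS→non-DOC, c: UWS→UWS, d: UWS→MCS, e: MCS→UWS, f: MCS→MCS). The
discharge outcome is taken from the recorded field of the cohort table,
not recomputed from the last assessment. `doc_comparisons()` enumerates
the fixed battery of nine group contrasts (class 1 vs class 2; a vs c, a
vs d, c vs d, a vs c+d; b vs e, b vs f, e vs f, b vs e+f); empty-sided
contrasts are returned flagged `degenerate` rather than dropped, because
which contrasts are empty is itself a property of a cohort (subclass e is
empty in the packaged cohort).

## Nonparametric testing choices

All group comparisons of ordinal or binary scores use the Mann-Whitney U
test, reflecting the multinomial (scores) and Bernoulli (items)
distributions of the data. `mw_utest()` uses midranks for ties and an
*exact* two-sided p-value by full enumeration of the permutation
distribution of U whenever the pooled sample size is at most 12
(`choose(12, 6) = 924` labelings); beyond that, a normal approximation
with tie-corrected variance and a 0.5 continuity correction. The
enumeration bound is configurable; 12 keeps the exact path active for the
small subclass contrasts where the approximation is least trustworthy,
at negligible cost.

Family-wise error is controlled with Holm's step-down procedure
(`holm_adjust()`, a validated wrapper over `stats::p.adjust`). The family
is always the set of simultaneous tests *within one comparison at one
analysis step*: the five subscales for CRS-R-based predictions (raw or
weighted at one increment), the ten items for the MBT prediction, the
five subscales per degree for the longitudinal coefficient tests, and
the seven descriptive variables (five continuous demographics plus the
two secondary endpoints). The increment sweep is a search, not a
simultaneous claim, so it is not corrected across increments.

Binary-predictor performance (`binary_predictor_metrics()`) reports
sensitivity a/(a+c), specificity d/(b+d) and Yule's Q = (ad−bc)/(ad+bc).
For the positive and negative MBT signs the outcome-positive state is
emergence; for the reflex signs it is remaining in DOC, since reflex
behaviours mark deeper impairment. The orientation table is an argument.
Metrics are reported only where the Holm-corrected p-value clears the
significance level, mirroring the convention of reporting performance
only for discriminating items.

For the descriptive comparison (`doc_descriptives()`), the unnamed
categorical test of the secondary endpoints is implemented as Fisher's
exact test (two-sided): the cells are small and conditioning on the
margins is standard. Endpoint records with missing values are excluded
pairwise. The "Midbrain" lesion tally aggregates the mesencephalon and
pons tokens — the convention that reproduces the published tallies —
and the aetiology-to-category lookup ships as an editable CSV because
combined aetiology strings cannot be mapped unambiguously.

## MBT weighting and the critical increment

When a CRS-R subscale sits exactly at its *reflex level* (auditory 1,
visual 1, motor 2, oromotor 1, communication 0) and at least one mapped
positive MBT item is present, the subscale score is raised by an
increment δ ∈ {0.1, …, 0.9}: the weighted score approaches, but never
reaches, the next level. The mapping follows the instrument's design:
items 1, 3, 5 raise all five subscales, item 2 the auditory and visual
subscales, item 4 the motor and oromotor subscales. Scores below or above
the reflex level are never altered, so `floor(weighted) = raw` always
holds, and the weighting cannot change any diagnosis computed on floored
scores.

`increment_sweep()` re-tests every comparison and subscale at each δ and
defines the *critical increment* as the smallest δ whose Holm-corrected
p-value falls below α. One mathematical property deserves emphasis:
because the weighting adds strictly less than one level at the reflex
level only, any δ > 0 induces the *same ordering* of patients — two
patients' weighted scores can only change order relative to δ = 0, never
across different positive δ. A rank test is therefore constant over the
grid, and when the weighted scores discriminate at all, the critical
increment is the smallest grid value. The sweep is retained as specified
— it is cheap, and it documents this invariance empirically in its output
— but users should read the critical increment as "the weighting
discriminates" rather than as a tuned threshold.

## The longitudinal model

Because assessments happen at irregular, patient-specific days, each
patient's subscale trajectory is fit by ordinary least squares (an
identity-link GLM) on a canonical polynomial basis: monomials of degree
0–3 on the analysis window (default 0–100 days), mapped to [−1, 1] and
orthonormalized by QR factorisation over a uniform 101-point reference
grid, with an orthonormality certificate max |GᵀG − I| ≤ 1e−8. The basis
is fixed by the window, *not* by any patient's visit days: that is what
makes coefficients comparable across patients. Ordinal scores are
treated as numeric, as is conventional for CRS-R trajectory summaries;
no ordinal link is attempted.

The *combinatorial* step (`coef_group_tests()`) refits every patient
under each non-empty subset of degrees {0,1,2,3} (15 subsets; the
baseline+slope subset {0,1} is the clinically decisive one) and, per
subset, subscale and degree, reports (i) a Lilliefors normality check of
the pooled coefficients, (ii) one-sample two-tailed t-tests of each
group's coefficients against zero, and (iii) a two-sample Welch t-test
between groups, Holm-corrected across the five subscales. Both the
one-sample and the two-sample routes are reported because the
between-class conclusion can be argued either way from a methods
description that names only the one-sample test; neither is silently
preferred. Patients with fewer regressors than assessments are fit
minimum-norm (SVD pseudoinverse) and flagged rather than dropped — the
behaviour for the unstated case of a cubic subset on exactly three
assessments.

`lilliefors_test()` computes the Kolmogorov–Smirnov distance to a normal
with estimated mean and SD and calibrates it against a seeded Monte-Carlo
null (default 10,000 replicates) rather than interpolated critical-value
tables; the seed is an explicit argument everywhere a Monte-Carlo p-value
appears.

### Group curves, discrimination time, cutoff attainment

`group_curves()` reconstructs each patient's fitted curve on a regular
1-day grid and summarises each group by the across-patient mean with its
SEM band. Three numerical choices, all visible in the code and arguments:

* **Support range.** Polynomial fits extrapolate badly past a patient's
  last visit, so the pipeline evaluates curves from day 0 up to the
  smaller of the two groups' median last-assessment day (configurable via
  `curve_window`).
* **Degree capping.** For curve reconstruction, a patient with *k*
  assessments is fit with at most *k* − 1 regressors (`cap_by_n`): an
  interpolating cubic through three visits is noise, and its
  extrapolation inflates the SEM band.
* **Floor at zero.** The mean curve is floored at 0 — scores cannot be
  negative, and unfloored fits can manufacture spurious "separation"
  before the first assessments exist.

`discrimination_time()` returns, per subscale, the earliest grid day from
which the two groups' mean ± SEM bands are disjoint *at every later day*
in the evaluated window (persistence rule): a transient touch resets the
clock. This is the package's resolution of "group distinction not earlier
than day d". `cutoff_attainment_time()` returns the earliest day the mean
curve reaches the emergence cutoffs (motor 6, communication 2).

## The synthetic cohort generator

No per-patient longitudinal CRS-R data are published for this design, so
the generator (`simulate_cohort()`) is a first-class, tested module. Per
patient it draws:

* an outcome by class (defaults: 20 UWS, 13 MCS; emergence probability
  0.55 and 0.77),
* a latent logistic recovery L(t) = 1/(1 + exp(−(t − t50)/τ)) shared
  across subscales — one latent per patient produces the correlated
  subscale recovery the CRS-R exhibits with only two parameters,
* subscale scores round(L(t)·max) with a ±1 ordinal perturbation with
  probability ε = 0.1, clipped to range,
* a weekly-jittered schedule: first assessment 11.2 ± 6 days (truncated
  to [1, 28]), intervals 7.5 ± 2.9 days (≥ 2), follow-up 52 ± 18 days —
  the first two families match the cohort's reported schedule statistics
  and the follow-up matches its delay-to-last-assessment statistics,
* one MBT evaluation from outcome-conditional Bernoullis whose default
  rates follow the published per-item sensitivities/specificities under
  each item's orientation (the confirmatory repeat two days later is
  modelled as identical),
* rejection sampling (capped at 1,000 attempts) enforcing that the first
  assessment's diagnosis matches the intended class, that emergers
  satisfy the emergence rule at the last assessment, and that
  non-emergers never do.

The per-(class, outcome) trajectory parameters are the one genuinely free
calibration. They were chosen once so that the *paper-like* scenario
reproduces the cohort's summary geometry — in particular, pooled-class
mean curves that track each other early and separate around day 20, the
published window — and then frozen: UWS-emerged t50 ≈ 34 ± 9 d (τ ≈ 7),
MCS-emerged t50 ≈ 18 ± 6 d (τ ≈ 7), UWS-remaining t50 ≈ 60 ± 20 d
(τ ≈ 25), MCS-remaining sharing the emerged-MCS t50 with a much flatter
slope (τ ≈ 45) so that remaining-MCS patients plausibly improve without
emerging. The realised per-patient (t50, τ) are returned in the cohort
table, and `noiseless_scores()`, `separation_day()` (ground-truth
separation, with a default margin of half a score level — the smallest
mean difference that can alter any rounded ordinal score) and
`latent_crossing_day()` expose the generator's own geometry for recovery
studies.

Three reference scenarios (`doc_scenario()`): **null** (outcome labels
independent of the data; exact null for type-I calibration),
**paper-like** (the cohort-like conditions above, with emerger counts
fixed at 11/10), and **strong-separation** (an all-UWS cohort of 33 with
21 emergers assessed around day 5, while every first CRS-R score still
sits at floor/reflex level, with near-deterministic positive MBT signs in
emergers — raw first scores carry no signal, the weighting and the
longitudinal split carry a strong one).

### What the generator does and does not emulate

It emulates: ordinal ranges and their correlation through a shared
latent, monotone-in-expectation recovery, irregular weekly scheduling,
class-conditional MBT rates, and the diagnostic consistency constraints.
It does *not* emulate: non-monotone clinical fluctuation, aetiology- or
lesion-dependent trajectories (hooks exist; defaults off), item-item
correlation within the MBT, or measurement dependence between visits.
Passing recovery tests therefore demonstrates that the pipeline measures
what the model family can express — not distributional fidelity to real
acute-DOC data beyond the summary statistics used for calibration.

## Problem sizes and tolerances in the shipped studies

The packaged simulation studies use 500 replicates for type-I
calibration (rejection rates compared to α = 0.05 within a 99%
Monte-Carlo band estimated from the replicate spread) and 50 seeded
replicates for the recovery studies: the weighted sweep must find a
critical increment while the raw first scores do not reject in ≥ 80% of
replicates; the discrimination day must land within one mean assessment
interval (7.5 days) of the generator's separation day; the motor-6
attainment day must match the noiseless-trajectory oracle within the
1-day grid; and the paper-like discrimination-day median must fall in
the 15–30-day window in ≥ 80% of replicates. These sizes put each study
in the minutes range on a single core while keeping Monte-Carlo error
well inside the asserted margins.

## Known limitations

* Ordinal scores are modelled as numeric throughout, as in the source
  analysis; a cumulative-link longitudinal model would be the natural
  next step.
* The discrimination time depends on group size through the SEM bands:
  it is a detectability statement, not a property of the mean curves
  alone. The antitone-in-SEM property test documents this.
* The critical-increment sweep is rank-invariant over δ (see above); the
  increment grid is kept for fidelity and reporting, not because δ is
  statistically identified.
* Aetiology tallies depend on a stated mapping convention for combined
  aetiology strings; the mapping ships as data and is editable.

## A minimal run

```{r example, eval = FALSE}
co <- doc_cohort()
doc_descriptives(co)$continuous

sim <- run_simulation("strong-separation", seed = 1)
pred <- run_prediction(sim$cohort, sim$assessments)
dplyr::filter(critical_deltas(pred$sweep), comparison == "class1 vs class2")

glm <- run_glm(sim$cohort, sim$assessments)
glm$discrimination
autoplot(glm$curves)
```
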