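---
title: "Precision cohorts and personalized treatment options: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision cohorts and personalized treatment options: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic diseases such as hypertension (HTN), type 2 diabetes (T2DM) and
hyperlipidemia (HL) are managed through repeated measurement of a control
analyte (blood pressure, HbA1c, LDL cholesterol) and stepwise adjustment of
medication.  Clinical guidelines derived from randomized trials cover only a
minority of real patients, so a natural complement is observational: when a
patient presents uncontrolled, what happened to *similar patients in a
similar situation* under each treatment choice that was actually made?

`pcto` implements that workflow end to end:

1. **Data extraction** — find *decision points* (DPs): encounter dates at
   which the disease is measurably uncontrolled; record the observed
   treatment decision and the follow-up outcome at each.
2. **Similarity model training** — learn a disease-specific distance
   between patient states from training DPs (locally supervised metric
   learning, LSML).
3. **Precision cohort identification** — for an index DP, exact-match on a
   small set of clinically designated *filter variables*, score the
   remaining candidates with the learned distance, and choose a score
   threshold trading cohort size against covariate balance.
4. **Treatment options analysis** — group the cohort by observed decision,
   compare each option's percent-controlled against the "no change"
   baseline with Bonferroni-corrected Pearson chi-squared tests, and report
   medication-complexity deltas and a Sankey-serializable summary.

A leave-one-out harness (`loocv_run()`) repeats steps 3–4 with every
scoring DP as the index patient and aggregates by filter-variable cohort.

## The similarity model

Patient states at DPs are vectors of baseline variables (active
medications, diagnoses, latest lab values, demographics).  The learned
distance is a generalized Mahalanobis form

$$D(x_i, x_j) = \sqrt{(x_i - x_j)^\top W W^\top (x_i - x_j)},$$

with $W$ (p × d, orthonormal columns) estimated by average neighborhood
margin maximization: for each training DP, collect its `k_hom` nearest
same-outcome neighbours and `k_het` nearest different-outcome neighbours
(Euclidean distance on z-scored variables, ties broken by row index), form
the compactness matrix $C=\sum_i \frac{1}{k_{hom}}\sum_{j\in hom(i)}
(x_i-x_j)(x_i-x_j)^\top$ and the analogous scatterness matrix $S$ over
heterogeneous neighbours, and take $W$ as leading eigenvectors of the
symmetrized $S-C$.  Per-variable similarity weights are reported as
$1^\top W W^\top$ (column sums), with $\mathrm{diag}(WW^\top)$ as a
secondary non-negative diagnostic.

**Choice of d.**  A rule of "keep all strictly positive eigenvalues" is
tempting but degenerate in practice: with finite samples, essentially
*every* eigenvalue of $S-C$ is positive (one or a few large discriminative
ones plus a flat sampling-noise bulk), so that rule returns $d=p$,
$WW^\top=I$ — plain Euclidean distance and uninformative unit weights.  The
package's `d = "auto"` therefore applies a Kaiser-style cut: keep the
eigenvalues exceeding the mean of the positive eigenvalues, with a minimum
of one.  In simulations with a known discriminative subspace this recovers
the informative directions and produces weight-concentration ratios far
above any reasonable acceptance margin, i.e. the choice is not delicately
tuned.  `d` can always be fixed explicitly.

**Other numerical choices.**  Binary variables are z-scored like continuous
ones so one scale enters the quadratic form (configurable in principle;
deviations documented here would be the place).  Eigenvector signs are
fixed by making each column's largest-magnitude entry positive, so
serialization is deterministic.  Model files store all doubles as C99
hex-float strings inside JSON, which round-trips bit-exactly (decimal JSON
numbers can lose the last ulp); the loader re-verifies orthonormality to
1e-8.  Zero-variance variables get unit scale rather than dividing by
zero.

## Stability selection

Salient-variable selection fits 200 L1-regularized logistic regressions
(glmnet), each on an independent 75% subsample drawn without replacement
("random subset" wording implies subsampling, not bootstrap), and flags
variables with nonzero coefficients in at least 150 of the 200 fits.
Because no penalty strength is prescribed anywhere, the operating point
must be explicit: by default the penalty is chosen from glmnet's lambda
path on the full training matrix so that the mean number of nonzero
coefficients is about twice the desired final variable count
(`target_vars`), and the grid and choice are logged.  Variables are
z-scored inside each resample so the penalty is scale-free; columns
constant in the full matrix are never selectable and trigger a warning.
Highly related survivors are linked by single-linkage clustering on
$|r| \ge 0.8$ and emitted as a review report — the final adjudication of
correlated variables is a human step, so the pipeline accepts an
approved-variable list file (`read_approved_variables()`) and otherwise
proceeds with the automatic stable set.  Filter variables are excluded
from the candidate pool (they are exact-matched later, so selecting them
would be circular); this is configurable by constructing templates
accordingly.

## Decision points, decisions and outcomes

The three shipped configurations (`inst/extdata/config/*.yaml`) encode:

| | HTN | T2DM | HL |
|---|---|---|---|
| DP rule | two consecutive uncontrolled readings (SBP ≥ 140 or DBP ≥ 90) 1–365 d apart; second date is the DP | encounters after the earliest diagnosis with most recent HbA1c ≥ 7.0 within 365 d | encounters after the earliest diagnosis with most recent LDL > 130 within 420 d |
| follow-up window | 1–365 d (14–365 if treatment changed) | 90–365 d | 30–450 d |
| outcome | first qualifying reading; controlled iff SBP < 140 and DBP < 90 | first HbA1c; controlled iff < 7.0 | first LDL; controlled iff ≤ 130 |

Common exclusions: age < 18 at the DP (or unknown), pregnancy marker in
the prior 12 months, refill encounters.  Notes on deliberately resolved
ambiguities:

* *Follow-up start for unchanged treatment (HTN).*  A literal "N = 0"
  would let the DP's own (uncontrolled, by construction) reading count as
  its follow-up; the window therefore starts at day 1 when no treatment
  changed and day 14 otherwise.
* *"Two consecutive" readings* means adjacent qualifying readings of the
  analyte pair — an intervening controlled reading necessarily breaks the
  pair because it is itself one of the adjacent readings.
* *Lab lookback* attaches the most recent lab in the window and requires
  *it* to be abnormal (an older abnormal value superseded by a normal one
  does not create a DP).
* *Refill encounters* are encounters whose code is listed in
  `refill_codes`; nothing in the event schema marks refills, so the code
  set is the dialect's responsibility.
* *Decision buffer*: the observed decision compares active ingredients on
  the day before the DP with those 14 days after (the "limited time
  buffer"; 14 matches the changed-treatment follow-up offset and is
  configurable).  Dose-only changes are invisible by construction — there
  is no dosage field — and appear as "no change".
* DPs whose follow-up window contains no qualifying measurement get
  outcome `missing`, are counted in the extraction report, and are dropped
  from analysis.

## The synthetic world

`simulate_population()` generates the stated test world; it is a fixed
model, not a tuning dial.  Per patient $i$ with idiosyncratic baseline
$b_i \sim N(0, 8)$ and latent severity $s_i \sim N(0, 8)$, visits occur at
geometric gaps with mean 30 days (min 1).  At each visit

$$\mathrm{SBP} = 150 + b_i + s_i - \textstyle\sum_t e_{it}\,[\text{t active}] + \varepsilon_1,\qquad
  \mathrm{DBP} = 86 + 0.5\,(b_i + s_i - \textstyle\sum_t e_{it}) + \varepsilon_2,$$

with $\varepsilon_1 \sim N(0,6)$, $\varepsilon_2 \sim N(0,4)$ independent
given the patient-level terms (DBP correlates with SBP through the shared
latent, and keeping the visit noises independent makes the ground-truth
control probabilities exact one-dimensional Gaussian quadratures instead
of Monte-Carlo estimates).  A visit is uncontrolled when SBP ≥ 140 or
DBP ≥ 90.  Default treatment effects (mmHg reductions) plant
heterogeneity: Lisinopril 12 (−6 if diabetic), Hydrochlorothiazide 9,
Amlodipine 7 (+6 if age ≥ 60) — so option rankings genuinely flip between
subgroups.  At each uncontrolled visit every inactive treatment starts
with the policy probability — 0.35 when $s_i > 5$, else 0.12 — which makes
treated patients systematically sicker than untreated ones: the
confounding is real, and the test suite asserts that the naive
treated-vs-untreated contrast understates the true benefit.  Active
treatments stop with probability 0.05 per visit so "stop" decision labels
occur.  Why these numbers: 150/86 with total patient-level SD ≈ 11 and
visit noise 6/4 mimic adult uncontrolled-hypertension populations
(visit-to-visit SBP variability of 5–10 mmHg; ~20% spontaneously
controlled visits untreated), 10–15 mmHg is a typical single-agent SBP
response, and monthly visits over three years give realistic DP counts.

Because the event schema has no demographic record, continuous covariates
(age) are emitted as day-0 measurement events and binary covariates as
day-0 diagnosis events; the `demographic` template reads the latest such
record.  All randomness flows from one seed; the same `(config, seed)`
reproduces the event table bit for bit, and the ground-truth object
(latent offsets, subgroup-by-treatment control probabilities, the policy)
regenerates with it.

What a green test on this world does **not** establish: robustness to
measurement error in codes, informative missingness, irregular refill
behaviour, dosage titration, time-varying covariates, or care patterns
beyond a memoryless initiation policy.  Real EHR data have all of these.

## Precision cohorts and balance

Candidates must match the index DP exactly on the filter variables (active
treatment indicators plus an age-60 flag by default).  Learned distances
to the index are normalized by the 99th percentile of the candidate
distances and capped at 1 — the p99 convention (rather than the maximum)
keeps thresholds comparable across index patients in the presence of a
single distant outlier; no published normalization exists, so this is a
declared package decision.  Covariate balance between the cohort's
"treatment change" and "no change" groups is measured per covariate by the
standardized bias (mean difference divided by the treated-group SD; an
exactly-zero mean difference is reported as 0 even for degenerate SDs,
which makes exact-matched variables exactly balanced), aggregated
conservatively as the maximum absolute value (mean available).  A grid of
score quantiles (5%, 10%, …, 100%) is scanned; the largest threshold whose
cohort has ≥ `min_cohort` members (default 100; chi-squared validity) and
aggregate balance ≤ `balance_max` (default 0.1, common matching practice;
stricter settings reproduce "balance < 0.03" behaviour) is selected.  If
no threshold meets the bound the minimum-balance sufficient threshold is
used and the cohort is flagged `balance_violating`; if none reaches
`min_cohort` the DP is reported `insufficient` and no options analysis
runs.  The full size/balance profile is retained for diagnostics.

## Options analysis

Within the cohort, DPs are grouped by decision label
(`"{Class}_{Ingredient}+"` / `"…−"` tokens sorted and joined, `no_change`
baseline).  Each option with at least `min_group_size` members (default
30, so expected cell counts stay reasonable; no published minimum exists)
is tested against the baseline with a 2×2 Pearson chi-squared test without
continuity correction (Yates available behind a switch); `m` counts only
the tests actually performed and an option is significant iff
`p < 0.05/m` strictly.  Medication complexity per option is the
half-away-from-zero-rounded median of members' post-decision medication
counts, reported as fewer/same/more versus baseline.  The LOOCV aggregator
records two variants of "a better option with fewer/same/more
medications": conditioned on significantly-better outcome, and conditioned
on comparable-or-better outcome (non-negative difference among tested
options), because the headline phrasing is ambiguous between the two; both
columns are labelled explicitly.

## Known limitations

Only pharmacologic, ingredient-level decisions are modelled (no dosage,
no lifestyle interventions).  The T2DM lab-only index-date path (two
consecutive HbA1c ≥ 6.5 without a diagnosis) is out of scope; the index
date always comes from a diagnosis event.  Matching is the only
confounder-adjustment strategy implemented (no IPW, g-estimation or
doubly robust alternatives).  Desk-scale targets are ≤ a few thousand
scoring DPs; the design is embarrassingly parallel over index DPs but the
package ships no cluster orchestration.
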