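---
title: "Grading mesenteric artery stenosis: the CSI-score model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading mesenteric artery stenosis: the CSI-score model and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiscore)
```

## The clinical problem

Chronic mesenteric ischemia (CMI) arises when atherosclerotic stenosis or
occlusion of the visceral arteries — celiac artery (CA), superior mesenteric
artery (SMA), inferior mesenteric artery (IMA) — chronically starves the gut
of arterial blood. Because the collateral network usually compensates,
severe lesions can stay silent while single-vessel disease occasionally
causes symptoms, and the presenting complaints overlap with common
gastrointestinal disease. A reproducible, purely morphological severity
grade computed from CT-angiography (CTA) measurements lets the lesion burden
be quantified independently of the clinical impression. This vignette
describes the model the package implements, every tunable choice in it, and
what the validation on synthetic cohorts does and does not demonstrate.

## Lesion classification

Each vessel contributes two ordinal scales.

**Extent** encodes how far the lesion reaches: none (0), ostial (1, within
the first 10 mm from the aortic lumen), proximal (2, from the aorta up to
the first SMA branch or the CA bifurcation), extended (3, beyond those
landmarks). For the IMA only ostial disease is scored — its distal branches
are hard to evaluate reliably and a long IMA lesion would otherwise be
over-weighted — so recorded proximal/extended IMA reach is capped at 1 with
a warning rather than rejected (`extent_class()`).

**Grade** encodes the maximum stenosis: 0–50% (0), 51–70% (1), 71–99% (2),
occlusion (3). Percent stenosis comes from the residual and reference
luminal diameters, `(1 − D_stenosis/D_normal) × 100`
(`percent_stenosis()`); when diameters are unusable (e.g. generalized
calcification, where the narrowest diameter defines the grade) a
precomputed percent may be supplied instead. The printed bands are integer
ranges; continuous measurements need a convention at the edges, and the
package uses half-open intervals that preserve the printed bands and leave
no gap: grade 0 iff percent ≤ 50, grade 1 iff 50 < percent ≤ 70, grade 2
iff 70 < percent < 100. The occlusion flag (or percent exactly 100)
dominates any measured percent; a lesion recorded as percent 100 with the
flag unset is resolved to grade 3 with a warning.

Two situations are genuinely under-determined by the scale definitions and
were decided here:

* **Band edges.** Whether 50% and 70% are inclusive is a convention, chosen
  as above; it only matters for measurements landing exactly on an edge.
* **Absent vessels** (anatomic variants). Morphologically there is no
  lesion to grade, hemodynamically a missing vessel behaves like an
  occlusion. The package takes the morphologic view by default — an absent
  vessel contributes (0, 0) and the patient is flagged — because the score
  is defined as a lesion description, not a flow model; users who prefer to
  exclude such patients set `absent_vessel_policy = "missing"`.

A component profile is **admissible** when every scale is in range (IMA
extent ≤ 1) and no vessel carries a positive grade without a lesion
(grade > 0 requires extent > 0; the converse is allowed — a mild ≤ 50%
lesion has extent > 0 and grade 0). There are `13 × 13 × 5 = 845`
admissible profiles (`admissible_components()`).

## The score

The CSI-score is the integer dot product

$$\mathrm{CSI} = 1\,C_{ext} + 2\,C_{grd} + 1\,S_{ext} + 2\,S_{grd} + 1\,I_{ext} + 1\,I_{grd},$$

kept as exact integers end to end — the equation has integer coefficients
and scales, so no floating point enters the scoring path. Enumerating all
admissible profiles gives the attainable range:

```{r}
score_range(csi_weights())
```

Patients dichotomize at a cut-off (default 8) into low (< cut-off) and high
(≥ cut-off) groups (`classify_risk()`), and `score_subgroup()` exposes the
five reporting strata 0–3, 4–7, 8–11, 12–15, > 15 so stratified summaries
are reproducible.

## Deriving weights and cut-off

`csi_fit()` is the estimator. Discrimination is measured by the
nonparametric rank-based AUC,
$\hat\theta = P(X_{pos} > X_{neg}) + \tfrac12 P(X_{pos} = X_{neg})$,
computed via midranks (`auc_rank()`); ties are frequent on a 23-point
integer scale, so the tie-aware estimator is essential.

**Weights** are found by exhaustive grid search: every vector in
`{0,1,2,3}^6` (4096 candidates, a set that contains the published solution
and is exhaustive at trivial cost) is scored by the AUC of its weighted sum.
Equal-AUC candidates are resolved deterministically — minimal coefficient
sum first (the most parsimonious equation), then lexicographic order — and
the full tie set is reported, since on modest cohorts many equations
discriminate equally well. AUC equality uses a `1e-9` tolerance so float
noise cannot break ties arbitrarily.

**Cut-off** selection maximises Youden's index
$J = \text{sensitivity} + \text{specificity} - 1$ over the distinct
observed score values under the rule "positive iff score ≥ cut-off"
(`youden_cutoff()`), matching a dichotomization at an attained integer
value. Ties go to the smallest cut-off, again within a `1e-9` tolerance.

**Confidence interval.** The AUC interval inverts the Brunner–Munzel rank
test (`bm_confint()`): with group sizes $n_1, n_2$ and within-group
variances $v_i$ of (overall midrank − within-group midrank), the standard
error is $\sqrt{n_1 v_1 + n_2 v_2}/(n_1 n_2)$ and the quantile is
Student-t with Satterthwaite–Welch degrees of freedom. No logit transform
is applied — the interval is the direct inversion of the test statistic on
the AUC scale — and endpoints are clamped to [0, 1]. Degenerate inputs are
distinguished: all-tied scores make the variance (and the interval)
undefined and raise an error, while perfect separation returns the
degenerate interval at the boundary with a warning. The construction was
cross-checked against an independent implementation of the test statistic,
and its 95% intervals cover a true AUC of 0.75 in 92–98% of simulated
normal-shift draws at $n = 50/50$ (2,000 replicates in the test suite).

## Internal validation

**Bootstrap** (`bootstrap_auc()`): patients (score and label jointly) are
resampled with replacement at the original size; each resample's rank AUC
is recorded, and the summary reports mean, minimum, maximum and a
percentile interval. The percentile interval is the simplest estimator
consistent with plain resampling; resamples that lose a class are skipped
and counted, and a `stratified` switch resamples within class for small
cohorts. Scores are deterministic per patient, so resampling precomputed
scores is equivalent to resampling raw measurements and rescoring. With a
fixed seed the summary is bit-reproducible.

**Agreement** (`percent_agreement()`, `cohen_kappa()`): exact score
equality between two readers, and unweighted Cohen's kappa over the exact
score categories — unweighted because the companion statistic is exact
percent agreement, so near-misses should not earn partial credit by
default (linear/quadratic weighting is available). The kappa interval uses
the Fleiss–Cohen–Everitt large-sample standard error with a normal
quantile, verified against an independent reference implementation.

**Cross-tabulation** (`csi_crosstab()`): 2×2 counts of a binary attribute
by risk group in the clinical "n (%)" style, with a Pearson chi-square
p-value (no continuity correction, the default of the major statistical
packages' crosstab procedures) switched to Fisher's exact test whenever an
expected cell is below 5.

## The synthetic cohort generator

No patient-level data are distributable, so `simulate_cohort()` stands in
for a referral cohort. Its mechanism is the simplest one that yields the
qualitative structure of such a cohort:

1. a latent severity drawn from a two-component Gaussian mixture
   (non-diseased vs diseased subpopulations, mixing weight = the CMI
   prevalence, 0.45 by default);
2. per-vessel severity = patient severity + independent noise
   (`vessel_sd`), so disease is correlated but not identical across
   vessels — severe patients have more affected vessels, greater reach and
   higher grades;
3. reach from ordered thresholds on the per-vessel scale (IMA forced
   ostial-only), percent stenosis from a logistic curve on the same scale,
   occlusion as an increasing Bernoulli probability, reference diameters
   uniform in a physiologic 5–9 mm range with the residual diameter
   back-computed from the percent;
4. labels from the latent severity through a logistic model whose centre is
   solved numerically so the expected prevalence equals the configured one.
   Labels deliberately do **not** come from the score, so the derived AUC
   is below 1 and cut-off estimation is a genuine statistical task; a
   `threshold` label mode (label = score ≥ 8) exists purely as an oracle
   for exact recovery tests.

All randomness flows from one seed through per-stage sub-seeds, so the
measurement stage is reproducible independently of the label model.
`simulate_raters()` adds a second reader who mis-grades one random vessel
by one level on a Bernoulli subset of patients (with the profile kept
admissible), giving an expected agreement of 1 − rate.

**Calibration.** The defaults (mixture locations 0.2 and 2.2 on a unit-SD
scale, `vessel_sd` 0.7, reach thresholds −0.15/1.35/2.7, percent-curve
location 1.1 and scale 0.8, occlusion location 3.3 and scale 0.55, label
slope 1.5) were fixed once, by simulation at n = 10,000, to bracket the
group-level score distributions of a real referral cohort: CMI-group
median score 14–15, non-CMI median 2–3, overall AUC ≈ 0.86, and a
Youden-optimal cut-off falling in the 6–10 window for 96% of 50 simulation
seeds at n = 500. Only group medians and ranges were targeted — full score
distributions of real cohorts are not published — so the calibration is a
bracket, not a match.

**What passing tests do and do not show.** The generator reproduces
monotone severity structure, score-scale discreteness, label noise, and
anatomic-variant flags; it does not reproduce real CTA measurement error
(reader-dependent, lesion-morphology-dependent), the etiologic mix
(e.g. median arcuate ligament compression), correlations between lesion
pattern and non-morphological risk factors, or treatment/outcome processes.
Recovery results on synthetic cohorts therefore validate the estimators —
that grid search, cut-off selection, intervals and bootstrap behave as
designed under a known truth — not the clinical performance of the score on
any real population.

## Numerical choices and degenerate inputs

* Scoring is all-integer; AUC and ranks use exact midranks.
* Tie tolerances: `1e-9` on AUC (grid search) and Youden's J; ties resolve
  to the most parsimonious weights / smallest cut-off.
* Single-class inputs raise a distinct degenerate-statistics error
  (exit code 3 in the CLI) as opposed to malformed-input validation errors
  (exit code 2).
* Bootstrap resamples that lose a class are skipped and counted rather
  than error; kappa is refused when expected agreement is 1.
* Reports serialize deterministically (sorted keys; AUC/kappa-scale values
  to 3 decimals, percentages to 1) so identical analyses give
  byte-identical files.

## Validation problem sizes

The shipped suite exercises: oracle equivalence of `auc_rank()` and
`youden_cutoff()` against brute-force counting on 1,000 random instances
(n ≤ 30); Brunner–Munzel coverage on 2,000 draws at n = 50/50;
grid-search recovery on a threshold-labelled cohort of n = 2,000 over the
full 4,096-vector grid; cut-off recovery over 50 seeds at n = 500; and
bootstrap consistency at 10,000 replicates on an n = 242 cohort. These
sizes were chosen to make Monte-Carlo error small relative to the bands
being checked while keeping the default test run fast.

## Known limitations

* The score is purely morphological by design: no clinical covariates
  (weight loss, cardiovascular disease, sex) enter the equation, so it
  complements rather than replaces clinical assessment.
* Internal bootstrap validation cannot substitute for external validation
  on an independent cohort; on the derivation cohort the reported AUC is
  optimistic by construction.
* The grid search covers the six coefficients only, not alternative
  encodings of the underlying scales.
* Weights and cut-off derived on small cohorts are unstable — the tie list
  returned by `csi_fit()` is the honest summary of that uncertainty.
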