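---
title: "Deriving and validating brief screening scales with mokkenscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating brief screening scales with mokkenscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mokkenscreen)
```

## The problem and the model

Screening for dementia in primary care, particularly in low- and
middle-income settings, needs instruments that are brief (administrable in
about five minutes), robust to low literacy, and usable with or without an
informant. The brief CSI-D meets these constraints with seven cognitive
test items and six informant items selected from the full instrument purely
on their *measurement* properties: how well they form a hierarchical
(Guttman-like) scale.

The measurement framework is Mokken scaling, a nonparametric item response
model. The monotone homogeneity model (MHM) assumes unidimensionality,
local independence and monotonicity — every item's probability of a keyed
response is non-decreasing in the latent trait. Under the MHM the total
count of keyed responses orders subjects on the trait. The double
monotonicity model (DMM) adds non-intersection of the item response
functions, so the difficulty ordering of items is the same at every trait
level.

Scalability is quantified by Guttman errors. With items ordered by
difficulty (the proportion *not* giving the keyed response), a Guttman
error is a keyed response on the harder item of a pair without one on the
easier. Writing $F$ for the observed error count and
$E = n\,P(\text{harder keyed})\,P(\text{easier not keyed})$ for its
expectation under marginal independence, the Loevinger coefficient is

$$H = 1 - F/E,$$

computed per pair ($H_{ij}$), per item ($H_i$, with $F_i$, $E_i$ summed
over the pairs containing the item) and for the whole scale
($F_{\text{tot}} = \tfrac12\sum_i F_i$, likewise $E$). $H = 1$ iff the
data contain no Guttman errors; $H = 0$ is the independence baseline.
Bands 0.3/0.4/0.5 separate unscalable, weak, moderate and strong
scalability.

## Assumption checks and the Crit statistic

`check_monotonicity()` uses the restscore method: for each item, subjects
are grouped by their total on the *other* items, adjacent rest scores being
merged until each group holds at least `max(50, n/10)` subjects (the
default is configurable; the merging rule keeps group proportions stable
without modelling assumptions). A decrease of at least `minvi = 0.03` in
the keyed proportion between a lower and a higher group counts as a
violation and is tested one-sided at `alpha = 0.05` by a pooled
two-proportion z test.

`check_nonintersection()` uses the P-matrix method: with items in
ascending difficulty order, the matrix of both-keyed probabilities
$P(X_i{=}1, X_j{=}1)$ must have non-increasing rows, and the both-unkeyed
matrix non-decreasing rows. For every anchor item and ordered pair of other
items, a reversal of at least `minvi` is a violation (McNemar z test on the
discordant counts), attributed to all three items involved.

Violation evidence per item is summarized by the composite
$$\mathrm{Crit} = 50\,(0.30 - H_i)_+ + \sqrt{vi} + 100\,vi/ac
  + 100\,\mathrm{maxvi} + 10\sqrt{\textstyle\sum vi}
  + 1000\,{\textstyle\sum vi}/ac,$$
with the conventional reading: at most 40 satisfactory, 40–79
questionable, 80 and over strongly suggesting an assumption violation.

The z statistic accompanying each $H$ tests $H = 0$ as
$z = (E - F)/\sqrt{V}$ with $V$ the null variance of the error count under
hypergeometric allocation at fixed margins
($V_{ij} = n^2 p_i q_i p_j q_j/(n-1)$ for a pair; aggregates sum the
pairwise variances). The exact statistic used by the historical Stata
implementation is not recoverable from its outputs, so this choice is
validated by Monte-Carlo calibration of its type-I error rather than
against published z values, which also depend on the undeposited raw data.

## Item reduction

`optimal_dichotomy()` converts polytomous (never/sometimes/often) items
into optimal dichotomies. "Optimal" is given a concrete, deterministic
meaning: each item's cut is chosen to maximize that item's $H_i$ within the
candidate scale, holding the other items at their current cuts, by a
coordinate-wise search started at the middle level with one refinement
pass. A full joint search over cut combinations is exponential and, in
practice, the coordinate-wise optimum is stable after one pass. Ties break
toward the lower cut (the more prevalent symptom), which keeps the plan
reproducible.

`select_items()` implements hierarchical subset selection: rank items by
$H_i$, walk the ranking, and pass over an item when its cognitive/
functional domain is already represented while an unrepresented domain
still offers a strongly scalable item, or when its difficulty lies within
`epsilon = 0.02` of an already selected item and a spaced strong
alternative remains. Both rules are priorities, not hard constraints: if
the walk ends short of `k`, skipped items return in rank order. Every
decision is logged. The historical seven-item cognitive scale shows that a
"six best items" rule can bend to keep a multi-point item (delayed recall)
that extends the score range; `k` is therefore a parameter, never
hard-coded.

## Scoring and triage

The brief cognitive score (0–9) sums six pass/fail items and the 0–3
delayed recall count; the informant score (0–6) counts symptoms at their
keyed cuts; the combined score subtracts the informant from the cognitive
total (range −6..9), because impairment lowers one and raises the other.
Cutpoints are stored as half-open thresholds with a direction flag
(`cutpoint(6, "below")` means positive iff score ≤ 5), avoiding off-by-one
drift between the "<6" and ">1" notations. The two-stage triage rule:
cognitive ≤ 4 positive, ≥ 7 negative, 5–6 decided by combined ≤ 4 when an
informant is available and indeterminate otherwise — the conservative
strategy when no informant attends. Scale totals use complete cases per
scale; a missing informant scale never blocks cognitive-only triage.

## Validation

`roc_curve()` evaluates thresholds at midpoints between adjacent distinct
scores (half-integers on these integer scales), making every operating
point unambiguous. `auroc()` is the tie-corrected rank statistic — the
probability a random case scores as more impaired than a random control,
ties counted half — with DeLong placement-value confidence intervals by
default (Hanley–McNeil as an option; the historical analyses do not name
their method, and DeLong is the modern standard for paired empirical
ROC). `optimal_cutpoint()` maximizes Youden's $J$ and co-reports an
adjacent threshold within `delta_j = 0.05` of the maximum, labelled by the
error it favors, reproducing the dual "<6 / <7" reporting style without
hard-coding it. Youden's index is implemented as
$J = \text{sens} + \text{spec} - 1$; the historical description prints a
formula with the sign reversed, but every published value is consistent
with this orientation, so the printed formula is treated as a typo.
`stratified_validation()` computes sensitivity within case-severity strata
and specificity within control-education strata at a fixed cutpoint.

## The synthetic cohort generator

The development and validation surveys are not publicly deposited, so
`generate_population()` and `generate_case_control()` emulate their
statistical structure. One latent trait $\theta$ drives both instruments:
cognitive items are Bernoulli with
$P(\text{correct}) = \text{logit}^{-1}(a(\theta - b_i))$, informant items
are graded (never/sometimes/often) in the impairment direction $-\theta$,
and delayed recall is a four-level graded item. Locations $b_i$ are
calibrated by root finding so that each item's model-implied marginal
difficulty under the population mixture matches its published development
value (residual < 1e-6); a Monte-Carlo check confirms the empirical
difficulties land within sampling error of the targets.

Stated-world defaults, chosen once:

* population design n = 15 022 (the development survey size), prevalence
  8% (typical of the surveyed populations aged 65+), 60% low education;
* case trait offsets −2.0 (mild, CDR 1) and −3.5 (moderate, CDR 2) SDs —
  severity is drawn first (default 50/50) and the trait from that
  component, which keeps the two offsets meaningful in both designs;
* education DIF +0.8 on cognitive item locations, sized so the synthetic
  low/high-education control specificities at the cognitive "<6" cutpoint
  reproduce the published stratified split (≈90%/97%);
* common discriminations 1.7, placing whole-scale H in the strong
  0.6–0.7 band reported for both brief scales;
* pilot case-control groups of 100 each (mild, moderate, high- and
  low-education controls), the scale of a per-region pilot validation;
* measurement noise defaults to 0; when enabled it inflates the trait SD
  inside calibration so marginal difficulties stay on target.

All randomness flows from one `seed` through a fixed draw order
(education, case status, severity, trait, noise, then one uniform per
subject-item in bank order), so identical configs are byte-identical. R
has no cheap counter-based per-subject streams; the single-stream design
delivers the same reproducibility contract and is tested for it.

What a green test on synthetic data does establish: the engine's
arithmetic identities, limit behavior, detection power for engineered
assumption violations, recovery of planted scalable subsets, and the
qualitative orderings (severity, education, combined > single-scale
AUROC). What it does not: the published AUROCs, z values and error counts
are functions of the undeposited field data — the generator targets
marginal difficulties and H bands only, and no claim is made to reproduce
those point estimates.

## Numerical choices and degenerate inputs

* Difficulty is the *non-keyed* proportion; the published tables list items
  in ascending order under this convention (e.g. a difficulty of 0.982 for
  a symptom nearly never reported). The convention is explicit, not
  silent.
* Difficulty ties break by ascending item index when fixing the Guttman
  error direction; H is invariant to row/column permutations up to this
  documented tie rule.
* Constant (difficulty 0 or 1) items make pairs degenerate: $E = 0$, the
  pair is flagged, excluded from aggregation with a warning, and a scale
  whose pairs are all degenerate is an error, not a silent zero.
* Complete cases per scale, matching the differing development sample
  sizes of the two instruments (15 022 cognitive vs 14 922 informant);
  `pairwise_guttman()` on its own uses pairwise-complete cases.
* Integer scores tie heavily: AUROC uses the half-tie convention and
  thresholds sit at half-integers.
* ROC curves with no interior operating point (all scores equal) raise a
  documented error; empty strata report as not estimable rather than NaN.

## Limitations

The package implements single-scale analysis: no automated partitioning of
a pool into multiple scales, no parametric IRT fitting (parametric models
exist only inside the generator), no site/cluster structure or survey
weights in the generator, and no verification-bias correction or pooled
meta-analysis in validation. Item administration and the clinical gold
standard are out of scope: responses arrive pre-coded and the diagnosis is
an input label.
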