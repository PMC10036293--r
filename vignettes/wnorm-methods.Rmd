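---
title: "Normative w-score modelling of regional brain measures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative w-score modelling of regional brain measures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wnorm)
```

## The problem

In genetic frontotemporal dementia (FTD), mutation carriers (C9orf72
repeat expansions, GRN and MAPT mutations) can be identified decades
before symptom onset, and trials increasingly target this presymptomatic
window. A natural question is whether a carrier whose regional brain
measures already look abnormal at baseline — relative to what would be
expected for their age, sex, head size and scanner — goes on to progress
clinically faster over the following year than a carrier whose measures
still look normal.

`wnorm` implements that analysis as a reusable, fully seeded pipeline
over *tabular* region-of-interest (ROI) data: grey matter volumes
(mm^3), and fractional anisotropy (FA) and mean diffusivity (MD) of
white matter tracts. Image processing is out of scope; the package
consumes already-derived ROI tables.

## The normative w-score model

For each (ROI, modality), an ordinary least squares regression is fitted
in cognitively normal controls:

$$x = \beta_0 + \beta_{age}\,\mathrm{age} + \beta_{sex}\,\mathrm{male} +
\beta_{TIV}\,\mathrm{TIV} + \gamma_{s(\cdot)} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with one additive offset $\gamma_s$ per non-reference scanner category.
A carrier's w-score is their standardized residual under the control
model,

$$w_i = \frac{x_i - \hat{x}_i}{\sigma},$$

where $\hat{x}_i$ is the control-model prediction at the carrier's
covariates and $\sigma$ is the control residual standard deviation. In
controls, w-scores have mean 0 and SD 1, so they read like Z-scores
against the control distribution: $-1.960$ sits at the 2.5th control
percentile, $-1.645$ at the 5th, $-1.282$ at the 10th and $-0.675$ at
the 25th (`percentile_cutpoint()`, `wscore_percentile()`).

Design choices the data could not settle, and what we chose:

* **$\sigma$ degrees of freedom.** "Residual variance" admits both
  $RSS/(n-p)$ and $RSS/(n-1)$. The default is the unbiased regression
  convention $n - p$; `sigma_df = "n-1"` switches. At $n = 240$ controls
  and $p = 8$ parameters the two differ by under 2%.
* **Scanner coding.** The scanner covariate is the five scanner *types*
  (Siemens Trio, Skyra, Prisma; Philips Achieva; GE Discovery MR750),
  not the three manufacturers. Users with a manufacturer-level
  convention can simply recode the `scanner` column before fitting. The
  reference category is the most frequent among controls, ties broken
  lexicographically, so the intercept is anchored at the best-estimated
  site.
* **Sex coding.** female = 0, male = 1 — arbitrary but fixed; w-scores
  are invariant to the choice.
* **Degenerate fits.** $\sigma = 0$ (constant control values) flags the
  model degenerate; it refuses to score rather than emit infinite
  w-scores.
* **Missing data.** Complete-case per ROI, no imputation; dropped counts
  are logged.

Two invariances are worth stating because the tests rely on them: w is
unchanged under any rescaling of the raw measure (unit changes cancel in
numerator and denominator), and under any constant shift of a covariate
(absorbed by the intercept).

## Abnormality classification and group maps

Classification is one-tailed and modality-aware: volumes and FA degrade
downward (abnormal $\iff w < -|c|$), MD degrades upward (abnormal
$\iff w > +|c|$). The default cut $c$ is the 10th control percentile,
$|w| = 1.282$. A w-score exactly at the cut is *normal*: the rule is a
strict inequality ("below the cut").

Group-level maps (`group_abnormality_map()`) summarise each
(gene-stage group, ROI, modality) cell by the mean w-score, a
non-parametric percentile 95% bootstrap confidence interval (1000
replicates by default — chosen because not all measures are normally
distributed), a two-sided one-sample t-test against 0, and a percentile
band: the abnormal-tail standard-normal probability of the mean w-score
mapped onto {<2.5th, <5th, <10th, <25th, not-abnormal}. Because the
source analyses describe the bootstrap CI in the methods but a t-test in
the figure annotations, both are computed; "CI excludes 0" is the
primary `significant` flag and the t p-value is reported alongside. No
multiple-testing correction is applied across ROIs by default;
`p_adjust = "BH"` adds a Benjamini–Hochberg column without changing the
primary flag.

## Progression analysis

Carriers are staged from the CDR® plus NACC FTLD global score:
0 or 0.5 is presymptomatic, 1+ is symptomatic. Presymptomatic carriers
of one gene are split per ROI into baseline-normal and
baseline-abnormal strata, and the change in CDR®+NACC FTLD sum-of-boxes
or CBI-R total between baseline and month 12 is tested within each
stratum with an **exact Wilcoxon signed-rank test**:

* zero differences are dropped before ranking (the classical exact-test
  convention; the count is reported so the choice is auditable);
* tied absolute differences receive midranks;
* for $n \le 20$ the null distribution of the positive-rank sum is the
  set of all $2^n$ equally likely sign assignments of the observed
  (possibly tied) rank vector, computed by a counting recursion over
  doubled ranks — mathematically identical to full enumeration, and
  exact under ties, unlike the closed-form null;
* the two-sided p doubles the smaller (inclusive) tail, capped at 1;
* beyond $n = 20$ (configurable) a tie-corrected normal approximation
  takes over; at that size it agrees with the enumerated p to well
  under the decision tolerance.

Because the minimum attainable two-sided p is $2^{1-n}$, significance
at the 5% level is impossible below $n = 6$ pairs
(`min_attainable_p(5)` = 0.0625, `min_attainable_p(6)` = 0.03125). The
pipeline therefore excludes strata with fewer than 3 paired carriers
outright and flags results on 3–5 carriers `caution_lt6`.

Follow-up is matched by visit label (`baseline` / `month12`), not by
date arithmetic: the tolerated scheduling slack around "12 months" is a
data-curation decision upstream of this package.

## The synthetic cohort generator

Real multi-centre genetic FTD cohort data are access-restricted, so the
package ships a generator that emulates the study population well enough
to exercise and validate every analysis stage. `default_genfi_spec()`
fixes the group sizes and covariate moments to the published cohort
table: 240 controls (age 44.8 ± 12.2, 42.9% male) and per-gene
presymptomatic/symptomatic groups of 113/47 (C9orf72), 52/15 (MAPT) and
130/30 (GRN) with their respective age and sex profiles.

Where the cohort table is silent we fixed plausible values once:

* TIV $\sim N(1.40 \times 10^6, (1.5 \times 10^5)^2)$ mm^3, shared
  across groups (typical adult intracranial volumes);
* scanner mix (0.25, 0.20, 0.20, 0.20, 0.15) over the five types —
  roughly even, with no site dominating;
* per-ROI generative models with cortical volumes around
  $2.2 \times 10^4$ mm^3 shrinking ~40 mm^3/year, subcortical
  structures around $6 \times 10^3$ mm^3, FA around 0.46 and MD around
  $7.5\times10^{-4}$ mm^2/s with slow age trends; scanner offsets are
  small non-zero multiples ($0, \pm 0.2$–$0.4$) of each ROI's residual
  SD so the multi-site adjustment is genuinely exercised;
* baseline clinical scores drawn to match the published presymptomatic
  means (sum-of-boxes ≈ 0.2, CBI-R ≈ 5–9 by gene), floored at scale
  minima.

Carrier regional effects are expressed in **control-residual SD units**
(`roi_effect_map()`), so the expected carrier w-score in a region equals
the configured effect *by construction* — that is what makes
parameter-recovery testing possible. The default maps encode the
qualitative published patterns (widespread mild thalamic/pulvinar
involvement in presymptomatic C9orf72; focal temporal–amygdala–
hippocampal involvement in MAPT; temporal pole and presubiculum in
presymptomatic GRN; uniformly severe symptomatic stages), with
magnitudes around $-0.8$ presymptomatically and $-2$ or beyond
symptomatically.

The 12-month clinical change model is additive Gaussian per
(gene, scale, abnormality status) cell with a floor at 0 (and a 180
cap for CBI-R) — the minimal structure that supports recovery tests.
Default cell means follow the published whole-brain-abnormal
magnitudes (sum-of-boxes +1/+3/+2 and CBI-R +8/+11/+16 points for
C9orf72/GRN/MAPT), with small changes in the normal strata; follow-up
availability defaults to the published per-gene follow-up fractions
(56/113, 69/130, 32/52).

What the generator deliberately does **not** model: spatial structure,
within-subject correlation between ROI residuals beyond the shared
covariates, correlation between the two clinical scales, scanner-by-ROI
interactions, and non-Gaussian measurement error. Passing tests
therefore demonstrate that the *analysis machinery* is correct and
well-calibrated under the stated generative assumptions — not that the
published biological effect sizes are reproduced, which restricted data
access precludes.

## Numerical choices and degenerate inputs

* OLS is solved by QR (`lm.fit`) on an explicitly built design matrix;
  rank deficiency is an error naming the collinear columns rather than a
  silent coefficient drop.
* An unseen scanner category at prediction time is an error — silently
  falling back to the reference would bias every w-score from that site.
* Bootstrap CIs use the empirical quantile (type 7) of the replicate
  means; `B = 1` degenerates cleanly to a zero-width interval, and a
  constant sample yields the constant.
* Constant w-score cells have no t-statistic; the map reports `NA` there
  and lets the bootstrap CI carry the flag.
* Physical bounds are enforced at generation (volume ≥ 0, FA ∈ [0, 1],
  MD > 0) with clamping always logged, never silent.
* All randomness flows through explicit integer seeds; the pipeline
  derives one sub-seed per stage from the master seed, so stages are
  individually reproducible and the end-to-end run is byte-identical
  across repetitions (`manifest.json` records the seeds and a config
  hash).

## Problem sizes used in the shipped checks

The package validates itself on sizes chosen to make sampling error
negligible relative to each check's tolerance while keeping the suite
quick: regression-slope recovery on 10,000 simulated controls (slope
within 1%); construction correctness at n = 2,000 carriers (3 standard
errors); classifier calibration with a 240-control fit against 10,000
held-out controls (≈10% abnormal at the default cut, ±1.5 percentage
points); bootstrap coverage over 1,000 simulations at n = 100 (93–97%);
exact-test equivalence against brute-force $2^n$ enumeration on 200
random fixtures up to n = 12; and null size of the exact test over
2,000 strata of n = 20 (rejection ≤ 5.5%).

## Known limitations

* The normative model is linear; no spline/GAM age curves and no
  harmonisation beyond the additive scanner term (e.g. no
  variance-scaling site correction).
* The exact-test conventions for zeros and ties (drop zeros, midranks,
  doubled smaller tail) follow the classical exact implementation; the
  original analyses' software conventions are unreported, so equality
  with them is documented as a choice, not a claim.
* Percentile bands of *group means* are a description of the group's
  average abnormality, not of individual prevalence; a group mean at
  the 10th percentile band does not imply 90% of its members are
  abnormal.
* The generator's independence assumptions (ROI residuals, scales) make
  multiplicity behave more benignly than in real data; users applying
  the pipeline to real tables should consider `p_adjust = "BH"` in the
  maps.
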