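---
title: "OPERAT: scoring model, development pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OPERAT: scoring model, development pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operat)
```

## 1. What the package models

OPERAT is an observational audit instrument: a trained rater walks a
postcode-sized area and records 16 items — presence/absence features
(e.g. public grass or verges, litter), ordinal quality gradings (e.g.
pavement maintenance) and proportions of properties (e.g. well-maintained
gardens). The items group into four domains: *Natural Elements*,
*Incivilities and Nuisance*, *Navigation and Mobility* and *Territorial
Functioning*. The package implements both halves of the life cycle of such
an instrument:

* **Scoring** — turning completed sheets into domain scores and a 0–100
  composite, where higher means a less desirable environment for older
  residents; and
* **Development** — the statistical pipeline that produced the instrument:
  importance-survey weighting, validation screening, exploratory factor
  analysis with iterative item deletion, and the battery of consistency,
  validity, utility and reliability statistics.

## 2. The composite score

Each observation is recoded onto $[0,1]$ with $0$ the most desirable
state. Binary and proportion items whose feature is desirable contribute
$1-v$; undesirable features contribute $v$; ordinal items are first placed
on an equally spaced grid over their declared levels. Equal spacing is the
minimal assumption for ordered quality gradings — no information about
unequal category distances is available, and any monotone re-spacing would
be arbitrary.

The recoded value is multiplied by the item's integer weight
$m_i \in \{1,\dots,4\}$ and summed within the domain (raw score). Domains
are then re-weighted onto a common scale by the expert-panel (EAG) weights
$w_d$ (here $1,1,2,1$ — navigation and mobility was judged "essential",
the rest "desirable"):

$$\chi = \frac{100}{\sum_d w_d}, \qquad
T_d = \frac{\text{raw}_d - \text{raw}^{\min}_d}{\text{range}_d}
      \,\chi\, w_d, \qquad \text{total} = \sum_d T_d .$$

With the shipped instrument $\chi = 20$ and the maximum transformed scores
are $20, 20, 40, 20$; the total always spans $[0, 100]$ for *any* valid
instrument because $\sum_d \chi w_d = 100$ by construction. The transform
is affine in the raw score, so the total decomposes into per-item
contributions $m_i r_i / \text{range}_d \cdot \chi w_d$ — the property the
test suite verifies against a brute-force per-item oracle, along with
monotonicity: worsening any single observation can never lower any score.

`raw_min` is kept symbolic (it is 0 for every shipped domain) so the
engine can serve instruments whose raw scales do not start at zero.
Missing items are a hard error by default; an explicit `prorate` policy
rescales the domain from the observed items' maximum, for partial walks,
and flags the result.

Scores are computed and compared at full precision; file output rounds to
2 decimals, the convention of printed score tables.

### Reconstructed multipliers

The published instrument's per-item weight table is not publicly
available; only the per-domain raw maxima (9, 10, 13, 14) are printed.
The shipped configuration therefore carries *reconstructed* multipliers,
constrained so each domain's multipliers sum to its printed maximum (e.g.
Natural Elements $3+3+3=9$), and every multiplier can be overridden via
the YAML configuration. All score arithmetic that depends only on the
printed constants (maxima, $\chi$, transformed ranges) is exact regardless
of the reconstruction.

### Proportion items

Proportion items were kept in their original form for factor analysis but
recoded like all other items for scoring. The package recodes a desirable
proportion as $1-p$ for scoring — the only reading that preserves "0 =
most desirable" — and exposes the recoding direction per item in the
configuration.

## 3. Thurstone weighting

The importance survey asks, per candidate feature: is it good or bad
(valence), and how much does it affect satisfaction (five ordered
magnitudes). The pair folds onto a 9-point scale — 1 = "a great deal
(unfavourably)" … 5 = "not at all" … 9 = "a great deal (favourably)" —
a bijection the tests assert. The item's raw weight is the **median** of
its 9-point distribution; the signed weight subtracts the midpoint 5; the
scoring multiplier is $|{\rm signed\ weight}|$.

Numerical conventions, each chosen once and documented here:

* **Even-count medians** falling between scale points are rounded toward
  the midpoint 5 (a median of 6.5 becomes 6; of 4.5 becomes 5). Weights
  must be integers in $-4..4$, and rounding toward the midpoint is the
  conservative choice — it never inflates a multiplier.
* **Consensus**: the published rule ("items omitted when there was no
  clear consensus about the positive or negative attributes") is
  qualitative. It is operationalised as: at least 70 % of non-midpoint
  responses share one valence. The threshold is a configurable argument;
  0.7 is a conventional supermajority.
* **Signed weight 0** (median exactly "not at all") excludes the item — a
  multiplier of 0 is outside the 1–4 rule and the item carries no signal.
* A non-midpoint magnitude with a missing valence is ambiguous; the
  response is dropped for that item only (counted in `n_dropped`), and
  respondents skipping an item are excluded listwise for that item only.

Distribution mirror symmetry (reversing every valence negates the signed
weight) is a property test.

## 4. Validation screening and factor analysis

### Screening

Each pilot item is correlated with its paired resident perception question
using Kendall's tau-b at the individual level (each respondent matched to
their area's observation), retained at $p < .05$ two-sided, with an
expert-override list for items important to subgroups under-represented in
surveys (e.g. dementia-relevant signage), and an optional collapsing map
for items merged into composites. Tau-b is implemented by direct pair
counting with tie corrections and a tie-adjusted normal approximation for
the p-value; the tests pin it to an exhaustive pair-enumeration oracle (to
$10^{-12}$, $n \le 50$) and to base R's independent estimate.

### Extraction, rotation, fit

Loadings are estimated by iterated **principal axis factoring** on the
Pearson correlation matrix (squared multiple correlations as starting
communalities; iteration stops when communalities move by less than
$10^{-3}$, the usual PAF practice — overfactored models creep toward a
Heywood bound and never reach machine precision). The reported pattern
matrix is the oblique **Geomin** rotation ($\epsilon = 0.01$, the standard
default) found by gradient projection with 10 seeded random starts plus
the identity start, keeping the lowest criterion value; Geomin's criterion
is non-convex and multiple starts guard against local minima. Factors are
ordered by sum of squared loadings and sign-anchored so each factor's
largest loading is positive.

The least-squares PAF objective carries no likelihood, so fit indices
(χ², CFI, TLI, RMSEA) are computed from a **parallel maximum-likelihood
factor model** of the same correlation matrix at the same number of
factors (`stats::factanal`), with the null-model χ² from Bartlett's
determinant test. This matches how applied EFA software of the period
reported fit for PAF solutions. TLI can exceed 1 in small samples and is
reported as computed. Pearson correlations (not polychoric) are used on
the mixed binary/ordinal/proportion matrix — the simplest defensible
convention; a polychoric option would refine, not change, the pipeline.

### Refinement

The factor count is selected by the eigenvalue-≥ 1 rule within the
candidate range, then walked down while any factor holds fewer than two
items loading at or above the threshold — the interpretability guard that
prefers four factors over a five-factor solution containing a single-item
factor. Items are then deleted **one per iteration**: the item whose
largest absolute loading is smallest, when below 0.4, with ties broken by
item id; the model is re-estimated after each deletion. The loop
terminates in at most one iteration per item, and a model whose factors
empty of salient items raises a degenerate-model error.

## 5. Validity, utility and reliability statistics

* **Item–domain consistency**: Spearman correlation of each weighted item
  score with its domain total, pass at ≥ 0.2. The item is *included* in
  the total (the letter of the published criterion); the stricter
  item-rest variant is available by flag. Constant items are reported as
  failures with reason rather than NA-propagated.
* **Aesthetic attachment**: the sum of the scenery/space/peacefulness
  importance items min–max transformed to 0–100 (higher = more attached).
  The exact anchoring of the original composite is not recoverable; the
  0–100 min–max map is this package's stated convention.
* **Convergent validity**: Spearman correlations of domain scores with
  each perception item at the individual level and with the deprivation
  index at the area level, $p < .05$ two-sided, no multiplicity
  correction — mirroring standard practice for instrument validation
  tables; a Benjamini–Hochberg adjustment can be applied downstream.
  `variance_explained()` turns $r_s$ into the integer percent
  $100 r_s^2$, rounded or truncated (both conventions appear in published
  prose; e.g. $0.67^2 = 44.89 \to 44$ truncated, $0.22^2 = 4.84 \to 5$
  rounded).
* **Utility**: one-way ANOVA of each domain across deprivation quintiles
  or settlement types (`stats::aov`), with Tukey HSD pairwise tests
  aggregated into SPSS-style homogeneous subsets: groups sorted by mean,
  greedy maximal runs whose pairwise comparisons are all non-significant,
  contained subsets dropped. Tests verify the between/within
  sum-of-squares decomposition and the two-group $F = t^2$ identity.
* **Krippendorff's alpha** is implemented via the coincidence-matrix
  formulation with nominal, ordinal and interval difference metrics,
  chosen per item by its value kind (binary → nominal, ordinal → ordinal,
  proportion → interval). Missing ratings are allowed; units with fewer
  than two ratings are ignored. Alpha can be negative mathematically and
  is reported as computed (the conventional description of its range as
  0–1 covers the chance-to-perfect span). All-identical ratings make the
  expected disagreement zero; this degenerate case returns alpha 1 with a
  flag. The tests pin the implementation to a brute-force within-unit
  pair-enumeration oracle ($10^{-10}$, up to 6 units × 3 raters).
  The pass threshold is 0.8.

## 6. The synthetic-data generator

The generator emulates the *design* of the original field study, not its
data: 405 areas in a 40/20/40 city/fringe/village mix, a 545-respondent
weighting survey, ~606 resident returns of which ~500 are eligible
(ineligible returns — underage, missing age, unlinkable postcode — are
injected at the observed 106/606 rate), and 10 re-rated areas for
reliability.

Areas carry four latent factors (oriented so higher = less desirable) drawn
jointly with a latent deprivation index under target correlations
defaulting to the published domain–deprivation pattern
($+0.22, +0.25, -0.17, +0.67$) and an inter-factor correlation of 0.2
(a mild oblique structure consistent with choosing an oblique rotation;
the true factor correlations are not printed anywhere and 0.2 is a
convention). Infeasible target combinations (non-positive-definite implied
correlation matrix) raise a configuration error. Item undesirability is
`|loading| × factor + residual` with uniqueness $1-\lambda^2$ by default,
then expressed on the item's observation scale: binary via a median
threshold, ordinal via equal-probability cut points (keeping marginal
categories roughly uniform so correlations stay estimable), proportions
via a clamped affine map. The weighting survey scatters respondents
normally (SD 1.5) around each item's planted 9-point position; resident
perception items discretise factor-coupled latents onto the 1–6
agree–disagree scale. The second rater copies rater A with per-item
disagreement at a configured rate (default 5 %): binary flips, ordinal
±1 jitter, Gaussian jitter on proportions.

Every generator takes an explicit integer seed and restores the caller's
RNG state; the same seed reproduces every stream byte-for-byte.

**What passing tests show — and do not.** On this synthetic world the
pipeline recovers planted multipliers, the four-factor structure (mean
Tucker congruence ≥ 0.90 at $n=405$), planted coupling signs, and the
reliability threshold behaviour. That demonstrates internal correctness of
the statistics and end-to-end coherence of the pipeline. It does not
demonstrate that real neighbourhood audits follow a clean linear factor
model: real items are skewed (litter is rare in affluent areas),
spatially autocorrelated, and missing not at random — none of which the
generator emulates. Field summary statistics (observed means, ranges,
specific correlation magnitudes at the item level) are therefore not
reproduction targets.

## 7. Problem sizes and runtime conventions

The test battery uses the study's own design scale where the property
concerns it — $n = 405$ areas for factor recovery (20 seeds), $n = 545$
weighting respondents (20 seeds, 50 items), 10 areas for reliability — and
small analytic fixtures where exactness is the point (oracle comparisons,
score arithmetic). Monte-Carlo assertions are phrased on means or medians
across seeds with margins wide enough that the checks are stable under any
seed choice.

## 8. Known limitations

* Confirmatory factor analysis is out of scope (the original development
  explicitly deferred it to future data).
* The per-item multiplier table is reconstructed, not recovered (§2).
* Geomin rotation can possess multiple local minima; random restarts
  mitigate but cannot guarantee the global optimum.
* ML fit indices assume multivariate normality that discretised items
  violate; they are comparative devices across factor counts here, not
  absolute fit judgements.
* The CLI is a thin wrapper over the exported functions; orchestration
  beyond single commands (pipelines, caching) is left to the caller.
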