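---
title: "Methods: differential correlation analysis of small-sample ionome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential correlation analysis of small-sample ionome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `ionomeNet`, the
choices made where the methodology was genuinely open, and what the
package's synthetic-data tests do and do not establish about real data.

## Data model

The unit of analysis is the *cell*: one group × one age, holding the
concentrations of each panel element in *n* independent animals
(*n* = 6 in the design the package mirrors; animals are sacrificed at
each age, so cells at different ages are independent cohorts, not
repeated measures). Data are kept in long form — one row per animal ×
element — which tolerates unbalanced designs such as a treated group that
starts two months after the others, without sentinel values.

## Quality control

**Outliers.** Each cell is screened with Dixon's Q (r10 variant):
Q = gap/range evaluated at both extremes, the larger ratio compared with
the classical two-tailed critical value at α = 0.05 (0.970, 0.829, 0.710,
0.625, 0.568, 0.526, 0.493, 0.466 for n = 3..10). A flagged suspect is
replaced by the arithmetic mean of the remaining values. The screen is
single-pass by design: Dixon's Q is defined for one suspect value, and at
n = 6 iterative re-testing would cascade on almost any skewed cell. The
published description names the test but neither the table's sidedness nor
a repetition policy; both choices here are declared, not inferred.

**Normality.** Because group comparisons are rank-based only when
normality fails somewhere, each cell gets a composite-normality KS test.
Normal parameters are estimated from the sample, so the Lilliefors
calibration is used (`nortest::lillie.test`, which requires n ≥ 5; every
design cell has n = 6). A plain KS test against the fitted normal is
exposed behind `estimated = FALSE` for comparison — it is known to be
conservative in p when parameters are plugged in, which is exactly why
the Lilliefors branch is the default.

## Differentially changed elements

The two-sample comparison is the Wilcoxon rank-sum (Mann–Whitney) test:
groups are independent animals, so the paired signed-rank reading of
"Wilcoxon" is not applicable. p-values are exact by enumeration whenever
both samples have ≤ 8 observations and the pooled values are tie-free,
and otherwise use the normal approximation with midranks, tie correction
and continuity correction. At n = m = 6 the exact two-sided test has an
achievable size of about 0.041 at the nominal 0.05, a discreteness the
calibration tests account for. Direction is the sign of the
comparison-minus-reference *median* difference, consistent with the
rank-based test. Raw p < 0.05 is the default flag rule (matching the
analysis the package reproduces); Benjamini–Hochberg adjustment is
available (`adjust = "BH"`) but off by default.

The supporting "group × time" analysis is a two-way *fixed-effects* ANOVA
(group, time, interaction). The published analysis calls this "repeated
measures", but with terminal sampling there is no within-animal repetition
to model; the deviation is deliberate and recorded here rather than
guessed around.

## Correlation networks and thresholds

Within each cell, the Spearman correlation (midranks for ties) of every
unordered element pair defines the network; 15 elements give 105 edges.

**The null threshold.** Significance cutoffs are estimated exactly as a
simulation protocol, not from asymptotic formulas, because at n = 6 the
permutation null of ρ is discrete with atoms 1/35 apart. One *inner run*
draws 1000 correlations of two independent random permutations of 1..n
and reduces them to the empirical 95th percentile with linear
interpolation between order statistics (interpolation matters: it is what
makes values between the atoms 0.714 and 0.771 attainable). The inner run
is repeated (default 1000 times); the threshold is the mean of the inner
percentiles, and the reported half-width is half their central-95% spread.
The ΔSCC threshold uses the same protocol with each draw the difference of
two independent null correlations. `exact_null_scc_tail()` enumerates all
n! permutations (n ≤ 8) and anchors the simulation in tests.

**Signed quantile, two-sided flag.** The protocol takes the 95th
percentile of the *signed* null — that convention is what reproduces the
published cutoffs near 0.749 and 1.050 at n = 6, whereas an |ρ| quantile
would land near 0.83–0.89. Edge significance is then applied as
|SCC| > τ so that strong negative correlations are also called. The
arithmetic consequence, confirmed by exact enumeration in the tests, is
that a null edge exceeds the flag in either tail with probability
≈ 2α (74/720 ≈ 10.3% at n = 6, α = 0.05): the flag is a two-sided test at
a one-sided critical value. The package keeps this behaviour because it is
the behaviour of the published analysis; users wanting strict 5% size can
pass their own `tau`.

Thresholds are simulated once per (statistic, n, α) and cached; any
numeric override (e.g. the published 0.749 and 1.05) can be passed for
exact replication. The ΔSCC scan uses the time points shared by both
groups, so comparisons against a late-starting group simply begin later.
A DCC shared by the disease-vs-control and treatment-vs-disease
comparisons is *reversed* when the two deltas have strictly opposite
signs (product < 0); zero deltas never count.

**Group-specific edges.** A pair is specific to a group when it is
significant at ≥ 1 time point there and at none in any other group
(the any-time rule); a per-time variant is available via
`by_time = TRUE`, since published "specific interaction" tables do not
state which convention they use.

## Clustering and classification

Element profiles are z-scored per element (sample sd, n − 1; constant
rows become zeros and are flagged) and clustered with the correlation
distance 1 − ρ between profiles — Spearman by default for consistency
with the network stage, Pearson behind a flag. The default linkage is
Ward (`ward.D2`): with a handful of correlated blocks inside a mostly
unstructured 15-element panel, average and complete linkage merge the
unstructured elements at essentially the same height at which blocks
would join them, making a flat cut unstable, while Ward's
variance-minimising criterion isolates the diffuse remainder first.
Average and complete remain available.

Classification pools samples across ages ("regardless of time point":
time is dropped from the feature set) and evaluates decision tree
(`rpart`, depth ≤ 3, minimum leaf 3 — sized for the ~60–66 samples of a
two-group pooled design), naive Bayes and random forest baselines by
stratified 5-fold cross-validation. Importances are the tree's native
measure (including surrogate credit), the forest's Gini decrease, or, for
naive Bayes, the absolute standardised mean class difference. The
published validation scheme behind its accuracy figure is unstated, so
the CV design here is a declared choice.

## The synthetic-data generator

`default_config()` mirrors the study design: WT and disease groups at 2,
4, 6, 8, 10, 12 months, the treated group from 4 months, n = 6, 102
animals, 15 elements. Marginals are log-normal — concentrations are
positive and ICP-MS data right-skewed — with log-scale sd (≈ CV) 0.2 per
element, baseline locations spanning realistic relative abundances, and
multiplicative single-observation outliers (rate 0.01, fold 5) matching
the single-suspect assumption of the Q screen.

Rank correlation is planted through a Gaussian copula with latent Pearson
r = 2 sin(πρ/6), the exact identity for the target Spearman ρ — planting
on the rank scale because every downstream statistic is rank-based.
Planted defaults encode the qualitative published pattern: Fe/Zn (+ Hg,
Cd) elevated and Mn depressed in disease; Se strongly elevated under
treatment from 4 months (+1.0 on the log scale, ≈ 5 cell-sd, a high-dose
supplement); Fe fully restored to the control level and Zn half-restored
from 8 months (−0.6 and −0.3); recurring correlation blocks Zn–Cu, Fe–V,
Pb–Cd–Bi (ρ = 0.8) in every cell; the Fe–Mn correlation at 4 months at
the three published group values (0.886 / −0.6 / −0.319); a
disease-only Zn–Se edge and a treatment-only Se–Ca edge. Two defaults
are weakened purely for coherence of the joint distribution: Fe–V is 0.3
in 4-month cells and Zn–Se 0.5, because stronger values alongside the
planted Fe–Mn and Zn–Cu correlations would make the implied latent matrix
non-positive-definite — and the generator *fails loudly* on such configs
rather than repairing them silently, so that planted targets are always
exactly honoured.

What the generator does **not** emulate: instrument noise physics,
isotope interference, digestion recovery, inter-element detection-limit
censoring, or any real covariance beyond the planted structure. Passing
tests therefore demonstrate that the machinery detects what it is pointed
at under the stated design — calibrated type-I error, power against
planted shifts and correlation flips, block recovery — not that any
particular biological finding would replicate.

## Numerical choices and problem sizes

* Empirical quantiles: R type-7 linear interpolation.
* Null simulation draws are tie-free random permutations (a
  continuous-data assumption); measured data use midranks.
* Degenerate inputs error early and loudly: constant vectors for
  correlations, zero-variance cells for normality tests, non-PD planted
  correlation matrices, out-of-table Dixon sizes.
* Determinism: every stochastic stage takes a seed; the pipeline derives
  per-stage substreams from one top-level seed, so stages rerun
  standalone reproduce their in-pipeline results.
* Test problem sizes: copula identity checks run at n = 5000 replicates;
  threshold reproduction at the full 1000 × 1000 protocol; type-I
  calibration over 1000 simulated panels; power/recovery properties over
  20–40 seeded replicates — sizes chosen so the whole suite stays
  comfortably reproducible on a laptop while keeping Monte-Carlo error
  well inside the asserted bands.

## Known limitations

* The ΔSCC confidence half-width produced by this protocol (~0.08 at
  n = 6) is larger than the published ±0.036, though the point estimates
  agree; the published ΔSCC interval protocol is evidently different and
  is not specified. Only the point is treated as reproducible.
* Dixon critical values ship for α = 0.05 only, n = 3..10.
* Sample-wise clustering (clustering animals rather than elements) is not
  implemented; the element-wise direction is the one with stated
  published structure.
* No network layout: exports are SIF/GraphML for Cytoscape.
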