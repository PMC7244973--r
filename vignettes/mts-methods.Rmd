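---
title: "The Mahalanobis-Taguchi system in mtsdx: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Mahalanobis-Taguchi system in mtsdx: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsdx)
```

## The measurement model

The Mahalanobis-Taguchi system (MTS) builds a *one-class* measurement scale:
only the healthy group is modelled. Given healthy subjects measured on $k$
biomarkers, the reference ("Mahalanobis") space consists of the per-variable
sample means $m_j$ and standard deviations $s_j$ (with the $n-1$ denominator),
and the Pearson correlation matrix $R$ of the standardized variables. Any
subject $x$ is scored by the scaled Mahalanobis distance

$$\mathrm{MD}(x) \;=\; \frac{1}{k}\, z^\top R^{-1} z,
\qquad z_j = \frac{x_j - m_j}{s_j}.$$

The $1/k$ scaling puts healthy subjects near 1: when the space is fit and
evaluated on the same $n$ complete rows, the sample mean of MD is exactly
$(n-1)/n$ — a useful internal consistency check, asserted in the test suite to
$10^{-10}$. An unscaled variant ($z^\top R^{-1} z$) is available through
`mts_config(md_scaled = FALSE)`; everything downstream (SN ratios, ROC) is
defined on whichever scale is configured, and the scaled form is the default
because the "healthy $\approx$ 1" convention and the decibel magnitudes of the
SN analysis rely on it.

Standardization makes MD invariant to affine rescaling of any variable and to
variable order (both property-tested), so units never matter.

**Numerical degeneracy.** Biomarker panels are collinear even after pruning.
When the condition number of $R$ exceeds $10^{10}$, or inversion fails,
`fit_space()` switches to the Moore-Penrose pseudo-inverse, flags the space
(`pseudo_inverse = TRUE`) and warns — never a silent fallback. A zero-variance
variable is a fit error naming the variable, since its standardization is
undefined.

## The pipeline

`mts(normal, abnormal, config)` runs, in order:

1. **Complete-case filtering.** Any row with a missing cell is removed
   (`drop_incomplete_rows()`); non-numeric cells become `NA` at parse time and
   are never coerced to 0. No imputation: the targeted missingness is sparse
   and completely at random, and the correlation matrix needs complete rows.

2. **Redundancy pruning** (`pearson_prune()`). Pairs with $|r| > 0.80$
   (configurable, strict inequality, absolute value) are resolved greedily in
   descending $|r|$; the kept member is decided by an ordered keep-list,
   falling back to the lower column index. The keep-list default is the
   14-variable complete-blood-count panel of `default_keep_list()` because
   reserved-variable choices in practice are domain judgments (e.g. preferring
   a count over a ratio), not rule-generated; an explicit ordered list is
   reproducible where a heuristic would be arbitrary. Pruning is fit on the
   healthy group only and applied to both groups.

3. **Reference-space refinement** (`refine_space()`). The healthy rows are
   scored against their own space and screened with the individuals/moving-range
   control limit $T = \mu + 2.66\,\bar R$, where $\mu$ is the mean MD and
   $\bar R$ the mean absolute successive difference; $2.66 = 3/d_2$ with
   $d_2 = 1.128$ is the standard XmR constant. Rows with $\mathrm{MD} > T$
   (strict) are removed and the space refit. The moving range depends on row
   order — inherent to individuals charts — so the input order is the
   observation order and is what the report records. One pass is the default;
   `refine_passes` allows iterating to convergence, under which the
   construction set is non-increasing (property-tested).

4. **Variable screening** (`run_oa_experiment()`). The pruned variables are
   assigned, in order, to the first columns of a two-level orthogonal array
   with the smallest power-of-two run count exceeding the variable count
   (Hadamard construction; balance and pairwise orthogonality are verified
   exhaustively in tests up to 64 runs). Level 1 means *included*, level 2
   *excluded* — so run 1, all ones, is the full model. Per run, the space is
   refit on the refinement survivors restricted to the included subset and
   the abnormal group is scored; the run statistic is the larger-the-better
   SN ratio
   $$\mathrm{SN} = -10 \log_{10}\Bigl(\tfrac1n \sum_i 1/\mathrm{MD}_i\Bigr)
   \ \text{dB},$$
   which rewards subsets that push *all* abnormal subjects far from the
   healthy space (the reciprocal mean is dominated by the least-separated
   patients). A variable's *gain* is its level-1 mean SN minus its level-2
   mean SN; variables with strictly positive gain are kept, ordered by
   descending gain (`select_variables()`). A gain of exactly zero is not
   selected. If nothing has positive gain the pipeline falls back to all
   pruned variables with a prominent warning rather than returning an empty
   model.

5. **Thresholding** (`roc_curve()`). The final space is refit on the selected
   variables; all complete healthy rows and all abnormal rows are scored and
   an ROC curve built for the strict rule "abnormal iff $\mathrm{MD} > t$".
   Candidate thresholds are the midpoints between consecutive sorted unique
   pooled scores plus sentinels beyond both extremes, so every achievable
   operating point occurs exactly once. AUC is computed by the trapezoidal
   rule *and* by the Mann-Whitney rank statistic with ties counted half; the
   two are asserted equal (to $10^{-12}$ across 1000 random instances in the
   tests). The diagnostic threshold maximizes the Youden index
   $J = \mathrm{Se} + \mathrm{Sp} - 1$; at ties the *smallest* threshold wins,
   favoring sensitivity — in a screening context a missed patient costs more
   than a false alarm.

6. **Evaluation** (`kfold_evaluate()`, optional). Both groups are partitioned
   independently into near-equal folds with the seeded RNG (stratification
   mirrors group-wise train/test counts); the whole pipeline, pruning
   included, is refit per fold on training data only. Per-fold and mean
   sensitivity/specificity are reported.

Two ambiguities were resolved as package design choices. The per-run spaces in
step 4 use the refinement *survivors* (the screened reference is the better
estimate of the healthy center, and the screen exists precisely to protect the
scale). The training ROC in step 5 scores *all* complete healthy rows, not
only the survivors: the removed rows are still healthy subjects and excluding
them would overstate specificity, while the space parameters themselves come
from the screened subset.

## The synthetic test bed

`generate_population()` draws the healthy group from a multivariate normal
with configured means, SDs and correlation; the disease group is identical
except for mean shifts expressed in healthy-SD units. Optional near-duplicate
columns (`(1-f)\,x + f\,\varepsilon`) manufacture $|r| > 0.9$ pairs so pruning
always has work, and missing cells are injected completely at random.
`default_blood_profile()` ships a routine-blood-count-like configuration:
the 14-variable panel with physiologically plausible scales, moderate
within-block correlations (leukocyte, red-cell, platelet), group sizes
1480/355, shifts concentrated on the 7 diagnostically useful variables
(largest on PDW, then MPV), and a plateletcrit-like `PCT` column at
$r \approx 0.99$ with PLT. Under these defaults the training AUC is about
0.93.

What the generator does *not* emulate: real blood counts are skewed,
heavy-tailed and device-dependent, and clinical missingness is rarely
completely at random. Passing tests on this Gaussian bed therefore validate
the *algorithmic* contracts (identities, invariances, recovery of planted
signal) — they say nothing about diagnostic accuracy on real cohorts, and the
published clinical operating characteristics of this workflow are not
reproducible from synthetic data by design. A log-normal generator is the
obvious extension point.

**Problem sizes used by the test suite** (the package's own choices): moment
convergence at $n = 10{,}000$; null-AUC checks at $n = 1{,}000$ per group over
5 seeds; signal recovery at $n = 200$ per group, shift 3 SD on 3 of 10
variables, 100 seeds; the end-to-end blood-profile fit at the default
1480/355.

## Two properties of the SN analysis worth knowing

Both surfaced while validating the screening stage and are inherent to
saturated two-level designs with the scaled MD, not implementation artifacts.

**Set-size offset.** Under the null (abnormal $\equiv$ healthy),
$k \cdot \mathrm{MD}$ of a new subject is asymptotically $\chi^2_k$, so
$E[1/\mathrm{MD}] \approx k/(k-2)$: runs that include more variables get
systematically *higher* SN ratios even with no signal anywhere. Because level-1
runs of any column average one more included variable than its level-2 runs,
every gain carries a common small positive offset (about $+0.6$ dB at 10
variables on a 16-run array). The null signature is therefore *exchangeability
across variables* — no column stands out once the common offset is removed —
which is exactly what the null-simulation test asserts. In the shifted case
the offset is swamped by, and partially cancels against, the dilution of the
$1/k$ scaling.

**Interaction aliasing.** In the Hadamard construction, column $a \oplus b$
(bitwise XOR) carries the two-factor interaction of columns $a$ and $b$. A
null variable assigned to the interaction column of two strongly shifted
variables absorbs their (negative) interaction into its gain — measured at
about $-1.7$ dB for a pair of 3-SD shifts. The recovery fixture in the tests
therefore plants its three shifted variables on the XOR-closed column triple
$\{1, 2, 3\}$, confining interaction aliasing within the shifted set. Users
screening real panels should remember that a saturated design cannot separate
main effects from interactions; gains are screening statistics, not effect
estimates.

## The packaged worked example

`blood_oa_example()` ships a complete published screening experiment — a 16-run
design over the 14-variable blood panel with its per-run SN ratios (recorded
to 2 decimals) from a clinical asthma study whose underlying data were never
deposited. From those 16 numbers alone, `compute_gains()` reproduces the
published level means and gains to within rounding (PDW gain 5.11 dB, MPV
0.70, WBC 0.39, EO# 0.31, MO# $-0.43$, ...) and `select_variables()` returns
exactly the published 7-variable panel {PDW, MPV, WBC, EO#, LY#, LY, MCHC} in
descending-gain order:

```{r worked-example}
ex <- blood_oa_example()
sn <- compute_gains(ex$run_sn, ex$oa, ex$variables)
round(sn$gain, 2)
select_variables(sn)
```

The study-scale quantities that *depend on the undeposited data* — the
clinical sensitivity/specificity/AUC, the refinement removal count, the exact
threshold, the observed correlation pairs — are computed and reported by the
package for whatever data it is given, but their published values are not
assertable and the package does not pretend otherwise.

## Known limitations

* One-class Gaussian-ish reference: no robust (minimum covariance determinant)
  estimation, so gross healthy-group contamination beyond what the XmR screen
  catches will distort the scale.
* Two-level arrays only; no interaction-column assignment, no three-level
  designs, no alternative SN definitions (nominal-the-best etc.).
* No cost-weighted or prevalence-adjusted thresholds and no confidence bands
  on the ROC; the Youden point is the single shipped operating rule.
* Binary diagnosis only; severity grading (a multiclass reference scale) is
  out of scope.
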