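---
title: "Constrained PCA with split-half reliability: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained PCA with split-half reliability: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpca)
```

## The model

Constrained PCA treats a standardized criterion block $Z$ ($N \times q$
cognitive scores) and predictor block $G$ ($N \times p$ symptom items) in
two stages. The *external analysis* is a multivariate least-squares
projection, $\hat Z = G (G^\top G)^{-1} G^\top Z$, which isolates the part
of every criterion predictable from the predictors; its size is summarized
by the overlap fraction
$\mathrm{tr}(\hat Z^\top \hat Z)/\mathrm{tr}(Z^\top Z)$, the variance-
weighted mean of the per-criterion regression $R^2$. The *internal
analysis* is an SVD of $\hat Z$: component scores are left singular vectors
rescaled to unit variance, and loadings are expressed as Pearson
correlations of the scores with the constrained criteria (component
loadings) and with the raw predictors (predictor loadings). Components are
varimax-rotated with Kaiser normalization — the convention of the major
commercial statistics packages — and each component's sign is fixed so its
dominant criterion loads positively.

Two facts shape everything downstream. First, with $p$ predictors and $N$
subjects the projection retains about $p/(N-1)$ of *any* criterion's
variance even under independence, so raw overlap and single-sample loadings
are optimistic; at $p = 27$, $N = 198$ the null overlap is
$27/197 \approx 13.7\%$, and in half-samples ($N/2 \approx 99$) it is
$27/98 \approx 27.6\%$. Second, component scores live inside the column
space of $G$, so their correlations with individual predictor columns are
inflated relative to the latent associations that generated the data.

## Split-half reliability (PLRP)

The iterative layer addresses the first problem empirically. For each of
`n_iter` (default 1,000) iterations the subjects are partitioned at random
into two halves (sizes $\lceil N/2 \rceil$ / $\lfloor N/2 \rfloor$, the
larger half assigned at random when $N$ is odd). Each half is standardized
and fitted independently, and both half-solutions are aligned to the
full-sample reference by maximizing total Tucker congruence between
component-loading columns — solved exactly by enumeration over column
permutations and signs. Congruence is computed on *component* loadings
because the criteria define what a component means. A predictor–component
cell succeeds in an iteration when its loading magnitude reaches the
threshold $r^\ast$ in both halves; the predictor loading reliability
proportion (PLRP) is the percentage of successful iterations. The default
is $r^\ast = 0.26$; a data-driven alternative is the two-tailed $\alpha = 0.05$ critical $r$ for the
half-sample size ($\approx 2/\sqrt{N/2}$, 0.20 at $N = 198$), and every run
records the threshold used.

## Permutation significance and FDR

A PLRP is only interpretable against what chance produces, so the null is
built by permutation: subject rows of $G$ are shuffled relative to $Z$,
destroying all predictor–criterion association while preserving both
blocks' marginal and internal correlation structure, and the whole
split-half engine is re-run on each permuted dataset (with a reduced
iteration count, default 200). Null PLRP values are pooled across
predictors within a component — predictors are exchangeable under the null,
and pooling gives fine p-value resolution from a modest number of
replicates — and the p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + \text{pool size})$,
which is monotone in the observed PLRP and never zero. Per-cell nulls are
available by option. Flags come from the Benjamini–Hochberg step-up rule
applied jointly to all $p \times m$ cells at $\alpha = 0.05$.

Note the granularity interaction: with $B$ permutation replicates the
smallest attainable p-value is $1/(1 + pB)$ under component pooling, and
Benjamini–Hochberg at rank $i$ requires $p \le i\alpha/(pm)$. Runs intended
for inference should therefore use enough replicates (the default
`n_perm = 199` gives a floor of $1/5374 \approx 1.9\times10^{-4}$, well
below the rank-1 cutoff).

## Component retention

The number of components is chosen by the scree eigenvalues of
$\hat Z^\top \hat Z/(N-1)$ together with Horn's parallel analysis. Because
the constraint step reshapes the spectrum (see the $p/(N-1)$ floor above),
the default parallel-analysis mode passes every null replicate of
independent normals through the external analysis before
eigendecomposition, so the null respects the constraint; classical parallel
analysis on the raw criteria is available as `mode = "on_criteria"`.
Components are retained while the observed eigenvalue exceeds the null
quantile (default 0.95), counting from the first.

How many *criterion* variables to interpret per component is a separate
question. The default strategy ranks criteria by reference loading
magnitude and, for each candidate count $k$, refits the split-half engine
on the top-$k$ subset (reduced iterations), identifies the refitted
component matching the target by congruence, and records the mean PLRP of
the component's significant predictors; the chosen $k$ maximizes this
curve, ties resolved toward fewer criteria. In our experiments this curve
is *not* sharply peaked when a component has a single strong predictor: a
constrained component built from even one or two criteria already
correlates reliably with its dominant predictor, so the curve sits near its
ceiling from very small $k$ and the argmax is driven by Monte-Carlo noise.
We also examined a variant that residualizes the retained criteria on the
non-retained ones before refitting (so an undersized set loses the variance
it shares with what was left out); it penalizes small $k$ but inherits the
same plateau above the true count. The curve strategy is therefore best
read as a diagnostic plot, and `retention = "fixed_k"` is provided for
analyses that fix the counts a priori (for instance, interpreting three
criteria for a verbal-memory component and four for an
attention/working-memory component). Averaged component scores are the
per-subject means of the aligned half-scores over all iterations, centered
per component.

## The synthetic generator

`synthetic_spec()` defines a latent-factor population: latents are iid
standard normal; criteria are latents times a loading matrix plus Gaussian
noise (noise SD defaults to $\sqrt{1-\text{communality}}$, giving
unit-variance columns); predictors are built the same way and then
discretized through fixed Gaussian quantile cut points into an ordinal
1–7 scale. The default cut points put 30% of mass at level 1 and only 1.5%
at level 7, mimicking outpatient symptom ratings where most items are mild;
ordinal items are z-scored downstream like any column. The
`preset_panss_mccb()` preset emulates a multisite chronic-schizophrenia
design: $N = 198$, the 27 PANSS items that remain after excluding the
scale's three cognitive-factor items (N5, G10, G11), and 15 MCCB-derived
scores. Two latents are planted: a verbal memory/learning dimension carried
by the HVLT trials (population loadings 0.62–0.70) and predicted by item N6
(latent loading $-0.62$), and a visual attention/working-memory dimension
carried by CPT-IP 3/4-digit, digit-symbol coding and backward spatial span
(0.52–0.65) predicted by item G7 ($-0.63$). All other symptom items load at
most 0.12. The planted predictor loadings were calibrated once, by
simulation, so that the two planted cells are reliably recovered
(PLRP > 80% across seeds) after discretization attenuation, and so that the
half-sample overlap averages in the low 30s of percent; both the
calibration target band and the recovered magnitudes are reported by the
acceptance script rather than assumed.

What the generator does *not* emulate: site effects and rater differences,
correlated residuals among symptom items (beyond the two latents), missing
data that depends on severity (its missingness is completely at random),
and floor effects in cognitive scores. Passing tests on this generator
therefore show that the machinery recovers a planted low-rank
symptom–cognition structure under realistic dimensions and ordinal
measurement — not that any particular clinical dataset satisfies the
model. One visible artifact of the single-dominant-indicator design is
that observed predictor loadings for N6 and G7 come out around $-0.7$ to
$-0.8$, larger in magnitude than the planted values, precisely because of
the predictor-span inflation described above.

## Numerical choices

* Standardization uses the $N-1$ variance and is applied *within* each
  half-sample, so half-solutions are self-contained.
* Rank checks treat singular values below $10^{-10}$ times the largest as
  zero; a rank-deficient predictor block is an error naming the collinear
  columns rather than a silent pseudo-inverse.
* Varimax convergence: relative criterion gain below $10^{-8}$, at most
  1,000 sweeps; non-convergence returns the best iterate.
* Alignment enumerates all $m!$ column assignments (components are few);
  congruence signs break ties toward $+1$.
* A singular half-fit (possible with degenerate ordinal columns) is
  resampled, at most 10 times per iteration, and counted in the run log.
* Missing data: listwise deletion is the default; mean imputation is
  offered. The choice is recorded in the provenance log of every assembled
  sample because published per-measure Ns often differ and the original
  handling is rarely stated.
* All randomness flows from one seeded generator; a fixed seed makes the
  whole pipeline, including permutation p-values, bit-reproducible.

## Summary-statistics inference

The `*_from_summary` family reconstructs classical tests exactly from
per-group $(n, \bar x, s)$: one-way ANOVA ($SS_b = \sum n_i(\bar x_i -
\bar x)^2$, $SS_w = \sum (n_i - 1) s_i^2$, $\eta^2 = SS_b/(SS_b + SS_w)$),
Scheffé contrasts ($|\bar x_i - \bar x_j| > \sqrt{(k-1) F_{\alpha}
MS_w (1/n_i + 1/n_j)}$), pooled-variance $t$ with Cohen's $d$, and
Pearson's chi-square without continuity correction (the correction applies
only to $2\times2$ tables and is not used here). SDs are sample SDs
($N-1$). When the inputs are a published table's rounded means and SDs, the
reconstructed statistics agree with the published ones only to the
precision the rounding permits — about $\pm0.02$ on an $F$ in the twenties
— which is the comparison convention used by the test suite.

## Problem sizes used by the tests

The packaged checks run the engine at reduced but non-trivial sizes chosen
to exercise every code path: null calibration uses 50 independent datasets
($N = 198$) with 60 split-half iterations and 29 permutation replicates of
30 iterations each; planted-structure recovery uses 20 datasets with 120
iterations and the same permutation settings; the reproducibility check
runs the full 1,000 iterations with 99 permutation replicates. These sizes
keep the whole suite in the tens of minutes on a single core while leaving
the Monte-Carlo error well inside the asserted margins.

## Known limitations

* The permutation null for the PLRP is this package's construction;
  absolute p-values should be compared across analyses only when the null
  settings (replicates, pooling, iteration counts) match.
* Tucker-congruence alignment can mislabel components when two components
  have nearly identical criterion profiles; the recorded congruence values
  should be inspected when components are weakly separated.
* Whether component scores should be correlated with predictors before or
  after rotation is a genuine fork; this package rotates scores jointly
  with loadings and correlates afterwards.
* Oblique rotations, bootstrap confidence intervals for loadings, and
  multi-site harmonization are out of scope.
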