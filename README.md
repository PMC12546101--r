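# icpca

Iterative constrained principal component analysis for symptom–cognition
modelling, with a synthetic-data generator and closed-form inference from
published group summaries.

## The problem

In schizophrenia-spectrum research a recurring question is which individual
symptoms — not symptom subscale totals — predict which combinations of
cognitive abilities. Constrained principal component analysis (CPCA) answers
this by combining multivariate multiple regression with dimensionality
reduction. Given a criterion block **Z** (N subjects × q cognitive scores)
and a predictor block **G** (N × p symptom ratings), both standardized:

1. **External analysis** regresses each criterion on all predictors, keeping
   only the predictable part: **Ẑ** = **G**(**G**ᵀ**G**)⁻¹**G**ᵀ**Z**. The
   *overlap* trace(**Ẑ**ᵀ**Ẑ**)/trace(**Z**ᵀ**Z**) is the share of criterion
   variance the symptoms can explain (the mean per-criterion R²).
2. **Internal analysis** extracts principal components of **Ẑ** by singular
   value decomposition; components are varimax-rotated (Kaiser-normalized).
3. **Component loadings** are Pearson correlations between component scores
   and the constrained criteria; **predictor loadings** correlate the scores
   with the symptom items.

Because **Ẑ** is fitted with many predictors on modest N, single-sample
loadings are optimistic. The *iterative* layer (iCPCA) quantifies their
reliability: the sample is split at random into two halves, each half is
fitted independently and aligned to the full-sample reference by Tucker
congruence, and a predictor–component cell counts a success when its loading
magnitude reaches a threshold r\* (default 0.26) in **both** halves. The
percentage of successes over many iterations is the **predictor loading
reliability proportion (PLRP)**. Significance comes from a permutation null
(subject rows of **G** shuffled against **Z**) with Benjamini–Hochberg
false-discovery-rate control, and the number of components is chosen by the
scree eigenvalues and Horn's parallel analysis.

The package also ships `anova_oneway_summary()`, `scheffe_summary()`,
`chisq_independence()`, `t_from_summary()` and `pearson_r()` — closed-form
inference from printed group summaries (n, mean, SD per group), so published
demographic tables can be re-analysed exactly without raw data.

## Worked example

```r
library(icpca)

spec <- preset_panss_mccb()          # 198 subjects, 27 PANSS items, 15 MCCB scores
m    <- generate_sample_matrix(spec, seed = 42)

res <- run_icpca(m, n_components = 2, n_iter = 1000, threshold = 0.26,
                 n_perm = 99, n_iter_perm = 100,
                 retention = "fixed_k", retain_k = c(3, 4), seed = 17)
print(res)
```

```
iterative constrained PCA (1000 split-half iterations, r* = 0.26)
  overlap: 34.62% of criterion variance (half-sample mean); 22.18% (full sample)
  constrained variance by component: 27.0%, 26.9% (total 53.9%)
  reliable predictors (BH-significant PLRP):
    G7 -> C1: loading -0.78, PLRP 98%, p = 0.000374
    N6 -> C2: loading -0.80, PLRP 92%, p = 0.000374
```

The overlap line says that about a third of the cognitive-score variance in
a random half-sample is predictable from the symptom items (the full-sample
figure is lower because half-samples fit 27 predictors to ~99 subjects). The
two flagged cells are exactly the associations the generator plants: *Lack
of Spontaneity and Flow of Conversation* (N6) predicting the verbal
memory/learning component and *Motor Retardation* (G7) predicting the
visual attention/working-memory component; all other 52 predictor cells
stay non-significant. Component labels (`C1`, `C2`) are arbitrary — use
`match_components()` to map them onto criterion profiles of interest.
`horns_parallel(m)` compares the constrained eigenvalues with null
quantiles and retains the two planted components in most samples (the
second sits near the 0.95 null boundary at this N, so occasional samples
retain one), and
`write_results(res, "results/")` exports the loading tables, averaged
component scores and run metadata.

Published summary tables are reproduced with the summary-inference tools:

```r
sc <- site_comparison(system.file("extdata", "table1_site_summaries.csv",
                                  package = "icpca"))
subset(sc$anova, variable == "panss_negative")
#>         variable        F df_between df_within            p eta_squared
#> 5 panss_negative 26.51037          2       195 6.543265e-11   0.2137754
#>   grand_mean
#> 5   16.88667
```

A thin command-line front end mirrors this workflow
(`inst/cli/icpca.R`: subcommands `simulate`, `fit`, `run`, `pa`, `table1`).

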