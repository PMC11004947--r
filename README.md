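# sbmpet

Source-based morphometry (SBM) for cohorts of parametric synaptic-density
PET images, with the nonparametric statistical battery used to relate the
resulting spatial patterns to diagnosis and cognition.

## The problem and the model

Synaptic loss in early Alzheimer's disease can be imaged *in vivo* with PET
tracers for the synaptic vesicle glycoprotein 2A (SV2A), quantified as
parametric distribution volume ratio (DVR) maps referenced to the whole
cerebellum, `DVR(v) = (BP_ND(v) + 1) / (BP_ND,Cb + 1)`, so that the
reference region sits at DVR = 1. Rather than comparing pre-defined
regions of interest, SBM asks which *spatial covariance patterns* the
cohort shares: the smoothed, masked images are stacked into a
subjects-by-voxels matrix `X` (each row demeaned), reduced by PCA, and
unmixed by spatial Infomax ICA into

```
X  ≈  A S,        A: subjects × K loading weights
                  S: K × voxels independent spatial sources
```

Each row of `S` is a covariance pattern of synaptic density, displayed as a
unit-SD Z map thresholded at `|Z| > 3` with connected clusters of more than
500 voxels tabulated. Each column of `A` gives per-subject loading
weights — how strongly a pattern is expressed in an individual — which are
compared between diagnostic groups (CN / MCI / AD dementia) with
Kruskal–Wallis tests under Benjamini–Hochberg FDR control, and correlated
(Spearman) with cognitive and functional scores (CDR-sb, MMSE, LMII,
RAVLT-delay) in the symptomatic-only and full cohorts.

Because clinical SV2A-PET cohorts are rarely shareable, the package ships a
synthetic-cohort generator that plants known spatial sources, group-graded
loading shifts and loading-linked scores into DVR-scale volumes, so every
stage of the pipeline can be validated against ground truth.

## Worked example

```r
library(sbmpet)

# a 57-subject synthetic cohort: 19 CN / 14 MCI / 24 AD, 32^3 grid,
# four planted sources, group shift and cognition links on source 1
coh <- make_cohort(cohort_config(), c(19, 14, 24), seed = 1)

run <- run_sbm_pipeline(coh, seed = 1, n_components = 6,
                        mask = coh$truth$anatomy$mask,
                        min_cluster_voxels = 100)
run
#> <sbm_run> 57 subjects, 6 components (seed 1)
#>   ICA converged after 50 passes; reconstruction RMSE 0.00172
#>   6 suprathreshold cluster(s) across 4 source(s)
#>   group differences: 2/6 components FDR-significant
```

Group comparison of the loading weights (one Kruskal–Wallis row per
component, BH-adjusted across the 6-component family):

```r
dplyr::select(run$group_stats, component:significant)
#>   component statistic    df  p_value p_adjusted significant
#> 1         1     0.606     2 0.738       0.738   FALSE
#> 2         2    15.9       2 0.000350    0.00170 TRUE
#> 3         3     1.05      2 0.590       0.738   FALSE
#> 4         4     0.663     2 0.718       0.738   FALSE
#> 5         5     3.06      2 0.216       0.432   FALSE
#> 6         6    15.0       2 0.000566    0.00170 TRUE
```

Component 2 is the estimate of the planted shifted source (the generator's
CN > MCI > AD gradient); its loading weights also recover the planted
cognition links in the symptomatic (MCI+AD) cohort:

```r
dplyr::filter(run$cognition_symptomatic, significant)
#>   component score     rho  p_value   n p_adjusted significant cohort
#> 1         2 cdr_sb  0.914 1.10e-15  38   2.63e-14 TRUE   symptomatic_only
#> 2         2 mmse   -0.902 1.11e-14  38   1.33e-13 TRUE   symptomatic_only
#> ...
```

(The signs are flipped relative to the planted slopes because ICA recovers
sources up to sign; `match_sources()` reports the `-1` sign for this pair.)
Recovery against the planted truth:

```r
match_sources(run$decomposition, coh$truth$sources_true,
              coh$truth$loadings_true)
#>   truth estimate spatial_r  sign loading_r
#> 1     1        2    -0.977    -1    -0.994
#> 2     2        3     0.975     1     0.990
#> 3     3        4     0.959     1     0.996
#> 4     4        5     0.979     1     0.995
```

Every planted source is recovered with |spatial r| ≥ 0.96 and loading
correlation ≥ 0.99. `run$clusters` holds the per-source cluster table
(peak Z, size, peak voxel), `run$zmaps` the unit-SD Z maps, and
`autoplot(run$decomposition)` / `plot_loadings()` / `plot_source_slice()`
give quick visual summaries. Real data enter through
`read_cohort_manifest()` (a TSV of NIfTI paths, diagnoses and scores) or
`read_volume()`; `inst/cli/sbm-pet.R` wraps the same functions as a thin
shell command (`simulate`, `dvr`, `decompose`, `run`).

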