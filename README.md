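# idiffr

Differential identifiability of functional connectomes and their
weighted-graph network properties.

## What problem this solves

A functional connectome (FC) — the symmetric matrix of Pearson correlations
between regional brain-activity time courses — carries a subject
fingerprint: the same person scanned twice ("test" and "retest") looks more
like themselves than like anyone else. `idiffr` is for researchers who want
to measure that fingerprint, for the connectome and for network properties
derived from it, and to ask two questions:

1. Does group-level PCA denoising sharpen the fingerprint, and at how many
   retained components is it sharpest?
2. Does the same reconstruction make the derived properties more sensitive
   to the task the subject performed?

The fingerprint score is **differential identifiability**. With S subjects,
stack the vectorized data as an F × 2S matrix (test and retest columns),
correlate every test column with every retest column to obtain the S × S
identifiability matrix **A**, and set

```
I_self   = mean_i A[i, i]          (same subject, across runs)
I_others = mean_{i != j} A[i, j]   (different subjects)
I_diff   = (I_self - I_others) x 100
```

The F × 2S matrix is decomposed by PCA (column-centered SVD) and
reconstructed from its top *m* variance-ranked components; sweeping *m*
yields the profile I_diff(m), its optimum m\*, and the variance retained
there (R²). The framework runs in both orders: **NP(𝕀f{FC})** reconstructs
the connectomes and then derives each network property, while **𝕀f{NP(FC)}**
derives the properties from the original connectomes and reconstructs the
properties themselves.

Eight network properties are implemented on the clamped weighted graph
(non-positive correlations replaced by machine epsilon, 2.22e-16): degree
strength, weighted shortest path length (lengths 1/w), search information,
mean first passage time of the weighted random walk, driftness (expected
walk journey over shortest path length, ≥ 1 by construction),
degree-normalized communicability, Onnela's weighted clustering coefficient,
and weighted betweenness centrality. Task sensitivity uses the one-way
intraclass correlation ICC(1,1) with conditions as groups and a subject's
two runs as members, averaged over subjects per feature.

A synthetic-cohort generator produces valid test–retest correlation matrices
with tunable subject, condition and noise components (time-series mixture →
Pearson correlation), so the full pipeline is testable without restricted
data.

## Worked example

```r
library(idiffr)

design <- cohort_design(
  n_subjects = 10, cortical_nodes = 30, subcortical_nodes = 0,
  conditions = c("rest", "motor"), timeseries_length = 300,
  subject_signal = 0.6, condition_signal = 0.2, noise_signal = 0.4,
  seed = 42
)
cohort <- generate_cohort(design)
cohort
#> <fc_cohort> 40 matrices (30 x 30): 10 subjects, 2 conditions, runs test/retest

study <- run_study(cohort, properties = c("spl", "search_info"),
                   m_range = seq(2, 20, by = 2))
study$summary
#> # A tibble: 10 × 7
#>    condition scenario            property m_star I_diff_star R2_star I_diff_full
#>    <chr>     <chr>               <chr>     <int>       <dbl>   <dbl>       <dbl>
#>  1 rest      FC_baseline         fc            8        95.2   0.684        51.2
#>  2 rest      NP_of_reconstructe… spl           8        88.2   0.684        28.7
#>  3 rest      NP_of_reconstructe… search_…      8        83.0   0.684        28.3
#>  4 rest      reconstructed_NP_o… spl           8        82.2   0.602        28.7
#>  5 rest      reconstructed_NP_o… search_…      6        88.1   0.462        28.3
#>  6 motor     FC_baseline         fc            8        95.8   0.685        51.9
#>  # ... 4 more rows
```

Reading the table: for the rest condition, the connectome fingerprint peaks
at m\* = 8 of 20 components (I_diff ≈ 95 with 68% of variance retained),
far above its value at full reconstruction (≈ 51) — denoising the group
decomposition roughly doubles the fingerprint. The same holds for the
properties under both scenario orders. `autoplot(study)` draws the
I_diff-versus-m profiles.

Task sensitivity at the per-condition optima:

```r
ts <- task_sensitivity(study)
dplyr::summarise(dplyr::group_by(ts, property, variant),
                 median_icc = median(mean_icc, na.rm = TRUE), .groups = "drop")
#> # A tibble: 6 × 3
#>   property    variant                median_icc
#>   <chr>       <chr>                       <dbl>
#> 1 search_info NP_of_original_FC         -0.0874
#> 2 search_info NP_of_reconstructed_FC     0.553
#> 3 search_info reconstructed_NP_of_FC     0.560
#> 4 spl         NP_of_original_FC         -0.0812
#> 5 spl         NP_of_reconstructed_FC     0.491
#> 6 spl         reconstructed_NP_of_FC     0.440
```

Unreconstructed properties barely distinguish the two conditions (median
ICC ≈ −0.08); after either reconstruction variant the median feature ICC
rises to ≈ 0.44–0.56.

Real data enter through `read_cohort()`: a manifest CSV
(`subject_id,condition,run,path`) pointing at plain delimited correlation
matrices, one per run. `write_cohort()` produces the same layout, and
`run_study_config()` drives everything from a single validated
configuration list, writing outputs plus a provenance record.

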