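# tractica

Group independent component analysis of whole-brain tractography
connectivity matrices, for researchers who want data-driven brain
parcellations that come *with* their white-matter wiring.

Probabilistic tractography seeded from every grey-matter position yields,
per subject, a large nonnegative matrix `M` (seeds × target voxels) of
streamline visitation counts. Seeds with similar connectivity fingerprints
make `M` approximately low-rank, so it can be written as a sum of outer
products

```
M ≈ Σₖ gₖ wₖᵀ,   k = 1 … K
```

pairing a grey-matter "node" map `gₖ` (over seeds) with a white-matter
"edge" map `wₖ` (over targets). `tractica` estimates these pairs by
incremental groupwise PCA over the target dimension (MIGP), FastICA with
independence imposed in the *seed* domain — so grey-matter parcels are
independent while white-matter pathways may overlap — and least-squares
back-projection of the maps onto the full matrix. Around that core it
provides the complete downstream toolkit:

* distance weighting of counts and group averaging (`distance_weight()`,
  `group_average()`);
* Gaussian/gamma mixture-model thresholding of maps at posterior signal
  probability > 0.5 (`fit_ggm()`, `threshold_map()`);
* winner-take-all hard parcellation and split-half reliability with Dice
  overlap, judged against contiguous random Voronoi parcellation nulls
  (`hard_parcellation()`, `dice()`, `run_splithalf()`,
  `voronoi_dice_null()`);
* left/right homologue symmetry scoring (`homologue_correlation()`);
* dual regression onto unseen subjects with scalar per-component weights
  (`dual_regress()`, `component_weights()`, `cohort_weights()`);
* Spearman covariate screening with Storey or Benjamini–Hochberg FDR
  control (`spearman_screen()`, `fdr_correct()`, `add_fdr()`);
* spatial comparison of structural components against functional network
  maps, with the 5%-variance (|r| > √0.05 ≈ 0.22) significance rule
  (`structure_function()`);
* I/O for probtrackx2 `matrix2` sparse triplet files, NIfTI volumes and
  GIFTI surface maps (`read_probtrackx_matrix()`, `export_maps()`), plus a
  versioned native container (`save_container()` / `load_container()`);
* a synthetic multi-subject generator with known ground truth
  (`make_ground_truth()`, `sample_subject_matrix()`), so every stage has a
  parameter-recovery test without external data.

A thin command-line wrapper with `simulate`, `average`, `decompose`,
`threshold`, `parcellate`, `splithalf`, `dualreg`, `associate` and
`structfunc` subcommands ships in `inst/scripts/tractica`.

## Worked example

A complete run on simulated data — twelve subjects, eight planted
components, Poisson count noise at 5000 streamlines per seed:

```r
library(tractica)

spaces <- make_toy_spaces(60, grid = c(6, 6, 6))
gt <- make_ground_truth(spaces$seed_space, spaces$target_space,
                        K_true = 8, n_subjects = 12, rng_seed = 1)
subjects <- lapply(1:12, function(s)
  sample_subject_matrix(gt, s, rng_seed = s)$matrix)

weighted <- lapply(subjects, distance_weight, lengths = gt$length_matrix)
avg <- group_average(weighted)
avg
#> <tractica_connmat> 120 seeds x 216 targets, weighting=averaged, n_subjects_averaged=12

comps <- decompose_group(avg, K = 8, rng_seed = 1)
comps
#> <tractica_components> K=8, gm_maps 8 x 120, wm_maps 8 x 216

glance(threshold_map(comps$gm_maps[1, ])$fit)
#> # A tibble: 1 × 10
#>   n_classes pi_pos      mu  sigma shape_pos scale_pos loglik n_iter converged
#>       <int>  <dbl>   <dbl>  <dbl>     <dbl>     <dbl>  <dbl>  <int> <lgl>
#> 1         2  0.150 -0.0149 0.0212      5.49     0.477   171.      2 TRUE

hard_parcellation(comps, spaces$seed_space)
#> <tractica_parcellation> 120 seeds, K=8 labels (0 unassigned), source=winner-take-all

sh <- run_splithalf(subjects, K_values = 8, spaces$seed_space,
                    n_null = 50, rng_seed = 1)
glance(sh)
#> # A tibble: 1 × 5
#>       K median_gm_r median_wm_r mean_dice null_mean_dice
#>   <dbl>       <dbl>       <dbl>     <dbl>          <dbl>
#> 1     8       1.000       1.000         1          0.511
```

Reading the output: the mixture fit estimates that 15% of the first map's
seeds carry signal (`pi_pos`); the split-half study shows matched
component correlations near 1 and a hard-parcellation Dice of 1.0 at this
(easy) noise level, against a chance level of ~0.51 from contiguous random
parcellations — the gap between those two numbers is the reliability
statement. `autoplot(sh)` draws the reliability boxplots, and
`ggplot2::autoplot()` methods exist for mixture fits and association
tables too.

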