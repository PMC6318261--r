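---
title: "Paired node/edge decomposition of tractography connectivity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired node/edge decomposition of tractography connectivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Probabilistic tractography seeded from every grey-matter position produces,
per subject, a matrix `M` of streamline visitation counts with one row per
seed (cortical vertex or subcortical voxel) and one column per white-matter
target voxel. A row is the seed's *connectivity fingerprint*. Because seeds
that share a fingerprint make `M` rank-deficient, `M` is well approximated
by a sum of K outer products

```
M  ~  sum_k  g_k  w_k^T
```

where `g_k` is a spatial map over seeds (the component's grey-matter
"node") and `w_k` a map over targets (its white-matter "edge"). `tractica`
estimates these pairs by:

1. **Distance weighting** (`distance_weight()`): counts are multiplied by
   the expected tract length (mm) per entry, compensating the systematic
   undercounting of long tracts whose streamlines accumulate orientation
   uncertainty.
2. **Group averaging** (`group_average()`): the element-wise mean across
   subjects gives one representative matrix.
3. **MIGP reduction** (`migp_reduce()`): incremental groupwise PCA over the
   target dimension. Random target-column blocks of size `b` are visited
   once each; the working matrix (left singular vectors scaled by singular
   values, `U diag(s)`) is concatenated with each new block and truncated
   back to rank `d` by an economy SVD. Memory never exceeds `d + b`
   columns, and the retained column space tracks the top-`d` left singular
   subspace of the full matrix. Full-size analyses use `d = 4000`,
   `b = 10000`; both are capped at the matrix dimensions for small inputs.
4. **Seed-domain FastICA** (`fit_ica()`): symmetric (parallel) fixed-point
   iteration with the log-cosh contrast, tolerance 1e-6, at most 1000
   iterations, 3 random restarts keeping the best negentropy objective.
   Independence is imposed across *seeds*, so the K grey-matter maps are
   mutually independent while their white-matter counterparts may overlap
   freely (crossing fibres share territory). A `domain = "tract"` flag
   transposes the problem for the variant where white-matter localisation
   is wanted instead.
5. **Back-projection** (`backproject()`): the K grey-matter maps jointly
   form a design matrix regressed against the full averaged matrix (one
   multiple regression per target column), yielding the paired white-matter
   maps in count units.

ICA leaves sign, scale and order unidentified. We fix them by convention:
each grey-matter map has positive skewness (ties broken by the sign of the
largest-magnitude element), unit variance, and components are ordered by
variance explained in the reduced matrix, descending. Component labels are
therefore not comparable across runs without explicit matching
(`match_components()`).

### Why the data are not demeaned

Classical spatial ICA removes each variable's mean before whitening. We do
not, for two reasons. First, a visitation count of zero is a meaningful
physical zero, not an arbitrary baseline. Second, on matrices whose rows
have been scaled to a common total (a natural normalisation when every
seed emits the same number of streamline samples), the constant seed
vector lies *exactly* in the span of the scaled component maps: demeaning
then removes one full rank of signal and makes a K-component model
unrecoverable at dimension K. Whitening is therefore performed on the raw
second-moment matrix; `fit_ica(center = TRUE)` restores the fMRI
convention if wanted.

## Thresholding: the Gaussian/gamma mixture

A component map mixes a null background with genuine signal. `fit_ggm()`
models the value distribution as Gaussian noise plus a gamma-distributed
positive signal class (optionally a mirrored negative class), the gamma
supported above the robust initial estimate of the noise centre
(interquartile-trimmed mean). Fitting is plain EM with exact M-steps —
weighted gamma maximum likelihood via Newton's method on the shape — so the
log-likelihood is non-decreasing at every iteration, which the tests
assert. Initialisation is deterministic (signal class seeded from the top
5% of values), making fits reproducible without a seed.

Numerical choices that matter:

* convergence is declared at a *relative* log-likelihood change below
  1e-9 (default). This is deliberately tight: mixing proportions keep
  drifting long after the log-likelihood has visually plateaued, and
  stopping early leaves an inflated signal proportion on null data;
* a class whose mixing proportion collapses below 1e-4 is removed and the
  model refitted, with the drop recorded in the `dropped` field;
* `threshold_map()` keeps locations with posterior signal probability
  above 0.5, the conventional cut; the full fit is returned for audit.

## Parcellation, reliability, and the Voronoi null

`hard_parcellation()` assigns each seed to its maximum-weight component
(ties to the lowest index, for determinism). Split-half reliability
(`run_splithalf()`) randomly halves the cohort, decomposes each half at
each requested dimensionality, matches components by maximum absolute
Pearson correlation (best match with replacement — the mapping may reuse a
component), and reports per-component matched correlations plus the Dice
overlap of the matched hard parcels. Dice matching uses maximum label
overlap by default; a greedy one-to-one assignment is available
(`method = "one-to-one"`) and the choice is recorded in the output.

Chance-level Dice is estimated with contiguous random parcellations
(`random_voronoi_parcellation()`): K seed-vertices sampled uniformly, all
seeds labelled by graph-geodesic nearest centre via multi-source
breadth-first search (ties to the earlier-queued centre). Contiguity makes
this null *conservative* — spatially compact parcels overlap more by
chance than arbitrary label sets — so an ICA parcellation beating it is a
meaningful reliability statement.

`homologue_correlation()` quantifies left/right symmetry by correlating
each map with itself re-indexed through the homologue pairing. A component
is called bilateral at self-flip r >= 0.9 (configurable; reported
correlations should always accompany the classification), otherwise
lateralised to the hemisphere holding more top-decile map mass.

## Individual subjects

`dual_regress()` projects a group decomposition onto an unseen subject in
two independent multiple regressions: group grey-matter maps as the design
over seeds give subject white-matter maps; group white-matter maps as the
design over targets give subject grey-matter maps. Designs are
variance-normalised per regressor; the data are not demeaned (same
rationale as above, exposed as `demean = TRUE`).

`component_weights()` condenses each subject-component pair to two
scalars, the dot products of group with subject maps in each domain. The
dot product is scale-ambiguous, so a convention is needed: by default the
*group* map is scaled to unit norm and the subject map enters raw. A
subject identical to the group then scores exactly 1, while genuine
subject-specific amplitude survives in the weight — which is the quantity
covariate screens care about. Cosine similarity (`normalize = "both"`) and
raw products (`"none"`) are available.

`spearman_screen()` rank-correlates every weight against every numeric
covariate (pairwise-complete, exact permutation p for n <= 9, large-sample
approximation otherwise), and `fdr_correct()` controls the false discovery
rate across the full table — Storey q-values (pi0 from the smoother over a
lambda grid) by default, Benjamini-Hochberg always computed alongside via
`add_fdr()` since the two disagree informatively when pi0 is far from 1.

`structure_function()` compares component maps with externally supplied
functional network maps by Pearson correlation over non-excluded seeds.
Because the structural maps have minimal co-linearity, squared correlations
act as variance fractions and are summed per network without capping at 1
(the maps are only approximately uncorrelated, and honesty beats
cosmetics). A pair is flagged when one component explains more than 5% of
a network's spatial variance, i.e. |r| > sqrt(0.05) ~ 0.22.

## The synthetic generator

`make_ground_truth()` / `sample_subject_matrix()` exist so every stage has
a parameter-recovery test with no external data. The generator emulates:

* K sparse grey-matter maps with dominantly disjoint supports built from a
  balanced random partition of seeds (guaranteeing coverage), plus
  configurable overlap via the `sparsity` target — overlap matters because
  ICA assumes independence, not disjointness;
* smooth white-matter fingerprints (two Gaussian bumps over the target
  grid, normalised to unit sum);
* log-normal subject loadings (`loading_sd`, default 0.5);
* exponential count attenuation with seed-target distance
  (`distance_decay`, default 0.02 per mm) together with the true
  length matrix, so `distance_weight()` can be shown to *reduce* (not
  exactly invert) the bias;
* Poisson count noise — visitation counts are counts — at `count_scale`
  5000 expected streamlines per seed, the standard per-seed sampling
  budget.

Rows are scaled by the *population-baseline* expected totals (unit
loadings), shared across subjects: an average subject's seeds emit
`count_scale` expected counts, while subject loading variation survives in
the matrix scale — a per-subject row normalisation would cancel a
component's loading exactly on its dominant seeds and make individual
variation unrecoverable by construction.

What the generator does **not** emulate: fibre geometry, crossing-fibre
ambiguity, registration error, spatially autocorrelated noise, and the
strong inter-regional heterogeneity of real tractography. Passing
recovery tests therefore demonstrate algorithmic correctness under the
stated generative model, not performance on real diffusion MRI.

## Problem sizes used by the tests

The suite runs on toy spaces of 120 seeds (60 per hemisphere) by 216
target voxels with K_true = 8, cohorts of 6-26 subjects; the MIGP oracle
comparison uses a 500 x 2000 rank-20 matrix with d = 50, b = 200; the
FDR simulation uses 1000 tests (10 true effects) over 200 replicates; the
Voronoi null enumeration uses a 12-seed ring where all centre choices can
be enumerated exhaustively. These sizes keep every independent oracle
(exact SVD, brute-force set counting, full enumeration) computable while
exercising the same code paths as a full-size analysis.

## Known limitations

* FastICA at a dimensionality far below the number of true generators can
  cycle without converging on exactly low-rank synthetic data; the fit
  then errors (by contract) rather than returning a half-converged
  solution. Real data, which are never exactly low-rank, do not trigger
  this.
* The Storey pi0 smoother is unstable for very small p-value tables
  (< ~50 tests); BH is the robust fallback and is always reported.
* The native container is an R serialisation with format/version metadata,
  not an HDF5 hierarchy; it is not readable from other languages.
* Graph distances stand in for geodesic surface distances in the Voronoi
  null; on strongly anisotropic meshes the null parcels will be biased
  accordingly.
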