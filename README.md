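# cbparcel

Data-driven functional parcellation of masked fMRI volumes via sparse
representation and dual regression, with quantitative boundary evaluation.

## The problem

Fine-grained functional subdivision of a brain structure (the motivating
case is the cerebellum, whose near-uniform cytoarchitecture defeats
anatomical parcellation) can be derived directly from multi-subject BOLD
fMRI. `cbparcel` implements a complete, testable pipeline for doing so:

1. **Group decomposition.** Subject time-by-voxel matrices are
   standardized per voxel and temporally concatenated into `X`
   (ΣT<sub>s</sub> × V). Batch dictionary learning solves

   min<sub>D,A</sub> ½‖X − DA‖²<sub>F</sub> + λ‖A‖₁,  ‖d<sub>k</sub>‖₂ = 1,

   giving K temporal atoms `D` (each a representative activity pattern
   across the concatenated scans) and sparse group spatial maps `A`
   (K × V). Sparse coding is exact coordinate descent verified against
   KKT optimality; the dictionary update is the exact block minimizer on
   the unit sphere, so the objective trace is provably non-increasing.
2. **Dual regression.** The group maps act as spatial templates: per
   subject, TC = X<sub>s</sub>Aᵀ(AAᵀ)⁻¹ (spatial regression) and then
   B = (TCᵀTC)⁻¹TCᵀX<sub>s</sub> (temporal regression) give
   subject-specific time courses and spatial maps, with regressors
   variance-normalized so map scales are comparable across subjects.
3. **Parcellation.** A one-sample t-test across subjects per (component,
   voxel), mapped to z-scores and FDR-corrected (Benjamini–Hochberg by
   default, Bonferroni optional), yields K significance maps. A global z
   threshold — swept over 1.6–3.0 in steps of 0.1 and chosen to balance
   repeated assignments against unassigned voxels, preferring fewer
   unassigned — converts them into hard labels (argmax of qualifying
   z-scores; 0 = unassigned).
4. **Evaluation.** PCA functional homogeneity (λ₁/Σλᵢ of each parcel's
   time-course covariance), the global distance-controlled boundary
   coefficient (DCBC: within-region minus between-region pair correlation
   compared within 3–30 mm distance bins), per-boundary local DCBC with a
   negative-boundary audit, and a permutation null for calibration.
5. **Connectivity contrast.** Parcel-masked spatial regression extracts
   seed time courses; Pearson correlations to target time courses are
   compared between two conditions with Fisher-z two-sample t-tests under
   FDR control.

A synthetic generator plants spatially compact components with smooth
temporal atoms, configurable SNR and condition-specific seed–target
connectivity, so every stage can be validated against known ground truth.

## Worked example

```r
library(cbparcel)
geom <- generate_geometry(c(8, 8, 8), spacing_mm = 2)
sim  <- generate_group_dataset(geom, K_true = 6, n_subjects = 6, n_time = 120,
                               snr = 5, seed = 3)
res  <- parcellate_bold(sim$subjects, K = 6, seed = 3)
res$parcellation
#> <parcellation> 512 voxels, K = 6, threshold = 3.00
#>   512 assigned (6 nonempty parcels), 0 unassigned

mclust::adjustedRandIndex(res$parcellation$labels, sim$truth$true_labels)
#> [1] 1

pairwise_bin_correlations(sim$subjects, res$parcellation, bin_edges = seq(0, 15, 3))
#> <dcbc_result> 5 distance bins (0-15 mm), global DCBC = 0.9658 (harmonic weights)

homogeneity(sim$subjects, res$parcellation)
#> <homogeneity_result> 36 (subject, parcel) entries; mean eigen ratio 0.9623
```

All 512 voxels are assigned, the six recovered regions coincide exactly
with the planted ones (ARI = 1), within-region pairs are far more
correlated than equally distant between-region pairs (global DCBC 0.97 —
on noisy real data typical values are an order of magnitude smaller), and
the first principal component explains ~96% of each parcel's variance.

## Analysis workflow

The numbered drivers under `analysis/` rerun the study end to end on
synthetic data: `01_simulate.R` (two independent 1000-voxel hemispheres
with 32 planted components each, plus a two-condition connectivity
dataset), `02_parcellate.R` (K = 32 per hemisphere), `03_evaluate.R`
(homogeneity, DCBC, boundary audit) and `04_connectivity.R` (planted
movie-vs-rest contrast). Small result tables land in `results/`, large
intermediates in `scratch/`.

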