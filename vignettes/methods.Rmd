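---
title: "Methods: sparse-representation parcellation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-representation parcellation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbparcel)
```

## The model

`cbparcel` assumes that the BOLD signal of a masked brain structure is a
sparse mixture of a small number of temporal sources. For subject $s$
with standardized data $X_s \in \mathbb{R}^{T_s \times V}$, the
concatenated group matrix $X = [X_1; \dots; X_S]$ is factorized as

$$\min_{D, A} \tfrac{1}{2}\lVert X - D A\rVert_F^2 + \lambda \lVert A \rVert_1,
\qquad \lVert d_k \rVert_2 = 1,$$

where the $K$ columns of $D$ are temporal atoms spanning all subjects'
scans and the rows of $A$ are sparse group spatial maps. Because the maps
are shared while each subject block of an atom is free, the model
tolerates subject-specific time courses — the same assumption that makes
dual regression meaningful. Dual regression then projects the group maps
into each subject (spatial regression: time courses; temporal regression:
subject maps), a one-sample t-test across subjects converts the subject
maps into z-scored group significance maps under FDR control, and a
single global z threshold turns the $K$ maps into one hard labeling.

Assumptions worth stating explicitly: voxel time courses are standardized
(so sparse coding weighs voxels equally and regression needs no
intercept); components have predominantly positive spatial loadings
(z maps are thresholded from above, see "sign orientation" below); and
hemispheres are parcellated independently, so label namespaces never mix.

## Tunable parameters

* **K (dictionary size)** — the number of regions extracted. There is no
  automatic order selection: the motivating study fixed K = 32 per
  hemisphere empirically, and the framework treats it as a design input.
* **λ (sparsity weight)** — default $0.1\sqrt{T}$, which scales with the
  norm $\sqrt{T}$ of a standardized column, keeping the soft threshold a
  fixed fraction of a typical atom–voxel inner product regardless of scan
  length. On the synthetic conditions this yields mean per-voxel support
  close to 1 component; it is exposed as configuration and logged in the
  provenance because no reference value exists.
* **n_iter (default 30)** with relative objective tolerance $10^{-5}$ —
  on planted data the batch solver typically converges in well under ten
  alternations.
* **q (default 0.05)** and the correction method. The source description
  of the procedure ("Bonferroni false discovery rate correction") mixes
  two distinct corrections; the default here is Benjamini–Hochberg FDR
  with Bonferroni available, and the choice is recorded in the
  parcellation provenance.
* **Threshold sweep** — 1.6 to 3.0 in steps of 0.1, applied to
  FDR-surviving z values (correction precedes thresholding). The choice
  policy minimizes $J(\theta) = n_{\mathrm{zeros}}/V + \gamma\,
  n_{\mathrm{overlap}}/V$ with $\gamma = 0.1$: weighting unassigned
  voxels ten times more than surplus assignments operationalizes
  "prefer reducing unassigned voxels" while keeping overlap in the
  objective. Ties go to the smaller threshold; a manual override exists.
  `n_overlap` is the total surplus $\sum_v \max(0, m_v - 1)$ by default
  (consistent with overlap counts exceeding the voxel count in the
  motivating study's reporting); counting multiply-covered voxels
  instead is available behind `overlap_count = "voxels"`.
* **DCBC bins** — $(0,3], (3,6], \dots, (27,30]$ mm; pairs beyond 30 mm
  are ignored. Per-bin weights are harmonic in the pair counts,
  $w_b \propto n_{w,b} n_{b,b} / (n_{w,b} + n_{b,b})$, which
  down-weights bins where either class is scarce (high-variance bin
  means); uniform weighting is available. Pairs touching an unassigned
  voxel are excluded from both classes. Correlations are computed per
  subject and averaged; an optional Fisher-z averaging mode exists but
  is off by default since plain averaging is what "averaging over
  participants" describes.
* **Connectivity contrast** — Fisher z-transform before the two-sample
  t-test (correlations are bounded; the transform is the standard
  variance-stabilizer), with a plain-r mode behind a flag. The test is
  unpaired by default, mirroring the described procedure even though the
  same subjects may appear in both conditions; a paired mode is offered.

## The synthetic generator

`generate_group_dataset()` emulates what the pipeline needs to be true of
real data, with known ground truth: spatially compact regions (seeded
round-robin region growing on the lattice — scattered labels would make
boundary metrics meaningless), smooth temporal atoms (white noise through
a 5-sample moving average, then standardized; BOLD-like autocorrelation
without committing to an HRF), shared spatial loadings with 10%
per-subject multiplicative jitter and per-subject atom draws, and
Gaussian noise scaled per voxel so that the signal/noise standard
deviation ratio equals the requested SNR (optionally AR(1) in time).
`generate_two_condition_dataset()` plants seed–target correlations by
construction, $y = r\,s + \sqrt{1-r^2}\,e$, so the population
correlation is exact.

What it does **not** emulate: hemodynamic response shape, physiological
and motion artifacts, spatial noise correlation, inter-subject spatial
misalignment, and the heavy-tailed signal statistics of naturalistic
stimulation. Passing the planted-recovery tests therefore demonstrates
the pipeline's correctness and identifiability under its own model, not
performance on real scanner data.

Study conditions used by the analysis scripts and the end-to-end tests:
two hemispheres of $V = 1000$ voxels ($10^3$ lattice, 2 mm), 32 planted
components, 20 subjects, $T = 200$, SNR 10 for the headline 64-region
run; SNR 5 with $K = 8$ for the recovery sweep over 10 seeds; 20
subjects, $T = 500$, $r = 0.8$ vs $0.0$ on 8 of 40 targets for the
connectivity contrast. Smaller grids (64–200 voxels) are used where a
brute-force oracle must enumerate every voxel pair.

## Numerical choices

* **Sparse coding** is Gram-based coordinate descent, vectorized over
  voxels, run until the KKT residual (checked every 5 sweeps) drops
  below $10^{-8}$; optimality is asserted in tests at $10^{-6}$. With
  $\lambda = 0$ the exact least-squares solution is returned instead.
* **Dictionary update** maximizes each atom's alignment with its
  residual on the unit sphere, $d_j \propto B_{\cdot j} - D C_{\cdot j}
  + d_j C_{jj}$: the exact block minimizer under $\lVert d\rVert = 1$,
  which keeps atoms unit-norm *and* the full objective monotone (a
  renormalize-after-update scheme would silently rescale the L1 term).
  Dead atoms (zero usage) are reinitialized from the worst-reconstructed
  data column, ties to the lowest voxel index; since their map row is
  zero this leaves the objective unchanged.
* **Initialization** is greedy farthest-point column selection (first
  column random, then repeatedly the column least similar in absolute
  inner product to those chosen), which lands one seed per planted
  component with high probability and is deterministic given the seed.
* **Sign orientation**: an (atom, map) pair is only identified up to a
  joint sign flip; each component is oriented so its map row has
  non-negative sum. Without this, a flipped component's z map would be
  negative everywhere and its region unassignable.
* **t→z conversion** runs through log-scale tail probabilities on both
  tails, so extreme t values map to finite z without underflow, and the
  transform is strictly monotone with sign preserved.
* **Degenerate inputs**: constant voxel columns are zeroed and masked at
  standardization; zero across-subject variance yields t = 0 plus a
  warning counter; constant connectivity targets yield r = 0 plus a
  warning; rank-deficient regression designs abort naming the offending
  components; label ties in hard assignment go to the lowest component
  index.

## Known limitations

Only the batch solver is provided (the online variant of dictionary
learning trades the monotonicity contract for scalability); there is no
spatial-contiguity enforcement or island cleanup on the labels, no
automatic choice of K, no surface-based (grayordinate) geometry, and no
HRF-aware simulation. The DCBC bin weighting is a package choice —
the metric's originating description delegates it — so absolute DCBC
values should be compared only within a fixed weighting scheme.
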