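#!/usr/bin/env Rscript
# Step 1: simulate the study's synthetic datasets.
#
# Two independent "hemispheres" of multi-subject BOLD data with 32 planted
# spatially compact components each (20 subjects, T = 200, V = 1000 voxels
# on a 10x10x10 lattice at 2 mm, SNR 10), plus a two-condition dataset with
# a planted seed-target connectivity difference (r = 0.8 movie-like vs 0.0
# rest-like). Large intermediates go to scratch/; small ground-truth tables
# to results/.

suppressPackageStartupMessages(library(cbparcel))
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

for (h in c("left", "right")) {
  seed <- if (h == "left") 1001L else 1002L
  geom <- generate_geometry(c(10, 10, 10), spacing_mm = 2, hemisphere = h)
  sim <- generate_group_dataset(geom, K_true = 32, n_subjects = 20,
                                n_time = 200, snr = 10, seed = seed)
  saveRDS(sim, sprintf("scratch/sim/%s.rds", h))
  write_geometry(geom, sprintf("results/geometry_%s.tsv", h))
  write.table(data.frame(voxel_id = geom$voxel_ids,
                         true_label = sim$truth$true_labels),
              sprintf("results/truth_labels_%s.tsv", h),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sizes <- table(sim$truth$true_labels)
  message(sprintf("%s hemisphere: V = %d, 32 regions of %d-%d voxels, seed %d",
                  h, n_voxels(geom), min(sizes), max(sizes), seed))
}

seed_geom <- generate_geometry(c(3, 3, 3), spacing_mm = 2, hemisphere = "synthetic")
conn <- generate_two_condition_dataset(seed_geom, n_cortex_targets = 40,
                                       n_subjects = 20, n_time = 500,
                                       r_A = 0.8, r_B = 0, n_planted = 8,
                                       seed = 1003L)
saveRDS(conn, "scratch/sim/two_condition.rds")
message(sprintf("two-condition dataset: %d targets (%d planted at r = 0.8 vs 0.0), 20 subjects x T = 500",
                40, 8))
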