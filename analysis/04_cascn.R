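#!/usr/bin/env Rscript
# Seed-based voxel-wise causal structural covariance maps: WMH-ordered
# pseudo-time, signed lag-1 GC in both directions, permutation cluster FDR.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_config.R"))

sim <- load_study()
pts <- build_pseudo_timeseries(sim$images, sim$cohort, COVARS)
seed_roi <- sim$truth$source_roi
seed_series <- extract_seed_series(pts, seed_roi)

maps <- voxelwise_cascn(pts, seed_series, seed = seed_roi, config = ACFG)
for (dir in names(maps)) {
  cl <- threshold_cascn(maps[[dir]], pts, seed_series, ACFG,
                        seed = STUDY_SEED + 17L)
  write_stat_map(maps[[dir]]$gc, sim$images$affine,
                 file.path(RESULTS_DIR, paste0("cascn_gc_", dir, ".nii.gz")))
  write_stat_map(maps[[dir]]$z, sim$images$affine,
                 file.path(RESULTS_DIR, paste0("cascn_z_", dir, ".nii.gz")))
  write_tsv(cl, paste0("cascn_clusters_", dir, ".tsv"))
  cat(sprintf("%s: %d cluster(s), %d significant\n",
              dir, nrow(cl), sum(cl$significant)))
}
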