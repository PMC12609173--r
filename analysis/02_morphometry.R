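#!/usr/bin/env Rscript
# Voxel-wise grey-matter group contrast (patients vs controls) with
# permutation cluster-level FDR.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_config.R"))

sim <- load_study()
res <- cluster_level_fdr(sim$images, sim$cohort$group, sim$cohort[, COVARS],
                         forming_p = ACFG$forming_p,
                         min_extent = ACFG$min_cluster_voxels,
                         n_perm = ACFG$n_perm, seed = STUDY_SEED + 11L,
                         fdr_alpha = ACFG$fdr_alpha, group1 = "patient")

write_stat_map(res$tmap$statistic, sim$images$affine,
               file.path(RESULTS_DIR, "vbm_tmap.nii.gz"))
write_tsv(res$clusters[, setdiff(names(res$clusters), "peak_gc")],
          "vbm_clusters.tsv")
cat(sprintf("df = %d; %d cluster(s), %d significant at FDR %.2f\n",
            res$tmap$df, nrow(res$clusters),
            sum(res$clusters$significant), ACFG$fdr_alpha))
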