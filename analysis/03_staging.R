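#!/usr/bin/env Rscript
# WMH severity staging: loess + piecewise-linear breakpoint thresholds on the
# patient GMV-vs-WMH curve, with a Fazekas-based grouping for comparison.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_config.R"))

sim <- load_study()
p <- sim$cohort$group == "patient"
wmh <- sim$cohort$wmh_volume[p]

th <- fit_stage_thresholds(wmh, sim$cohort$global_gmv[p])
stages <- assign_stages(wmh, th)
faz <- group_by_fazekas(sim$cohort$fazekas[p])

write_tsv(data.frame(threshold = c("t1", "t2", "t3"), wmh_ml = th),
          "stage_thresholds.tsv")
write_tsv(data.frame(subject_id = sim$cohort$subject_id[p],
                     wmh_volume = wmh, stage = as.character(stages),
                     fazekas_stage = as.character(faz)),
          "stage_assignments.tsv")
write_tsv(as.data.frame(table(stage = stages)), "stage_counts.tsv")

cat("thresholds (mL):", sprintf("%.2f", th), "\n")
print(table(stages))
print(table(gmv_stage = stages, fazekas = faz))
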