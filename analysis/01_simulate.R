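#!/usr/bin/env Rscript
# Generate the synthetic study cohort and report its demographic table
# alongside the published group comparisons it is calibrated against.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_config.R"))

sim <- load_study()
cohort <- sim$cohort
write_phenotype(cohort, file.path(RESULTS_DIR, "phenotype.csv"))
message("wrote ", file.path(RESULTS_DIR, "phenotype.csv"))

p <- cohort$group == "patient"
row_stat <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
demo <- data.frame(
  variable = c("age", "education_years", "tiv", "global_gmv", "moca", "mmse",
               "dst", "wmh_volume_median"),
  patients = c(vapply(cohort[p, c("age", "education_years", "tiv", "global_gmv",
                                  "moca", "mmse", "dst")], row_stat, ""),
               sprintf("%.2f", median(cohort$wmh_volume[p]))),
  controls = c(vapply(cohort[!p, c("age", "education_years", "tiv", "global_gmv",
                                   "moca", "mmse", "dst")], row_stat, ""),
               "0"))
write_tsv(demo, "cohort_demographics.tsv")

# group tests on the realised cohort
gmv_t <- summary_two_sample_t(mean(cohort$global_gmv[p]), sd(cohort$global_gmv[p]), sum(p),
                              mean(cohort$global_gmv[!p]), sd(cohort$global_gmv[!p]), sum(!p))
tiv_t <- summary_two_sample_t(mean(cohort$tiv[p]), sd(cohort$tiv[p]), sum(p),
                              mean(cohort$tiv[!p]), sd(cohort$tiv[!p]), sum(!p))
sx <- table(cohort$group, cohort$sex)
sex_chi <- chi_square_2x2(sx["patient", "male"], sx["patient", "female"],
                          sx["control", "male"], sx["control", "female"])
tests <- data.frame(
  test = c("GMV pooled t", "TIV pooled t", "sex chi-square"),
  statistic = c(gmv_t$t, tiv_t$t, sex_chi$statistic),
  p = c(gmv_t$p, tiv_t$p, sex_chi$p))
write_tsv(tests, "cohort_group_tests.tsv")

cat(sprintf("r(WMH, global GMV) in patients: %.4f; median WMH: %.3f mL\n",
            cor(cohort$wmh_volume[p], cohort$global_gmv[p]),
            median(cohort$wmh_volume[p])))
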