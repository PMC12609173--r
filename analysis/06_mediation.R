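#!/usr/bin/env Rscript
# Mediation of cognition by global grey-matter volume: WMH -> GMV -> DST and
# WMH -> GMV -> 1/TMT-A, with bias-corrected bootstrap intervals.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_config.R"))

sim <- load_study()

rows <- lapply(c(dst = "dst", inv_tmt = "inv_tmt"), function(oc) {
  med <- mediate_cognition(sim$cohort, oc, n_boot = 5000,
                           seed = STUDY_SEED + if (oc == "dst") 23L else 29L)
  cat(sprintf(paste0("%s: a = %.3f, b = %.3f, c' = %.3f, indirect = %.3f ",
                     "[%.3f, %.3f], %.1f%% direct / %.1f%% indirect\n"),
              oc, med$a, med$b, med$c_prime, med$indirect,
              med$ci["indirect", "lower"], med$ci["indirect", "upper"],
              med$pct_direct, med$pct_indirect))
  data.frame(outcome = oc, a = med$a, b = med$b, c_prime = med$c_prime,
             indirect = med$indirect, total = med$total,
             ci_low = med$ci["indirect", "lower"],
             ci_high = med$ci["indirect", "upper"],
             significant = med$significant[["indirect"]],
             pct_direct = med$pct_direct, pct_indirect = med$pct_indirect,
             n_boot = med$n_boot)
})
write_tsv(do.call(rbind, rows), "mediation.tsv")
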