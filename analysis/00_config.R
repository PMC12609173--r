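# Shared settings for the numbered analysis scripts.
#
# Each script is a thin driver over the cascnet package: it re-derives the
# deterministic synthetic study from STUDY_SEED (generation takes ~1 s, so no
# binary caching is needed) and writes plain-text tables under results/.

suppressPackageStartupMessages(library(cascnet))

STUDY_SEED <- 1L
N_PATIENTS <- 185L
N_CONTROLS <- 40L
RESULTS_DIR <- file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "..", "results")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# desk-scale analysis profile: 24^3 grid with radius-2 planted regions, so the
# conventional 200-voxel cluster extent is replaced by 10
ACFG <- analysis_config(min_cluster_voxels = 10, n_perm = 200)
COVARS <- c("age", "sex", "education_years", "tiv")

load_study <- function() {
  simulate_study(N_PATIENTS, N_CONTROLS, cohort_config(), ground_truth(),
                 seed = STUDY_SEED)
}

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
  invisible(path)
}
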