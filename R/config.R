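#' Analysis configuration
#'
#' Thresholds and settings of the causal structural covariance analysis.
#' Defaults follow the study's reported settings: voxel criteria |z| > 1.96
#' and |GC| > 0.20, cluster extent > 200 voxels, cluster-level FDR 0.05,
#' lag-1 Granger model, 5000 bootstrap resamples, grey-matter mask
#' probability threshold 0.27. `min_cluster_voxels` should be scaled to the
#' grid in use (200 is meaningful at full MRI resolution; desk-scale
#' synthetic grids use smaller extents).
#'
#' @param ... named overrides.
#' @return a list of class `cascn_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    z_threshold = 1.96,
    gc_threshold = 0.20,
    min_cluster_voxels = 200,
    fdr_alpha = 0.05,
    gc_order = 1L,
    bootstrap_n = 5000L,
    mask_threshold = 0.27,
    forming_p = 0.001,
    n_perm = 500L,
    seed_cor_max = 0.8
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown analysis_config settings: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  num <- unlist(cfg[c("z_threshold", "gc_threshold", "min_cluster_voxels",
                      "gc_order", "bootstrap_n", "mask_threshold", "n_perm")])
  if (any(num <= 0)) stop("analysis_config values must be positive")
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stop("fdr_alpha must be in (0,1)")
  if (cfg$forming_p <= 0 || cfg$forming_p >= 1) stop("forming_p must be in (0,1)")
  structure(cfg, class = "cascn_config")
}
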