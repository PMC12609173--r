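#' Pipeline configuration
#'
#' Settings for [run_full_pipeline()]. With `phenotype_path` /
#' `image_paths` unset, a synthetic study is simulated from the ground
#' truth. The embedded [analysis_config()] defaults to the desk-scale
#' profile (`min_cluster_voxels = 10`, `n_perm = 200`) appropriate for the
#' default 24-cube grid with radius-2 planted regions; full-resolution runs
#' should restore the conventional 200-voxel extent.
#'
#' @param ... named overrides.
#' @return a list of class `cascn_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = NULL,
    seed = 1L,
    n_patients = 185L, n_controls = 40L,
    grid_shape = c(24L, 24L, 24L),
    analysis = analysis_config(min_cluster_voxels = 10, n_perm = 200),
    cohort = cohort_config(),
    truth = NULL,          # defaults to ground_truth(grid_shape)
    stage_method = "gmv",  # or "fazekas"
    stage_span = 0.75,
    seed_world = c(46.5, 15, -6),
    seed_radius_mm = 6,
    phenotype_path = NULL,
    image_paths = NULL, mask_path = NULL,
    domain_table = NULL,
    n_boot = NULL,         # defaults to analysis$bootstrap_n
    write_images = FALSE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown pipeline_config settings: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$analysis$n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(cfg$truth)) cfg$truth <- ground_truth(cfg$grid_shape)
  if (is.null(cfg$n_boot)) cfg$n_boot <- cfg$analysis$bootstrap_n
  structure(cfg, class = "cascn_pipeline_config")
}

## peak-centred spherical seed within a cluster (keeps the seed local even
## when widespread atrophy merges into one large cluster)
seed_from_cluster <- function(clusters, dim, affine, radius_vox = 2) {
  sig <- clusters[clusters$significant & clusters$sign < 0, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  top <- sig[which.max(sig$n_voxels), ]
  ctr <- world_to_voxel(c(top$peak_x, top$peak_y, top$peak_z), affine)
  region(round(ctr), radius_vox, "auto_seed")
}

#' Run the complete causal structural covariance analysis
#'
#' Executes the full pipeline: group VBM contrast, WMH staging and
#' stage-wise contrasts, seed selection from the earliest stage's largest
#' significant atrophy cluster (peak-centred sphere; falls back to the
#' configured world coordinate), pseudo-time construction, seed-based
#' voxel-wise CaSCN in both directions with cluster-level FDR, ROI-to-ROI
#' causal graph with degree/hub metrics and directed weighted modularity,
#' optional binomial functional decoding, and mediation of DST and 1/TMT-A
#' by global GMV. All randomness derives from `config$seed`; identical
#' configurations give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage's result; when
#'   `config$out_dir` is set, all artifacts plus `summary.json` are written
#'   there.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  seed <- as.integer(config$seed)
  acfg <- config$analysis

  # -- inputs: simulate or load -------------------------------------------
  if (is.null(config$phenotype_path)) {
    sim <- simulate_study(config$n_patients, config$n_controls, config$cohort,
                          config$truth, config$grid_shape, seed)
    cohort <- sim$cohort; images <- sim$images
  } else {
    cohort <- read_phenotype(config$phenotype_path)
    images <- read_image_set(config$image_paths, config$mask_path)
  }
  covars <- c("age", "sex", "education_years", "tiv")

  # -- A: overall VBM contrast --------------------------------------------
  vbm <- cluster_level_fdr(images, cohort$group, cohort[, covars],
                           forming_p = acfg$forming_p,
                           min_extent = acfg$min_cluster_voxels,
                           n_perm = acfg$n_perm, seed = seed + 11L,
                           fdr_alpha = acfg$fdr_alpha, group1 = "patient")

  # -- B: staging and earliest-stage contrast -----------------------------
  pat <- cohort$group == "patient"
  if (config$stage_method == "fazekas") {
    stage <- rep(NA_character_, nrow(cohort))
    stage[pat] <- as.character(group_by_fazekas(cohort$fazekas[pat]))
    thresholds <- NULL
  } else {
    thresholds <- fit_stage_thresholds(cohort$wmh_volume[pat],
                                       cohort$global_gmv[pat],
                                       span = config$stage_span)
    stage <- rep(NA_character_, nrow(cohort))
    stage[pat] <- as.character(assign_stages(cohort$wmh_volume[pat], thresholds))
  }
  cohort$stage <- stage
  early <- pat & stage == "I"
  sub <- early | !pat
  img_sub <- images
  img_sub$data <- images$data[sub, , drop = FALSE]
  img_sub$subject_id <- images$subject_id[sub]
  stage1 <- cluster_level_fdr(img_sub, cohort$group[sub], cohort[sub, covars],
                              forming_p = acfg$forming_p,
                              min_extent = acfg$min_cluster_voxels,
                              n_perm = acfg$n_perm, seed = seed + 13L,
                              fdr_alpha = acfg$fdr_alpha, group1 = "patient")

  # -- C: seed selection ---------------------------------------------------
  seed_roi <- seed_from_cluster(stage1$clusters, images$dim, images$affine)
  if (is.null(seed_roi)) {
    ctr <- round(world_to_voxel(config$seed_world, images$affine))
    seed_roi <- region(ctr, max(1, round(config$seed_radius_mm / images$voxel_size) + 1),
                       "configured_seed")
  }

  # -- D/E: pseudo-time series and voxel-wise CaSCN -----------------------
  pts <- build_pseudo_timeseries(images, cohort, covars)
  seed_series <- extract_seed_series(pts, seed_roi)
  maps <- voxelwise_cascn(pts, seed_series, seed = seed_roi, config = acfg)
  cascn_clusters <- lapply(maps, threshold_cascn, pts = pts,
                           seed_series = seed_series, config = acfg,
                           n_perm = acfg$n_perm, seed = seed + 17L)

  # -- F: ROI graph, degrees, hubs ----------------------------------------
  fwd <- cascn_clusters$seed_to_target
  sig <- fwd[fwd$significant, , drop = FALSE]
  rois <- list(seed = seed_roi)
  vox_lists <- list(seed = region_voxels(seed_roi, images$dim))
  if (nrow(sig) > 0) {
    all_vox <- attr(fwd, "voxels")
    for (i in seq_len(nrow(sig))) {
      nm <- sprintf("cluster_%02d_%s", sig$cluster_id[i],
                    ifelse(sig$sign[i] > 0, "pos", "neg"))
      vox_lists[[nm]] <- all_vox[[sig$cluster_id[i]]]
    }
  }
  graph <- NULL; degrees <- NULL; partition <- NULL
  if (length(vox_lists) >= 2) {
    roi_series <- vapply(vox_lists, function(v) {
      cols <- match(intersect(v, pts$feature_index), pts$feature_index)
      rowMeans(pts$data[, cols, drop = FALSE])
    }, numeric(nrow(pts$data)))
    graph <- roi_gc_matrix(roi_series, acfg)
    degrees <- classify_hubs(degree_metrics(graph))
    if (nrow(graph$edges) > 0)
      partition <- newman_modularity(graph, seed = seed + 19L)
  }

  # -- G: functional decoding ---------------------------------------------
  decoding <- NULL
  if (!is.null(config$domain_table))
    decoding <- forward_inference_decoding(config$domain_table, acfg$fdr_alpha)

  # -- H: mediation --------------------------------------------------------
  mediation <- list(
    dst = mediate_cognition(cohort, "dst", n_boot = config$n_boot,
                            seed = seed + 23L),
    inv_tmt = mediate_cognition(cohort, "inv_tmt", n_boot = config$n_boot,
                                seed = seed + 29L)
  )

  bundle <- list(cohort = cohort, images = images,
                 vbm = vbm, thresholds = thresholds, stage1 = stage1,
                 seed_roi = seed_roi, pts = pts, maps = maps,
                 cascn_clusters = cascn_clusters, graph = graph,
                 degrees = degrees, partition = partition,
                 decoding = decoding, mediation = mediation,
                 config = config)

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

## serialize a pipeline bundle to disk, with a summary JSON carrying the
## config hash and seed so every output is traceable to its run
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  write_phenotype(bundle$cohort, file.path(out_dir, "phenotype.csv"))
  img <- bundle$images
  if (isTRUE(cfg$write_images)) write_image_set(img, file.path(out_dir, "images"))
  write_stat_map(bundle$vbm$tmap$statistic, img$affine,
                 file.path(out_dir, "vbm_tmap.nii.gz"))
  write_cluster_table(bundle$vbm$clusters, file.path(out_dir, "vbm_clusters.tsv"))
  for (dir in names(bundle$maps)) {
    write_stat_map(bundle$maps[[dir]]$gc, img$affine,
                   file.path(out_dir, paste0("cascn_gc_", dir, ".nii.gz")))
    write_stat_map(bundle$maps[[dir]]$z, img$affine,
                   file.path(out_dir, paste0("cascn_z_", dir, ".nii.gz")))
    write_cluster_table(bundle$cascn_clusters[[dir]],
                        file.path(out_dir, paste0("cascn_clusters_", dir, ".tsv")))
  }
  if (!is.null(bundle$graph)) {
    write_cluster_table(bundle$graph$edges, file.path(out_dir, "edges.tsv"))
    write_cluster_table(bundle$degrees, file.path(out_dir, "degrees.tsv"))
    write_graphml(bundle$graph, file.path(out_dir, "causal_graph.graphml"))
  }
  if (!is.null(bundle$partition))
    write_cluster_table(data.frame(node = names(bundle$partition$membership),
                                   module = unname(bundle$partition$membership)),
                        file.path(out_dir, "modules.tsv"))
  if (!is.null(bundle$decoding))
    write_cluster_table(bundle$decoding, file.path(out_dir, "decoding.tsv"))

  med <- lapply(bundle$mediation, function(m)
    list(a = m$a, b = m$b, c_prime = m$c_prime, indirect = m$indirect,
         total = m$total, pct_direct = m$pct_direct,
         pct_indirect = m$pct_indirect,
         ci = apply(m$ci, 1, as.list), significant = as.list(m$significant),
         n_boot = m$n_boot, seed = m$seed))
  # out_dir is where the bundle lands, not what was computed: exclude it so
  # identical analyses hash identically wherever they are written
  hash_cfg <- cfg[setdiff(names(cfg), c("domain_table", "truth", "out_dir"))]
  summary <- list(
    seed = cfg$seed,
    config_hash = config_hash(hash_cfg),
    n_patients = sum(bundle$cohort$group == "patient"),
    n_controls = sum(bundle$cohort$group == "control"),
    stage_thresholds = bundle$thresholds,
    stage_counts = as.list(table(bundle$cohort$stage)),
    seed_region = list(center = bundle$seed_roi$center,
                       radius = bundle$seed_roi$radius,
                       world = as.numeric(voxel_to_world(bundle$seed_roi$center,
                                                         img$affine))),
    n_vbm_significant = sum(bundle$vbm$clusters$significant),
    n_cascn_clusters = lapply(bundle$cascn_clusters,
                              function(cl) sum(cl$significant)),
    top_causal_hub = if (!is.null(bundle$degrees))
      bundle$degrees$node[which.max(bundle$degrees$outin_degree)] else NULL,
    modularity_Q = if (!is.null(bundle$partition)) bundle$partition$Q else NULL,
    mediation = med
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
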