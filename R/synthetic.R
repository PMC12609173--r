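#' Default cohort generator settings
#'
#' Marginal calibration targets for the synthetic cohort. Lesion burden is
#' lognormal with parameters obtained by quantile-matching the printed
#' patient median and quartiles (5.24 [2.64, 11.68] mL):
#' meanlog = ln 5.24, sdlog = (ln 11.68 - ln 2.64) / (2 * qnorm(0.75)).
#' Demographics, volumes and control-group cognitive scores use the group
#' means and SDs of the study cohort. `gmv_wmh_r` is the target correlation
#' between raw WMH volume and global grey-matter volume in patients.
#'
#' Volumes are in mL throughout (the source table labels them mm^3, but the
#' magnitudes are plainly mL/cm^3).
#'
#' @param ... named overrides of the defaults.
#' @return a list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    wmh_meanlog = log(5.24),
    wmh_sdlog = (log(11.68) - log(2.64)) / (2 * stats::qnorm(0.75)),
    age_patient = c(57.7, 6.5), age_control = c(45.5, 7.8),
    edu_patient = c(10.8, 3.06), edu_control = c(11.5, 5.4),
    tiv_patient = c(1424.74, 110.79), tiv_control = c(1505.07, 147.42),
    gmv_patient = c(548.92, 25.81), gmv_control = c(592.64, 46.92),
    gmv_wmh_r = -0.954,
    moca_patient = c(27.37, 1.28), moca_control = c(27.50, 1.43),
    mmse_patient = c(27.94, 1.08), mmse_control = c(28.13, 1.07),
    dst_patient = c(50.63, 18.28), dst_control = c(41.42, 12.33),
    tmt_patient = c(41.30, 9.91), tmt_control = c(54.48, 15.12),
    p_male_patient = 86 / 185, p_male_control = 21 / 40,
    # Fazekas grade cutoffs on WMH volume: lognormal quantiles at the
    # cumulative grade proportions of the study cohort (88/52/45).
    fazekas_props = c(88, 52, 45) / 185,
    age_gmv_slope = 0
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown cohort_config settings: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Planted ground truth for the synthetic study
#'
#' Defines the seed (source) region, propagation targets with signed path
#' weights and pseudo-time lags, the atrophy model, noise levels, and the
#' mediation coefficients used to generate cognition. The default layout
#' plants a source plus five targets whose source-relative lags increase
#' along a chain (1..5) with signs (+, +, -, -, -), so the effective lag-1
#' causal graph is a six-node chain splitting into two modules
#' ({source, A, B} and {C, D, E}) with the source as the unique strongest
#' causal hub.
#'
#' @param grid_shape grid extents the regions must fit in.
#' @param ... named overrides (`source_roi`, `positive_targets`,
#'   `negative_targets`, `atrophy_slope`, `voxel_noise_sd`,
#'   `signal_noise_sd`, `mediation_coeffs`).
#' @return an object of class `cascn_truth`.
#' @export
ground_truth <- function(grid_shape = c(24L, 24L, 24L), ...) {
  tr <- list(
    source_roi = region(c(20, 15, 12), 2, "source_R_insula_like"),
    positive_targets = list(
      list(roi = region(c(8, 18, 12), 2, "target_A"), weight = 0.80, lag = 1L),
      list(roi = region(c(12, 8, 16), 2, "target_B"), weight = 0.64, lag = 2L)
    ),
    negative_targets = list(
      list(roi = region(c(16, 18, 8), 2, "target_C"), weight = -0.60, lag = 3L),
      list(roi = region(c(7, 10, 9), 2, "target_D"), weight = -0.48, lag = 4L),
      list(roi = region(c(17, 7, 15), 2, "target_E"), weight = -0.384, lag = 5L)
    ),
    atrophy_slope = 0.02,     # density units per log-mL of lesion volume
    voxel_noise_sd = 0.02,    # iid voxel noise, density units
    signal_noise_sd = 0.25,   # region-level innovation on the source series
    mediation_coeffs = list(
      # a is realised by the cohort generator (WMH -> GMV correlation);
      # b and c_prime are chosen so the planted direct/indirect shares match
      # the study's reported 39%/61% (DST) and 33.4%/66.6% (1/TMT-A) splits.
      dst = c(a = -0.954, b = 0.59 / 0.954, c_prime = -0.38),
      inv_tmt = c(a = -0.954, b = 0.64 / 0.954, c_prime = -0.32)
    ),
    grid_shape = as.integer(grid_shape)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(tr))
  if (length(bad)) stop("unknown ground_truth settings: ", paste(bad, collapse = ", "))
  tr[names(ov)] <- ov
  validate_truth(tr)
  structure(tr, class = "cascn_truth")
}

truth_regions <- function(truth) {
  c(list(source = truth$source_roi),
    stats::setNames(lapply(truth$positive_targets, `[[`, "roi"),
                    vapply(truth$positive_targets, function(t) t$roi$label, "")),
    stats::setNames(lapply(truth$negative_targets, `[[`, "roi"),
                    vapply(truth$negative_targets, function(t) t$roi$label, "")))
}

validate_truth <- function(tr) {
  regs <- c(list(tr$source_roi),
            lapply(tr$positive_targets, `[[`, "roi"),
            lapply(tr$negative_targets, `[[`, "roi"))
  vox <- lapply(regs, region_voxels, dim = tr$grid_shape)
  if (any(lengths(vox) == 0)) stop("ground-truth region falls outside the grid")
  for (i in seq_along(vox)) for (j in seq_len(i - 1L)) {
    if (length(intersect(vox[[i]], vox[[j]])))
      stop("ground-truth regions overlap")
  }
  w <- c(vapply(tr$positive_targets, `[[`, 0, "weight"),
         vapply(tr$negative_targets, `[[`, 0, "weight"))
  if (any(!is.finite(w))) stop("non-finite path weight")
  if (any(vapply(tr$positive_targets, `[[`, 0, "weight") <= 0))
    stop("positive targets need weight > 0")
  if (any(vapply(tr$negative_targets, `[[`, 0, "weight") >= 0))
    stop("negative targets need weight < 0")
  lags <- c(vapply(tr$positive_targets, `[[`, 0L, "lag"),
            vapply(tr$negative_targets, `[[`, 0L, "lag"))
  if (any(lags < 1)) stop("lags must be >= 1")
  invisible(tr)
}

## stratified (systematic) inverse-CDF sample of a lognormal: the empirical
## quantiles of every draw match the target distribution to O(1/n), so each
## cohort reproduces the calibrated median and quartiles.
rlnorm_stratified <- function(n, meanlog, sdlog) {
  u <- (sample.int(n) - stats::runif(n)) / n
  stats::qlnorm(u, meanlog, sdlog)
}

rnorm2 <- function(n, ms) stats::rnorm(n, ms[1], ms[2])

#' Generate a synthetic cohort phenotype table
#'
#' Patients receive lognormal WMH volumes (stratified quantile sampling of
#' the calibrated distribution), Fazekas grades keyed to volume cutoffs, and
#' a global grey-matter volume linear in sample-standardized WMH with the
#' configured correlation. Controls are lesion-free. Patient cognitive
#' scores (DST, TMT-A) are left `NA`; [generate_cognition()] fills them from
#' the mediation ground truth.
#'
#' @param n_patients,n_controls group sizes (`n_patients >= 4`).
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return a `data.frame` phenotype table (one row per subject).
#' @export
generate_cohort <- function(n_patients = 185, n_controls = 40,
                            config = cohort_config(), seed = 1) {
  if (n_patients < 4 || n_controls < 0) stop("need n_patients >= 4 and n_controls >= 0")
  set.seed(as.integer(seed))
  np <- n_patients; nc <- n_controls

  wmh <- rlnorm_stratified(np, config$wmh_meanlog, config$wmh_sdlog)
  zw <- as.numeric(scale(wmh))
  r <- config$gmv_wmh_r
  ze <- as.numeric(scale(stats::rnorm(np)))
  age_p <- rnorm2(np, config$age_patient)
  gmv_p <- config$gmv_patient[1] +
    config$gmv_patient[2] * (r * zw + sqrt(1 - r^2) * ze) +
    config$age_gmv_slope * (age_p - config$age_patient[1])
  cuts <- stats::qlnorm(cumsum(config$fazekas_props)[1:2],
                        config$wmh_meanlog, config$wmh_sdlog)
  faz <- 1L + (wmh > cuts[1]) + (wmh > cuts[2])

  pat <- data.frame(
    subject_id = sprintf("P%03d", seq_len(np)),
    group = "patient",
    wmh_volume = wmh,
    fazekas = as.integer(faz),
    age = age_p,
    sex = ifelse(stats::runif(np) < config$p_male_patient, "male", "female"),
    education_years = pmax(0, rnorm2(np, config$edu_patient)),
    tiv = rnorm2(np, config$tiv_patient),
    global_gmv = gmv_p,
    moca = pmin(30, pmax(0, rnorm2(np, config$moca_patient))),
    mmse = pmin(30, pmax(0, rnorm2(np, config$mmse_patient))),
    dst = NA_real_,
    tmt_a = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nc > 0) {
    ctl <- data.frame(
      subject_id = sprintf("C%03d", seq_len(nc)),
      group = "control",
      wmh_volume = 0,
      fazekas = 0L,
      age = rnorm2(nc, config$age_control),
      sex = ifelse(stats::runif(nc) < config$p_male_control, "male", "female"),
      education_years = pmax(0, rnorm2(nc, config$edu_control)),
      tiv = rnorm2(nc, config$tiv_control),
      global_gmv = rnorm2(nc, config$gmv_control),
      moca = pmin(30, pmax(0, rnorm2(nc, config$moca_control))),
      mmse = pmin(30, pmax(0, rnorm2(nc, config$mmse_control))),
      dst = rnorm2(nc, config$dst_control),
      tmt_a = pmax(10, rnorm2(nc, config$tmt_control)),
      stringsAsFactors = FALSE
    )
    pat <- rbind(pat, ctl)
  }
  rownames(pat) <- NULL
  validate_cohort(pat, allow_na_scores = TRUE)
  pat
}

#' Validate a cohort phenotype table
#'
#' Checks column presence, types, uniqueness of subject ids, and the
#' patient/control lesion invariants (patients: Fazekas >= 1 and
#' wmh_volume > 0; controls: both zero).
#'
#' @param cohort a phenotype `data.frame`.
#' @param allow_na_scores allow `NA` in dst / tmt_a (pre-cognition tables).
#' @return the table, invisibly; stops with a named error otherwise.
#' @export
validate_cohort <- function(cohort, allow_na_scores = FALSE) {
  req <- c("subject_id", "group", "wmh_volume", "fazekas", "age", "sex",
           "education_years", "tiv", "global_gmv", "moca", "mmse", "dst", "tmt_a")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(cohort$subject_id[duplicated(cohort$subject_id)]), collapse = ", "))
  if (!all(cohort$group %in% c("patient", "control"))) stop("group must be patient/control")
  p <- cohort$group == "patient"
  if (any(p & (cohort$wmh_volume <= 0 | cohort$fazekas < 1)))
    stop("patients must have wmh_volume > 0 and fazekas >= 1")
  if (any(!p & (cohort$wmh_volume != 0 | cohort$fazekas != 0)))
    stop("controls must have wmh_volume = 0 and fazekas = 0")
  tm <- cohort$tmt_a
  if (any(!is.na(tm) & tm <= 0)) stop("tmt_a must be strictly positive")
  if (!allow_na_scores && any(is.na(cohort$dst) | is.na(cohort$tmt_a)))
    stop("dst / tmt_a contain missing values")
  invisible(cohort)
}

## WMH-ascending patient ordering, ties broken by subject_id
wmh_order <- function(cohort) {
  p <- which(cohort$group == "patient")
  p[order(cohort$wmh_volume[p], cohort$subject_id[p])]
}

#' Generate grey-matter images with planted causal propagation
#'
#' Each subject's image is a smooth radial density template scaled to the
#' subject's global grey-matter volume. In patients, the source region loses
#' `atrophy_slope * ln(1 + wmh)` density plus a region-level innovation
#' (`signal_noise_sd`); each target gains/loses `weight` times the realised
#' source deficit of the patient `lag` positions earlier in the
#' WMH-ascending order (zero for the first `lag` patients). Independent
#' Gaussian voxel noise is added last, followed by optional isotropic
#' smoothing and clamping to [0, 1.5].
#'
#' @param cohort a phenotype table from [generate_cohort()].
#' @param truth a [ground_truth()].
#' @param grid_shape 3D grid extents.
#' @param seed RNG seed.
#' @param voxel_size isotropic voxel size (mm) for the affine.
#' @param fwhm_vox Gaussian smoothing FWHM in voxels (0 = off, the default:
#'   planted regions are already spatially coherent).
#' @return a `gmv_image_set`: list with `data` (subjects x voxels matrix over
#'   the full grid), `dim`, `mask` (logical array), `affine`, `subject_id`,
#'   and the realised `source_series` (attribute, WMH-ascending order).
#' @export
generate_images <- function(cohort, truth = ground_truth(grid_shape),
                            grid_shape = c(24L, 24L, 24L), seed = 1,
                            voxel_size = 6, fwhm_vox = 0) {
  set.seed(as.integer(seed))
  dm <- as.integer(grid_shape)
  if (!identical(as.integer(truth$grid_shape), dm))
    stop("truth regions were laid out for a different grid")
  n <- nrow(cohort)
  ord <- wmh_order(cohort)
  lags <- c(vapply(truth$positive_targets, `[[`, 0L, "lag"),
            vapply(truth$negative_targets, `[[`, 0L, "lag"))
  if (length(lags) && max(lags) >= length(ord)) stop("lag >= number of patients")

  ctr <- (dm + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(dm[k]) - ctr[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  template <- exp(-d2 / (2 * 7^2))
  mask <- template > 0.27
  tvec <- as.numeric(template)

  scale_i <- cohort$global_gmv / mean(cohort$global_gmv)
  data <- outer(scale_i, tvec)

  # realised source deficit along the pseudo-time (WMH-ascending) order
  wmh_sorted <- cohort$wmh_volume[ord]
  src_def <- truth$atrophy_slope * log1p(wmh_sorted) +
    truth$signal_noise_sd * stats::rnorm(length(ord))
  src_vox <- region_voxels(truth$source_roi, dm)
  data[ord, src_vox] <- data[ord, src_vox] - src_def

  for (tg in c(truth$positive_targets, truth$negative_targets)) {
    vox <- region_voxels(tg$roi, dm)
    delta <- c(rep(0, tg$lag), tg$weight * src_def[seq_len(length(ord) - tg$lag)])
    data[ord, vox] <- data[ord, vox] - delta
  }

  if (truth$voxel_noise_sd > 0)
    data <- data + stats::rnorm(length(data), sd = truth$voxel_noise_sd)
  if (fwhm_vox > 0)
    for (i in seq_len(n))
      data[i, ] <- as.numeric(smooth_gaussian3d(array(data[i, ], dm), fwhm_vox))
  if (truth$voxel_noise_sd > 0 || fwhm_vox > 0)
    data <- pmin(pmax(data, 0), 1.5)

  structure(list(data = data, dim = dm, mask = mask,
                 affine = default_affine(voxel_size, dm),
                 voxel_size = voxel_size,
                 subject_id = cohort$subject_id,
                 source_series = src_def, ordering = ord),
            class = "gmv_image_set")
}

#' Generate cognitive scores from the mediation ground truth
#'
#' Patient scores follow the planted path structure on standardized scales:
#' `z(score) = c_prime * z(WMH) + b * z(GMV) + noise`, with the residual SD
#' set so the standardized score has unit variance given the realised
#' WMH--GMV correlation `a`. DST is mapped to the patient-group mean/SD; the
#' same structure generates 1/TMT-A, which is inverted (and floored at
#' 4 ms^-1) to give TMT-A seconds.
#'
#' @param cohort table with `global_gmv` populated.
#' @param truth a [ground_truth()] (supplies `mediation_coeffs`).
#' @param config a [cohort_config()] (score scale calibration).
#' @param seed RNG seed.
#' @return the cohort with patient `dst` and `tmt_a` filled.
#' @export
generate_cognition <- function(cohort, truth = ground_truth(),
                               config = cohort_config(), seed = 1) {
  if (any(is.na(cohort$global_gmv))) stop("global_gmv must be populated")
  set.seed(as.integer(seed) + 1L)
  p <- cohort$group == "patient"
  zw <- as.numeric(scale(cohort$wmh_volume[p]))
  zg <- as.numeric(scale(cohort$global_gmv[p]))
  a_real <- stats::cor(zw, zg)

  score_z <- function(co) {
    sig2 <- co[["c_prime"]]^2 + co[["b"]]^2 + 2 * co[["c_prime"]] * co[["b"]] * a_real
    nsd <- sqrt(max(0, 1 - sig2))
    co[["c_prime"]] * zw + co[["b"]] * zg + nsd * stats::rnorm(sum(p))
  }
  dst_z <- score_z(truth$mediation_coeffs$dst)
  inv_z <- score_z(truth$mediation_coeffs$inv_tmt)

  cohort$dst[p] <- config$dst_patient[1] + config$dst_patient[2] * dst_z
  inv_mean <- 1 / config$tmt_patient[1]
  inv_sd <- config$tmt_patient[2] * inv_mean^2   # delta method on 1/x
  inv <- pmax(inv_mean + inv_sd * inv_z, 0.004)
  cohort$tmt_a[p] <- 1 / inv
  cohort
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_cohort()], [generate_images()] and
#' [generate_cognition()] under one seed.
#'
#' @inheritParams generate_cohort
#' @inheritParams generate_images
#' @param truth a [ground_truth()].
#' @return list with `cohort`, `images`, `truth`.
#' @export
simulate_study <- function(n_patients = 185, n_controls = 40,
                           config = cohort_config(),
                           truth = ground_truth(grid_shape),
                           grid_shape = c(24L, 24L, 24L),
                           seed = 1, fwhm_vox = 0) {
  cohort <- generate_cohort(n_patients, n_controls, config, seed)
  images <- generate_images(cohort, truth, grid_shape, seed, fwhm_vox = fwhm_vox)
  cohort <- generate_cognition(cohort, truth, config, seed)
  list(cohort = cohort, images = images, truth = truth)
}
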