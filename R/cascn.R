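#' Residualize features on nuisance covariates
#'
#' Per-feature least-squares residuals of a subjects x features matrix on a
#' covariate design (intercept always included).
#'
#' @param m subjects x features numeric matrix.
#' @param covariates data.frame (factors expanded) or numeric matrix; `NULL`
#'   means intercept only (column demeaning).
#' @return residual matrix, same shape as `m`.
#' @export
residualize_covariates <- function(m, covariates = NULL) {
  m <- as.matrix(m)
  X <- matrix(1, nrow(m), 1)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate design is rank deficient")
  m - X %*% qr.coef(qrX, m)
}

#' Build a WMH-ordered pseudo-time series
#'
#' Residualizes patient grey-matter features on nuisance covariates, then
#' orders subjects by ascending WMH volume (ties broken by subject_id) so
#' that cross-sectional maps can be treated as successive time points of
#' disease progression.
#'
#' @param x a `gmv_image_set` (in-mask voxels become features) or a
#'   subjects x features matrix aligned with `cohort` rows.
#' @param cohort phenotype table; only `group == "patient"` rows are used.
#' @param covariates character vector of cohort column names (default age,
#'   sex, education_years, tiv) or a data.frame aligned with cohort rows;
#'   `NULL` for intercept-only residualization.
#' @return a `cascn_pts`: list(data = T x F residual matrix in pseudo-time
#'   order, subject_id, wmh, feature_index (mask voxel indices or column
#'   names), dim/mask/affine when built from images, covariates).
#' @export
build_pseudo_timeseries <- function(x, cohort,
                                    covariates = c("age", "sex", "education_years", "tiv")) {
  if (any(is.na(cohort$wmh_volume))) stop("missing WMH values")
  p <- which(cohort$group == "patient")
  if (length(p) < 3) stop("need at least 3 patients")
  geom <- NULL
  if (inherits(x, "gmv_image_set")) {
    feat_idx <- which(x$mask)
    m <- x$data[p, feat_idx, drop = FALSE]
    geom <- list(dim = x$dim, mask = x$mask, affine = x$affine)
  } else {
    m <- as.matrix(x)[p, , drop = FALSE]
    feat_idx <- colnames(m)
  }
  cov_df <- NULL
  if (is.character(covariates)) {
    miss <- setdiff(covariates, names(cohort))
    if (length(miss)) stop("covariate column(s) not in cohort: ", paste(miss, collapse = ", "))
    cov_df <- cohort[p, covariates, drop = FALSE]
  } else if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)[p, , drop = FALSE]
  }
  res <- residualize_covariates(m, cov_df)
  ord <- order(cohort$wmh_volume[p], cohort$subject_id[p])
  structure(list(data = res[ord, , drop = FALSE],
                 subject_id = cohort$subject_id[p][ord],
                 wmh = cohort$wmh_volume[p][ord],
                 feature_index = feat_idx,
                 geometry = geom,
                 covariates = if (is.null(cov_df)) character(0) else names(cov_df)),
            class = "cascn_pts")
}

#' Extract the seed series from a pseudo-time series
#'
#' Mean residual grey-matter value over the seed voxels for each ordered
#' subject.
#'
#' @param pts a `cascn_pts` built from images.
#' @param seed a [region()] or an integer vector of linear voxel indices.
#' @return numeric series of length T.
#' @export
extract_seed_series <- function(pts, seed) {
  if (is.null(pts$geometry)) stop("pts has no voxel geometry; pass voxel indices of features instead")
  vox <- if (inherits(seed, "cascn_region")) region_voxels(seed, pts$geometry$dim) else as.integer(seed)
  cols <- match(intersect(vox, pts$feature_index), pts$feature_index)
  if (!length(cols)) stop("seed region does not intersect the analysis mask")
  rowMeans(pts$data[, cols, drop = FALSE])
}

#' Signed-path-coefficient Granger causality for a series pair
#'
#' Both series are z-standardized; a lag-1 autoregression
#' `y_t = alpha + rho * y_(t-1) + beta * x_(t-1) + e` is fit by least
#' squares and the signed path coefficient `beta` of the lagged exogenous
#' series is returned. Positive values mean decline in `x` precedes decline
#' in `y` (propagation); negative values mean decline in `x` precedes
#' increase in `y` (compensation).
#'
#' @param x,y numeric series of equal length >= 10, non-constant.
#' @param order autoregressive order; `y` lags 1..order and `x` lags
#'   1..order enter the design, and the lag-1 coefficient of `x` is returned.
#' @return signed GC path coefficient.
#' @export
signed_gc_pair <- function(x, y, order = 1L) {
  T <- length(x)
  if (length(y) != T) stop("series lengths differ")
  if (T < 10) stop("series must have length >= 10")
  if (order < 1 || order >= T - 2) stop("invalid model order")
  xs <- zscore_vec(x); ys <- zscore_vec(y)
  idx <- (order + 1):T
  X <- cbind(1, sapply(1:order, function(l) ys[idx - l]),
             sapply(1:order, function(l) xs[idx - l]))
  cf <- qr.coef(qr(X), ys[idx])
  unname(cf[2 + order])
}

## vectorized lag-1 signed GC between one series and every column.
## seed_to_target: x Granger-causes each column; target_to_seed: each
## column Granger-causes x. Closed-form 2x2 normal equations after
## within-window centering; returns NA for constant/degenerate columns.
gc_all_columns <- function(Y, x, direction = c("seed_to_target", "target_to_seed"),
                           standardized = FALSE) {
  direction <- match.arg(direction)
  T <- length(x)
  if (standardized) { Ys <- Y; xs <- x } else { Ys <- zscore_cols(Y); xs <- zscore_vec(x) }
  n <- T - 1
  if (direction == "seed_to_target") {
    r <- Ys[-1, , drop = FALSE]; a <- Ys[-T, , drop = FALSE]; b <- xs[-T]
    am <- colMeans(a); bm <- mean(b); rm <- colMeans(r)
    Saa <- colSums(a * a) - n * am^2
    Sab <- colSums(a * b) - n * am * bm
    Sbb <- sum(b^2) - n * bm^2
    Sar <- colSums(a * r) - n * am * rm
    Sbr <- colSums(r * b) - n * bm * rm
    det <- Saa * Sbb - Sab^2
    beta <- (Saa * Sbr - Sab * Sar) / det
  } else {
    r <- xs[-1]; a <- xs[-T]; B <- Ys[-T, , drop = FALSE]
    am <- mean(a); rm <- mean(r); Bm <- colMeans(B)
    Saa <- sum(a^2) - n * am^2
    Sab <- colSums(B * a) - n * Bm * am
    Sbb <- colSums(B * B) - n * Bm^2
    Sar <- sum(a * r) - n * am * rm
    Sbr <- colSums(B * r) - n * Bm * rm
    det <- Saa * Sbb - Sab^2
    beta <- (Saa * Sbr - Sab * Sar) / det
  }
  beta[!is.finite(beta)] <- NA_real_
  beta
}

#' Seed-based voxel-wise causal structural covariance maps
#'
#' Computes the signed lag-1 GC path coefficient between the seed series and
#' every in-mask voxel of the pseudo-time series, in both directions, and
#' z-scores each map within the mask.
#'
#' Voxels whose series is nearly collinear with the seed (the seed's own
#' voxels and partial-volume neighbours) have non-identifiable lag-1
#' coefficients; they are excluded (set NA) when their contemporaneous
#' correlation with the seed series exceeds `config$seed_cor_max`. The
#' exclusion is invariant under reordering of the pseudo-time index, so the
#' permutation null of [threshold_cascn()] remains exchangeable.
#'
#' @param pts a `cascn_pts` with voxel geometry.
#' @param seed_series seed series from [extract_seed_series()].
#' @param seed optional seed descriptor; its voxels are always excluded.
#' @param config an [analysis_config()] (supplies `seed_cor_max`).
#' @return list of two `cascn_gcmap` objects named `seed_to_target` and
#'   `target_to_seed`, each with `gc` and `z` 3D arrays (NA outside mask).
#' @export
voxelwise_cascn <- function(pts, seed_series, seed = NULL,
                            config = analysis_config()) {
  if (is.null(pts$geometry)) stop("pts has no voxel geometry")
  if (length(seed_series) < 10) stop("pseudo-time series too short")
  dm <- pts$geometry$dim
  Ys <- zscore_cols(pts$data)
  xs <- zscore_vec(seed_series)
  cors <- as.numeric(crossprod(Ys, xs)) / (length(xs) - 1)
  excl <- !is.na(cors) & abs(cors) > config$seed_cor_max
  if (!is.null(seed)) {
    sv <- if (inherits(seed, "cascn_region")) region_voxels(seed, dm) else as.integer(seed)
    excl <- excl | pts$feature_index %in% sv
  }
  out <- lapply(c("seed_to_target", "target_to_seed"), function(dir) {
    gc <- gc_all_columns(Ys, xs, dir, standardized = TRUE)
    gc[excl] <- NA_real_
    arr <- array(NA_real_, dm)
    arr[pts$feature_index] <- gc
    zscore_map(structure(list(gc = arr, z = NULL, direction = dir, seed = seed,
                              mask = pts$geometry$mask, affine = pts$geometry$affine),
                         class = "cascn_gcmap"))
  })
  names(out) <- c("seed_to_target", "target_to_seed")
  out
}

#' Z-score a GC map within the mask
#'
#' `z = (gc - mean) / sd` over defined in-mask voxels (sample sd).
#'
#' @param map a `cascn_gcmap` with `gc` filled.
#' @return the map with `z` filled.
#' @export
zscore_map <- function(map) {
  v <- map$gc[!is.na(map$gc)]
  if (length(v) < 2) stop("need at least 2 defined voxels")
  s <- stats::sd(v)
  if (s == 0) stop("constant GC map cannot be z-scored")
  map$z <- (map$gc - mean(v)) / s
  map
}

#' Threshold a CaSCN map with permutation cluster-level FDR
#'
#' Voxels pass if `|z| > z_threshold` and `|gc| > gc_threshold`; clusters
#' (26-connectivity) must exceed `min_cluster_voxels`. Cluster p-values come
#' from a permutation null of maximum cluster mass (sum of |z|) obtained by
#' randomly reordering the pseudo-time index and recomputing the map;
#' Benjamini-Hochberg FDR is applied across clusters. Positive and negative
#' clusters are reported with their sign.
#'
#' @param map a `cascn_gcmap` (one direction).
#' @param pts the `cascn_pts` the map was computed from.
#' @param seed_series the observed seed series.
#' @param config an [analysis_config()].
#' @param n_perm number of reorderings (>= 100).
#' @param seed RNG seed.
#' @return cluster data.frame as in [cluster_level_fdr()], with `peak_gc`.
#' @export
threshold_cascn <- function(map, pts, seed_series, config = analysis_config(),
                            n_perm = config$n_perm, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  cl <- extract_clusters(map$z, map$mask, config$z_threshold,
                         config$min_cluster_voxels, map$affine,
                         gc = map$gc, gc_thr = config$gc_threshold)
  if (nrow(cl) == 0) {
    cl$p <- numeric(0); cl$q <- numeric(0); cl$significant <- logical(0)
    return(cl)
  }
  set.seed(as.integer(seed))
  T <- length(seed_series)
  dm <- dim(map$gc)
  # column standardization is permutation invariant: standardize once
  Ys <- zscore_cols(pts$data)
  xs <- zscore_vec(seed_series)
  excl <- is.na(map$gc[pts$feature_index])  # same exclusions as observed map
  nm <- vapply(seq_len(n_perm), function(b) {
    pi <- sample.int(T)
    gc <- gc_all_columns(Ys[pi, , drop = FALSE], xs[pi], map$direction,
                         standardized = TRUE)
    gc[excl] <- NA_real_
    arr <- array(NA_real_, dm)
    arr[pts$feature_index] <- gc
    v <- gc[!is.na(gc)]
    s <- stats::sd(v)
    z <- if (is.finite(s) && s > 0) (arr - mean(v)) / s else arr * NA
    null_max_mass(z, map$mask, config$z_threshold, config$min_cluster_voxels,
                  gc = arr, gc_thr = config$gc_threshold)
  }, 0)
  cl$p <- perm_cluster_pvalues(cl$mass, nm)
  cl$q <- stats::p.adjust(cl$p, "BH")
  cl$significant <- cl$q < config$fdr_alpha
  cl
}
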