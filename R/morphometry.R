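#' Pooled-variance two-sample t test from summary statistics
#'
#' Student t with pooled variance, df = n1 + n2 - 2, two-sided p. This is
#' the test whose statistics the study's demographics table reports (it
#' reproduces the printed GMV and TIV statistics exactly).
#'
#' @param mean1,sd1,n1 group 1 summary.
#' @param mean2,sd2,n2 group 2 summary.
#' @return list(t, df, p).
#' @export
summary_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table, no continuity correction
#'
#' @param a,b,c,d cell counts, rows = groups, columns = categories.
#' @return list(statistic, df, p).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  n <- sum(cnt)
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("zero margin")
  stat <- n * (a * d - b * c)^2 / prod(m)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

## vectorized per-voxel GLM t for one coefficient; Y n x V, X n x p
glm_t_columns <- function(Y, X, coef_index) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[coef_index, coef_index])
  t <- beta[coef_index, ] / se
  t[se == 0] <- 0
  list(t = t, df = df)
}

#' Voxel-wise GLM two-group contrast
#'
#' Per-voxel least-squares fit of density on intercept + group indicator +
#' covariates; returns the t statistic for the group coefficient
#' (group1 - group2, i.e. positive t = higher density in `group1`).
#'
#' @param images a `gmv_image_set`.
#' @param group factor/character of length n_subjects with two levels.
#' @param covariates optional data.frame of nuisance covariates (numeric
#'   columns; character/factor columns are expanded via model.matrix).
#' @param group1 level treated as the positive side (default: first level).
#' @return a `cascn_tmap`: list(statistic = 3D array with NA outside mask,
#'   df, mask, affine, contrast, covariates).
#' @export
voxelwise_glm_ttest <- function(images, group, covariates = NULL, group1 = NULL) {
  g <- as.character(group)
  lv <- unique(g)
  if (length(lv) != 2) stop("need exactly two groups")
  if (is.null(group1)) group1 <- lv[1]
  if (min(table(g)) < 2) stop("need >= 2 subjects per group")
  ind <- as.numeric(g == group1)
  X <- cbind(intercept = 1, group = ind)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, C)
  }
  mvox <- which(images$mask)
  Y <- images$data[, mvox, drop = FALSE]
  fit <- glm_t_columns(Y, X, 2L)
  stat <- array(NA_real_, images$dim)
  stat[mvox] <- fit$t
  structure(list(statistic = stat, df = fit$df, mask = images$mask,
                 affine = images$affine,
                 contrast = paste0(group1, " - ", setdiff(lv, group1)),
                 covariates = colnames(X)[-(1:2)]),
            class = "cascn_tmap")
}

#' Select a grey-matter mask threshold by correlation maximization
#'
#' Over candidate probability cutoffs, picks the one maximizing the Pearson
#' correlation between the mean tissue-probability map and the mean density
#' map across voxels above the cutoff. With selection disabled the
#' conventional default 0.27 is returned.
#'
#' @param mean_probability,mean_gmv aligned 3D arrays.
#' @param candidates candidate thresholds (default seq(0.05, 0.5, 0.01)).
#' @param select if `FALSE`, skip the scan and return `default`.
#' @param default threshold used when selection is skipped.
#' @param min_voxels candidates leaving fewer voxels are ineligible.
#' @return the chosen threshold (attribute `correlation` carries the scan).
#' @export
select_mask_threshold <- function(mean_probability, mean_gmv,
                                  candidates = seq(0.05, 0.5, by = 0.01),
                                  select = TRUE, default = 0.27,
                                  min_voxels = 100) {
  if (!select) return(default)
  if (!all(dim(mean_probability) == dim(mean_gmv))) stop("grids are not aligned")
  rs <- vapply(candidates, function(th) {
    keep <- which(mean_probability > th)
    if (length(keep) < min_voxels) return(NA_real_)
    suppressWarnings(stats::cor(mean_probability[keep], mean_gmv[keep]))
  }, 0)
  if (all(is.na(rs))) stop("no candidate threshold leaves >= ", min_voxels, " voxels")
  best <- candidates[which.max(rs)]
  attr(best, "correlation") <- stats::setNames(rs, candidates)
  best
}
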