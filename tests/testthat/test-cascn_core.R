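test_that("covariate residualization is exact and orthogonal", {
  set.seed(2)
  n <- 40
  covs <- data.frame(age = rnorm(n, 55, 6), sex = sample(c("m", "f"), n, TRUE),
                     tiv = rnorm(n, 1450, 100))
  X <- model.matrix(~ ., covs)
  # a feature that is an exact linear function of the covariates residualizes
  # to zero; residuals are orthogonal to every covariate column
  m <- cbind(exact = as.numeric(X %*% c(3, -0.5, 1.2, 0.01)),
             noisy = rnorm(n))
  r <- residualize_covariates(m, covs)
  expect_lt(max(abs(r[, "exact"])), 1e-9)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  # NULL covariates = demeaning
  expect_equal(residualize_covariates(m, NULL), sweep(m, 2, colMeans(m)),
               tolerance = 1e-12)
  expect_error(residualize_covariates(m, data.frame(a = covs$age, b = covs$age)),
               "rank deficient")
})

test_that("pseudo-time ordering is WMH-ascending with id tie-breaks", {
  co <- generate_cohort(12, 4, seed = 3)
  co$wmh_volume[co$group == "patient"][1:2] <- 5  # force a tie
  m <- matrix(rnorm(16 * 6), 16, dimnames = list(NULL, paste0("f", 1:6)))
  pts <- build_pseudo_timeseries(m, co, covariates = NULL)
  expect_s3_class(pts, "cascn_pts")
  expect_equal(nrow(pts$data), 12)      # patients only
  expect_true(all(diff(pts$wmh) >= 0))
  tie <- which(pts$wmh == 5)
  expect_equal(pts$subject_id[tie], sort(pts$subject_id[tie]))
  # permuting cohort rows does not change the ordered series
  perm <- sample(16)
  pts2 <- build_pseudo_timeseries(m[perm, , drop = FALSE], co[perm, ],
                                  covariates = NULL)
  expect_equal(pts2$data, pts$data, tolerance = 1e-12)
  expect_error(build_pseudo_timeseries(m, co, covariates = "nope"),
               "covariate column")
})

test_that("seed series extraction averages the in-mask seed voxels", {
  sim <- simulate_study(20, 0, seed = 4)
  pts <- build_pseudo_timeseries(sim$images, sim$cohort)
  roi <- sim$truth$source_roi
  ss <- extract_seed_series(pts, roi)
  vox <- intersect(region_voxels(roi, sim$images$dim), pts$feature_index)
  cols <- match(vox, pts$feature_index)
  expect_equal(ss, rowMeans(pts$data[, cols]), tolerance = 1e-12)
  # a single-voxel seed reproduces that voxel's series
  one <- vox[1]
  expect_equal(extract_seed_series(pts, one), pts$data[, match(one, pts$feature_index)],
               tolerance = 1e-12)
  expect_error(extract_seed_series(pts, region(c(1, 1, 1), 1)), "does not intersect")
})

test_that("signed GC matches the least-squares oracle and known limits", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(60); y <- rnorm(60)
    expect_equal(signed_gc_pair(x, y), lm_gc_oracle(x, y), tolerance = 1e-10)
  }
  # y_t = x_{t-1}: near-unit positive path; sign flips with the driver
  set.seed(31)
  x <- rnorm(500)
  y <- c(0, x[-500]) + rnorm(500, 0, 0.05)
  expect_gt(signed_gc_pair(x, y), 0.9)
  expect_lt(signed_gc_pair(x, -y), -0.9)
  # independent white noise: no path
  set.seed(32)
  expect_lt(abs(signed_gc_pair(rnorm(2000), rnorm(2000))), 0.08)
  expect_error(signed_gc_pair(rep(1, 30), rnorm(30)), "constant")
  expect_error(signed_gc_pair(rnorm(5), rnorm(5)), "length >= 10")
  expect_error(signed_gc_pair(rnorm(30), rnorm(29)), "lengths differ")
})

test_that("vectorized GC equals the scalar fit in both directions", {
  set.seed(8)
  T <- 50
  Y <- matrix(rnorm(T * 30), T)
  x <- rnorm(T)
  fwd <- cascnet:::gc_all_columns(Y, x, "seed_to_target")
  bwd <- cascnet:::gc_all_columns(Y, x, "target_to_seed")
  for (j in seq_len(30)) {
    expect_equal(fwd[j], signed_gc_pair(x, Y[, j]), tolerance = 1e-10)
    expect_equal(bwd[j], signed_gc_pair(Y[, j], x), tolerance = 1e-10)
  }
  # constant columns are NA, not errors
  Y[, 3] <- 1
  expect_true(is.na(cascnet:::gc_all_columns(Y, x, "seed_to_target")[3]))
})

test_that("GC maps are z-scored within the mask and exclude seed collinearity", {
  sim <- simulate_study(60, 0, seed = 6)
  pts <- build_pseudo_timeseries(sim$images, sim$cohort)
  roi <- sim$truth$source_roi
  ss <- extract_seed_series(pts, roi)
  maps <- voxelwise_cascn(pts, ss, seed = roi, config = desk_config())
  expect_named(maps, c("seed_to_target", "target_to_seed"))
  for (mp in maps) {
    v <- mp$z[!is.na(mp$z)]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
    # the seed's own voxels are excluded from the map
    expect_true(all(is.na(mp$gc[region_voxels(roi, sim$images$dim)])))
    expect_true(all(is.na(mp$gc[!sim$images$mask])))
  }
  # the planted lag-1 target carries a strong positive forward path
  tgt <- region_voxels(sim$truth$positive_targets[[1]]$roi, sim$images$dim)
  expect_gt(mean(maps$seed_to_target$gc[tgt]), 0.5)
})

test_that("two-voxel z-scoring gives the closed-form +-1/sqrt(2)", {
  arr <- array(NA_real_, c(2, 1, 1)); arr[1] <- 0.4; arr[2] <- 0.1
  mp <- structure(list(gc = arr, z = NULL, direction = "seed_to_target",
                       mask = array(TRUE, c(2, 1, 1)), affine = diag(4)),
                  class = "cascn_gcmap")
  z <- zscore_map(mp)$z
  expect_equal(as.numeric(z)[1:2], c(1, -1) / sqrt(2), tolerance = 1e-12)
})

test_that("permutation thresholding flags planted clusters, null maps stay clean", {
  acfg <- desk_config()
  truth <- lag1_truth()
  sim <- simulate_study(100, 0, truth = truth, seed = 14)
  pts <- build_pseudo_timeseries(sim$images, sim$cohort)
  ss <- extract_seed_series(pts, truth$source_roi)
  maps <- voxelwise_cascn(pts, ss, seed = truth$source_roi, config = acfg)
  cl <- threshold_cascn(maps$seed_to_target, pts, ss, acfg, seed = 14)
  expect_true(any(cl$significant & cl$sign > 0))
  expect_true(any(cl$significant & cl$sign < 0))
  # determinism of the permutation p-values
  cl2 <- threshold_cascn(maps$seed_to_target, pts, ss, acfg, seed = 14)
  expect_identical(cl$p, cl2$p)

  # shuffled pseudo-time should carry roughly nominal supra-threshold mass
  set.seed(15)
  sh <- pts; ord <- sample(nrow(pts$data)); sh$data <- pts$data[ord, ]
  m0 <- voxelwise_cascn(sh, ss[ord], seed = truth$source_roi, config = acfg)
  frac <- mean(abs(m0$seed_to_target$z) > 1.96, na.rm = TRUE)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})
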