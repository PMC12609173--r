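test_that("summary two-sample t matches stats::t.test and degenerate cases", {
  # random summaries vs t.test on raw data with matching moments
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(25, 10, 2); y <- rnorm(30, 11, 3)
    ours <- summary_two_sample_t(mean(x), sd(x), 25, mean(y), sd(y), 30)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(summary_two_sample_t(5, 1, 10, 5, 2, 12)$t, 0)
  expect_error(summary_two_sample_t(5, 1, 1, 5, 2, 12), "n >= 2")
  expect_error(summary_two_sample_t(5, 0, 10, 5, 2, 12), "positive")
})

test_that("2x2 chi-square matches stats::chisq.test without continuity correction", {
  for (s in 1:10) {
    set.seed(s)
    tab <- matrix(rpois(4, 30) + 1, 2)
    ours <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # proportional rows carry no association
  expect_equal(chi_square_2x2(10, 20, 30, 60)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("voxel-wise GLM t is antisymmetric in the contrast and exact under covariates", {
  sim <- simulate_study(20, 20, seed = 5)
  covs <- sim$cohort[, c("age", "sex", "education_years", "tiv")]
  t1 <- voxelwise_glm_ttest(sim$images, sim$cohort$group, covs, group1 = "patient")
  t2 <- voxelwise_glm_ttest(sim$images, sim$cohort$group, covs, group1 = "control")
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-10)
  expect_true(all(is.na(t1$statistic[!sim$images$mask])))
  expect_equal(t1$df, 40 - 2 - ncol(model.matrix(~ ., covs)[, -1]))

  # covariate-free GLM t equals the per-voxel two-sample pooled t: adding an
  # exactly group-coded covariate makes the design rank deficient
  expect_error(voxelwise_glm_ttest(sim$images, sim$cohort$group,
                                   data.frame(g = as.numeric(sim$cohort$group == "patient"))),
               "rank deficient")
})

test_that("identical image sets in both groups give a zero t map", {
  sim <- simulate_study(10, 0, seed = 9)
  img <- sim$images
  img$data <- rbind(img$data, img$data)
  img$subject_id <- c(paste0(img$subject_id, "_a"), paste0(img$subject_id, "_b"))
  t0 <- voxelwise_glm_ttest(img, rep(c("a", "b"), each = 10), group1 = "a")
  expect_equal(max(abs(t0$statistic), na.rm = TRUE), 0)
})

test_that("null group contrast has approximately standard t moments", {
  # hand-built image set with iid voxel noise: the per-voxel t statistics
  # are iid Student t with n - 2 degrees of freedom
  set.seed(21)
  dm <- c(20L, 10L, 10L)
  img <- structure(list(data = matrix(rnorm(30 * prod(dm)), 30),
                        dim = dm, mask = array(TRUE, dm),
                        affine = default_affine(6, dm), voxel_size = 6,
                        subject_id = sprintf("S%02d", 1:30)),
                   class = "gmv_image_set")
  tm <- voxelwise_glm_ttest(img, rep(c("a", "b"), each = 15), group1 = "a")
  v <- tm$statistic[!is.na(tm$statistic)]
  expect_lt(abs(mean(v)), 0.1)
  expect_equal(sd(v), sqrt(28 / 26), tolerance = 0.08)
})

test_that("mask threshold selection maximizes probability-density correlation", {
  tm <- template_and_mask()
  set.seed(4)
  # density tracks probability only above 0.3; pure noise below
  gmv <- array(rnorm(length(tm$template), 0, 0.05), dim(tm$template))
  hi <- tm$template > 0.3
  gmv[hi] <- tm$template[hi] + rnorm(sum(hi), 0, 0.01)
  cand <- seq(0.1, 0.45, by = 0.05)
  got <- select_mask_threshold(tm$template, gmv, cand)
  # independent scan oracle
  rs <- sapply(cand, function(th) {
    keep <- tm$template > th
    if (sum(keep) < 100) NA_real_ else cor(tm$template[keep], gmv[keep])
  })
  expect_equal(as.numeric(got), cand[which.max(rs)])
  expect_gte(as.numeric(got), 0.3)
  expect_equal(select_mask_threshold(tm$template, gmv, select = FALSE), 0.27)
  expect_error(select_mask_threshold(tm$template, gmv, candidates = 0.99),
               "no candidate")
})

test_that("cluster-level FDR detects the planted group atrophy", {
  sim <- simulate_study(30, 30, seed = 13)
  res <- cluster_level_fdr(sim$images, sim$cohort$group,
                           sim$cohort[, c("age", "sex", "education_years", "tiv")],
                           min_extent = 10, n_perm = 200, seed = 99,
                           group1 = "patient")
  expect_true(all(c("p", "q", "significant") %in% names(res$clusters)))
  expect_true(all(res$clusters$p >= 1 / 201))
  # patients lose grey matter globally relative to controls: at least one
  # significant negative cluster must appear
  expect_gt(sum(res$clusters$significant & res$clusters$sign < 0), 0)
})

test_that("connected components respect 26-connectivity", {
  dm <- c(5L, 5L, 5L)
  flag <- array(FALSE, dm)
  flag[1, 1, 1] <- TRUE; flag[2, 2, 2] <- TRUE  # diagonal neighbours: one component
  flag[5, 5, 5] <- TRUE                          # isolated voxel
  comps <- cascnet:::label_components(flag, dm)
  expect_equal(length(comps), 2)
  expect_equal(sort(unname(lengths(comps))), c(1L, 2L))
})
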