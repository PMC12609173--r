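test_that("cohort generation is deterministic and satisfies the lesion invariants", {
  c1 <- generate_cohort(60, 15, seed = 7)
  c2 <- generate_cohort(60, 15, seed = 7)
  expect_identical(c1, c2)
  c3 <- generate_cohort(60, 15, seed = 8)
  expect_false(identical(c1$wmh_volume, c3$wmh_volume))

  p <- c1$group == "patient"
  expect_equal(sum(p), 60)
  expect_true(all(c1$wmh_volume[p] > 0))
  expect_true(all(c1$fazekas[p] %in% 1:3))
  expect_true(all(c1$wmh_volume[!p] == 0))
  expect_true(all(c1$fazekas[!p] == 0))
  expect_false(anyDuplicated(c1$subject_id) > 0)
  # patient cognition is filled by the cognition generator, not here
  expect_true(all(is.na(c1$dst[p])))
  expect_true(all(!is.na(c1$dst[!p])))
  # Fazekas grades are monotone in lesion volume
  expect_true(all(diff(c1$fazekas[p][order(c1$wmh_volume[p])]) >= 0))
})

test_that("lesion-burden parameters follow quantile matching of the printed summaries", {
  cfg <- cohort_config()
  expect_equal(cfg$wmh_meanlog, log(5.24))
  expect_equal(cfg$wmh_sdlog, (log(11.68) - log(2.64)) / (2 * qnorm(0.75)))
  # the calibrated lognormal reproduces the printed median and quartiles
  expect_equal(qlnorm(0.5, cfg$wmh_meanlog, cfg$wmh_sdlog), 5.24, tolerance = 1e-10)
  # the scale parameter matches the printed interquartile ratio exactly
  expect_equal(qlnorm(0.75, cfg$wmh_meanlog, cfg$wmh_sdlog) /
                 qlnorm(0.25, cfg$wmh_meanlog, cfg$wmh_sdlog), 11.68 / 2.64,
               tolerance = 1e-10)
})

test_that("stratified sampling reproduces the calibrated quartiles in-sample", {
  cfg <- cohort_config()
  for (s in 1:5) {
    co <- generate_cohort(185, 0, cfg, seed = s)
    q <- quantile(co$wmh_volume, c(0.25, 0.5, 0.75), names = FALSE)
    expect_lt(abs(q[1] - 2.64) / 2.64, 0.10)
    expect_lt(abs(q[2] - 5.24) / 5.24, 0.10)
    expect_lt(abs(q[3] - 11.68) / 11.68, 0.10)
  }
})

test_that("noiseless image generator plants exact lagged propagation", {
  # no voxel noise, no innovations, perfect lesion-morphometry coupling:
  # region means are exactly reconstructable from the generative equations
  truth <- ground_truth(voxel_noise_sd = 0, signal_noise_sd = 0)
  cfg <- cohort_config(gmv_wmh_r = -1)
  cohort <- generate_cohort(40, 0, cfg, seed = 3)
  images <- generate_images(cohort, truth, seed = 3)

  tm <- template_and_mask(images$dim)
  ord <- order(cohort$wmh_volume, cohort$subject_id)
  scale_i <- cohort$global_gmv / mean(cohort$global_gmv)
  src_def <- truth$atrophy_slope * log1p(cohort$wmh_volume[ord])

  # source region mean: baseline minus deficit, strictly decreasing
  sv <- region_voxels(truth$source_roi, images$dim)
  src_mean <- rowMeans(images$data[ord, sv])
  expect_equal(src_mean, scale_i[ord] * mean(tm$template[sv]) - src_def,
               tolerance = 1e-12)
  expect_true(all(diff(src_mean) < 0))

  # each target's deficit equals weight x lag-shifted source deficit, exactly
  for (tg in c(truth$positive_targets, truth$negative_targets)) {
    vv <- region_voxels(tg$roi, images$dim)
    baseline <- scale_i[ord] * mean(tm$template[vv])
    deficit <- baseline - rowMeans(images$data[ord, vv])
    expected <- c(rep(0, tg$lag),
                  tg$weight * src_def[seq_len(length(ord) - tg$lag)])
    expect_equal(deficit, expected, tolerance = 1e-12)
  }
})

test_that("planted cognition follows the path structure exactly in the noise-free case", {
  # c_prime = 1, b = 0 makes the standardized score variance exactly 1, so the
  # residual noise is zero and DST is an affine function of WMH alone
  truth <- ground_truth(mediation_coeffs = list(
    dst = c(a = -0.954, b = 0, c_prime = 1),
    inv_tmt = c(a = -0.954, b = 0, c_prime = 1)))
  cohort <- generate_cohort(50, 10, seed = 2)
  cohort <- generate_cognition(cohort, truth, seed = 2)
  p <- cohort$group == "patient"
  cfg <- cohort_config()
  zw <- as.numeric(scale(cohort$wmh_volume[p]))
  expect_equal(cohort$dst[p], cfg$dst_patient[1] + cfg$dst_patient[2] * zw,
               tolerance = 1e-12)
  expect_true(all(cohort$tmt_a[p] > 0))
})

test_that("simulated cognitive scores match the calibrated DST scale", {
  sim <- simulate_study(185, 40, seed = 11)
  p <- sim$cohort$group == "patient"
  expect_lt(abs(mean(sim$cohort$dst[p]) - 50.63), 3)
  expect_lt(abs(sd(sim$cohort$dst[p]) - 18.28), 3)
  validate_cohort(sim$cohort)  # complete table passes strict validation
  expect_identical(dim(sim$images$data), c(225L, 24L * 24L * 24L))
  expect_gt(sum(sim$images$mask), 1000)
})

test_that("degenerate generator inputs raise errors", {
  expect_error(generate_cohort(3, 10), "n_patients")
  expect_error(ground_truth(positive_targets = list(
    list(roi = region(c(20, 15, 12), 2, "clash"), weight = 0.5, lag = 1L))),
    "overlap")
  expect_error(ground_truth(negative_targets = list(
    list(roi = region(c(4, 4, 4), 2, "bad"), weight = 0.5, lag = 1L))),
    "weight")
  # a lag as long as the patient ordering cannot be realised
  co <- generate_cohort(5, 0, seed = 1)
  expect_error(generate_images(co, ground_truth(), seed = 1), "lag")
  bad <- generate_cohort(10, 5, seed = 1)
  bad$wmh_volume[bad$group == "control"][1] <- 2
  expect_error(validate_cohort(bad), "controls")
})
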