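test_that("cohort simulation is reproducible and internally consistent", {
  cfg <- simulation_config(n_subjects = 20, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$cohort), 20)
  expect_setequal(unique(s1$truth$vt$region), default_regions())
  # Stored V_T equals the microparameter formula to 1e-10 relative.
  v <- s1$truth$vt
  expect_lt(max(abs(v$VT - (v$K1 / v$k2) * (1 + v$k3 / v$k4)) / v$VT), 1e-10)
  # Covariate invariants.
  expect_true(all(s1$cohort$pcl5_total >= 0 & s1$cohort$pcl5_total <= 80))
  expect_true(all(s1$cohort$months_wtc >= 0))
  expect_true(all(s1$cohort$genotype %in% c("HAB", "MAB")))
  expect_true(all(c("pcl5_re_experiencing", "pcl5_avoidance",
                    "pcl5_negative_cognitions_mood", "pcl5_arousal",
                    "mci_status", "response_time", "visuospatial_memory")
                  %in% names(s1$cohort)))
})

test_that("genotype mix matches the configured MAB probability", {
  # Expected MAB count at n = 20, p = 0.55 is 11; check the long-run rate.
  counts <- vapply(1:40, function(i) {
    s <- simulate_cohort(simulation_config(n_subjects = 20, seed = i))
    sum(s$cohort$genotype == "MAB")
  }, numeric(1))
  expect_equal(mean(counts), 11, tolerance = 0.12)
  expect_true(abs(counts[1] - 11) <= 5)
})

test_that("zero effects with vanishing dispersion pin V_T at its regional baseline", {
  cfg <- simulation_config(n_subjects = 12, seed = 2, effect_beta_pcl = 0,
                           effect_beta_months = 0, effect_beta_hab = 0,
                           gamma_shape = 1e8)
  s <- simulate_cohort(cfg)
  for (r in default_regions()) {
    v <- s$truth$vt$VT[s$truth$vt$region == r]
    expect_lt(max(abs(v - exp(cfg$alpha_region[[r]])) / exp(cfg$alpha_region[[r]])),
              1e-3)
  }
})

test_that("generated log V_T carries the configured PCL-5 effect", {
  cfg <- simulation_config(n_subjects = 2000, seed = 31, effect_beta_pcl = 0.1)
  s <- simulate_cohort(cfg)
  z <- scale(s$cohort$pcl5_total)[, 1]
  lv <- log(s$truth$vt$VT[s$truth$vt$region == "hippocampus"])
  expect_lt(abs(cor(z, lv) - 0.1 / sd(lv)), 0.05)
})

test_that("per-region V_T moments follow the Gamma(mean, shape) prescription", {
  cfg <- simulation_config(n_subjects = 5000, seed = 13, gamma_shape = 25)
  s <- simulate_cohort(cfg)
  for (r in c("frontal", "hippocampus")) {
    v <- s$truth$vt[s$truth$vt$region == r, ]
    n <- nrow(v)
    expected_mean <- mean(v$mu)
    expected_var <- mean(v$mu^2) / 25 + var(v$mu)
    se_mean <- sqrt(expected_var / n)
    expect_lt(abs(mean(v$VT) - expected_mean), 3 * se_mean)
    # Variance check with a generous moment-based MC error bound.
    se_var <- expected_var * sqrt(2 / (n - 1)) * 2
    expect_lt(abs(var(v$VT) - expected_var), 3 * se_var)
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(gamma_shape = 0), "gamma_shape")
  expect_error(simulation_config(tac_noise_cv = -0.1), "tac_noise_cv")
  expect_error(simulation_config(p_mab = 1.5), "p_mab")
  expect_error(simulate_blood_data(fixture_input(),
                                   parent_fraction_model(0.2, 2, 20),
                                   wb_plasma_ratio_model(0.9, 0.6, 0.1),
                                   noise_cv = -1), "noise_cv")
})

test_that("blood simulation honours the sampling protocol", {
  bt <- default_blood_truth()
  ds <- simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = 0, seed = 1)
  expect_equal(ds$manual_times_min, c(2.5, 7, 15, 30, 60, 90, 120))
  expect_equal(range(ds$auto_times_s), c(0, 360))
  expect_length(ds$auto_times_s, 361)  # 1 Hz over the first 6 min
  # Noiseless parent fractions equal the Hill model exactly.
  expect_equal(ds$manual_parent_fraction,
               predict_parent_fraction(bt$hill, ds$manual_times_min))
  # Identical seeds give identical datasets.
  ds2 <- simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = 0.05, seed = 9)
  ds3 <- simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = 0.05, seed = 9)
  expect_identical(ds2, ds3)
})

test_that("replicate blood noise reproduces the requested CV", {
  bt <- default_blood_truth()
  vals <- vapply(1:500, function(i) {
    ds <- simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = 0.05,
                              seed = 1000 + i)
    ds$manual_plasma_activity[ds$manual_times_min == 30]
  }, numeric(1))
  cv <- sd(vals) / mean(vals)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("TAC simulation matches the forward model exactly without noise", {
  cfg <- simulation_config(n_subjects = 2, seed = 21)
  s <- simulate_cohort(cfg)
  st <- subject_truth_from_cohort(s$truth, "S001")
  bt <- cfg$blood_truth
  blood <- simulate_blood_data(st$input, bt$hill, bt$ratio, noise_cv = 0, seed = 1)
  sch <- default_frame_scheme()
  tacs <- simulate_tacs(st, blood, sch, noise_cv = 0, seed = 1)
  expect_setequal(names(tacs), default_regions())
  expect_equal(vapply(tacs, function(x) length(x$activity), numeric(1)),
               setNames(rep(20, 7), names(tacs)))
  wb <- make_wb_curve(blood)
  for (r in c("frontal", "hippocampus")) {
    direct <- frame_average(function(t) forward_2tc(st$kinetics[[r]], st$input,
                                                    wb, t), sch)
    expect_equal(tacs[[r]]$activity, direct)
  }
  # Null kinetics with no vascular signal gives an identically zero TAC.
  st0 <- st
  st0$kinetics <- list(dead = two_tc_params(0, 0.08, 0.04, 0.02, vB = 0))
  tac0 <- simulate_tacs(st0, blood, sch, noise_cv = 0, seed = 1)
  expect_equal(tac0$dead$activity, rep(0, 20))
})

test_that("phantom simulation blurs piecewise-constant truth as specified", {
  labs <- two_cube_labels()
  # Delta PSF returns the exact truth.
  ph0 <- simulate_phantom(labs$labels, c(4, 1), psf_fwhm_mm = 0)
  expect_identical(ph0$activity, ph0$truth)
  # 6 mm FWHM: the hot cube loses signal to its surround, and spill-in
  # from the hot neighbour raises the cold cube above its isolated blur
  # (with zero background, spill-out lowers both absolute means).
  close_labs <- two_cube_labels(gap = 1)
  ph <- simulate_phantom(close_labs$labels, c(4, 1), psf_fwhm_mm = 6,
                         voxel_size_mm = 2)
  expect_lt(mean(ph$activity[close_labs$labels == 1]), 4)
  ph_cold_alone <- simulate_phantom(close_labs$labels, c(0, 1), psf_fwhm_mm = 6,
                                    voxel_size_mm = 2)
  expect_gt(mean(ph$activity[close_labs$labels == 2]),
            mean(ph_cold_alone$activity[close_labs$labels == 2]))
  # A constant image is PSF-invariant away from the volume edge.
  phc <- simulate_phantom(labs$labels, c(3, 3), psf_fwhm_mm = 8,
                          voxel_size_mm = 2, background = 3)
  core <- phc$activity[10:30, 10:30, 10:30]
  expect_lt(max(abs(core - 3)), 1e-6)
  # Overlapping masks are refused.
  m1 <- array(FALSE, dim = c(8, 8, 8)); m1[1:5, , ] <- TRUE
  m2 <- array(FALSE, dim = c(8, 8, 8)); m2[4:8, , ] <- TRUE
  expect_error(simulate_phantom(list(a = m1, b = m2), c(1, 2), 0), "overlap")
})
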