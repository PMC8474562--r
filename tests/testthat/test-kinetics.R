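test_that("frame scheme derives contiguous frames and the default spans 120 min", {
  sch <- default_frame_scheme()
  expect_equal(sch$n_frames, 20L)
  expect_equal(max(sch$frame_end_s), 7200)
  expect_equal(sch$frame_start_s[1], 0)
  expect_equal(sch$frame_start_s[-1], sch$frame_end_s[-sch$n_frames])
  expect_equal(sch$frame_mid_s, (sch$frame_start_s + sch$frame_end_s) / 2)
  expect_error(frame_scheme(list(c(0, 60))), "count")
})

test_that("V_T follows (K1/k2)(1+k3/k4) and rejects non-positive rates", {
  expect_equal(compute_vt(c(0.2, 0.1, 0.05, 0.03)), (0.2 / 0.1) * (1 + 0.05 / 0.03))
  expect_equal(compute_vt(c(0.1, 0.1, 1e-9, 0.02)), 1, tolerance = 1e-6)
  expect_error(compute_vt(c(0.2, -0.1, 0.05, 0.03)), "positive")
  expect_error(compute_vt(c(0.2, 0.1, 0, 0.03)), "positive")
})

test_that("impulse response integrates to V_T over random admissible draws", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_2tc_draw()
    num <- stats::integrate(function(t) impulse_response_2tc(p, t), 0, Inf,
                            rel.tol = 1e-10)$value
    expect_equal(num, p$VT, tolerance = 1e-6)
  }
})

test_that("macro rates are ordered and amplitudes are consistent", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_2tc_draw()
    expect_gte(p$theta1, p$theta2)
    expect_gt(p$theta2, 0)
    expect_equal(p$phi1 + p$phi2, p$K1, tolerance = 1e-10)
  }
})

test_that("semi-analytic convolution matches brute-force quadrature", {
  set.seed(11)
  input <- fixture_input()
  tpts <- c(0.5, 1, 2, 10, 60, 119)
  for (i in 1:100) {
    p0 <- random_2tc_draw()
    p <- two_tc_params(p0$K1, p0$k2, p0$k3, p0$k4, vB = 0)
    semi <- forward_2tc(p, input, NULL, tpts)
    brute <- brute_force_tissue(p, input, tpts)
    expect_equal(semi, brute, tolerance = 1e-6)
  }
})

test_that("forward model agrees with direct ODE integration of the compartment system", {
  input <- fixture_input()
  p <- two_tc_params(0.2, 0.1, 0.05, 0.03, vB = 0)
  times <- seq(0, 120, by = 2)
  ode_rhs <- function(t, y, parms) {
    cp <- evaluate_input(input, t)
    list(c(p$K1 * cp - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), times, ode_rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  tissue_ode <- sol[, 2] + sol[, 3]
  expect_equal(forward_2tc(p, input, NULL, times), tissue_ode,
               tolerance = 1e-6)
})

test_that("null delivery leaves only the vascular term", {
  input <- fixture_input()
  wb <- function(t) 5 * exp(-0.05 * t)
  p <- two_tc_params(0, 0.1, 0.05, 0.03, vB = 0.05)
  t <- c(0.5, 5, 50)
  expect_equal(forward_2tc(p, input, wb, t), 0.05 * wb(t))
  p2 <- two_tc_params(0, 0.1, 0.05, 0.03, vB = 0)
  expect_equal(forward_2tc(p2, input, wb, t), rep(0, 3))
})

test_that("repeated macro roots are handled by the limiting form", {
  # k2 = k4, k3 -> 0 drives the discriminant towards zero.
  p <- two_tc_params(0.1, 0.05, 1e-9, 0.05)
  expect_true(is.finite(p$phi1) && is.finite(p$phi2))
  input <- fixture_input()
  val <- forward_2tc(two_tc_params(0.1, 0.05, 1e-9, 0.05, vB = 0),
                     input, NULL, c(1, 10, 60))
  expect_true(all(is.finite(val)) && all(val > 0))
  # Against brute force with the (finite-difference-free) impulse limit.
  brute <- brute_force_tissue(p, input, c(1, 10, 60))
  expect_equal(val, brute, tolerance = 1e-4)
})

test_that("frame averaging is exact for constants, linear curves and exponentials", {
  sch <- default_frame_scheme()
  expect_equal(frame_average(function(t) rep(3.7, length(t)), sch),
               rep(3.7, 20))
  lin <- frame_average(function(t) 2 * t, sch)
  expect_equal(lin, 2 * sch$frame_mid_s / 60, tolerance = 1e-12)
  one <- frame_scheme(list(c(1, 60)))
  expect_equal(frame_average(function(t) exp(-t), one), 1 - exp(-1),
               tolerance = 1e-12)
})

test_that("noiseless 2TC fits recover the generating rates and V_T", {
  input <- fixture_input()
  truth <- two_tc_params(0.15, 0.08, 0.04, 0.02)
  tac <- make_noiseless_tac(two_tc_params(0.15, 0.08, 0.04, 0.02, vB = 0),
                            input)
  fit <- fit_2tc(tac, input, NULL, vB = 0, n_starts = 5, seed = 42)
  est <- with(fit$params, c(K1, k2, k3, k4))
  expect_lt(max(abs(est - c(0.15, 0.08, 0.04, 0.02)) / c(0.15, 0.08, 0.04, 0.02)),
            0.01)
  expect_lt(abs(fit$VT - truth$VT) / truth$VT, 0.005)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$covariance)))
  expect_gte(fit$VT_se, 0)  # zero when the noiseless fit is exact
})

test_that("2TC fitting is deterministic given the multi-start seed", {
  input <- fixture_input()
  truth <- two_tc_params(0.2, 0.1, 0.03, 0.015, vB = 0)
  act <- make_noiseless_tac(truth, input)$activity
  set.seed(9)
  act <- act * (1 + 0.05 * rnorm(length(act)))
  tac <- time_activity_curve("roi", default_frame_scheme()$frame_start_s,
                             default_frame_scheme()$frame_dur_s, act)
  f1 <- fit_2tc(tac, input, NULL, vB = 0, n_starts = 5, seed = 7)
  f2 <- fit_2tc(tac, input, NULL, vB = 0, n_starts = 5, seed = 7)
  expect_identical(f1$VT, f2$VT)
  expect_identical(coef_vec <- unlist(f1$params[1:4]), unlist(f2$params[1:4]))
})

test_that("scaling K1 scales the noiseless curve and fitted V_T linearly", {
  input <- fixture_input()
  p1 <- two_tc_params(0.1, 0.08, 0.04, 0.02, vB = 0)
  p3 <- two_tc_params(0.3, 0.08, 0.04, 0.02, vB = 0)
  t <- c(1, 10, 60, 110)
  expect_equal(3 * forward_2tc(p1, input, NULL, t),
               forward_2tc(p3, input, NULL, t), tolerance = 1e-12)
  tac3 <- make_noiseless_tac(p3, input)
  fit3 <- fit_2tc(tac3, input, NULL, vB = 0, n_starts = 5, seed = 42)
  expect_equal(fit3$VT, 3 * p1$VT, tolerance = 0.01)
})

test_that("a pure-blood TAC drives K1 to the lower bound and is flagged", {
  input <- fixture_input()
  wb <- function(t) evaluate_input(input, t) * 0.8
  sch <- default_frame_scheme()
  wb_frames <- frame_average(wb, sch)
  tac <- time_activity_curve("blood", sch$frame_start_s, sch$frame_dur_s,
                             0.05 * wb_frames)
  fit <- fit_2tc(tac, input, wb, vB = 0.05, n_starts = 5, seed = 42)
  expect_lt(fit$params$K1, 5e-3)
  expect_false(fit$converged)  # bound-constrained solution is flagged
  # Tissue contribution is negligible: fit reproduces the vascular curve.
  expect_equal(fit$fitted, 0.05 * wb_frames, tolerance = 0.02)
})
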