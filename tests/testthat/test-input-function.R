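seven_times <- c(2.5, 7, 15, 30, 60, 90, 120)

make_blood <- function(noise_cv = 0, seed = 1) {
  bt <- default_blood_truth()
  simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = noise_cv,
                      seed = seed)
}

test_that("constant whole-blood/plasma ratios yield a flat ratio model", {
  ds <- blood_dataset(numeric(0), numeric(0), seven_times,
                      rep(8, 7), rep(10, 7), rep(0.5, 7))
  m <- fit_wb_plasma_ratio(ds)
  expect_equal(m$r0, 0.8)
  expect_equal(m$r_inf, 0.8)
  expect_equal(predict_ratio(m, c(0, 30, 120)), rep(0.8, 3))
})

test_that("ratio fit recovers generating parameters from noiseless protocol samples", {
  ds <- make_blood()
  expect_length(ds$manual_times_min, 7)
  expect_equal(ds$manual_times_min, seven_times)
  m <- fit_wb_plasma_ratio(ds)
  expect_equal(m$r0, 0.9, tolerance = 1e-4)
  expect_equal(m$r_inf, 0.6, tolerance = 1e-4)
  expect_equal(m$k_r, 0.1, tolerance = 1e-4)
})

test_that("ratio fit validates its inputs", {
  ds2 <- blood_dataset(numeric(0), numeric(0), c(2.5, 7), c(1, 1),
                       c(2, 2), c(0.9, 0.8))
  expect_error(fit_wb_plasma_ratio(ds2), "under-determined")
  expect_error(blood_dataset(numeric(0), numeric(0), seven_times,
                             rep(1, 7), rep(-1, 7), rep(0.5, 7)),
               "non-negative")
  ds0 <- blood_dataset(numeric(0), numeric(0), seven_times,
                       rep(1, 7), rep(0, 7), rep(0.5, 7))
  expect_error(fit_wb_plasma_ratio(ds0), "positive plasma")
})

test_that("Hill fit recovers generating parameters and keeps PF(0) = 1", {
  ds <- make_blood()
  m <- fit_parent_fraction(ds)
  expect_equal(m$p_inf, 0.2, tolerance = 1e-3)
  expect_equal(m$h, 2, tolerance = 1e-3)
  expect_equal(m$t50, 20, tolerance = 1e-3)
  expect_equal(predict_parent_fraction(m, 0), 1)
  # Monotone non-increasing on a 1-min grid for any admissible parameters.
  set.seed(3)
  for (i in 1:20) {
    mm <- parent_fraction_model(runif(1, 0, 0.9), runif(1, 0.3, 5),
                                runif(1, 1, 80))
    pf <- predict_parent_fraction(mm, 0:120)
    expect_true(all(diff(pf) <= 1e-12))
    expect_gte(min(pf), mm$p_inf - 1e-12)
  }
})

test_that("plasma curve composition applies ratio and parent-fraction corrections", {
  # Identity corrections pass raw samples through.
  ds <- make_blood()
  ratio1 <- wb_plasma_ratio_model(1, 1, 0)
  pf1 <- parent_fraction_model(1 - 1e-12, 1, 1)
  cv <- build_plasma_curve(ds, ratio1, pf1)
  raw <- c(ds$auto_wb_activity[!(ds$auto_times_s / 60) %in% ds$manual_times_min],
           ds$manual_plasma_activity)
  expect_equal(sort(cv$activity), sort(raw), tolerance = 1e-9)
  expect_true(all(diff(cv$time_min) > 0))

  # Stated arithmetic: wb 10 at 2 min, ratio 0.8, PF 0.95 -> 11.875.
  ds2 <- blood_dataset(120, 10, seven_times,
                       rep(1, 7), rep(2, 7), rep(0.5, 7))
  ratio_c <- wb_plasma_ratio_model(0.8, 0.8, 0)
  pf_c <- parent_fraction_model(0.95, 1, 1e-6)  # PF ~ 0.95 for t >> t50
  cv2 <- build_plasma_curve(ds2, ratio_c, pf_c)
  expect_equal(cv2$activity[cv2$time_min == 2], 10 / 0.8 * 0.95,
               tolerance = 1e-6)
})

test_that("noiseless simulated blood reproduces the true corrected plasma", {
  bt <- default_blood_truth()
  ds <- make_blood()
  r <- fit_wb_plasma_ratio(ds)
  pf <- fit_parent_fraction(ds)
  cv <- build_plasma_curve(ds, r, pf)
  expect_equal(cv$activity, evaluate_input(bt$input, cv$time_min),
               tolerance = 1e-9)
})

test_that("curve building warns without automated samples and proceeds", {
  ds <- blood_dataset(numeric(0), numeric(0), seven_times,
                      seq(70, 10, length.out = 7), seq(100, 20, length.out = 7),
                      seq(0.95, 0.3, length.out = 7))
  r <- wb_plasma_ratio_model(0.8, 0.7, 0.1)
  pf <- parent_fraction_model(0.2, 2, 20)
  expect_warning(cv <- build_plasma_curve(ds, r, pf), "manual draws only")
  expect_equal(nrow(cv), 7)
})

test_that("tri-exponential input fit is continuous, exact on noiseless data, and deterministic", {
  truth <- fixture_input()
  t <- sort(unique(c(seq(0, 1, by = 0.1), seq(1, 120, by = 0.5))))
  curve <- data.frame(time_min = t, activity = evaluate_input(truth, t))
  fit <- fit_input_model(curve, seed = 42)
  expect_equal(evaluate_input(fit, fit$t_peak), fit$c_peak, tolerance = 1e-12)
  expect_equal(sum(fit$A), fit$c_peak, tolerance = 1e-10)
  expect_lt(attr(fit, "rss"), 1e-6)
  # Analytic integral: c_peak*t_peak/2 + sum A_i (1 - exp(-119 lambda_i))/lambda_i.
  exact <- 100 * 1 / 2 + sum(c(60, 30, 10) * (1 - exp(-c(3, 0.4, 0.02) * 119)) /
                               c(3, 0.4, 0.02))
  expect_equal(integrate_input(fit, 120), exact, tolerance = 1e-6)
  fit2 <- fit_input_model(curve, seed = 42)
  expect_identical(fit$A, fit2$A)
  expect_identical(fit$lambda, fit2$lambda)
})

test_that("degenerate and short curves are rejected or downgraded", {
  flat <- data.frame(time_min = 0:10, activity = rep(5, 11))
  expect_error(fit_input_model(flat), "unique peak")
  expect_error(fit_input_model(data.frame(time_min = 0:5,
                                          activity = c(0, 1, 2, 1.5, 1, 0.5))),
               ">= 8 points")
  # Few post-peak points: bi-exponential fallback flagged.
  tr <- fixture_input()
  t <- c(0.2, 0.5, 0.8, 1, 5, 30, 60, 120)
  curve <- data.frame(time_min = t, activity = evaluate_input(tr, t))
  fit <- fit_input_model(curve, seed = 42)
  expect_true(attr(fit, "fallback_2exp"))
  expect_length(fit$A, 2)
  expect_equal(sum(fit$A), fit$c_peak, tolerance = 1e-10)
})

test_that("input evaluation follows the piecewise definition", {
  m <- input_function_model(2, 80, c(50, 20, 10), c(2, 0.3, 0.01))
  expect_equal(evaluate_input(m, 0), 0)
  expect_equal(evaluate_input(m, 1), 40)  # half-way up the rise
  m1 <- input_function_model(1, 50, c(50, 0, 0), c(2, 0.3, 0.01))
  expect_equal(evaluate_input(m1, 1 + 1 / 2), 50 / exp(1), tolerance = 1e-12)
  expect_error(evaluate_input(m, -1), ">= 0")
})

test_that("plasma curve construction is invariant to input row order", {
  bt <- default_blood_truth()
  ds <- make_blood(noise_cv = 0.05, seed = 4)
  r <- fit_wb_plasma_ratio(ds)
  pf <- fit_parent_fraction(ds)
  cv1 <- build_plasma_curve(ds, r, pf)
  # Rebuild the dataset with permuted construction order via CSV round trip.
  tmp <- tempfile(fileext = ".csv")
  write_blood_csv(ds, tmp)
  df <- utils::read.csv(tmp)
  df <- df[rev(seq_len(nrow(df))), ]
  utils::write.csv(df, tmp, row.names = FALSE)
  ds2 <- read_blood_csv(tmp)
  cv2 <- build_plasma_curve(ds2, r, pf)
  expect_equal(cv1$time_min, cv2$time_min)
  expect_equal(cv1$activity, cv2$activity)
})

test_that("full input chain round-trips the generator within 1e-3 relative", {
  ch <- fit_input_chain(make_blood(), seed = 42)
  expect_equal(ch$ratio$r0, 0.9, tolerance = 1e-3)
  expect_equal(ch$ratio$r_inf, 0.6, tolerance = 1e-3)
  expect_equal(ch$parent_fraction$t50, 20, tolerance = 1e-3 * 20)
  expect_equal(ch$input$A, c(60, 30, 10), tolerance = 1e-3 * 60)
  expect_equal(ch$input$lambda, c(3, 0.4, 0.02), tolerance = 1e-3 * 3)
  # Correct-after mode fits total plasma (outside the tri-exponential
  # family) before the metabolite correction, so the two orderings agree on
  # the overall scale but not point-by-point.
  ch2 <- fit_input_chain(make_blood(), correct_first = FALSE, seed = 42)
  expect_s3_class(ch2$input, "input_function_model")
  expect_equal(sum(ch2$input$A), ch2$input$c_peak, tolerance = 1e-8)
  expect_equal(integrate_input(ch2$input, 120), integrate_input(ch$input, 120),
               tolerance = 0.15)
  t <- seq(1, 120, by = 1)
  expect_gt(max(abs(evaluate_input(ch2$input, t) - evaluate_input(ch$input, t))),
            0)
})

test_that("fitted component models survive JSON serialization", {
  ch <- fit_input_chain(make_blood(), seed = 42)
  path <- tempfile(fileext = ".json")
  write_input_models_json(list(ratio = ch$ratio,
                               parent_fraction = ch$parent_fraction,
                               input = ch$input), path)
  back <- read_input_models_json(path)
  expect_equal(back$ratio$r0, ch$ratio$r0)
  expect_equal(back$parent_fraction$t50, ch$parent_fraction$t50)
  expect_equal(back$input$A, ch$input$A)
})
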