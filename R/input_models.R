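#' Arterial blood dataset
#'
#' Container for one subject's arterial blood data: a dense automated
#' whole-blood curve covering the early scan (typically the first 6 minutes,
#' sampled at 1 Hz) and a small set of discrete manual arterial draws (the
#' sampling protocol uses seven, at 2.5, 7, 15, 30, 60, 90 and 120 min) with
#' whole-blood activity, plasma activity and the parent (unmetabolized)
#' fraction measured by HPLC.
#'
#' @param auto_times_s Automated sample times, seconds post injection.
#' @param auto_wb_activity Automated whole-blood activity, kBq/mL.
#' @param manual_times_min Manual draw times, minutes post injection.
#' @param manual_wb_activity,manual_plasma_activity Whole-blood and plasma
#'   activity of the manual draws, kBq/mL.
#' @param manual_parent_fraction Parent fraction of the manual draws, in
#'   `[0, 1]`.
#' @return An object of class `blood_dataset`.
#' @export
blood_dataset <- function(auto_times_s, auto_wb_activity,
                          manual_times_min, manual_wb_activity,
                          manual_plasma_activity, manual_parent_fraction) {
  auto_times_s <- as.numeric(auto_times_s)
  auto_wb_activity <- as.numeric(auto_wb_activity)
  if (length(auto_times_s) != length(auto_wb_activity)) {
    stopf("automated times and activities differ in length")
  }
  if (length(auto_times_s) > 1 && any(diff(auto_times_s) <= 0)) {
    stopf("automated sample times must be strictly increasing")
  }
  m <- length(manual_times_min)
  if (length(manual_wb_activity) != m || length(manual_plasma_activity) != m ||
      length(manual_parent_fraction) != m) {
    stopf("manual sample vectors differ in length")
  }
  if (m > 1 && any(diff(manual_times_min) <= 0)) {
    stopf("manual sample times must be strictly increasing")
  }
  if (any(c(auto_wb_activity, manual_wb_activity, manual_plasma_activity) < 0)) {
    stopf("activities must be non-negative")
  }
  if (any(manual_parent_fraction < 0 | manual_parent_fraction > 1)) {
    stopf("parent fractions must lie in [0, 1]")
  }
  structure(list(
    auto_times_s = auto_times_s,
    auto_wb_activity = auto_wb_activity,
    manual_times_min = as.numeric(manual_times_min),
    manual_wb_activity = as.numeric(manual_wb_activity),
    manual_plasma_activity = as.numeric(manual_plasma_activity),
    manual_parent_fraction = as.numeric(manual_parent_fraction)
  ), class = "blood_dataset")
}

#' Whole-blood-to-plasma ratio model
#'
#' Mono-exponential approach to an asymptote:
#' `ratio(t) = r_inf + (r0 - r_inf) * exp(-k_r * t)`, with `t` in minutes.
#' Used to convert the early automated whole-blood samples to plasma before
#' concatenation with the manual plasma draws.
#'
#' @param r0 Ratio at t = 0 (unitless, > 0).
#' @param r_inf Asymptotic ratio (unitless, > 0).
#' @param k_r Rate of approach, 1/min (>= 0).
#' @export
wb_plasma_ratio_model <- function(r0, r_inf, k_r) {
  assert_positive(r0, "r0"); assert_positive(r_inf, "r_inf")
  if (!is.finite(k_r) || k_r < 0) stopf("'k_r' must be finite and >= 0")
  structure(list(r0 = r0, r_inf = r_inf, k_r = k_r),
            class = "wb_plasma_ratio_model")
}

#' @rdname wb_plasma_ratio_model
#' @param model A `wb_plasma_ratio_model`.
#' @param times_min Times in minutes (>= 0).
#' @export
predict_ratio <- function(model, times_min) {
  model$r_inf + (model$r0 - model$r_inf) * exp(-model$k_r * times_min)
}

#' Hill-type parent fraction model
#'
#' Fraction of plasma radioactivity that is unmetabolized parent tracer,
#' modelled as `PF(t) = 1 - (1 - p_inf) * t^h / (t^h + t50^h)` with `t` in
#' minutes. The form enforces `PF(0) = 1` and monotone decay towards the
#' asymptote `p_inf`.
#'
#' @param p_inf Asymptotic parent fraction, in `[0, 1)`.
#' @param h Hill exponent (> 0, unitless).
#' @param t50 Time at which half the asymptotic metabolite loss has occurred,
#'   minutes (> 0).
#' @export
parent_fraction_model <- function(p_inf, h, t50) {
  if (!is.finite(p_inf) || p_inf < 0 || p_inf >= 1) stopf("'p_inf' must lie in [0, 1)")
  assert_positive(h, "h"); assert_positive(t50, "t50")
  structure(list(p_inf = p_inf, h = h, t50 = t50),
            class = "parent_fraction_model")
}

#' @rdname parent_fraction_model
#' @param model A `parent_fraction_model`.
#' @param times_min Times in minutes (>= 0).
#' @export
predict_parent_fraction <- function(model, times_min) {
  th <- times_min^model$h
  1 - (1 - model$p_inf) * th / (th + model$t50^model$h)
}

#' Parametric plasma input-function model
#'
#' Metabolite-corrected arterial plasma concentration modelled as a straight
#' line from time zero to the peak followed by the sum of three exponentials:
#' `C(t) = c_peak * t / t_peak` for `0 <= t <= t_peak` and
#' `C(t) = sum_i A_i * exp(-lambda_i * (t - t_peak))` for `t > t_peak`.
#' Continuity at the peak requires `sum(A) = c_peak`; the decay rates are
#' stored in decreasing order.
#'
#' @param t_peak Peak time, minutes (> 0).
#' @param c_peak Peak activity, kBq/mL (> 0).
#' @param A Amplitudes `A1, A2, A3` (kBq/mL) summing to `c_peak`. Two
#'   amplitudes are accepted for the bi-exponential fallback fit.
#' @param lambda Decay rates (1/min, > 0), same length as `A`.
#' @export
input_function_model <- function(t_peak, c_peak, A, lambda) {
  assert_positive(t_peak, "t_peak"); assert_positive(c_peak, "c_peak")
  if (length(A) != length(lambda) || !length(A) %in% c(2L, 3L)) {
    stopf("'A' and 'lambda' must both have length 2 or 3")
  }
  assert_positive(lambda, "lambda")
  if (abs(sum(A) - c_peak) > 1e-8 * max(1, c_peak)) {
    stopf("continuity requires sum(A) == c_peak (got %g vs %g)", sum(A), c_peak)
  }
  ord <- order(lambda, decreasing = TRUE)
  structure(list(t_peak = t_peak, c_peak = c_peak,
                 A = as.numeric(A[ord]), lambda = as.numeric(lambda[ord])),
            class = "input_function_model")
}

#' Evaluate a plasma input-function model
#'
#' @param model An `input_function_model`.
#' @param times_min Times in minutes (>= 0); vectorized.
#' @return Activities in kBq/mL; `C(0) = 0`.
#' @examples
#' m <- input_function_model(1, 100, c(60, 30, 10), c(3, 0.4, 0.02))
#' evaluate_input(m, c(0, 0.5, 1))  # 0, 50, 100
#' @export
evaluate_input <- function(model, times_min) {
  if (any(times_min < 0)) stopf("times must be >= 0")
  out <- numeric(length(times_min))
  rise <- times_min <= model$t_peak
  out[rise] <- model$c_peak * times_min[rise] / model$t_peak
  if (any(!rise)) {
    tau <- times_min[!rise] - model$t_peak
    out[!rise] <- colSums(model$A * exp(-outer(model$lambda, tau)))
  }
  out
}

#' Analytic time integral of a plasma input-function model
#'
#' Integral of the piecewise model from 0 to `t_end_min`: the triangular rise
#' plus the exact exponential tail integrals.
#'
#' @param model An `input_function_model`.
#' @param t_end_min Upper integration limit, minutes (>= t_peak).
#' @export
integrate_input <- function(model, t_end_min) {
  if (t_end_min < model$t_peak) {
    return(model$c_peak / model$t_peak * t_end_min^2 / 2)
  }
  tau <- t_end_min - model$t_peak
  model$c_peak * model$t_peak / 2 +
    sum(model$A * (1 - exp(-model$lambda * tau)) / model$lambda)
}

# Serialization: fitted blood-component models to/from JSON with explicit
# parameter names and units.

#' Serialize fitted input-function component models to JSON
#'
#' @param models Named list of fitted models (any of `ratio`, `parent_fraction`,
#'   `input`).
#' @param path Output JSON path.
#' @export
write_input_models_json <- function(models, path) {
  ser <- list()
  if (!is.null(models$ratio)) {
    m <- models$ratio
    ser$wb_plasma_ratio <- list(r0 = m$r0, r_inf = m$r_inf, k_r_per_min = m$k_r)
  }
  if (!is.null(models$parent_fraction)) {
    m <- models$parent_fraction
    ser$parent_fraction_hill <- list(p_inf = m$p_inf, hill_exponent = m$h,
                                     t50_min = m$t50)
  }
  if (!is.null(models$input)) {
    m <- models$input
    ser$plasma_input <- list(t_peak_min = m$t_peak, c_peak_kBq_mL = m$c_peak,
                             A_kBq_mL = m$A, lambda_per_min = m$lambda)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_input_models_json
#' @export
read_input_models_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(ser$wb_plasma_ratio)) {
    s <- ser$wb_plasma_ratio
    out$ratio <- wb_plasma_ratio_model(s$r0, s$r_inf, s$k_r_per_min)
  }
  if (!is.null(ser$parent_fraction_hill)) {
    s <- ser$parent_fraction_hill
    out$parent_fraction <- parent_fraction_model(s$p_inf, s$hill_exponent, s$t50_min)
  }
  if (!is.null(ser$plasma_input)) {
    s <- ser$plasma_input
    out$input <- input_function_model(s$t_peak_min, s$c_peak_kBq_mL,
                                      s$A_kBq_mL, s$lambda_per_min)
  }
  out
}
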