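#' Fit the whole-blood-to-plasma ratio model
#'
#' Least-squares fit of `ratio(t) = r_inf + (r0 - r_inf) * exp(-k_r * t)` to
#' the manual whole-blood / plasma activity ratios.
#'
#' @param dataset A [blood_dataset()].
#' @return A `wb_plasma_ratio_model` with attributes `rss` and `residuals`.
#' @export
fit_wb_plasma_ratio <- function(dataset) {
  t <- dataset$manual_times_min
  if (length(t) < 3) stopf("ratio fit is under-determined: need >= 3 manual samples")
  if (any(dataset$manual_plasma_activity <= 0)) {
    stopf("ratio fit requires strictly positive plasma activities")
  }
  ratio <- dataset$manual_wb_activity / dataset$manual_plasma_activity

  # Constant data has no identifiable rate: return the flat model directly.
  if (diff(range(ratio)) < 1e-12 * max(abs(ratio), 1)) {
    m <- wb_plasma_ratio_model(ratio[1], ratio[1], 0)
    attr(m, "rss") <- 0
    attr(m, "residuals") <- rep(0, length(ratio))
    return(m)
  }

  resid_fn <- function(p) {
    p["r_inf"] + (p["r0"] - p["r_inf"]) * exp(-p["k_r"] * t) - ratio
  }
  start <- c(r0 = ratio[1], r_inf = ratio[length(ratio)], k_r = 0.1)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1e-8, 1e-8, 0), upper = c(Inf, Inf, Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                 ftol = 1e-14,
                                                                 ptol = 1e-14))
  p <- coef(fit)
  m <- wb_plasma_ratio_model(p[["r0"]], p[["r_inf"]], p[["k_r"]])
  attr(m, "rss") <- sum(resid_fn(p)^2)
  attr(m, "residuals") <- resid_fn(p)
  m
}

#' Fit the Hill parent-fraction model
#'
#' Bounded least-squares fit of
#' `PF(t) = 1 - (1 - p_inf) * t^h / (t^h + t50^h)` to the manual
#' parent-fraction measurements.
#'
#' @param dataset A [blood_dataset()].
#' @return A `parent_fraction_model` with attribute `rss`.
#' @export
fit_parent_fraction <- function(dataset) {
  t <- dataset$manual_times_min
  pf <- dataset$manual_parent_fraction
  if (length(t) < 3) stopf("parent-fraction fit needs >= 3 manual samples")
  if (any(pf < 0 | pf > 1)) stopf("parent fractions must lie in [0, 1]")

  resid_fn <- function(p) {
    th <- t^p[["h"]]
    1 - (1 - p[["p_inf"]]) * th / (th + p[["t50"]]^p[["h"]]) - pf
  }
  # Multi-start over a small deterministic grid: the Hill surface has flat
  # valleys when the data barely curve.
  starts <- expand.grid(p_inf = c(0.05, 0.2, 0.5), h = c(1, 2, 4),
                        t50 = c(5, 20, 60))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(starts[i, ]), fn = resid_fn,
                         lower = c(0, 1e-6, 1e-6),
                         upper = c(1 - 1e-9, 50, 1e4),
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(coef(fit))^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stopf("parent-fraction fit failed from all starts")
  p <- coef(best$fit)
  m <- parent_fraction_model(p[["p_inf"]], p[["h"]], p[["t50"]])
  attr(m, "rss") <- best$rss
  m
}

#' Build the metabolite-corrected plasma curve
#'
#' Converts the automated early whole-blood samples to plasma using the
#' fitted whole-blood-to-plasma ratio, concatenates them with the manual
#' plasma draws (manual draws take precedence where the series overlap in
#' time), and multiplies every point by the fitted parent fraction to obtain
#' the metabolite-corrected plasma activity.
#'
#' @param dataset A [blood_dataset()].
#' @param ratio A fitted `wb_plasma_ratio_model`.
#' @param pf A fitted `parent_fraction_model`.
#' @param correct_first If `TRUE` (default) the parent-fraction correction is
#'   applied to the sampled curve before any downstream input-function fit;
#'   if `FALSE` the returned curve is total plasma and the correction is left
#'   to the caller.
#' @return A data frame with columns `time_min`, `activity` (kBq/mL) and
#'   `source` (`"auto"`/`"manual"`), sorted with strictly increasing times.
#' @export
build_plasma_curve <- function(dataset, ratio, pf, correct_first = TRUE) {
  has_auto <- length(dataset$auto_times_s) > 0
  if (!has_auto) {
    warning("no automated samples: building plasma curve from manual draws only",
            call. = FALSE)
  }
  auto_min <- dataset$auto_times_s / 60
  if (has_auto) {
    auto_plasma <- dataset$auto_wb_activity / predict_ratio(ratio, auto_min)
  } else {
    auto_plasma <- numeric(0)
  }
  # Manual precedence: drop automated points colliding with a manual draw
  # time (within half the nominal 1 s automated sampling interval).
  if (has_auto && length(dataset$manual_times_min)) {
    collide <- vapply(auto_min, function(tm) {
      any(abs(tm - dataset$manual_times_min) < 0.5 / 60)
    }, logical(1))
    auto_min <- auto_min[!collide]
    auto_plasma <- auto_plasma[!collide]
  }
  df <- rbind(
    data.frame(time_min = auto_min, activity = auto_plasma,
               source = rep("auto", length(auto_min))),
    data.frame(time_min = dataset$manual_times_min,
               activity = dataset$manual_plasma_activity,
               source = rep("manual", length(dataset$manual_times_min)))
  )
  df <- df[order(df$time_min), , drop = FALSE]
  df <- df[!duplicated(df$time_min), , drop = FALSE]
  if (correct_first) {
    df$activity <- df$activity * predict_parent_fraction(pf, df$time_min)
  }
  rownames(df) <- NULL
  df
}

#' Fit the linear-rise plus tri-exponential input-function model
#'
#' The peak is placed at the empirical maximum of the sampled curve; the
#' post-peak points are then fitted by least squares to a sum of three
#' exponentials under the continuity constraint `sum(A) = c_peak`, using
#' Levenberg-Marquardt from multiple deterministic random starts. If fewer
#' post-peak points than free parameters are available the fit falls back to
#' a bi-exponential model (flagged in the result).
#'
#' @param curve Data frame with columns `time_min` and `activity` (e.g. from
#'   [build_plasma_curve()]).
#' @param n_starts Number of random multi-starts (default 10).
#' @param seed Seed for the multi-start draws (default 42); the fit is
#'   deterministic given this seed.
#' @param weights Optional per-point weights for the post-peak fit (default
#'   unweighted).
#' @return An `input_function_model` with attributes `rss`, `n_exp` and
#'   `fallback_2exp`.
#' @export
fit_input_model <- function(curve, n_starts = 10, seed = 42, weights = NULL) {
  t <- curve$time_min
  y <- curve$activity
  if (any(!is.finite(t)) || any(!is.finite(y))) stopf("non-finite values in plasma curve")
  if (length(t) < 8) stopf("input-function fit needs >= 8 points")
  imax <- which(y == max(y))
  if (length(imax) != 1) stopf("no unique peak in the plasma curve")
  t_peak <- t[imax]
  c_peak <- y[imax]
  if (t_peak <= 0 || c_peak <= 0) stopf("degenerate peak at t=%g, C=%g", t_peak, c_peak)

  post <- t > t_peak
  tp <- t[post] - t_peak
  yp <- y[post]
  w <- if (is.null(weights)) rep(1, sum(post)) else weights[post]
  sw <- sqrt(w)

  n_exp <- if (sum(post) >= 5) 3L else 2L
  if (sum(post) < 3) stopf("too few post-peak points (%d) for an exponential fit", sum(post))
  fallback <- n_exp == 2L

  # Parameters: free amplitudes A[1..n_exp-1] and log decay rates; the last
  # amplitude absorbs the continuity constraint.
  resid_fn <- function(p) {
    k <- n_exp
    A <- p[seq_len(k - 1)]
    A <- c(A, c_peak - sum(A))
    lam <- exp(p[k:(2 * k - 1)])
    pred <- colSums(A * exp(-outer(lam, tp)))
    sw * (pred - yp)
  }

  t_span <- max(tp)
  fit_one <- function(start) {
    tryCatch({
      fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
      list(par = coef(fit), rss = sum(resid_fn(coef(fit))^2))
    }, error = function(e) NULL)
  }

  best <- with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      if (s == 1) {
        # Heuristic start: amplitudes split geometrically, rates spread over
        # the sampled decades.
        fr <- if (n_exp == 3L) c(0.6, 0.3) else 0.7
        lam0 <- log(c(5, 0.5, 0.02)[seq_len(n_exp)] / max(1e-3, t_span / 119))
        start <- c(c_peak * fr, lam0)
      } else {
        fr <- runif(n_exp - 1, 0.05, 0.8)
        start <- c(c_peak * fr,
                   log(sort(exp(runif(n_exp, log(0.3 / t_span), log(20 / t_span))),
                            decreasing = TRUE)))
      }
      res <- fit_one(start)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
    best
  })
  if (is.null(best)) stopf("input-function fit failed from all starts")

  k <- n_exp
  A <- best$par[seq_len(k - 1)]
  A <- c(A, c_peak - sum(A))
  lam <- exp(best$par[k:(2 * k - 1)])
  m <- input_function_model(t_peak, c_peak, A, lam)
  attr(m, "rss") <- best$rss
  attr(m, "n_exp") <- n_exp
  attr(m, "fallback_2exp") <- fallback
  m
}

#' Whole-blood activity curve interpolator
#'
#' Builds a continuous whole-blood activity function from the automated early
#' samples and the manual whole-blood draws: linear interpolation over the
#' automated segment, log-linear interpolation between manual draws beyond
#' it, and log-linear extrapolation of the final segment.
#'
#' @param dataset A [blood_dataset()].
#' @return A function of time in minutes returning whole-blood activity in
#'   kBq/mL.
#' @export
make_wb_curve <- function(dataset) {
  t_all <- c(dataset$auto_times_s / 60, dataset$manual_times_min)
  y_all <- c(dataset$auto_wb_activity, dataset$manual_wb_activity)
  keep <- !duplicated(t_all)
  ord <- order(t_all[keep])
  t_all <- t_all[keep][ord]
  y_all <- pmax(y_all[keep][ord], 1e-12)
  t_auto_end <- if (length(dataset$auto_times_s)) max(dataset$auto_times_s) / 60 else 0
  ly <- log(y_all)
  function(times_min) {
    out <- numeric(length(times_min))
    early <- times_min <= t_auto_end
    if (any(early)) {
      out[early] <- approx(t_all, y_all, xout = times_min[early], rule = 2)$y
    }
    if (any(!early)) {
      out[!early] <- exp(approx(t_all, ly, xout = pmin(times_min[!early], max(t_all)),
                                rule = 2)$y)
      beyond <- times_min > max(t_all)
      if (any(beyond)) {
        n <- length(t_all)
        slope <- (ly[n] - ly[n - 1]) / (t_all[n] - t_all[n - 1])
        out[beyond] <- exp(ly[n] + slope * (times_min[beyond] - t_all[n]))
      }
    }
    out
  }
}

#' Fit the full input-function chain for one subject
#'
#' Convenience wrapper running [fit_wb_plasma_ratio()], [fit_parent_fraction()],
#' [build_plasma_curve()] and [fit_input_model()] in sequence.
#'
#' @inheritParams fit_input_model
#' @param dataset A [blood_dataset()].
#' @param correct_first Apply the parent-fraction correction before the
#'   tri-exponential fit (default) or after.
#' @return A list with elements `ratio`, `parent_fraction`, `plasma_curve`,
#'   `input` and `wb_curve`.
#' @export
fit_input_chain <- function(dataset, correct_first = TRUE, n_starts = 10, seed = 42) {
  ratio <- fit_wb_plasma_ratio(dataset)
  pf <- fit_parent_fraction(dataset)
  curve <- build_plasma_curve(dataset, ratio, pf, correct_first = correct_first)
  input <- fit_input_model(curve, n_starts = n_starts, seed = seed)
  if (!correct_first) {
    # Correct-after mode: the tri-exponential above was fitted to total
    # plasma; apply the parent fraction to its dense prediction and project
    # the corrected curve back onto the parametric family.
    tgrid <- seq(0, max(curve$time_min), length.out = 400)
    corrected <- data.frame(
      time_min = tgrid,
      activity = evaluate_input(input, tgrid) * predict_parent_fraction(pf, tgrid))
    input <- fit_input_model(corrected, n_starts = n_starts, seed = seed)
  }
  list(ratio = ratio, parent_fraction = pf, plasma_curve = curve,
       input = input, wb_curve = make_wb_curve(dataset))
}
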