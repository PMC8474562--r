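# Shared fixtures and independent test oracles. Oracles here are written
# from first principles (direct enumeration, brute-force quadrature,
# derivative-free likelihood search) and never call the code paths they
# check.

fixture_input <- function() {
  input_function_model(t_peak = 1, c_peak = 100,
                       A = c(60, 30, 10), lambda = c(3, 0.4, 0.02))
}

make_noiseless_tac <- function(params, input, scheme = default_frame_scheme(),
                               wb_curve = NULL) {
  act <- frame_average(function(t) forward_2tc(params, input, wb_curve, t),
                       scheme)
  time_activity_curve("roi", scheme$frame_start_s, scheme$frame_dur_s, act)
}

# Random admissible 2TC microparameters (log-uniform inside the fit bounds,
# kept away from the edges).
random_2tc_draw <- function() {
  two_tc_params(exp(runif(1, log(0.01), log(1))),
                exp(runif(1, log(0.01), log(1))),
                exp(runif(1, log(0.005), log(0.5))),
                exp(runif(1, log(0.005), log(0.5))))
}

# Direct Benjamini-Hochberg step-up enumeration from the definition:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, restore
# input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force Gamma log-likelihood maximization over the coefficients with
# a derivative-free simplex search (the ML coefficients do not depend on
# the shape, which is held at 1).
gamma_ml_oracle <- function(y, X, start = NULL) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    if (any(eta > 50)) return(1e12)
    mu <- exp(eta)
    -sum(stats::dgamma(y, shape = 1, rate = 1 / mu, log = TRUE))
  }
  if (is.null(start)) start <- c(log(mean(y)), rep(0, ncol(X) - 1))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  fit$par
}

# Brute-force convolution of the 2TC impulse response with the parametric
# input by adaptive numerical quadrature (tissue term only, vB = 0).
brute_force_tissue <- function(params, input, t) {
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(s) {
      impulse_response_2tc(params, tt - s) * evaluate_input(input, s)
    }, 0, tt, rel.tol = 1e-10, subdivisions = 2000L)$value
  }, numeric(1))
}
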