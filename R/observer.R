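#' Observer model parameters
#'
#' The three observer models are one Kalman filter with different parameter
#' constraints. Measurement-noise variance is normalized to `r = 1`, because
#' only the ratios `v/r` and `q/r` are identifiable from response time
#' courses; the ratios are the free parameters.
#'
#' * `"static"`: stimuli are believed i.i.d. around a fixed mean;
#'   `q_over_r = 0`.
#' * `"iterative"`: stimuli are believed to follow a random walk;
#'   `v_over_r = 0`.
#' * `"two_state"`: stimuli are believed drawn around a drifting mean; both
#'   ratios free.
#'
#' @param model_kind `"static"`, `"iterative"` or `"two_state"`.
#' @param v_over_r Relative variability of the stimulus distribution
#'   (variance ratio, nonnegative).
#' @param q_over_r Relative variability of the additive change of the mean
#'   (variance ratio, nonnegative).
#' @param delta_x Log-domain shift applied at back-transform; accounts for
#'   global over- or underestimation.
#' @param d0 Positive linear-unit constant of the log transform; fixed, not
#'   fitted.
#'
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(model_kind = c("two_state", "static", "iterative"),
                            v_over_r = 1, q_over_r = 0, delta_x = 0, d0 = 1) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.numeric(v_over_r), is.numeric(q_over_r), is.numeric(delta_x),
            is.numeric(d0))
  if (v_over_r < 0 || q_over_r < 0) stop("variance ratios must be nonnegative")
  if (d0 <= 0) stop("d0 must be positive")
  if (model_kind == "static" && q_over_r != 0) {
    stop("static model requires q_over_r = 0")
  }
  if (model_kind == "iterative" && v_over_r != 0) {
    stop("iterative model requires v_over_r = 0")
  }
  structure(list(model_kind = model_kind, v_over_r = v_over_r,
                 q_over_r = q_over_r, delta_x = delta_x, d0 = d0),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> %s: v/r = %.4g, q/r = %.4g, dx = %.4g, d0 = %.4g\n",
              x$model_kind, x$v_over_r, x$q_over_r, x$delta_x, x$d0))
  invisible(x)
}

# free parameter names per model kind (fitting order)
free_param_names <- function(model_kind) {
  switch(model_kind,
         static = c("v_over_r", "delta_x"),
         iterative = c("q_over_r", "delta_x"),
         two_state = c("v_over_r", "q_over_r", "delta_x"),
         stop("unknown model kind"))
}

#' Logarithmic (Weber-Fechner) transform of a magnitude
#'
#' `z = log(1 + d / d0)`. Variability that grows with magnitude on the linear
#' scale becomes approximately constant on this scale.
#'
#' @param d Nonnegative magnitudes, linear units.
#' @param d0 Positive linear-unit constant.
#'
#' @return Log-domain values, strictly increasing in `d`, with `z = 0` at
#'   `d = 0`.
#' @export
log_transform <- function(d, d0 = 1) {
  if (d0 <= 0) stop("d0 must be positive")
  d <- as.numeric(d)
  if (anyNA(d) || any(d < 0)) stop("magnitudes must be nonnegative")
  log1p(d / d0)
}

#' Back-transform a log-domain estimate to a linear magnitude
#'
#' The default is the exact inverse of [log_transform()],
#' `d = d0 * (exp(x + delta_x) - 1)`, so that the composition with the
#' forward transform is the identity at `delta_x = 0`.
#' `paper_literal_inverse = TRUE` selects the convention
#' `d = d0 * exp(x + delta_x)`, which drops the `- 1`; the two agree for
#' magnitudes much larger than `d0`.
#'
#' @param x_hat Log-domain estimates.
#' @param d0 Positive linear-unit constant.
#' @param delta_x Log-domain shift.
#' @param paper_literal_inverse Use the approximate exponential convention.
#'
#' @return Linear magnitudes.
#' @export
back_transform <- function(x_hat, d0 = 1, delta_x = 0,
                           paper_literal_inverse = FALSE) {
  if (d0 <= 0) stop("d0 must be positive")
  if (paper_literal_inverse) d0 * exp(x_hat + delta_x)
  else d0 * expm1(x_hat + delta_x)
}

#' Static observer estimate
#'
#' The static model takes every stimulus as an independent draw from a fixed
#' distribution and returns the elementwise weighted average of the
#' measurement and the prior mean, `y_i = w * x_i + (1 - w) * prior_mean`.
#' Its central tendency is `1 - w`.
#'
#' @param x_seq Measurements (any consistent domain).
#' @param w Weight on the measurement, in `[0, 1]`.
#' @param prior_mean Prior mean, same domain as `x_seq`.
#'
#' @return Estimates, same length as `x_seq`; `y_i` depends only on `x_i`.
#' @export
static_estimate <- function(x_seq, w, prior_mean) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * as.numeric(x_seq) + (1 - w) * prior_mean
}

#' Simple iterative observer estimate (exponential smoothing)
#'
#' The steady state of the random-walk observer: `y_i = k * z_i +
#' (1 - k) * y_{i-1}`. With `k = 1` the response is veridical; with `k = 0`
#' it never departs from `y0`.
#'
#' @param z_seq Measurements.
#' @param k Gain in `[0, 1]`.
#' @param y0 Initial estimate (defaults to the first measurement).
#'
#' @return Estimates, same length as `z_seq`.
#' @export
iterative_estimate <- function(z_seq, k, y0 = z_seq[1]) {
  if (k < 0 || k > 1) stop("k must lie in [0, 1]")
  z_seq <- as.numeric(z_seq)
  y <- numeric(length(z_seq))
  prev <- y0
  for (i in seq_along(z_seq)) {
    prev <- k * z_seq[i] + (1 - k) * prev
    y[i] <- prev
  }
  y
}

# default diffuse initial covariance, scaled to the process variances
default_p0 <- function(v, q) 10 * (v + q + 1)

#' Two-state Kalman filter in log space
#'
#' Full time-varying Kalman recursion for the two-state generative model
#' (state = current stimulus and current distribution mean) with
#' `F = [[0, 1], [0, 1]]`, `H = [1, 0]`, `Q = diag(v, q)` and measurement
#' noise normalized to `r = 1`. Initialization is diffuse: both state
#' estimates start at the first measurement and the prior covariance is
#' `diag(10 * (v + q + 1))`, so the steady state dominates after a few
#' trials; the first filtered estimate is emitted at trial 1 after the first
#' update.
#'
#' @param z_seq Measurements in log units; must be finite.
#' @param params An [observer_params()]; the model kind's constraint
#'   (`q = 0` for static, `v = 0` for iterative) is applied.
#' @param init Optional list overriding the initialization, with elements
#'   `m0` (initial mean estimate) and `p0` (initial variance of the mean
#'   estimate, nonnegative).
#'
#' @return A list with per-trial vectors `x_hat`, `m_hat`, gains `k1`, `k2`,
#'   and the posterior covariance entries `p11`, `p12`, `p22`.
#' @export
kalman_filter_two_state <- function(z_seq, params, init = NULL) {
  stopifnot(inherits(params, "observer_params"))
  z_seq <- as.numeric(z_seq)
  if (length(z_seq) < 1L || anyNA(z_seq) || any(!is.finite(z_seq))) {
    stop("measurements must be finite and non-missing")
  }
  v <- if (params$model_kind == "iterative") 0 else params$v_over_r
  q <- if (params$model_kind == "static") 0 else params$q_over_r
  m0 <- if (!is.null(init$m0)) init$m0 else z_seq[1]
  p0 <- if (!is.null(init$p0)) init$p0 else default_p0(v, q)
  if (p0 < 0) stop("initial variance must be nonnegative")
  kalman_two_state_cpp(z_seq, v, q, m0, p0)
}

#' Steady-state Kalman gains of an observer model
#'
#' Iterates the covariance (Riccati) recursion of the two-state filter with a
#' constant input structure until the gains change by less than `tol`,
#' returning the fixed-point gains `(k1, k2)` on stimulus and mean.
#'
#' @param params An [observer_params()].
#' @param tol Convergence tolerance on the gain change per iteration.
#' @param max_iter Iteration cap; exceeding it raises an error (does not
#'   occur for valid parameters).
#'
#' @return Named numeric vector `c(k1, k2)` with `0 <= k2 <= k1 <= 1`, plus
#'   attribute `iterations`.
#' @export
steady_state_gains <- function(params, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(params, "observer_params"))
  v <- if (params$model_kind == "iterative") 0 else params$v_over_r
  q <- if (params$model_kind == "static") 0 else params$q_over_r
  if (q == 0) {
    # the covariance recursion contracts the mean-estimate variance to its
    # unique fixed point 0 only algebraically (~1/i), so return the exact
    # fixed-point gains for this boundary case
    k <- c(k1 = v / (v + 1), k2 = 0)
    attr(k, "iterations") <- 0L
    return(k)
  }
  a22 <- default_p0(v, q)
  k_prev <- c(Inf, Inf)
  for (i in seq_len(max_iter)) {
    b11 <- a22 + v
    b12 <- a22
    s <- b11 + 1
    k <- c(k1 = b11 / s, k2 = b12 / s)
    a22 <- (a22 + q) - k[[2]] * b12
    if (max(abs(k - k_prev)) < tol) {
      attr(k, "iterations") <- i
      return(k)
    }
    k_prev <- k
  }
  stop("steady-state gain iteration did not converge within max_iter")
}

#' Deterministic response time course of an observer model
#'
#' Composition of the log transform, the Kalman filter (with the model kind's
#' constraints) and the back-transform with shift `delta_x`. This is the
#' noise-free simulation used during fitting and prediction: the model
#' receives the stimuli in exactly the presented order.
#'
#' @param stimuli A [stimulus_sequence()] or numeric vector, linear units.
#' @param params An [observer_params()].
#' @param paper_literal_inverse Back-transform convention, see
#'   [back_transform()].
#'
#' @return Numeric vector of simulated responses, linear units.
#' @export
simulate_response_timecourse <- function(stimuli, params,
                                         paper_literal_inverse = FALSE) {
  d <- stim_values(stimuli)
  z <- log_transform(d, d0 = params$d0)
  filt <- kalman_filter_two_state(z, params)
  back_transform(filt$x_hat, d0 = params$d0, delta_x = params$delta_x,
                 paper_literal_inverse = paper_literal_inverse)
}

#' Simulate a noisy observer on a stimulus sequence
#'
#' Runs the deterministic model time course in log space and adds Gaussian
#' response noise of SD `response_noise_sd` in the log domain before
#' back-transforming, so responses inherit magnitude-proportional
#' variability.
#'
#' @param stimuli A [stimulus_sequence()] or numeric vector.
#' @param params An [observer_params()] describing the simulated observer.
#' @param response_noise_sd Log-domain response noise SD (log-units).
#' @param seed Optional integer seed.
#' @param subject_id,condition Labels for the returned [trial_sequence()].
#' @param paper_literal_inverse Back-transform convention.
#'
#' @return A [trial_sequence()] with the `truth` field set to `params`.
#' @export
simulate_observer <- function(stimuli, params, response_noise_sd = 0.1,
                              seed = NULL, subject_id = "sim",
                              condition = "sim",
                              paper_literal_inverse = FALSE) {
  stopifnot(inherits(params, "observer_params"), response_noise_sd >= 0)
  if (!inherits(stimuli, "stimulus_sequence")) {
    stimuli <- stimulus_sequence(stimuli)
  }
  z <- log_transform(stimuli$values, d0 = params$d0)
  filt <- kalman_filter_two_state(z, params)
  noise <- with_seed_(seed, rnorm(length(z), 0, response_noise_sd))
  responses <- back_transform(filt$x_hat + noise, d0 = params$d0,
                              delta_x = params$delta_x,
                              paper_literal_inverse = paper_literal_inverse)
  trial_sequence(subject_id, condition, stimuli, responses, truth = params)
}
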