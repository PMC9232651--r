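# Least-squares fitting of observer models in the linear stimulus domain,
# linearized confidence intervals, windowed LOO cross-validation and
# cross-condition prediction.

params_from_theta <- function(theta, model_kind, d0) {
  nm <- free_param_names(model_kind)
  th <- setNames(as.numeric(theta), nm)
  observer_params(model_kind,
                  v_over_r = if ("v_over_r" %in% nm) max(th[["v_over_r"]], 0) else 0,
                  q_over_r = if ("q_over_r" %in% nm) max(th[["q_over_r"]], 0) else 0,
                  delta_x = th[["delta_x"]],
                  d0 = d0)
}

# residual vector (response - simulation), optionally weighted by a 0/1 mask
fit_residuals <- function(theta, model_kind, stimuli, responses, d0, mask) {
  p <- params_from_theta(theta, model_kind, d0)
  r <- responses - simulate_response_timecourse(stimuli, p)
  if (!is.null(mask)) r * mask else r
}

# log-spaced multi-start grid over the variance ratios, delta_x = 0
start_grid <- function(model_kind, n_starts = 8L) {
  if (model_kind == "two_state") {
    g <- expand.grid(v = 10^seq(-2, 1, length.out = 4L),
                     q = 10^seq(-2, 1, length.out = 2L))
    lapply(seq_len(nrow(g)), function(i) c(g$v[i], g$q[i], 0))
  } else {
    lapply(10^seq(-2, 1, length.out = n_starts), function(v) c(v, 0))
  }
}

#' Fit an observer model to a trial sequence
#'
#' Minimizes the linear-domain sum of squared differences between the
#' observed responses and the model's deterministic response time course
#' (the model receives the stimuli in presented order) over the model kind's
#' free parameters, using Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) with nonnegativity bounds on the variance
#' ratios. To guard against local minima the optimizer is restarted from a
#' log-spaced grid over the variance ratios and the best solution is kept.
#'
#' @param trials A [trial_sequence()] (at least 10 trials).
#' @param model_kind `"static"`, `"iterative"` or `"two_state"`.
#' @param init Optional [observer_params()] used as an additional start.
#' @param d0 Log-transform constant (fixed, not fitted).
#' @param mask Optional 0/1 vector; residuals are multiplied by it, so
#'   trials with 0 are excluded from the loss while the simulation still
#'   runs the full stimulus sequence.
#' @param multi_start Use the multi-start grid (`FALSE` fits only from
#'   `init`).
#' @param ci Compute linearized 95% confidence intervals?
#' @param control Passed to [minpack.lm::nls.lm.control()].
#'
#' @return An object of class `observer_fit`: a list with `params`
#'   (fitted [observer_params()]), `theta` (free-parameter vector), `sse`,
#'   `simulated`, `n_trials`, `ci` (matrix or `NULL`), `model_kind`,
#'   `converged` and `info` (per-start diagnostics).
#' @export
fit_model <- function(trials, model_kind = c("two_state", "static",
                                             "iterative"),
                      init = NULL, d0 = 1, mask = NULL, multi_start = TRUE,
                      ci = TRUE,
                      control = minpack.lm::nls.lm.control(maxiter = 200)) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(trials, "trial_sequence"))
  stimuli <- trials$stimuli$values
  responses <- trials$responses
  n <- length(responses)
  if (n < 10) stop("need at least 10 trials to fit")
  if (!is.null(mask)) {
    stopifnot(length(mask) == n, all(mask %in% c(0, 1)))
  }
  nm <- free_param_names(model_kind)
  lower <- ifelse(nm == "delta_x", -Inf, 0)
  upper <- rep(Inf, length(nm))

  starts <- if (multi_start) start_grid(model_kind) else list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "observer_params"))
    th0 <- vapply(nm, function(p) init[[p]], numeric(1))
    starts <- c(list(unname(th0)), starts)
  }
  if (length(starts) == 0) stop("no starting values")

  best <- NULL
  diags <- list()
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = pmax(s, lower), lower = lower, upper = upper,
                         fn = fit_residuals, model_kind = model_kind,
                         stimuli = stimuli, responses = responses,
                         d0 = d0, mask = mask, control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      diags[[length(diags) + 1L]] <- conditionMessage(res)
      next
    }
    diags[[length(diags) + 1L]] <- res$message
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop("optimizer failed from every start: ",
         paste(unique(unlist(diags)), collapse = "; "))
  }
  theta <- setNames(as.numeric(best$par), nm)
  params <- params_from_theta(theta, model_kind, d0)
  simulated <- simulate_response_timecourse(stimuli, params)
  resid_full <- responses - simulated
  w <- if (is.null(mask)) rep(1, n) else mask
  fit <- structure(list(params = params, theta = theta,
                        sse = sum((resid_full * w)^2),
                        simulated = simulated, n_trials = n,
                        mask = mask, d0 = d0, ci = NULL,
                        model_kind = model_kind,
                        converged = best$info %in% 1:4,
                        info = unlist(diags)),
                   class = "observer_fit")
  if (ci) fit$ci <- parameter_confidence_intervals(fit, trials)
  fit
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("<observer_fit> %s model, %d trials, sse = %.6g\n",
              x$model_kind, x$n_trials, x$sse))
  est <- x$theta
  for (i in seq_along(est)) {
    ci <- if (!is.null(x$ci)) sprintf(" [%.4g, %.4g]", x$ci[i, 1], x$ci[i, 2])
          else ""
    cat(sprintf("  %s = %.4g%s\n", names(est)[i], est[i], ci))
  }
  invisible(x)
}

# numeric Jacobian of the residual vector wrt theta (central differences)
residual_jacobian <- function(theta, model_kind, stimuli, responses, d0,
                              mask) {
  p <- length(theta)
  J <- matrix(0, length(responses), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    up <- replace(theta, j, theta[j] + h)
    dn <- replace(theta, j, max(theta[j] - h,
                                if (names(theta)[j] == "delta_x") -Inf else 0))
    ru <- fit_residuals(up, model_kind, stimuli, responses, d0, mask)
    rd <- fit_residuals(dn, model_kind, stimuli, responses, d0, mask)
    J[, j] <- (ru - rd) / (up[j] - dn[j])
  }
  J
}

# linearized CIs from a Jacobian and residual vector (nlparci-style)
ci_from_jacobian <- function(J, residuals, level = 0.95) {
  n <- length(residuals)
  p <- ncol(J)
  df <- n - p
  if (df <= 0) stop("not enough residual degrees of freedom")
  sse <- sum(residuals^2)
  sigma2 <- sse / df
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
  se <- if (is.null(cov)) rep(Inf, p) else sqrt(pmax(diag(cov), 0))
  # singular directions get unbounded intervals
  if (!is.null(cov) && any(!is.finite(se))) se[!is.finite(se)] <- Inf
  tq <- qt(1 - (1 - level) / 2, df)
  cbind(lower = -tq * se, upper = tq * se)
}

#' Linearized confidence intervals for fitted observer parameters
#'
#' 95% (by default) intervals from the residual variance and the numeric
#' Jacobian of the residuals at the optimum, using the t distribution with
#' `n - p` degrees of freedom — the standard linearization used for
#' nonlinear least-squares fits. A singular Jacobian yields an unbounded
#' interval for the affected parameter.
#'
#' @param fit An `observer_fit` from [fit_model()].
#' @param trials The [trial_sequence()] that was fitted.
#' @param level Confidence level.
#'
#' @return Matrix with one row per free parameter and columns `lower`,
#'   `upper`, bracketing the point estimate.
#' @export
parameter_confidence_intervals <- function(fit, trials, level = 0.95) {
  stopifnot(inherits(fit, "observer_fit"), inherits(trials, "trial_sequence"))
  stimuli <- trials$stimuli$values
  responses <- trials$responses
  theta <- fit$theta
  J <- residual_jacobian(theta, fit$model_kind, stimuli, responses, fit$d0,
                         fit$mask)
  r <- fit_residuals(theta, fit$model_kind, stimuli, responses, fit$d0,
                     fit$mask)
  hw <- ci_from_jacobian(J, r, level)
  out <- cbind(lower = theta + hw[, "lower"], upper = theta + hw[, "upper"])
  rownames(out) <- names(theta)
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` against the mean-only baseline. A model that
#' reproduces the observations exactly scores 1, the baseline scores 0, and
#' models worse than the baseline score negative.
#'
#' @param observed,modeled Equal-length numeric vectors (length >= 2).
#'
#' @return Scalar R-squared.
#' @export
r_squared <- function(observed, modeled) {
  observed <- as.numeric(observed)
  modeled <- as.numeric(modeled)
  stopifnot(length(observed) == length(modeled), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop("zero total variance; R^2 undefined")
  1 - sum((observed - modeled)^2) / ss_tot
}

#' Windowed leave-one-out cross-validation for model selection
#'
#' Time-series LOO: for each validation center `t`, the `window_k` trials
#' centered on `t` (truncated at the sequence edges) are excluded from the
#' fitting loss, the model is refitted to the remaining responses (the
#' filter still consumes the full stimulus sequence, since the stimuli are
#' known to the observer; only held-out responses are masked from the
#' loss), and the squared prediction error at the center trial is recorded.
#' Every trial except trial 1 (which has no prediction history) serves as a
#' center. The model with the smallest mean validation error is chosen;
#' ties (relative difference below `1e-12`) go to the model with fewer free
#' parameters. `window_k = 1` is plain LOO.
#'
#' @param trials A [trial_sequence()].
#' @param model_kinds Character vector of models to compare.
#' @param window_k Odd window size; the sequence must be longer than
#'   `2 * window_k`.
#' @param d0 Log-transform constant.
#' @param control Optimizer control for the per-center refits.
#'
#' @return An object of class `model_selection`: list with `window_k`,
#'   `per_model_cv_error`, `chosen`, `full_fits` and `n_centers`.
#' @export
loo_timeseries <- function(trials,
                           model_kinds = c("static", "iterative",
                                           "two_state"),
                           window_k = 11L, d0 = 1,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 60)) {
  stopifnot(inherits(trials, "trial_sequence"))
  window_k <- as.integer(window_k)
  if (window_k < 1L || window_k %% 2L == 0L) stop("window_k must be odd")
  n <- length(trials$responses)
  if (n <= 2L * window_k) stop("sequence too short for this window_k")
  half <- (window_k - 1L) %/% 2L
  centers <- 2:n

  cv <- setNames(numeric(length(model_kinds)), model_kinds)
  full_fits <- list()
  for (mk in model_kinds) {
    full <- fit_model(trials, mk, d0 = d0, ci = FALSE)
    full_fits[[mk]] <- full
    errs <- vapply(centers, function(t) {
      mask <- rep(1, n)
      mask[max(1L, t - half):min(n, t + half)] <- 0
      refit <- fit_model(trials, mk, init = full$params, d0 = d0,
                         mask = mask, multi_start = FALSE, ci = FALSE,
                         control = control)
      (trials$responses[t] - refit$simulated[t])^2
    }, numeric(1))
    cv[mk] <- mean(errs)
  }
  n_free <- vapply(model_kinds, function(mk) length(free_param_names(mk)),
                   numeric(1))
  # ties at relative 1e-12 go to the simpler model
  best_err <- min(cv)
  tied <- cv <= best_err * (1 + 1e-12) + 1e-300
  chosen <- model_kinds[tied][which.min(n_free[tied])]
  structure(list(window_k = window_k, per_model_cv_error = cv,
                 chosen = chosen, full_fits = full_fits,
                 n_centers = length(centers)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> window k = %d, chosen: %s\n", x$window_k,
              x$chosen))
  print(round(x$per_model_cv_error, 6))
  invisible(x)
}

#' Predict a new condition from fitted parameters
#'
#' Zero-free-parameter simulation: runs the deterministic observer with the
#' given (previously fitted) parameters on a new stimulus sequence, e.g.
#' parameters fitted on a randomized session applied to the random-walk
#' session of the same values.
#'
#' @param params An [observer_params()] (typically `fit$params`).
#' @param new_trials A [trial_sequence()] providing the new stimulus order
#'   (its responses are only used for comparison by the caller).
#' @param max_lag Largest lag for the prediction's bias summary.
#'
#' @return List with `predicted` (numeric vector) and `metrics` (the
#'   [bias_summary()] of the predicted responses).
#' @export
predict_condition <- function(params, new_trials, max_lag = 3L) {
  stopifnot(inherits(params, "observer_params"),
            inherits(new_trials, "trial_sequence"))
  predicted <- simulate_response_timecourse(new_trials$stimuli, params)
  pred_trials <- trial_sequence(new_trials$subject_id,
                                paste0(new_trials$condition, "_predicted"),
                                new_trials$stimuli, predicted)
  list(predicted = predicted,
       metrics = bias_summary(pred_trials, max_lag = max_lag))
}

#' Binned average error across a cohort
#'
#' Bins each subject's reproduction errors by stimulus magnitude, averages
#' within subject per bin, then averages the subject means across subjects
#' and reports the between-subject SEM. Bins covered by a single subject
#' get an `NA` SEM and are flagged; empty bins are flagged, not dropped.
#'
#' @param cohort List of [trial_sequence()] objects (one per subject), or a
#'   single `trial_sequence`.
#' @param bin_edges Numeric vector of bin edges covering the stimulus
#'   range, or `NULL` to use `n_bins` equal-width bins over the pooled
#'   range.
#' @param n_bins Number of equal-width bins when `bin_edges` is `NULL`.
#' @param value `"error"` (response - stimulus) or `"response"`.
#'
#' @return Data frame with columns `bin`, `mid`, `n_subjects`, `mean`,
#'   `sem` and `flag` (`""`, `"empty"` or `"single_subject"`).
#' @export
binned_average <- function(cohort, bin_edges = NULL, n_bins = 10L,
                           value = c("error", "response")) {
  value <- match.arg(value)
  if (inherits(cohort, "trial_sequence")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1,
            all(vapply(cohort, inherits, logical(1), "trial_sequence")))
  all_x <- unlist(lapply(cohort, function(tr) tr$stimuli$values))
  if (is.null(bin_edges)) {
    bin_edges <- seq(min(all_x), max(all_x), length.out = n_bins + 1L)
  }
  bin_edges <- sort(as.numeric(bin_edges))
  if (min(all_x) < min(bin_edges) || max(all_x) > max(bin_edges)) {
    stop("bin_edges do not cover the stimulus range")
  }
  nb <- length(bin_edges) - 1L
  per_subject <- vapply(cohort, function(tr) {
    x <- tr$stimuli$values
    val <- if (value == "error") tr$responses - x else tr$responses
    idx <- findInterval(x, bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    vapply(seq_len(nb), function(b) {
      if (any(idx == b)) mean(val[idx == b]) else NA_real_
    }, numeric(1))
  }, numeric(nb))
  per_subject <- matrix(per_subject, nrow = nb)
  n_subj <- rowSums(!is.na(per_subject))
  mn <- ifelse(n_subj > 0, rowMeans(per_subject, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_len(nb), function(b) {
    v <- per_subject[b, !is.na(per_subject[b, ])]
    if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  flag <- ifelse(n_subj == 0, "empty",
                 ifelse(n_subj == 1, "single_subject", ""))
  data.frame(bin = seq_len(nb),
             mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
             n_subjects = n_subj, mean = mn, sem = sem, flag = flag,
             stringsAsFactors = FALSE)
}
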