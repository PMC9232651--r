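# Bias metrics are computed in the linear stimulus domain throughout, on
# response/stimulus pairs; reproduction error is response - stimulus.

# coerce trial_sequence / data.frame to (stimulus, response) vectors
trial_xy <- function(trials) {
  if (inherits(trials, "trial_sequence")) {
    list(x = trials$stimuli$values, y = trials$responses)
  } else if (is.data.frame(trials)) {
    if (!all(c("stimulus", "response") %in% names(trials))) {
      stop("data frame needs 'stimulus' and 'response' columns")
    }
    list(x = trials$stimulus, y = trials$response)
  } else {
    stop("trials must be a trial_sequence or a data frame")
  }
}

ols_slope <- function(y, x) {
  if (var(x) <= 0) stop("regressor has zero variance; slope undefined")
  fit <- lm(y ~ x)
  slope <- coef(fit)[["x"]]
  # summary.lm warns on exact fits; the SE (then 0) is still what we report
  se <- suppressWarnings(summary(fit)$coefficients["x", "Std. Error"])
  c(slope = slope, se = se)
}

#' Central tendency of reproduction
#'
#' One minus the ordinary least-squares slope of response on stimulus
#' (linear domain). Veridical reproduction gives 0; a constant response
#' gives 1.
#'
#' @param trials A [trial_sequence()] or data frame with `stimulus` and
#'   `response` columns.
#' @param se Also return the standard error of the underlying slope?
#'
#' @return Central tendency `c` (scalar), or `c(c, se)` when `se = TRUE`.
#' @export
central_tendency <- function(trials, se = FALSE) {
  d <- trial_xy(trials)
  if (length(d$x) < 3) stop("need at least 3 trials")
  s <- ols_slope(d$y, d$x)
  if (se) c(c = 1 - s[["slope"]], se = s[["se"]]) else 1 - s[["slope"]]
}

#' Sequential dependence of reproduction
#'
#' Slope of the current trial's reproduction error (response minus stimulus)
#' regressed on the previous trial's stimulus, using trials `2..n` (trial 1
#' has no predecessor).
#'
#' @inheritParams central_tendency
#'
#' @return Sequential dependence `s` (scalar), or `c(s, se)`.
#' @export
sequential_dependence <- function(trials, se = FALSE) {
  d <- trial_xy(trials)
  n <- length(d$x)
  if (n < 4) stop("need at least 4 trials")
  err <- (d$y - d$x)[-1]
  prev <- d$x[-n]
  if (all(err == 0)) {
    out <- c(slope = 0, se = 0)
  } else {
    out <- ols_slope(err, prev)
  }
  if (se) c(s = out[["slope"]], se = out[["se"]]) else out[["slope"]]
}

#' Sequential dependence predicted by the simple iterative model
#'
#' For randomly presented stimuli the simple iterative (exponential
#' smoothing) observer has the closed-form relation `s = (1 - c) * c`
#' between central tendency and sequential dependence: a parabola with
#' maximum 0.25 at `c = 0.5`.
#'
#' @param c Central tendency in `[0, 1]` (vectorized).
#'
#' @return Predicted sequential dependence.
#' @export
iterative_prediction_curve <- function(c) {
  if (any(c < 0 | c > 1)) stop("central tendency must lie in [0, 1]")
  (1 - c) * c
}

#' Partial correlation between reproduction error and a stimulus
#'
#' First-order partial correlation of the current error with either the
#' previous stimulus controlling for the current one (`target = "prev"`,
#' the serial-bias measure robust to stimulus autocorrelation) or the
#' current stimulus controlling for the previous one (`target = "curr"`,
#' which reveals the central tendency as a negative value). Computed by
#' correlating the residuals of the two control regressions.
#'
#' @inheritParams central_tendency
#' @param target `"prev"` or `"curr"`.
#'
#' @return Partial correlation coefficient in `[-1, 1]`.
#' @export
partial_correlation <- function(trials, target = c("prev", "curr")) {
  target <- match.arg(target)
  d <- trial_xy(trials)
  n <- length(d$x)
  if (n < 5) stop("need at least 5 trials")
  err <- (d$y - d$x)[-1]
  curr <- d$x[-1]
  prev <- d$x[-n]
  a <- if (target == "prev") prev else curr
  ctrl <- if (target == "prev") curr else prev
  if (var(a) <= 0 || var(ctrl) <= 0 || var(err) <= 0) {
    stop("degenerate (zero-variance) column in partial correlation")
  }
  cor(resid(lm(err ~ ctrl)), resid(lm(a ~ ctrl)))
}

# closed-form first-order partial correlation; independent oracle for tests
partial_cor_closed_form <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Lagged dependence of error on past stimuli
#'
#' For each lag `j = 1..max_lag`, the slope of the current error on the
#' stimulus `j` trials back (and the corresponding correlation). Lag 1
#' equals [sequential_dependence()].
#'
#' @inheritParams central_tendency
#' @param max_lag Largest lag; must be below a quarter of the sequence
#'   length.
#'
#' @return Data frame with columns `lag`, `slope`, `se`, `correlation`.
#' @export
lagged_dependence <- function(trials, max_lag = 3L) {
  d <- trial_xy(trials)
  n <- length(d$x)
  if (max_lag < 1 || max_lag >= n / 4) {
    stop("max_lag must be at least 1 and below n/4")
  }
  err <- d$y - d$x
  rows <- lapply(seq_len(max_lag), function(j) {
    e <- err[(j + 1):n]
    s <- d$x[1:(n - j)]
    sl <- ols_slope(e, s)
    data.frame(lag = j, slope = sl[["slope"]], se = sl[["se"]],
               correlation = if (var(e) > 0) cor(e, s) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-sequence bias summary
#'
#' Convenience wrapper computing all trial-level bias metrics for one
#' subject and condition.
#'
#' @inheritParams central_tendency
#' @param max_lag Largest lag for [lagged_dependence()].
#'
#' @return An object of class `bias_summary`: a list with `c`, `s`,
#'   `partial_r_prev`, `partial_r_curr` and `lag_slopes`.
#' @export
bias_summary <- function(trials, max_lag = 3L) {
  structure(list(c = central_tendency(trials),
                 s = sequential_dependence(trials),
                 partial_r_prev = partial_correlation(trials, "prev"),
                 partial_r_curr = partial_correlation(trials, "curr"),
                 lag_slopes = lagged_dependence(trials, max_lag)),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> c = %.3f, s = %.3f, partial r(prev) = %.3f, partial r(curr) = %.3f\n",
              x$c, x$s, x$partial_r_prev, x$partial_r_curr))
  invisible(x)
}

#' Group-level summary of a per-subject metric
#'
#' One-sample two-sided t-test of the per-subject values against a null
#' value, with Cohen's d = (mean - null) / sd.
#'
#' @param values Numeric vector of per-subject metric values, length >= 2.
#' @param null_value Null hypothesis value.
#'
#' @return A list with `mean`, `sd`, `n`, `t`, `df`, `p` and `cohens_d`.
#' @export
group_summary <- function(values, null_value = 0) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (sd(values) == 0) {
    if (all(values == null_value)) {
      return(list(mean = null_value, sd = 0, n = length(values), t = 0,
                  df = length(values) - 1, p = 1, cohens_d = 0))
    }
    stop("zero variance in values; t statistic undefined")
  }
  tt <- t.test(values, mu = null_value)
  list(mean = mean(values), sd = sd(values), n = length(values),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = (mean(values) - null_value) / sd(values))
}
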