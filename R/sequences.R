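#' Stimulus sequence
#'
#' An ordered series of positive stimulus magnitudes (linear units, e.g. ms,
#' metres or degrees) together with metadata about how it was generated.
#'
#' @param values Numeric vector of positive magnitudes.
#' @param generator_kind One of `"iid"`, `"random_walk"`, `"two_state"`,
#'   `"permuted"`.
#' @param bounds Optional length-2 numeric `(low, high)`; when set, every value
#'   must fall inside.
#' @param seed Integer seed used for generation, or `NULL`.
#' @param source_sequence_id Optional identifier of the source sequence when
#'   `generator_kind = "permuted"`.
#' @param meta Optional list of extra generator metadata (e.g. the
#'   distributional parameters used), kept for downstream reproducibility.
#'
#' @return An object of class `stimulus_sequence`.
#' @export
stimulus_sequence <- function(values, generator_kind = "iid", bounds = NULL,
                              seed = NULL, source_sequence_id = NULL,
                              meta = list()) {
  generator_kind <- match.arg(generator_kind,
                              c("iid", "random_walk", "two_state", "permuted"))
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values))) {
    stop("stimulus values must be finite and non-missing")
  }
  if (any(values <= 0)) stop("all stimulus values must be positive")
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
      stop("bounds must be (low, high) with low < high")
    }
    if (any(values < bounds[1] | values > bounds[2])) {
      stop("stimulus values fall outside the declared bounds")
    }
  }
  structure(list(values = values, generator_kind = generator_kind,
                 bounds = bounds, seed = seed,
                 source_sequence_id = source_sequence_id, meta = meta),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %d trials, kind '%s'\n",
              length(x$values), x$generator_kind))
  cat(sprintf("  range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (!is.null(x$bounds)) {
    cat(sprintf(", bounds [%.4g, %.4g]", x$bounds[1], x$bounds[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.stimulus_sequence <- function(x) length(x$values)

# Accept either a stimulus_sequence or a bare numeric vector.
stim_values <- function(stimuli) {
  if (inherits(stimuli, "stimulus_sequence")) stimuli$values
  else as.numeric(stimuli)
}

#' Generative parameters of the two-state stimulus process
#'
#' Parameters of the process that generates stimuli in log space: on trial
#' \eqn{i} the stimulus is drawn around a latent mean, \eqn{x_i = m_{i-1} +
#' \epsilon_x} with \eqn{\epsilon_x \sim N(0, v)}, and the mean itself drifts
#' as a random walk, \eqn{m_i = m_{i-1} + \epsilon_m} with \eqn{\epsilon_m
#' \sim N(0, q)}. A measurement of the stimulus adds sensory noise of
#' variance `r`. Setting `q = 0` gives i.i.d. stimuli around a fixed mean;
#' setting `v = 0` gives a pure random walk.
#'
#' @param v Variance of the stimulus distribution around its mean
#'   (log-units squared), `v >= 0`.
#' @param q Variance of the trial-to-trial change of the mean
#'   (log-units squared), `q >= 0`.
#' @param r Measurement-noise variance (log-units squared), `r > 0`.
#' @param init_mean Starting mean \eqn{m_0} in log units.
#'
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(v, q, r = 1, init_mean = 0) {
  stopifnot(is.numeric(v), is.numeric(q), is.numeric(r), is.numeric(init_mean))
  if (v < 0 || q < 0) stop("v and q must be nonnegative")
  if (r <= 0) stop("r must be positive")
  structure(list(v = v, q = q, r = r, init_mean = init_mean),
            class = "generative_params")
}

#' Trial sequence: paired stimuli and responses for one subject and condition
#'
#' @param subject_id Subject label.
#' @param condition Condition label.
#' @param stimuli A [stimulus_sequence()] or numeric vector of magnitudes.
#' @param responses Numeric vector of reproduced magnitudes, same length as
#'   the stimuli, all positive.
#' @param truth Optional [observer_params()] used to generate the responses
#'   (synthetic data only).
#'
#' @return An object of class `trial_sequence`.
#' @export
trial_sequence <- function(subject_id, condition, stimuli, responses,
                           truth = NULL) {
  if (!inherits(stimuli, "stimulus_sequence")) {
    stimuli <- stimulus_sequence(stimuli, generator_kind = "iid")
  }
  responses <- as.numeric(responses)
  if (length(responses) != length(stimuli$values)) {
    stop("responses and stimuli must have the same length")
  }
  if (anyNA(responses) || any(!is.finite(responses)) || any(responses <= 0)) {
    stop("all responses must be finite and positive")
  }
  if (!is.null(truth) && !inherits(truth, "observer_params")) {
    stop("truth must be observer_params or NULL")
  }
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 stimuli = stimuli, responses = responses, truth = truth),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> subject '%s', condition '%s', %d trials\n",
              x$subject_id, x$condition, length(x$responses)))
  invisible(x)
}

#' @export
length.trial_sequence <- function(x) length(x$responses)

#' @export
as.data.frame.trial_sequence <- function(x, ...) {
  data.frame(subject_id = x$subject_id, condition = x$condition,
             trial = seq_along(x$responses),
             stimulus = x$stimuli$values, response = x$responses,
             stringsAsFactors = FALSE)
}

#' Generate an i.i.d. truncated-normal stimulus sequence
#'
#' Draws stimuli independently from a normal distribution truncated to the
#' given bounds, via the inverse-CDF method.
#'
#' @param n Number of trials.
#' @param mean,sd Mean and standard deviation of the underlying (untruncated)
#'   normal, in linear units.
#' @param bounds Length-2 `(low, high)` truncation interval, `low > 0`.
#' @param seed Optional integer seed.
#'
#' @return A [stimulus_sequence()] with `generator_kind = "iid"`.
#' @export
gen_iid_sequence <- function(n, mean, sd, bounds, seed = NULL) {
  stopifnot(n >= 1)
  if (sd <= 0) stop("sd must be positive")
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("bounds must be (low, high) with low < high")
  }
  if (bounds[1] <= 0) stop("lower bound must be positive for magnitudes")
  plo <- pnorm(bounds[1], mean, sd)
  phi <- pnorm(bounds[2], mean, sd)
  if (phi - plo < .Machine$double.eps) {
    stop("bounds have negligible probability mass under N(mean, sd)")
  }
  values <- with_seed_(seed, qnorm(runif(n, plo, phi), mean, sd))
  # guard against qnorm rounding exactly onto the bound
  values <- pmin(pmax(values, bounds[1]), bounds[2])
  stimulus_sequence(values, "iid", bounds = bounds, seed = seed,
                    meta = list(mean = mean, sd = sd))
}

# Exact mean of the truncated normal, used as an independent check on the
# sampler in the tests.
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Generate a bounded random-walk stimulus sequence
#'
#' Cumulative sum of zero-mean Gaussian increments, started at the midpoint of
#' the bounds. Whole sequences are rejection-sampled until all values lie
#' inside the bounds, which preserves exact Gaussian increments (reflection
#' would distort them).
#'
#' @param n Number of trials.
#' @param step_sd Standard deviation of the Gaussian increments, linear units.
#' @param bounds Length-2 `(low, high)` interval the whole walk must stay in.
#' @param seed Optional integer seed.
#' @param max_attempts Number of whole-sequence draws before giving up.
#'
#' @return A [stimulus_sequence()] with `generator_kind = "random_walk"`. The
#'   number of attempts used is stored in `meta$attempts`.
#' @export
gen_random_walk_sequence <- function(n, step_sd, bounds, seed = NULL,
                                     max_attempts = 10000L) {
  stopifnot(n >= 1)
  if (step_sd <= 0) stop("step_sd must be positive")
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("bounds must be (low, high) with low < high")
  }
  mid <- mean(bounds)
  walk <- with_seed_(seed, {
    res <- NULL
    for (attempt in seq_len(max_attempts)) {
      w <- mid + cumsum(rnorm(n, 0, step_sd))
      if (all(w >= bounds[1] & w <= bounds[2])) {
        res <- list(w = w, attempts = attempt)
        break
      }
    }
    res
  })
  if (is.null(walk)) {
    stop(sprintf(paste0("no random walk of length %d stayed within [%g, %g] ",
                        "after %d attempts; try a smaller step_sd"),
                 n, bounds[1], bounds[2], max_attempts))
  }
  stimulus_sequence(walk$w, "random_walk", bounds = bounds, seed = seed,
                    meta = list(step_sd = step_sd, attempts = walk$attempts))
}

#' Calibrate the random-walk step size for a given bounds interval
#'
#' Finds, by bisection on `log(step_sd)`, the increment SD at which the
#' probability that a whole length-`n` walk stays inside the bounds is close
#' to `target_accept`. The acceptance probability is estimated by Monte Carlo
#' at each bisection step.
#'
#' @param bounds Length-2 `(low, high)` interval.
#' @param n Walk length the calibration refers to.
#' @param target_accept Desired whole-sequence acceptance probability.
#' @param n_mc Monte Carlo walks per acceptance estimate.
#' @param seed Optional integer seed.
#'
#' @return The calibrated `step_sd` (linear units).
#' @export
calibrate_step_sd <- function(bounds, n = 400L, target_accept = 0.10,
                              n_mc = 400L, seed = NULL) {
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], n >= 2)
  half <- diff(bounds) / 2
  accept_rate <- function(step_sd) {
    inc <- matrix(rnorm(n * n_mc, 0, step_sd), nrow = n)
    walks <- apply(inc, 2, cumsum)
    mean(apply(abs(walks) <= half, 2, all))
  }
  with_seed_(seed, {
    # bracket: tiny steps always accepted, huge steps never
    lo <- log(half / n)        # acceptance ~ 1
    hi <- log(half)            # acceptance ~ 0
    for (iter in 1:25) {
      midp <- (lo + hi) / 2
      if (accept_rate(exp(midp)) > target_accept) lo <- midp else hi <- midp
    }
    exp((lo + hi) / 2)
  })
}

#' Generate a two-state stimulus sequence
#'
#' Generates the sequence in log space: the latent mean performs a random walk
#' with increment variance `q`, and each stimulus is drawn around the previous
#' mean with variance `v`. Log values are back-transformed to linear units via
#' [back_transform()] with `delta_x = 0`.
#'
#' @param n Number of trials.
#' @param params A [generative_params()] object (`v`, `q`, `init_mean` are
#'   used; `init_mean` is in log units).
#' @param seed Optional integer seed.
#' @param d0 Linear-unit constant of the log transform.
#' @param paper_literal_inverse Back-transform convention, see
#'   [back_transform()].
#'
#' @return A [stimulus_sequence()] with `generator_kind = "two_state"`.
#' @export
gen_two_state_sequence <- function(n, params, seed = NULL, d0 = 1,
                                   paper_literal_inverse = FALSE) {
  stopifnot(n >= 1, inherits(params, "generative_params"))
  logs <- with_seed_(seed, {
    m <- params$init_mean + cumsum(rnorm(n, 0, sqrt(params$q)))
    m_prev <- c(params$init_mean, m[-n])
    m_prev + rnorm(n, 0, sqrt(params$v))
  })
  values <- back_transform(logs, d0 = d0, delta_x = 0,
                           paper_literal_inverse = paper_literal_inverse)
  if (any(values <= 0)) {
    stop("two-state generation produced nonpositive magnitudes; ",
         "increase init_mean or d0")
  }
  stimulus_sequence(values, "two_state", seed = seed,
                    meta = list(v = params$v, q = params$q,
                                init_mean = params$init_mean, d0 = d0))
}

#' Permute a stimulus sequence
#'
#' Returns the same multiset of values in scrambled order (the "randomized"
#' counterpart of a random-walk session).
#'
#' @param x A [stimulus_sequence()].
#' @param seed Optional integer seed.
#'
#' @return A [stimulus_sequence()] with `generator_kind = "permuted"`.
#' @export
permute_sequence <- function(x, seed = NULL) {
  stopifnot(inherits(x, "stimulus_sequence"))
  values <- with_seed_(seed, sample(x$values))
  stimulus_sequence(values, "permuted", bounds = x$bounds, seed = seed,
                    source_sequence_id = x$generator_kind, meta = x$meta)
}

#' Kullback-Leibler divergence between two histograms
#'
#' Bins both sequences on a common equal-width grid spanning the union of
#' their ranges, adds a pseudo-count of `pseudo` to every bin, normalizes,
#' and returns `sum(p * log(p / q))` with `x` as `p` and `reference` as `q`
#' (the reference distribution).
#'
#' @param x,reference Numeric vectors or [stimulus_sequence()] objects.
#' @param n_bins Number of equal-width bins.
#' @param pseudo Additive pseudo-count per bin before normalization.
#'
#' @return Nonnegative scalar divergence (nats); exactly 0 when the two
#'   histograms coincide.
#' @export
histogram_kl <- function(x, reference, n_bins = 20L, pseudo = 0.5) {
  a <- stim_values(x)
  b <- stim_values(reference)
  stopifnot(length(a) > 0, length(b) > 0, n_bins >= 2, pseudo > 0)
  lo <- min(a, b)
  hi <- max(a, b)
  if (hi <= lo) return(0)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  p <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts + pseudo
  q <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts + pseudo
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

lag1_autocor <- function(x) {
  x <- stim_values(x)
  cor(x[-1], x[-length(x)])
}

#' Tune a generator so its histogram matches a reference sequence
#'
#' Searches the variance parameters of the requested generator so that the
#' histogram of the generated sequence minimizes the Kullback-Leibler
#' divergence to the reference sequence's histogram. For the two-state
#' generator the search is additionally penalized toward a target lag-1
#' autocorrelation (default 0.66, the value used for illustrating a sequence
#' that compromises between randomness and slow drift); set
#' `lag1_target = NULL` to minimize the divergence alone.
#'
#' The objective is evaluated on a fixed generation seed, so it is a
#' deterministic (though rough) function of the parameters; a coarse
#' log-spaced grid search is followed by a Nelder-Mead polish.
#'
#' @param reference A [stimulus_sequence()] (or numeric vector) to match.
#' @param generator_kind `"random_walk"` or `"two_state"`.
#' @param n_bins Histogram bins for the divergence.
#' @param seed Integer seed for the candidate sequences.
#' @param lag1_target Optional target lag-1 autocorrelation (two-state only).
#' @param n_out Length of the generated sequence (defaults to the reference
#'   length).
#' @param pseudo Histogram pseudo-count, see [histogram_kl()].
#'
#' @return A list with elements `sequence` (the tuned [stimulus_sequence()]),
#'   `kl` (achieved divergence), `params` (tuned generator parameters),
#'   `lag1` (realized lag-1 autocorrelation) and `converged` (FALSE when the
#'   polish step hit its iteration cap; the best candidate is still returned).
#' @export
match_histograms <- function(reference, generator_kind = c("random_walk",
                                                           "two_state"),
                             n_bins = 20L, seed = 1L, lag1_target = NULL,
                             n_out = NULL, pseudo = 0.5) {
  generator_kind <- match.arg(generator_kind)
  ref <- stim_values(reference)
  stopifnot(length(ref) > 1)
  if (is.null(n_out)) n_out <- length(ref)
  if (missing(lag1_target) && generator_kind == "two_state") lag1_target <- 0.66

  if (generator_kind == "random_walk") {
    bounds <- range(ref)
    gen <- function(step_sd) {
      tryCatch(gen_random_walk_sequence(n_out, step_sd, bounds, seed = seed,
                                        max_attempts = 2000L),
               error = function(e) NULL)
    }
    objective <- function(lpar) {
      s <- gen(exp(lpar))
      if (is.null(s)) return(1e6)
      histogram_kl(s, ref, n_bins = n_bins, pseudo = pseudo)
    }
    grid <- seq(log(diff(bounds) / (4 * sqrt(n_out))),
                log(diff(bounds) / 8), length.out = 200L)
    vals <- vapply(grid, objective, numeric(1))
    best <- grid[which.min(vals)]
    opt <- optim(best, objective, method = "Brent",
                 lower = best - 0.5, upper = best + 0.5)
    step_sd <- exp(opt$par)
    seq_out <- gen(step_sd)
    list(sequence = seq_out,
         kl = histogram_kl(seq_out, ref, n_bins = n_bins, pseudo = pseudo),
         params = list(step_sd = step_sd),
         lag1 = lag1_autocor(seq_out),
         converged = opt$convergence == 0)
  } else {
    m0 <- mean(log_transform(ref, d0 = 1))
    gen <- function(v, q) {
      gen_two_state_sequence(n_out, generative_params(v, q, init_mean = m0),
                             seed = seed)
    }
    objective <- function(lpar) {
      s <- tryCatch(gen(exp(lpar[1]), exp(lpar[2])), error = function(e) NULL)
      if (is.null(s)) return(1e6)
      val <- histogram_kl(s, ref, n_bins = n_bins, pseudo = pseudo)
      if (!is.null(lag1_target)) {
        val <- val + (lag1_autocor(s) - lag1_target)^2
      }
      val
    }
    # total log-variance scale of the reference anchors the grid
    vref <- var(log_transform(ref, d0 = 1))
    lv <- log(vref * c(0.02, 0.05, 0.15, 0.4, 0.8, 1.2))
    lq <- log(vref / length(ref) * c(0.02, 0.1, 0.3, 1, 3, 10, 30))
    grid <- as.matrix(expand.grid(lv = lv, lq = lq))
    vals <- apply(grid, 1, objective)
    # polish from the best few grid points; the landscape is rough
    starts <- grid[order(vals)[1:4], , drop = FALSE]
    opts <- lapply(seq_len(nrow(starts)), function(i) {
      optim(starts[i, ], objective,
            control = list(maxit = 400L, reltol = 1e-10))
    })
    opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
    v <- exp(opt$par[1]); q <- exp(opt$par[2])
    seq_out <- gen(v, q)
    list(sequence = seq_out,
         kl = histogram_kl(seq_out, ref, n_bins = n_bins, pseudo = pseudo),
         params = list(v = v, q = q),
         lag1 = lag1_autocor(seq_out),
         converged = opt$convergence == 0)
  }
}
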