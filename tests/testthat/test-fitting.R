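test_that("noiseless two-state data are recovered essentially exactly", {
  stim <- fix_iid(300, seed = 5)
  tru <- observer_params("two_state", 1.2, 0.3, 0.02)
  tr <- simulate_observer(stim, tru, response_noise_sd = 0, seed = 6)
  ft <- fit_model(tr, "two_state")
  expect_lt(abs(ft$params$v_over_r - 1.2), 1e-3)
  expect_lt(abs(ft$params$q_over_r - 0.3), 1e-3)
  expect_lt(abs(ft$params$delta_x - 0.02), 1e-3)
  # zero-residual fit: intervals collapse onto the point estimate
  expect_lt(max(ft$ci[, "upper"] - ft$ci[, "lower"]), 1e-4)
})

test_that("reported sse equals the recomputed residual sum of squares", {
  tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 200,
                            noise = 0.1, seed = 9)
  ft <- fit_model(tr, "two_state", ci = FALSE)
  sse <- sum((tr$responses -
                simulate_response_timecourse(tr$stimuli, ft$params))^2)
  expect_equal(ft$sse, sse, tolerance = 1e-9)

  # masked variant: held-out residuals do not enter the loss
  mask <- rep(1, 200); mask[50:60] <- 0
  ftm <- fit_model(tr, "two_state", mask = mask, ci = FALSE)
  ssem <- sum(((tr$responses -
                  simulate_response_timecourse(tr$stimuli, ftm$params)) *
                 mask)^2)
  expect_equal(ftm$sse, ssem, tolerance = 1e-9)
})

test_that("the two-state fit dominates its nested special cases", {
  for (s in 1:3) {
    tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 150,
                              noise = 0.15, seed = 20 + s)
    sse <- vapply(c("static", "iterative", "two_state"), function(mk) {
      fit_model(tr, mk, ci = FALSE)$sse
    }, numeric(1))
    expect_lte(sse[["two_state"]], sse[["static"]] * (1 + 1e-6))
    expect_lte(sse[["two_state"]], sse[["iterative"]] * (1 + 1e-6))
  }
})

test_that("fitting the full model to static data leaves q/r at zero", {
  tr <- fix_observer_trials(observer_params("static", 1, 0, 0.01), n = 300,
                            noise = 0.05, seed = 24)
  ft <- fit_model(tr, "two_state")
  expect_lt(ft$params$q_over_r, 0.05)
  expect_lte(ft$ci["q_over_r", "lower"], 0)
  expect_gte(ft$ci["q_over_r", "upper"], 0)
})

test_that("interval widths scale with information and residual size", {
  # duplicating every residual/jacobian row shrinks widths by ~1/sqrt(2)
  withr::with_seed(1, {
    J <- matrix(rnorm(300), 100, 3)
    r <- rnorm(100, 0, 0.5)
  })
  w1 <- kalmag:::ci_from_jacobian(J, r)
  w2 <- kalmag:::ci_from_jacobian(rbind(J, J), c(r, r))
  ratio <- (w2[, "upper"] - w2[, "lower"]) / (w1[, "upper"] - w1[, "lower"])
  expect_equal(unname(ratio), rep(1 / sqrt(2), 3), tolerance = 0.02)

  # singular jacobian: unbounded interval
  Js <- cbind(J[, 1], J[, 1], J[, 2])
  ws <- kalmag:::ci_from_jacobian(Js, r)
  expect_true(any(!is.finite(ws)))
})

test_that("confidence intervals achieve near-nominal coverage", {
  stim <- gen_iid_sequence(200, 1150, 300, c(400, 1900), seed = 77)
  tru <- observer_params("two_state", 1.0, 0.3, 0.02)
  truth_vec <- c(1.0, 0.3, 0.02)
  cover <- withr::with_seed(42, {
    replicate(100, {
      tr <- simulate_observer(stim, tru, response_noise_sd = 0.1)
      ft <- fit_model(tr, "two_state", init = tru, multi_start = FALSE)
      truth_vec >= ft$ci[, 1] & truth_vec <= ft$ci[, 2]
    })
  })
  expect_gt(mean(cover), 0.85)
  expect_lte(mean(cover), 1)
})

test_that("recovery error shrinks with sequence length", {
  err_at <- function(n) {
    median(sapply(1:3, function(s) {
      tr <- fix_observer_trials(observer_params("two_state", 1, 0.3, 0),
                                n = n, noise = 0.1, seed = 60 + s)
      ft <- fit_model(tr, "two_state", ci = FALSE)
      abs(ft$params$v_over_r - 1) + abs(ft$params$q_over_r - 0.3)
    }))
  }
  expect_lt(err_at(800), err_at(50))
})

test_that("r_squared follows the baseline convention", {
  obs <- c(1, 2, 3, 4, 5)
  expect_identical(r_squared(obs, obs), 1)
  expect_identical(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_lt(r_squared(obs, rev(obs)), 0)
  expect_error(r_squared(rep(1, 5), obs), "zero total variance")
})

test_that("windowed LOO selects the generating model class", {
  # static truth: the simpler model family wins or ties via the nested model,
  # the iterative model never wins
  chosen_static <- sapply(1:6, function(s) {
    stim <- gen_iid_sequence(120, 1150, 300, c(400, 1900), seed = 300 + s)
    tr <- simulate_observer(stim, observer_params("static", 1, 0, 0.01),
                            response_noise_sd = 0.05, seed = 400 + s)
    loo_timeseries(tr, window_k = 11)$chosen
  })
  expect_true(all(chosen_static %in% c("static", "two_state")))

  # two-state truth with clear drift belief: the full model wins
  chosen_ts <- sapply(1:6, function(s) {
    stim <- gen_iid_sequence(150, 1150, 300, c(400, 1900), seed = 500 + s)
    tr <- simulate_observer(stim, observer_params("two_state", 1, 0.5, 0),
                            response_noise_sd = 0.05, seed = 600 + s)
    loo_timeseries(tr, window_k = 11)$chosen
  })
  expect_gte(mean(chosen_ts == "two_state"), 0.8)
})

test_that("LOO machinery: window edges, k = 1, and error bookkeeping", {
  tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 60,
                            noise = 0.1, seed = 70)
  sel1 <- loo_timeseries(tr, model_kinds = "two_state", window_k = 1)
  sel3 <- loo_timeseries(tr, model_kinds = "two_state", window_k = 3)
  expect_identical(sel1$n_centers, 59L)
  expect_identical(sel3$n_centers, 59L)
  expect_true(is.finite(sel1$per_model_cv_error[["two_state"]]))
  expect_error(loo_timeseries(tr, window_k = 4), "odd")
  expect_error(loo_timeseries(tr, window_k = 31), "too short")
})

test_that("condition prediction is a zero-parameter simulation", {
  tr <- fix_observer_trials(observer_params("two_state", 1, 0.4), n = 200,
                            noise = 0.1, seed = 80)
  ft <- fit_model(tr, "two_state", ci = FALSE)
  # applying the fitted params to the fitted condition reproduces the fit
  pr <- predict_condition(ft$params, tr)
  expect_identical(pr$predicted, ft$simulated)
  expect_s3_class(pr$metrics, "bias_summary")
})

test_that("binned averages aggregate subject-first with flags", {
  stim <- stimulus_sequence(c(500, 600, 1500, 1600))
  tr <- trial_sequence("a", "x", stim, c(550, 640, 1400, 1450))
  one <- binned_average(tr, bin_edges = c(400, 1900))
  expect_equal(one$mean, mean(c(50, 40, -100, -150)))
  expect_identical(one$flag, "single_subject")

  # identical subjects: zero SEM
  two <- binned_average(list(tr, tr), bin_edges = c(400, 1000, 1900))
  expect_equal(two$sem, c(0, 0))
  expect_identical(two$flag, c("", ""))

  # empty bins are flagged, not dropped
  gap <- binned_average(tr, bin_edges = c(400, 700, 1100, 1900))
  expect_identical(gap$flag[2], "empty")
  expect_true(is.na(gap$mean[2]))
  expect_error(binned_average(tr, bin_edges = c(600, 1900)), "cover")
})

test_that("binned model errors track binned observed errors on a cohort", {
  # well-fit synthetic cohort: R^2 between binned observed and binned
  # simulated error patterns is high
  cohort <- lapply(1:6, function(s) {
    fix_observer_trials(observer_params("two_state", 0.8 + 0.1 * s,
                                        0.05 * s, 0),
                        n = 200, noise = 0.08, seed = 90 + s)
  })
  fits <- lapply(cohort, fit_model, model_kind = "two_state", ci = FALSE)
  simulated <- Map(function(tr, ft) {
    trial_sequence(tr$subject_id, "sim", tr$stimuli, ft$simulated)
  }, cohort, fits)
  edges <- seq(400, 1900, length.out = 11)
  obs <- binned_average(cohort, bin_edges = edges)
  mod <- binned_average(simulated, bin_edges = edges)
  ok <- !is.na(obs$mean) & !is.na(mod$mean)
  expect_gt(r_squared(obs$mean[ok], mod$mean[ok]), 0.9)
})
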