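test_that("central tendency follows its defining regression", {
  stim <- fix_iid(200, seed = 30)
  x <- stim$values
  verid <- trial_sequence("a", "x", stim, x)
  expect_equal(central_tendency(verid), 0)
  const <- trial_sequence("a", "x", stim, rep(900, 200))
  expect_equal(central_tendency(const), 1)
  # compressed responses with slope 0.58 give c = 0.42
  comp <- trial_sequence("a", "x", stim, 0.58 * x + 300)
  expect_equal(central_tendency(comp), 0.42)
  expect_error(central_tendency(trial_sequence("a", "x", rep(1000, 10),
                                               rep(900, 10))),
               "zero variance")
})

test_that("sequential dependence separates static from iterative observers", {
  stim <- fix_iid(200, seed = 31)
  zero_err <- trial_sequence("a", "x", stim, stim$values)
  expect_identical(sequential_dependence(zero_err), 0)

  # static observer: no dependence on the previous stimulus
  big <- fix_iid(20000, seed = 32)
  resp <- static_estimate(big$values, 0.5, mean(big$values))
  s_stat <- sequential_dependence(trial_sequence("a", "x", big, resp),
                                  se = TRUE)
  expect_lt(abs(s_stat[["s"]]), 3 * s_stat[["se"]])

  # steady-state iterative observer with k = 0.5: s near the 0.25 maximum
  resp_it <- iterative_estimate(big$values, 0.5)
  s_it <- sequential_dependence(trial_sequence("a", "x", big, resp_it),
                                se = TRUE)
  expect_lt(abs(s_it[["s"]] - 0.25), 3 * s_it[["se"]])
})

test_that("iterative prediction curve is the (1-c)c parabola", {
  expect_identical(iterative_prediction_curve(0), 0)
  expect_identical(iterative_prediction_curve(1), 0)
  expect_identical(iterative_prediction_curve(0.5), 0.25)
  expect_error(iterative_prediction_curve(1.2), "\\[0, 1\\]")
})

test_that("partial correlation matches the closed-form identity", {
  for (s in 1:5) {
    tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 150,
                              noise = 0.1, seed = s)
    x <- tr$stimuli$values
    n <- length(x)
    err <- (tr$responses - x)[-1]
    curr <- x[-1]
    prev <- x[-n]
    rho <- partial_correlation(tr, "prev")
    rho_cf <- kalmag:::partial_cor_closed_form(cor(err, prev),
                                               cor(err, curr),
                                               cor(prev, curr))
    expect_equal(rho, rho_cf, tolerance = 1e-12)
    expect_lte(abs(rho), 1)
    expect_lte(abs(partial_correlation(tr, "curr")), 1)
  }
})

test_that("partial correlations read out serial bias and central tendency", {
  # static observer: error independent of the previous stimulus given the
  # current one
  big <- fix_iid(20000, seed = 33)
  resp <- static_estimate(big$values, 0.5, mean(big$values))
  tr <- trial_sequence("a", "x", big, resp)
  expect_lt(abs(partial_correlation(tr, "prev")), 3 / sqrt(20000))
  # central tendency appears as a negative error-vs-current correlation
  expect_lt(partial_correlation(tr, "curr"), -0.9)

  # serially dependent observer: positive partial correlation with the
  # previous stimulus
  tr2 <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 5000,
                             noise = 0.1, seed = 34)
  expect_gt(partial_correlation(tr2, "prev"), 0.05)
})

test_that("lagged dependence generalizes the lag-1 regression", {
  tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 300,
                            noise = 0.1, seed = 35)
  ld <- lagged_dependence(tr, 3)
  expect_identical(ld$slope[1], sequential_dependence(tr))
  expect_error(lagged_dependence(tr, 100), "max_lag")

  # veridical responses: zero errors, zero slopes
  stim <- fix_iid(100, seed = 36)
  ld0 <- lagged_dependence(trial_sequence("a", "x", stim, stim$values), 3)
  expect_equal(ld0$slope, rep(0, 3))

  # two-state observers on i.i.d. stimuli: positive influence decaying
  # over the recent past (average over simulated observers)
  sl <- sapply(1:10, function(s) {
    stim <- gen_iid_sequence(400, 1150, 300, c(400, 1900), seed = 100 + s)
    trs <- simulate_observer(stim, observer_params("two_state", 1, 0.3),
                             response_noise_sd = 0.1, seed = 200 + s)
    lagged_dependence(trs, 3)$slope
  })
  m <- rowMeans(sl)
  expect_true(all(m > 0))
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3] - 0.01)
})

test_that("bias metrics use the linear domain", {
  tr <- fix_observer_trials(observer_params("two_state", 1, 0.3), n = 400,
                            noise = 0.1, seed = 37)
  log_tr <- data.frame(stimulus = log_transform(tr$stimuli$values),
                       response = log_transform(tr$responses))
  expect_false(isTRUE(all.equal(central_tendency(tr),
                                central_tendency(log_tr))))
  expect_false(isTRUE(all.equal(sequential_dependence(tr),
                                sequential_dependence(log_tr))))
})

test_that("simulated observers respect the (c, s) boundary geometry", {
  stim <- gen_iid_sequence(2000, 1150, 300, c(400, 1900), seed = 7)
  cases <- list(observer_params("static", 0.5), observer_params("static", 2),
                observer_params("iterative", 0, 0.2),
                observer_params("iterative", 0, 1),
                observer_params("two_state", 1, 0.3),
                observer_params("two_state", 0.3, 0.05))
  for (p in cases) {
    tr <- simulate_observer(stim, p, response_noise_sd = 0.05, seed = 8)
    cc <- central_tendency(tr)
    ss <- sequential_dependence(tr, se = TRUE)
    parab <- iterative_prediction_curve(min(max(cc, 0), 1))
    # below or on the iterative parabola, above or on the static floor
    expect_lte(ss[["s"]], parab + 3 * ss[["se"]])
    expect_gte(ss[["s"]], -3 * ss[["se"]])
    if (p$model_kind == "static") {
      expect_lt(abs(ss[["s"]]), 3 * ss[["se"]])
    }
    if (p$model_kind == "iterative") {
      expect_lt(abs(ss[["s"]] - parab), 3 * ss[["se"]])
    }
    if (p$model_kind == "two_state") {
      expect_gt(ss[["s"]], 3 * ss[["se"]])
      expect_lt(ss[["s"]], parab)
    }
  }
})

test_that("static-model central tendency estimate is consistent", {
  big <- fix_iid(100000, seed = 38)
  for (w in c(0.3, 0.7)) {
    resp <- static_estimate(big$values, w, mean(big$values))
    cc <- central_tendency(trial_sequence("a", "x", big, resp))
    expect_lt(abs(cc - (1 - w)), 0.01)
  }
})

test_that("group summary implements the one-sample t-test and Cohen's d", {
  g0 <- group_summary(rep(0.2, 5), null_value = 0.2)
  expect_identical(g0$t, 0)
  expect_identical(g0$cohens_d, 0)

  # reconstructed cohort metric: mean 0.107, sd 0.055
  vals <- 0.107 + 0.055 * c(-1, 0, 1)
  g <- group_summary(vals, 0)
  expect_equal(g$mean, 0.107)
  expect_equal(g$sd, 0.055)
  expect_equal(g$cohens_d, 0.107 / 0.055)

  # doubling the sample with identical values: d unchanged up to the n-1
  # variance denominator, |t| scales as sqrt(2)
  g2 <- group_summary(rep(vals, 2), 0)
  expect_equal(g2$cohens_d,
               g$cohens_d * sqrt((2 * g$n - 1) / (2 * (g$n - 1))))
  expect_equal(g2$cohens_d, g$cohens_d, tolerance = 0.15)
  ratio <- abs(g2$t) / abs(g$t)
  # sqrt(2) up to the n-1 vs 2n-1 variance denominators
  expect_equal(ratio, sqrt(2) * sqrt((2 * g$n - 1) / (2 * (g$n - 1))),
               tolerance = 1e-6)
  expect_error(group_summary(rep(1, 4), 0), "zero variance")
})
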