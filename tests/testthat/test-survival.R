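test_that("product-limit estimate matches hand computation", {
  # four deaths, no censoring: survival steps 0.75, 0.5, 0.25, 0
  km <- km_estimate(make_records(c(1, 2, 3, 4)))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, 4:1)

  # single subject
  km1 <- km_estimate(make_records(5))
  expect_equal(km1$survival, 0)

  # deaths {2,2,4} with a censoring at 3:
  # day 2: 4 at risk, 2 deaths -> S = 1/2; day 4: 1 at risk, 1 death -> S = 0
  rec <- tibble::tibble(group = "g", day = c(2, 2, 4, 3),
                        event = c(TRUE, TRUE, TRUE, FALSE))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 2], 0.5)
  expect_equal(km$survival[km$time == 4], 0)
  expect_equal(km$n_censor[km$time == 3], 1L)

  expect_error(km_estimate(tibble::tibble()), class = "androdyn_data_error")
})

test_that("uncensored KM reproduces the empirical survival function", {
  days <- gen_survival_cohort(200, calibrate_hazard(10, 0.2), seed = 7)$day
  km <- km_estimate(make_records(days))
  emp <- vapply(km$time, function(t) mean(days > t), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("mean lifespan matches figure-legend style summaries", {
  s <- mean_lifespan(make_records(c(10, 14)))
  expect_equal(s$mean, 12)
  expect_equal(s$se, 2)

  s0 <- mean_lifespan(make_records(c(5, 5, 5)))
  expect_equal(s0$mean, 5)
  expect_equal(s0$se, 0)

  # Monte-Carlo: exponential mean 10
  days <- gen_survival_cohort(1e5, hazard_params(0.1), seed = 31)$day
  s <- mean_lifespan(make_records(days))
  expect_lt(abs(s$mean - 10), 3 * s$se)

  expect_error(mean_lifespan(make_records(c(3, 4), event = FALSE)),
               class = "androdyn_data_error")
})

test_that("censored groups fall back to the KM restricted mean", {
  skip_if_not_installed("survival")
  rec <- tibble::tibble(group = "g", day = c(2, 2, 4, 5, 7, 9),
                        event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  s <- mean_lifespan(rec)
  expect_equal(s$method, "km_restricted")
  # restrict the reference to the last death, the same upper limit we use
  ref <- summary(survival::survfit(survival::Surv(day, event) ~ 1,
                                   data = rec),
                 rmean = max(rec$day[rec$event]))$table
  expect_equal(s$mean, unname(ref["rmean"]))
  expect_equal(s$se, unname(ref["se(rmean)"]))
})

test_that("KM restricted mean equals the arithmetic mean on uncensored data", {
  for (seed in 1:5) {
    days <- gen_survival_cohort(50, calibrate_hazard(9, 0.3), seed = seed)$day
    curve <- km_estimate(make_records(days))
    rm <- androdyn:::km_restricted_mean(curve)
    expect_equal(rm$rmean, mean(days))
  }
})

test_that("percent lifespan reduction reproduces the legend effect sizes", {
  expect_equal(percent_reduction(12.0, 7.7), 35.8, tolerance = 1e-3)
  expect_equal(percent_reduction(10.9, 6.8), 37.6, tolerance = 1e-3)
  expect_equal(percent_reduction(10, 10), 0)

  # antitone in the treated mean, invariant to rescaling both means
  r1 <- percent_reduction(12, 7)
  r2 <- percent_reduction(12, 8)
  expect_gt(r1, r2)
  expect_equal(percent_reduction(12, 7), percent_reduction(24, 14))

  # data-frame front end
  summ <- tibble::tibble(group = c("ctrl", "trt"), mean = c(12, 7.7))
  expect_equal(percent_reduction(summ, "trt", ctrl_group = "ctrl"),
               percent_reduction(12, 7.7))

  expect_error(percent_reduction(0, 5), class = "androdyn_parameter_error")
})

test_that("hypergeometric overlap agrees with exhaustive enumeration", {
  # worked examples
  expect_equal(hypergeometric_overlap(10, 5, 5, 0)$p_value, 1)
  expect_equal(hypergeometric_overlap(4, 2, 2, 2)$p_value, 1 / 6)

  # random configurations over small universes
  set.seed(17)
  for (i in 1:25) {
    u <- sample(4:12, 1)
    a <- sample.int(u, 1)
    b <- sample.int(u, 1)
    ks <- seq.int(max(0, a + b - u), min(a, b))
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeometric_overlap(u, a, b, k)$p_value,
                 oracle_overlap_enum(u, a, b, k))
  }

  expect_error(hypergeometric_overlap(10, 3, 4, 5),
               class = "androdyn_parameter_error")
  expect_error(hypergeometric_overlap(10, 11, 4, 2),
               class = "androdyn_parameter_error")
})

test_that("unpaired t-test matches stats::t.test and handles degenerate input", {
  a <- c(0.1, 0.4, 0.3, 0.6)
  b <- c(0.5, 0.8, 0.7)
  fit <- unpaired_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(fit$statistic, unname(ref$statistic))
  expect_equal(fit$p_value, ref$p.value)
  expect_equal(fit$df, 5)

  w <- unpaired_t_test(a, b, welch = TRUE)
  expect_equal(w$p_value, t.test(a, b)$p.value)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(flat <- unpaired_t_test(c(0, 0), c(0, 0)))
  expect_equal(flat$p_value, 1)
  expect_warning(apart <- unpaired_t_test(c(0, 0), c(1, 1)))
  expect_equal(apart$p_value, 0)

  expect_error(unpaired_t_test(1, c(1, 2)), class = "androdyn_data_error")
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(1234)
  reject <- vapply(1:1000, function(i) {
    unpaired_t_test(rnorm(200), rnorm(200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})
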