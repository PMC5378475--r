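test_that("hazard calibration reproduces the target mean lifespan", {
  # exponential special case is exact
  h <- calibrate_hazard(10, aging_rate = 0)
  expect_equal(h$baseline_rate, 0.1)

  # with ageing, the quadrature mean of the calibrated hazard hits the target
  for (case in list(c(12, 0.2), c(7.7, 0.25), c(18.5, 0.1))) {
    h <- calibrate_hazard(case[1], aging_rate = case[2])
    expect_equal(oracle_gompertz_mean(h$baseline_rate, h$aging_rate),
                 case[1], tolerance = 1e-6)
  }

  expect_error(calibrate_hazard(0), class = "androdyn_parameter_error")
  expect_error(hazard_params(-1, 0), class = "androdyn_parameter_error")
})

test_that("generated cohorts recover the calibrated mean at large n", {
  # exponential limit: aging_rate 0, rate 0.1 -> mean 10
  co <- gen_survival_cohort(1e5, hazard_params(0.1, 0), seed = 11)
  expect_equal(nrow(co), 1e5)
  expect_lt(abs(mean(co$day) - 10), 3 * sd(co$day) / sqrt(1e5))

  # Gompertz calibrated to 12.0 d
  h <- calibrate_hazard(12, aging_rate = 0.25)
  co <- gen_survival_cohort(1e5, h, seed = 12)
  expect_lt(abs(mean(co$day) - 12), 0.1)
  expect_lt(abs(mean(co$day) - 12), 3 * sd(co$day) / sqrt(1e5))
  expect_true(all(co$event))
  expect_true(all(co$day > 0))
})

test_that("cohort generation is deterministic given the seed and censors correctly", {
  h <- calibrate_hazard(12, aging_rate = 0.25)
  a <- gen_survival_cohort(500, h, group = "g", seed = 42)
  b <- gen_survival_cohort(500, h, group = "g", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, gen_survival_cohort(500, h, group = "g", seed = 43)))

  cen <- gen_survival_cohort(500, h, seed = 42, censor_day = 10)
  expect_true(all(cen$day <= 10))
  expect_identical(cen$event, a$day <= 10)
  expect_identical(cen$day[!cen$event], rep(10, sum(!cen$event)))
})

test_that("fertility schedules interpolate anchors linearly and clip", {
  sched <- gen_fertility_schedules()
  ctrl <- sched[sched$condition == "ctrl", ]
  trt <- sched[sched$condition == "trt", ]

  # Day 1 defaults to fully fertile; Day 5 is the Day 4 / Day 6 midpoint
  expect_equal(ctrl$fraction_fertile[ctrl$day == 1], 1)
  expect_equal(ctrl$fraction_fertile[ctrl$day == 4], 0.82)
  expect_equal(ctrl$fraction_fertile[ctrl$day == 5], 0.755)
  expect_equal(ctrl$fraction_fertile[ctrl$day == 6], 0.69)
  expect_equal(trt$fraction_fertile[trt$day == 5], 0.49)

  # identical anchors give identical schedules
  same <- gen_fertility_schedules(trt_anchors = c("4" = 0.82, "6" = 0.69))
  expect_equal(same$fraction_fertile[same$condition == "ctrl"],
               same$fraction_fertile[same$condition == "trt"])

  # monotone anchors give monotone interpolated values
  expect_true(all(diff(ctrl$fraction_fertile) <= 0))
  expect_true(all(sched$fraction_fertile >= 0 & sched$fraction_fertile <= 1))

  expect_error(gen_fertility_schedules(ctrl_anchors = c("4" = 1.2)),
               class = "androdyn_parameter_error")
})

test_that("chemotaxis plate draws conserve counts and obey the multinomial law", {
  # degenerate: everything at the supernatant spot
  p <- gen_chemotaxis_plate(10, 1, 0, 0, seed = 1)
  expect_equal(p$n_super, 10L)
  expect_equal(p$n_ctrl + p$n_origin, 0L)

  # empty plate
  p0 <- gen_chemotaxis_plate(0, 0.5, 0.3, 0.1, seed = 1)
  expect_equal(unlist(p0), c(n_super = 0L, n_ctrl = 0L, n_origin = 0L,
                             n_total = 0L))

  # law of large numbers at n = 1e5
  big <- gen_chemotaxis_plate(1e5, 0.5, 0.3, 0.1, seed = 2)
  expect_lt(abs(big$n_super / 1e5 - 0.5), 0.01)
  expect_lt(abs(big$n_ctrl / 1e5 - 0.3), 0.01)
  expect_lt(abs(big$n_origin / 1e5 - 0.1), 0.01)

  # conservation over a batch, and determinism
  batch <- gen_chemotaxis_plates(20, 30, 0.4, 0.3, 0.2, seed = 3)
  expect_true(all(batch$n_super + batch$n_ctrl + batch$n_origin <= batch$n_total))
  expect_identical(batch, gen_chemotaxis_plates(20, 30, 0.4, 0.3, 0.2, seed = 3))

  expect_error(gen_chemotaxis_plate(10, 0.6, 0.5, 0.2, seed = 1),
               class = "androdyn_parameter_error")
})

test_that("offspring sexes follow the selfing and outcrossing rates", {
  self <- gen_offspring_sexes(1e6, "selfing", seed = 21)
  expect_equal(self$n_male + self$n_hermaphrodite, 1e6L)
  expect_lt(abs(self$male_fraction - 0.002),
            3 * sqrt(0.002 * 0.998 / 1e6))

  cross <- gen_offspring_sexes(1e6, "cross", seed = 22)
  expect_lt(abs(cross$male_fraction - 0.5), 3 * sqrt(0.25 / 1e6))

  empty <- gen_offspring_sexes(0, "selfing", seed = 1)
  expect_equal(empty$n_male + empty$n_hermaphrodite, 0L)

  expect_identical(gen_offspring_sexes(1000, "cross", seed = 5),
                   gen_offspring_sexes(1000, "cross", seed = 5))
})

test_that("survival CSV round-trips through the on-disk schema", {
  co <- gen_survival_cohort(25, calibrate_hazard(8, 0.2), group = "grp",
                            seed = 9, censor_day = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(co, path)
  back <- read_survival_csv(path)
  expect_equal(back$day, co$day)
  expect_equal(back$event, co$event)
  expect_equal(back$group, co$group)
})
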