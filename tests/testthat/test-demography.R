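test_that("progeny bookkeeping gives the relative progeny factor", {
  sched <- gen_fertility_schedules()

  # identical schedules -> r = 1
  same <- dplyr::mutate(sched[sched$condition == "ctrl", ], condition = "trt")
  r1 <- relative_progeny_factor(dplyr::bind_rows(
    sched[sched$condition == "ctrl", ], same))
  expect_equal(r1$r, 1)

  # halving all treated fractions halves r
  half <- dplyr::mutate(sched[sched$condition == "ctrl", ],
                        condition = "trt",
                        fraction_fertile = fraction_fertile / 2)
  rh <- relative_progeny_factor(dplyr::bind_rows(
    sched[sched$condition == "ctrl", ], half))
  expect_equal(rh$r, 0.5)

  # invariant to rescaling n_males and progeny counts
  r_a <- relative_progeny_factor(sched)$r
  r_b <- relative_progeny_factor(sched, n_males = 600)$r
  scaled <- dplyr::mutate(sched, progeny_per_mating = progeny_per_mating * 7)
  r_c <- relative_progeny_factor(scaled)$r
  expect_equal(r_a, r_b)
  expect_equal(r_a, r_c)

  zero <- dplyr::mutate(sched, fraction_fertile = 0)
  expect_error(relative_progeny_factor(zero),
               class = "androdyn_undefined_factor_error")
})

test_that("the geometric recursion matches its closed form", {
  traj <- male_fraction_trajectory(0.768, 15)
  expect_equal(traj$male_fraction[traj$generation == 0], 0.5)
  expect_equal(traj$male_fraction[traj$generation == 1], 0.384)
  expect_equal(traj$male_fraction, 0.5 * 0.768^(0:15))
  expect_true(all(diff(traj$male_fraction) < 0))

  # control curve is constant at 50%
  ctrl <- male_fraction_trajectory(1, 10)
  expect_equal(ctrl$male_fraction, rep(0.5, 11))
})

test_that("generations_to_threshold equals the closed-form ceiling", {
  expect_equal(generations_to_threshold(0.5, threshold = 0.3, m0 = 0.5), 1L)
  set.seed(55)
  for (i in 1:1000) {
    r <- runif(1, 0.05, 0.95)
    m0 <- runif(1, 0.1, 1)
    th <- runif(1, 1e-4, m0 * 0.99)
    expect_equal(generations_to_threshold(r, th, m0),
                 as.integer(ceiling(log(th / m0) / log(r))))
  }
  expect_error(generations_to_threshold(1, 0.01),
               class = "androdyn_never_reached_error")
  expect_error(generations_to_threshold(0.768, threshold = 0.6, m0 = 0.5),
               class = "androdyn_parameter_error")
})

test_that("benchmark conversion turns generations into days", {
  traj <- male_fraction_trajectory(0.768, 20)
  bench <- compare_to_benchmark(traj, threshold = 0.01, days_per_generation = 3)
  expect_true(bench$reached)
  expect_equal(bench$generation, 15L)
  expect_equal(bench$days, 45)

  five <- tibble::tibble(generation = 0:5,
                         male_fraction = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.005))
  expect_equal(compare_to_benchmark(five, 0.01, 3)$days, 15)

  flat <- male_fraction_trajectory(1, 10)
  expect_false(compare_to_benchmark(flat)$reached)
})

test_that("stochastic simulation conserves counts and is seed-deterministic", {
  p <- mating_system_params(relative_progeny_factor = 0.768)
  s <- simulate_sex_ratio(p, n_hermaphrodites = 500, n_males = 500,
                          generations = 12, seed = 3, cap = 2000)
  expect_true(all(s$n_males + s$n_hermaphrodites <= 2000))
  expect_true(all(s$n_males >= 0 & s$n_hermaphrodites >= 0))
  expect_equal(s$male_fraction, s$n_males / (s$n_males + s$n_hermaphrodites))
  expect_identical(s, simulate_sex_ratio(p, 500, 500, 12, seed = 3, cap = 2000))
})

test_that("with mating disabled the male fraction settles at the selfing rate", {
  p <- mating_system_params(encounter_efficacy = 0, selfing_male_rate = 0.002)
  s <- simulate_sex_ratio(p, n_hermaphrodites = 20000, n_males = 0,
                          generations = 20, seed = 8, cap = 20000)
  frac <- s$male_fraction[s$generation >= 1]
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.002), 3 * max(se, 1e-5))
})

test_that("saturated mating with r = 1 holds the Mendelian 50% equilibrium", {
  p <- mating_system_params(relative_progeny_factor = 1,
                            encounter_efficacy = 1e6)
  s <- simulate_sex_ratio(p, n_hermaphrodites = 10000, n_males = 10000,
                          generations = 15, seed = 13, cap = 20000)
  expect_true(all(abs(s$male_fraction - 0.5) < 0.02))
})

test_that("the mean-field recursion reduces to the geometric model in the scarce-male limit", {
  # c = 2, no selfing males: the expected step is m -> r * m / (1 - m) * ...
  # whose linearisation at small m is exactly m -> r * m
  p <- mating_system_params(relative_progeny_factor = 0.768,
                            encounter_efficacy = 2, selfing_male_rate = 0)
  mf <- expected_sex_ratio(p, 6, m0 = 1e-4)
  geom <- 1e-4 * 0.768^(0:6)
  expect_equal(mf$male_fraction, geom, tolerance = 1e-3)
})

test_that("extinction truncates the trajectory with an explicit flag", {
  p <- mating_system_params(selfing_male_rate = 0, encounter_efficacy = 0,
                            brood_size = 0)
  s <- simulate_sex_ratio(p, n_hermaphrodites = 5, n_males = 0,
                          generations = 10, seed = 2, cap = 100)
  expect_true(all(s$extinct))
  expect_lt(max(s$generation), 10)
})
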