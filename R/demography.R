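#' Mating-system parameters
#'
#' Bundles the parameters of the androdioecious mating-system model. The key
#' quantity is the relative progeny factor `r`: the ratio of expected total
#' cross progeny sired by pheromone-exposed males to that of control males
#' over the mating window. Under the generational bookkeeping this factor
#' multiplies the male fraction once per generation,
#' `m_X = m0 * r^X`.
#'
#' @param relative_progeny_factor `r` in (0, 1]; the printed value for
#'   lifelong pheromone exposure is 0.768.
#' @param selfing_male_rate Probability a self-progeny is male via
#'   spontaneous X nondisjunction (default 0.002).
#' @param cross_male_rate Probability a cross-progeny is male (default 0.5).
#' @param encounter_efficacy Scale `c` of the per-hermaphrodite mating
#'   probability `min(1, c * M / H)`; `c = 0` disables mating. The default
#'   10 is near-saturating at balanced sex ratios and male-limited when
#'   males are scarce; the encounter model is a free parameter of the
#'   stochastic extension, not a measured quantity.
#' @param initial_male_fraction `m0`, the starting male fraction (default
#'   0.5, the cross-progeny expectation).
#' @param brood_size Offspring per hermaphrodite per generation in the
#'   stochastic model (default 238, the printed self-brood mean; pheromone
#'   does not change hermaphrodite brood size).
#'
#' @return A list of class `mating_system_params`.
#' @export
#' @examples
#' mating_system_params()                            # control-like defaults
#' mating_system_params(relative_progeny_factor = 0.768)
mating_system_params <- function(relative_progeny_factor = 1,
                                 selfing_male_rate = 0.002,
                                 cross_male_rate = 0.5,
                                 encounter_efficacy = 10,
                                 initial_male_fraction = 0.5,
                                 brood_size = 238) {
  check_number(relative_progeny_factor, "relative_progeny_factor",
               min = 0, max = 1, strict_min = TRUE)
  check_number(selfing_male_rate, "selfing_male_rate", min = 0, max = 1)
  check_number(cross_male_rate, "cross_male_rate", min = 0, max = 1)
  check_number(encounter_efficacy, "encounter_efficacy", min = 0)
  check_number(initial_male_fraction, "initial_male_fraction", min = 0, max = 1)
  check_number(brood_size, "brood_size", min = 0)
  structure(
    list(relative_progeny_factor = relative_progeny_factor,
         selfing_male_rate = selfing_male_rate,
         cross_male_rate = cross_male_rate,
         encounter_efficacy = encounter_efficacy,
         initial_male_fraction = initial_male_fraction,
         brood_size = brood_size),
    class = "mating_system_params"
  )
}

#' Relative progeny factor from fertility schedules
#'
#' Progeny bookkeeping over the male mating window: a fixed pool of `n_males`
#' males each has an equal chance of mating every day of the window (no male
#' attrition inside the window), so the expected total progeny of a condition
#' is `sum_d n_males * f_d * k_d` with `f_d` the fraction of males fertile on
#' day `d` and `k_d` the expected progeny per successful mating. The relative
#' progeny factor is the treated total divided by the control total; it is
#' invariant to rescaling `n_males` or multiplying all progeny counts by a
#' constant.
#'
#' @param schedules A fertility-schedule tibble as returned by
#'   [gen_fertility_schedules()]: columns `condition`, `day`,
#'   `fraction_fertile`, `progeny_per_mating`.
#' @param n_males Starting male count (default 60). Cancels in the ratio but
#'   is kept so per-condition totals are on the bookkeeping's scale.
#' @param days Mating window (default days 1-6 of adulthood).
#' @param ctrl,trt Condition labels for the numerator's reference and the
#'   treated group.
#'
#' @return A one-row tibble: `total_ctrl`, `total_trt`, `r`.
#' @export
#' @examples
#' sched <- gen_fertility_schedules()
#' relative_progeny_factor(sched)
relative_progeny_factor <- function(schedules, n_males = 60, days = 1:6,
                                    ctrl = "ctrl", trt = "trt") {
  check_number(n_males, "n_males", min = 1)
  needed <- c("condition", "day", "fraction_fertile", "progeny_per_mating")
  if (!is.data.frame(schedules) || !all(needed %in% names(schedules))) {
    abort("`schedules` must have columns condition, day, fraction_fertile, progeny_per_mating.",
          class = "androdyn_parameter_error")
  }
  total_for <- function(label) {
    sub <- schedules[schedules$condition == label & schedules$day %in% days, ]
    if (!all(days %in% sub$day)) {
      abort(sprintf("Condition '%s' does not cover the full mating window.", label),
            class = "androdyn_parameter_error")
    }
    sum(n_males * sub$fraction_fertile * sub$progeny_per_mating)
  }
  total_ctrl <- total_for(ctrl)
  total_trt <- total_for(trt)
  if (total_ctrl <= 0) {
    abort("Control schedule yields zero expected progeny; factor undefined.",
          class = "androdyn_undefined_factor_error")
  }
  tibble(total_ctrl = total_ctrl, total_trt = total_trt,
         r = total_trt / total_ctrl)
}

#' Deterministic male-fraction trajectory
#'
#' The geometric recursion at the heart of the generational model: starting
#' from male fraction `m0`, every generation of pheromone exposure multiplies
#' the male fraction by the relative progeny factor, `m_X = m0 * r^X`. With
#' `r = 1` (control) the curve is constant at `m0`.
#'
#' @param r Relative progeny factor in (0, 1].
#' @param generations Last generation index `X` to compute (>= 0).
#' @param m0 Starting male fraction (default 0.5).
#'
#' @return A tibble of class `sex_ratio_trajectory` with columns
#'   `generation` (0...`generations`) and `male_fraction`.
#' @seealso [generations_to_threshold()], [simulate_sex_ratio()]
#' @export
#' @examples
#' male_fraction_trajectory(0.768, 15)
male_fraction_trajectory <- function(r, generations, m0 = 0.5) {
  check_number(r, "r", min = 0, max = 1, strict_min = TRUE)
  generations <- check_count(generations, "generations")
  check_number(m0, "m0", min = 0, max = 1)
  gen <- 0:generations
  out <- tibble(generation = gen, male_fraction = m0 * r^gen)
  class(out) <- c("sex_ratio_trajectory", class(out))
  out
}

#' Generations until the population is primarily hermaphroditic
#'
#' Smallest generation index `X` at which the deterministic male fraction
#' `m0 * r^X` first falls below `threshold`. Computed by iterating the
#' recursion; the result coincides with the closed form
#' `ceiling(log(threshold / m0) / log(r))`. The default threshold of 1%
#' males is the convention for "primarily hermaphroditic"; the 0.2%
#' spontaneous-male baseline is a stricter alternative.
#'
#' @inheritParams male_fraction_trajectory
#' @param threshold Male fraction defining "primarily hermaphroditic"
#'   (default 0.01); must satisfy `0 < threshold < m0`.
#'
#' @return Integer generation count.
#' @export
#' @examples
#' generations_to_threshold(0.768)   # 15 generations
generations_to_threshold <- function(r, threshold = 0.01, m0 = 0.5) {
  check_number(r, "r", min = 0, max = 1, strict_min = TRUE)
  check_number(m0, "m0", min = 0, max = 1, strict_min = TRUE)
  check_number(threshold, "threshold", min = 0, max = m0,
               strict_min = TRUE, strict_max = TRUE)
  if (r >= 1) {
    abort("With r >= 1 the male fraction never falls below the threshold.",
          class = "androdyn_never_reached_error")
  }
  x <- 0L
  m <- m0
  while (m >= threshold) {
    x <- x + 1L
    m <- m0 * r^x
  }
  x
}

# Mean-field counterpart of simulate_sex_ratio(): per-hermaphrodite mating
# probability q(m) = min(1, c m / (1 - m)) * r; expected next male fraction
# q * cross_male_rate + (1 - q) * selfing_male_rate. In the scarce-male limit
# with c = 2 and selfing_male_rate = 0 this reduces to m -> r m, i.e. the
# geometric recursion of male_fraction_trajectory().
#' Mean-field sex-ratio recursion of the stochastic mating model
#'
#' Iterates the expected-value recursion of [simulate_sex_ratio()]: each
#' hermaphrodite mates with probability `q = min(1, c * m / (1 - m)) * r`
#' (males are the scarce resource; treated males succeed at rate `r` relative
#' to control), mated hermaphrodites produce cross progeny (male with
#' probability `cross_male_rate`), unmated ones self (male with probability
#' `selfing_male_rate`), and every hermaphrodite contributes the same brood,
#' so the next male fraction is `q * cross_male_rate + (1 - q) *
#' selfing_male_rate`. This is the deterministic trajectory the stochastic
#' simulator fluctuates around at large population size; in the scarce-male
#' linearisation (small `m`, `c = 2`, no selfing males) it coincides with
#' the geometric `m0 * r^X`.
#'
#' @param params A [mating_system_params()] object.
#' @param generations Number of generations to iterate (>= 0).
#' @param m0 Starting male fraction; defaults to
#'   `params$initial_male_fraction`.
#'
#' @return A tibble of class `sex_ratio_trajectory` with `generation` and
#'   `male_fraction`.
#' @export
expected_sex_ratio <- function(params, generations, m0 = NULL) {
  stopifnot(inherits(params, "mating_system_params"))
  generations <- check_count(generations, "generations")
  m0 <- m0 %||% params$initial_male_fraction
  check_number(m0, "m0", min = 0, max = 1)
  m <- numeric(generations + 1L)
  m[1L] <- m0
  for (x in seq_len(generations)) {
    m[x + 1L] <- meanfield_step(m[x], params)
  }
  out <- tibble(generation = 0:generations, male_fraction = m)
  class(out) <- c("sex_ratio_trajectory", class(out))
  out
}

meanfield_step <- function(m, params) {
  if (m >= 1) {
    # no hermaphrodites left: no offspring; fraction is degenerate
    return(1)
  }
  q <- min(1, params$encounter_efficacy * m / (1 - m)) *
    params$relative_progeny_factor
  q * params$cross_male_rate + (1 - q) * params$selfing_male_rate
}

#' Stochastic discrete-generation mating-system simulation
#'
#' Simulates an androdioecious population through non-overlapping
#' generations. Each generation with `H` hermaphrodites and `M` males: every
#' hermaphrodite independently mates with probability
#' `min(1, c * M / H) * r` (the encounter term saturates when males are
#' plentiful; the relative progeny factor `r` scales treated males' mating
#' success, with `r = 1` for control). Mated hermaphrodites produce
#' `brood_size` cross offspring each (male with `cross_male_rate`); unmated
#' hermaphrodites self (`brood_size` offspring, male with
#' `selfing_male_rate`). The next generation is down-sampled without
#' replacement to at most `cap` animals. If a generation produces no
#' hermaphrodites the population cannot continue and the trajectory is
#' truncated with `extinct = TRUE`.
#'
#' @param params A [mating_system_params()] object; `r = 1` for control
#'   populations, e.g. 0.768 for lifelong pheromone exposure.
#' @param n_hermaphrodites,n_males Founding counts (total >= 1).
#' @param generations Number of generations to simulate.
#' @param seed Integer RNG seed.
#' @param cap Maximum population per generation (>= founding total).
#'
#' @return A tibble of class `sex_ratio_trajectory`: `generation`,
#'   `n_males`, `n_hermaphrodites`, `male_fraction`, `extinct`.
#' @export
#' @examples
#' p <- mating_system_params(relative_progeny_factor = 0.768)
#' simulate_sex_ratio(p, n_hermaphrodites = 500, n_males = 500,
#'                    generations = 10, seed = 1, cap = 2000)
simulate_sex_ratio <- function(params, n_hermaphrodites, n_males, generations,
                               seed, cap = 10000) {
  stopifnot(inherits(params, "mating_system_params"))
  n_hermaphrodites <- check_count(n_hermaphrodites, "n_hermaphrodites")
  n_males <- check_count(n_males, "n_males")
  generations <- check_count(generations, "generations")
  cap <- check_count(cap, "cap", min = 1L)
  if (n_hermaphrodites + n_males < 1L) {
    abort("The founding population must contain at least one animal.",
          class = "androdyn_parameter_error")
  }
  if (cap < n_hermaphrodites + n_males) {
    abort("`cap` must be at least the founding population size.",
          class = "androdyn_parameter_error")
  }

  with_seed(seed, {
    H <- n_hermaphrodites
    M <- n_males
    gen <- 0:generations
    out_m <- integer(generations + 1L)
    out_h <- integer(generations + 1L)
    out_m[1L] <- M
    out_h[1L] <- H
    extinct <- FALSE
    last <- generations
    for (x in seq_len(generations)) {
      if (H == 0L) {
        extinct <- TRUE
        last <- x - 1L
        break
      }
      q <- min(1, params$encounter_efficacy * M / H) *
        params$relative_progeny_factor
      n_mated <- rbinom(1L, H, q)
      n_cross <- round(n_mated * params$brood_size)
      n_self <- round((H - n_mated) * params$brood_size)
      male_cross <- if (n_cross > 0) rbinom(1L, n_cross, params$cross_male_rate) else 0L
      male_self <- if (n_self > 0) rbinom(1L, n_self, params$selfing_male_rate) else 0L
      males_next <- male_cross + male_self
      herms_next <- (n_cross + n_self) - males_next
      total <- males_next + herms_next
      if (total == 0L) {
        extinct <- TRUE
        last <- x - 1L
        break
      }
      if (total > cap) {
        males_next <- rhyper(1L, males_next, herms_next, cap)
        herms_next <- cap - males_next
      }
      M <- as.integer(males_next)
      H <- as.integer(herms_next)
      out_m[x + 1L] <- M
      out_h[x + 1L] <- H
    }
    keep <- seq_len(last + 1L)
    out <- tibble(
      generation = gen[keep],
      n_males = out_m[keep],
      n_hermaphrodites = out_h[keep],
      male_fraction = out_m[keep] / pmax(out_m[keep] + out_h[keep], 1L),
      extinct = extinct
    )
    class(out) <- c("sex_ratio_trajectory", class(out))
    out
  })
}

#' Days to reach a male-fraction threshold
#'
#' Converts a trajectory's generations-to-threshold into days, using the
#' species' generation time. The default of 3 days per generation makes the
#' benchmark interval of 12-20 days for male disappearance correspond to
#' 4-7 generations.
#'
#' @param trajectory A `sex_ratio_trajectory` tibble (deterministic or
#'   simulated).
#' @param threshold Male fraction defining "primarily hermaphroditic"
#'   (default 0.01).
#' @param days_per_generation Generation time in days (default 3).
#'
#' @return A one-row tibble: `reached` (logical), `generation` (first
#'   generation with male fraction below the threshold; `NA` if never) and
#'   `days`.
#' @export
#' @examples
#' traj <- male_fraction_trajectory(0.768, 20)
#' compare_to_benchmark(traj)   # 15 generations = 45 days
compare_to_benchmark <- function(trajectory, threshold = 0.01,
                                 days_per_generation = 3) {
  if (!is.data.frame(trajectory) ||
      !all(c("generation", "male_fraction") %in% names(trajectory))) {
    abort("`trajectory` must have columns generation and male_fraction.",
          class = "androdyn_parameter_error")
  }
  check_number(threshold, "threshold", min = 0, max = 1, strict_min = TRUE)
  check_number(days_per_generation, "days_per_generation", min = 0,
               strict_min = TRUE)
  below <- which(trajectory$male_fraction < threshold)
  if (length(below) == 0L) {
    return(tibble(reached = FALSE, generation = NA_integer_, days = NA_real_))
  }
  g <- trajectory$generation[min(below)]
  tibble(reached = TRUE, generation = as.integer(g),
         days = g * days_per_generation)
}
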