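#' Gompertz hazard parameters
#'
#' Container for the two-parameter ageing hazard `h(t) = a * exp(b * t)`
#' used to generate worm lifespans: `baseline_rate` (`a`, the per-day hazard
#' at day 0) and `aging_rate` (`b`, the exponential acceleration of mortality
#' with age). `b = 0` recovers a constant-hazard (exponential) lifespan with
#' mean `1/a`, which is convenient for analytic checks.
#'
#' @param baseline_rate Per-day hazard at day 0; must be > 0.
#' @param aging_rate Exponential hazard acceleration per day; must be >= 0.
#'
#' @return A list of class `hazard_params` with elements `baseline_rate` and
#'   `aging_rate`.
#' @seealso [calibrate_hazard()], [gen_survival_cohort()]
#' @export
#' @examples
#' hazard_params(0.1, 0)        # exponential, mean lifespan 10 d
#' hazard_params(0.02, 0.25)    # accelerating Gompertz mortality
hazard_params <- function(baseline_rate, aging_rate = 0) {
  check_number(baseline_rate, "baseline_rate", min = 0, strict_min = TRUE)
  check_number(aging_rate, "aging_rate", min = 0)
  structure(list(baseline_rate = baseline_rate, aging_rate = aging_rate),
            class = "hazard_params")
}

# Theoretical mean lifespan under h(t) = a exp(b t): integral of the survival
# function S(t) = exp(-(a/b)(exp(bt) - 1)); closed form 1/a at b = 0.
gompertz_mean <- function(hazard) {
  a <- hazard$baseline_rate
  b <- hazard$aging_rate
  if (b == 0) {
    return(1 / a)
  }
  surv <- function(t) exp(-(a / b) * (exp(b * t) - 1))
  integrate(surv, 0, Inf, rel.tol = 1e-10)$value
}

# Inverse-CDF draw of n Gompertz lifespans.
gompertz_sample <- function(n, hazard) {
  a <- hazard$baseline_rate
  b <- hazard$aging_rate
  u <- runif(n)
  if (b == 0) {
    -log(u) / a
  } else {
    log1p(-(b / a) * log(u)) / b
  }
}

#' Calibrate a Gompertz hazard to a target mean lifespan
#'
#' Finds the baseline hazard `a` such that the theoretical mean lifespan of
#' `h(t) = a * exp(b * t)` equals `target_mean`, with the ageing rate `b`
#' held fixed. Lets cohorts be generated whose expected mean matches a
#' printed group mean (e.g. 12.0 d for solitary males, 7.7 d for males
#' grouped eight per plate).
#'
#' The mean is computed by quadrature on the survival function and the root
#' found with [stats::uniroot()] to an absolute tolerance of 1e-9 days, so
#' the returned parameters reproduce `target_mean` to well within 1e-6.
#'
#' @param target_mean Desired mean lifespan in days; must be > 0.
#' @param aging_rate Fixed exponential acceleration `b` (per day); >= 0.
#'
#' @return A `hazard_params` object whose theoretical mean is `target_mean`.
#' @export
#' @examples
#' calibrate_hazard(10, aging_rate = 0)    # baseline_rate = 0.1 exactly
#' calibrate_hazard(12, aging_rate = 0.2)
calibrate_hazard <- function(target_mean, aging_rate = 0) {
  check_number(target_mean, "target_mean", min = 0, strict_min = TRUE)
  check_number(aging_rate, "aging_rate", min = 0)
  if (aging_rate == 0) {
    return(hazard_params(1 / target_mean, 0))
  }
  objective <- function(log_a) {
    gompertz_mean(hazard_params(exp(log_a), aging_rate)) - target_mean
  }
  root <- tryCatch(
    uniroot(objective, lower = log(1e-8), upper = log(1e4), tol = 1e-9),
    error = function(e) {
      abort(sprintf("Cannot calibrate a hazard with mean %g d at aging_rate %g.",
                    target_mean, aging_rate),
            class = "androdyn_calibration_error")
    }
  )
  hazard_params(exp(root$root), aging_rate)
}

#' Generate a synthetic survival cohort
#'
#' Draws `n` per-animal lifespans from a Gompertz-type hazard and returns
#' them in the per-worm survival schema used throughout the package (one row
#' per animal: `animal_id`, `group`, `day`, `event`). Death days are
#' continuous (fractional days of adulthood). Animals surviving past
#' `censor_day` are recorded at `censor_day` with `event = FALSE`; by default
#' no censoring is applied, matching assays that follow every animal to
#' death.
#'
#' @param n Number of animals (>= 1).
#' @param hazard A [hazard_params()] object (or the output of
#'   [calibrate_hazard()]).
#' @param group Group label attached to every record.
#' @param censor_day Optional administrative censoring day (> 0).
#' @param seed Integer RNG seed; required, so cohorts are reproducible.
#'
#' @return A tibble with columns `animal_id` (character), `group`
#'   (character), `day` (double, > 0) and `event` (logical; `TRUE` = death).
#' @export
#' @examples
#' h <- calibrate_hazard(12, aging_rate = 0.2)
#' gen_survival_cohort(40, h, group = "solitary", seed = 1)
gen_survival_cohort <- function(n, hazard, group = "cohort",
                                censor_day = NULL, seed) {
  n <- check_count(n, "n", min = 1L)
  if (!inherits(hazard, "hazard_params")) {
    hazard <- hazard_params(hazard$baseline_rate, hazard$aging_rate)
  }
  if (!is.null(censor_day)) {
    check_number(censor_day, "censor_day", min = 0, strict_min = TRUE)
  }
  days <- with_seed(seed, gompertz_sample(n, hazard))
  event <- rep(TRUE, n)
  if (!is.null(censor_day)) {
    censored <- days > censor_day
    days[censored] <- censor_day
    event[censored] <- FALSE
  }
  tibble(
    animal_id = paste0(group, "_", seq_len(n)),
    group = as.character(group),
    day = days,
    event = event
  )
}

#' Build per-day male fertility schedules for two conditions
#'
#' Expands sparse printed anchors (fraction of males fertile on given days,
#' expected progeny per successful mating) into contiguous per-day schedules
#' for a control and a pheromone-treated condition, by linear interpolation
#' between anchors. Day 1 fertility defaults to 1.0 when not anchored
#' (young adult males are assumed fully fertile); values beyond the last
#' anchor are held constant; fractions are clipped to \[0, 1\].
#'
#' The default anchors are the printed fertility fractions for the
#' male-conditioned-plate experiment: control 82% fertile on Day 4 and 69%
#' on Day 6, versus 69% and 29% under lifelong pheromone exposure. Per-day
#' progeny counts are not printed anywhere, so the default progeny anchors
#' are illustrative placeholders (equal across conditions); override them
#' when real counts are available.
#'
#' @param ctrl_anchors,trt_anchors Named numeric vectors mapping day ->
#'   fraction fertile (values in \[0, 1\]); names are day indices.
#' @param progeny_anchors,trt_progeny_anchors Named numeric vectors mapping
#'   day -> expected progeny per successful mating (>= 0). `trt_progeny_anchors`
#'   defaults to the control anchors.
#' @param days Contiguous integer vector of adulthood days to cover.
#'
#' @return A tibble with columns `condition` (`"ctrl"`/`"trt"`), `day`,
#'   `fraction_fertile` and `progeny_per_mating`.
#' @seealso [relative_progeny_factor()]
#' @export
#' @examples
#' sched <- gen_fertility_schedules()
#' sched[sched$day == 5, ]   # midpoint of the Day 4 / Day 6 anchors
gen_fertility_schedules <- function(ctrl_anchors = c("4" = 0.82, "6" = 0.69),
                                    trt_anchors = c("4" = 0.69, "6" = 0.29),
                                    progeny_anchors = c("1" = 40, "6" = 40),
                                    trt_progeny_anchors = progeny_anchors,
                                    days = 1:6) {
  if (length(days) == 0L || any(diff(sort(days)) != 1L)) {
    abort("`days` must be a non-empty contiguous range.",
          class = "androdyn_parameter_error")
  }
  days <- sort(as.integer(days))
  one <- function(frac_anchors, prog_anchors, condition) {
    tibble(
      condition = condition,
      day = days,
      fraction_fertile = interp_anchors(frac_anchors, days, default_day1 = 1,
                                        lo = 0, hi = 1),
      progeny_per_mating = interp_anchors(prog_anchors, days, default_day1 = NULL,
                                          lo = 0, hi = Inf)
    )
  }
  bind_rows(one(ctrl_anchors, progeny_anchors, "ctrl"),
            one(trt_anchors, trt_progeny_anchors, "trt"))
}

interp_anchors <- function(anchors, days, default_day1, lo, hi) {
  if (is.null(names(anchors)) || any(names(anchors) == "")) {
    abort("Anchor vectors must be named by day, e.g. c(`4` = 0.82).",
          class = "androdyn_parameter_error")
  }
  x <- as.numeric(names(anchors))
  y <- as.numeric(anchors)
  if (any(y < lo) || any(y > hi)) {
    abort(sprintf("Anchor values must lie in [%g, %g].", lo, hi),
          class = "androdyn_parameter_error")
  }
  if (!is.null(default_day1) && !1 %in% x) {
    x <- c(1, x)
    y <- c(default_day1, y)
  }
  ord <- order(x)
  out <- approx(x[ord], y[ord], xout = days, rule = 2)$y
  pmin(pmax(out, lo), hi)
}

#' Simulate one chemotaxis plate
#'
#' Places `n_worms` at the origin of a plate and draws their final locations
#' from a multinomial over four destinations: the test (supernatant) spot,
#' the control spot, the origin (never moved), and elsewhere on the plate
#' (the remainder probability). Counts always sum to `n_worms`.
#'
#' @param n_worms Worms placed at the origin (>= 0).
#' @param p_super,p_ctrl,p_origin Probabilities of ending at the supernatant
#'   spot, the control spot, or staying at the origin. Must be >= 0 and sum
#'   to at most 1; the remainder is "elsewhere".
#' @param seed Integer RNG seed.
#'
#' @return A one-row tibble with columns `n_super`, `n_ctrl`, `n_origin`,
#'   `n_total`.
#' @seealso [gen_chemotaxis_plates()] for many plates, [chemotaxis_index()]
#' @export
#' @examples
#' gen_chemotaxis_plate(30, p_super = 0.5, p_ctrl = 0.2, p_origin = 0.1, seed = 7)
gen_chemotaxis_plate <- function(n_worms, p_super, p_ctrl, p_origin, seed) {
  plates <- gen_chemotaxis_plates(1L, n_worms, p_super, p_ctrl, p_origin, seed)
  plates[, c("n_super", "n_ctrl", "n_origin", "n_total")]
}

#' Simulate a batch of chemotaxis plates
#'
#' Vectorised version of [gen_chemotaxis_plate()]: draws `n_plates`
#' independent multinomial plates under one seed.
#'
#' @inheritParams gen_chemotaxis_plate
#' @param n_plates Number of plates (>= 1).
#' @param group Optional group label column value.
#'
#' @return A tibble with one row per plate: `plate_id`, `group`, `n_super`,
#'   `n_ctrl`, `n_origin`, `n_total`.
#' @export
gen_chemotaxis_plates <- function(n_plates, n_worms, p_super, p_ctrl, p_origin,
                                  seed, group = "group") {
  n_plates <- check_count(n_plates, "n_plates", min = 1L)
  n_worms <- check_count(n_worms, "n_worms", min = 0L)
  check_number(p_super, "p_super", min = 0, max = 1)
  check_number(p_ctrl, "p_ctrl", min = 0, max = 1)
  check_number(p_origin, "p_origin", min = 0, max = 1)
  if (p_super + p_ctrl + p_origin > 1 + 1e-12) {
    abort("p_super + p_ctrl + p_origin must not exceed 1.",
          class = "androdyn_parameter_error")
  }
  p <- c(p_super, p_ctrl, p_origin, max(0, 1 - p_super - p_ctrl - p_origin))
  counts <- if (n_worms == 0L) {
    matrix(0L, nrow = 4L, ncol = n_plates)
  } else {
    with_seed(seed, rmultinom(n_plates, n_worms, p))
  }
  tibble(
    plate_id = paste0(group, "_", seq_len(n_plates)),
    group = as.character(group),
    n_super = counts[1L, ],
    n_ctrl = counts[2L, ],
    n_origin = counts[3L, ],
    n_total = as.integer(n_worms)
  )
}

#' Draw offspring sexes under selfing or outcrossing
#'
#' In androdioecious *Caenorhabditis*, hermaphrodite self-progeny are male
#' only through spontaneous X-chromosome nondisjunction (about 0.2% in the
#' N2 lab strain), whereas cross-progeny inherit the paternal X or no X with
#' equal probability and are therefore 50% male. Each offspring is drawn
#' independently as male with the mode's probability.
#'
#' @param n Number of offspring (>= 0).
#' @param mode `"selfing"` or `"cross"`.
#' @param nondisjunction_rate Per-offspring male probability under selfing
#'   (default 0.002).
#' @param seed Integer RNG seed.
#'
#' @return A one-row tibble: `mode`, `n`, `n_male`, `n_hermaphrodite`,
#'   `male_fraction`. Counts always sum to `n`.
#' @export
#' @examples
#' gen_offspring_sexes(1e5, "selfing", seed = 1)
#' gen_offspring_sexes(1e5, "cross", seed = 1)
gen_offspring_sexes <- function(n, mode = c("selfing", "cross"),
                                nondisjunction_rate = 0.002, seed) {
  mode <- match.arg(mode)
  n <- check_count(n, "n", min = 0L)
  check_number(nondisjunction_rate, "nondisjunction_rate", min = 0, max = 1)
  p_male <- if (mode == "selfing") nondisjunction_rate else 0.5
  n_male <- if (n == 0L) 0L else with_seed(seed, rbinom(1L, n, p_male))
  tibble(
    mode = mode,
    n = n,
    n_male = as.integer(n_male),
    n_hermaphrodite = as.integer(n - n_male),
    male_fraction = if (n == 0L) NA_real_ else n_male / n
  )
}

#' Read or write the per-worm survival CSV schema
#'
#' The on-disk schema is one row per animal with columns `animal_id`,
#' `group`, `day` (event or censoring day of adulthood, fractional allowed)
#' and `event` (1/TRUE = death, 0/FALSE = censored).
#'
#' @param path File path.
#' @param records A survival-record data frame (see [gen_survival_cohort()]).
#' @return `read_survival_csv()` returns a validated tibble;
#'   `write_survival_csv()` invisibly returns `records`.
#' @export
read_survival_csv <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE)
  check_survival_records(records)
}

#' @rdname read_survival_csv
#' @export
write_survival_csv <- function(records, path) {
  records <- check_survival_records(records)
  readr::write_csv(dplyr::mutate(records, event = as.integer(.data$event)), path)
  invisible(records)
}
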