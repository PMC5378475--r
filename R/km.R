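#' Kaplan-Meier product-limit estimator
#'
#' Estimates survival curves from per-worm event records, one curve per
#' group. At each distinct event day the at-risk count, deaths and censorings
#' are tallied with the standard tie convention that deaths at a day are
#' processed before censorings at the same day, and the survival probability
#' is the running product of `(n_i - d_i) / n_i`.
#'
#' With no censoring the estimate equals the empirical survival function
#' exactly, and its restricted mean equals the arithmetic mean of the death
#' days.
#'
#' @param records Data frame with columns `group`, `day` (> 0) and `event`
#'   (logical or 0/1; `TRUE` = death). An `animal_id` column is permitted and
#'   ignored.
#'
#' @return A tibble of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor` and `survival` (one row per group x
#'   distinct observed day).
#' @seealso [logrank_test()], [mean_lifespan()], [autoplot.km_curve()]
#' @export
#' @examples
#' rec <- tibble::tibble(group = "a", day = c(1, 2, 3, 4), event = TRUE)
#' km_estimate(rec)   # survival 0.75, 0.50, 0.25, 0
km_estimate <- function(records) {
  records <- check_survival_records(records)
  curves <- lapply(split(records, records$group), km_one_group)
  out <- bind_rows(curves)
  class(out) <- c("km_curve", class(out))
  out
}

km_one_group <- function(records) {
  tab <- records |>
    group_by(day = .data$day) |>
    summarise(n_event = sum(.data$event),
              n_censor = sum(!.data$event),
              .groups = "drop") |>
    arrange(.data$day)
  n <- nrow(records)
  # at risk just before each day; deaths and censorings at earlier days have left
  removed <- cumsum(tab$n_event + tab$n_censor)
  n_risk <- n - c(0, head(removed, -1))
  survival <- cumprod((n_risk - tab$n_event) / n_risk)
  tibble(
    group = records$group[[1L]],
    time = tab$day,
    n_risk = as.integer(n_risk),
    n_event = as.integer(tab$n_event),
    n_censor = as.integer(tab$n_censor),
    survival = survival
  )
}

# Restricted mean survival time up to the largest event time: the area under
# the KM step function. Returns mean and its Greenwood-type standard error.
km_restricted_mean <- function(curve) {
  dth <- curve[curve$n_event > 0L, ]
  if (nrow(dth) == 0L) {
    abort("Restricted mean is undefined without any death event.",
          class = "androdyn_data_error")
  }
  tmax <- max(dth$time)
  keep <- curve$time <= tmax
  times <- c(0, curve$time[keep])
  surv <- c(1, curve$survival[keep])
  rmean <- sum(surv[-length(surv)] * diff(times))
  # variance: sum over death times of A_j^2 d_j / (n_j (n_j - d_j)),
  # A_j the area under the curve from t_j to tmax
  areas <- rev(cumsum(rev(surv[-1] * diff(c(times[-1], tmax)))))
  idx <- which(keep & curve$n_event > 0L)
  a <- areas[match(curve$time[idx], curve$time[keep])]
  d <- curve$n_event[idx]
  nr <- curve$n_risk[idx]
  terms <- ifelse(nr - d > 0, a^2 * d / (nr * (nr - d)), 0)
  list(rmean = rmean, se = sqrt(sum(terms)))
}

#' Mean lifespan per group, with standard error
#'
#' Summarises per-worm survival records as mean +/- SE per group, the format
#' used in lifespan figure legends (e.g. "12.0 +/- 0.4 days, n = 40"). With
#' no censoring the summary is the arithmetic mean of death days with
#' SE = sd/sqrt(n). When a group contains censored records the arithmetic
#' mean is biased, so the Kaplan-Meier restricted mean up to the last death
#' (with its Greenwood-type SE) is reported instead; the `method` column
#' records which estimator was used.
#'
#' @inheritParams km_estimate
#'
#' @return A tibble with columns `group`, `mean`, `se`, `n`, `n_event`,
#'   `method` (`"arithmetic"` or `"km_restricted"`).
#' @export
#' @examples
#' rec <- tibble::tibble(group = "a", day = c(10, 14), event = TRUE)
#' mean_lifespan(rec)   # mean 12, se 2
mean_lifespan <- function(records) {
  records <- check_survival_records(records)
  one <- function(grp) {
    n <- nrow(grp)
    n_event <- sum(grp$event)
    if (n_event == 0L) {
      abort(sprintf("Group '%s' has no death events; mean lifespan undefined.",
                    grp$group[[1L]]),
            class = "androdyn_data_error")
    }
    if (all(grp$event)) {
      tibble(group = grp$group[[1L]],
             mean = mean(grp$day),
             se = if (n > 1L) sd(grp$day) / sqrt(n) else 0,
             n = n, n_event = n_event, method = "arithmetic")
    } else {
      rm <- km_restricted_mean(km_one_group(grp))
      tibble(group = grp$group[[1L]],
             mean = rm$rmean, se = rm$se,
             n = n, n_event = n_event, method = "km_restricted")
    }
  }
  bind_rows(lapply(split(records, records$group), one))
}

#' Percent lifespan reduction between two groups
#'
#' Computes `100 * (1 - trt / ctrl)`, the percent by which a treatment
#' shortens mean lifespan relative to control. Accepts either two numeric
#' mean lifespans, or a [mean_lifespan()] summary table plus the two group
#' labels.
#'
#' @param ctrl Control mean lifespan (days, > 0), or a summary tibble with
#'   `group` and `mean` columns.
#' @param trt Treatment mean lifespan (days), or (when `ctrl` is a data
#'   frame) the treated group's label.
#' @param ctrl_group When `ctrl` is a data frame, the control group's label.
#'
#' @return A single number: the percent reduction (negative if the treated
#'   group lives longer).
#' @export
#' @examples
#' percent_reduction(12.0, 7.7)   # 35.8
#' percent_reduction(10.9, 6.8)   # 37.6
percent_reduction <- function(ctrl, trt, ctrl_group = NULL) {
  if (is.data.frame(ctrl)) {
    if (is.null(ctrl_group)) {
      abort("Supply `ctrl_group` when passing a summary table.",
            class = "androdyn_parameter_error")
    }
    means <- setNames(ctrl$mean, ctrl$group)
    if (!all(c(ctrl_group, trt) %in% names(means))) {
      abort("Group labels not found in the summary table.",
            class = "androdyn_parameter_error")
    }
    return(percent_reduction(means[[ctrl_group]], means[[trt]]))
  }
  check_number(ctrl, "ctrl", min = 0, strict_min = TRUE)
  check_number(trt, "trt")
  100 * (1 - trt / ctrl)
}
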