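#' Log-rank (Mantel-Cox) test
#'
#' Compares survival across two or more groups with the standard
#' observed-minus-expected statistic. At every distinct death time a
#' groups x (death/survive) contingency table is formed; under the null the
#' per-group deaths follow a (multivariate) hypergeometric distribution
#' conditional on the margins, giving the expected counts and the full
#' variance-covariance matrix. The statistic is the quadratic form
#' `(O - E)' V^{-1} (O - E)` over the first `k - 1` groups, referred to a
#' chi-square distribution with `k - 1` degrees of freedom; ties follow the
#' deaths-before-censorings convention.
#'
#' @inheritParams km_estimate
#'
#' @return An object of class `logrank_test`: a list with `chi_square`,
#'   `df`, `p_value` and a `by_group` tibble (`group`, `n`, `observed`,
#'   `expected`). Use [tidy()] for the per-group table and [glance()] for
#'   the one-row test summary.
#' @export
#' @examples
#' rec <- dplyr::bind_rows(
#'   tibble::tibble(group = "a", day = c(1, 2), event = TRUE),
#'   tibble::tibble(group = "b", day = c(3, 4), event = TRUE)
#' )
#' logrank_test(rec)
logrank_test <- function(records) {
  records <- check_survival_records(records)
  groups <- sort(unique(records$group))
  k <- length(groups)
  if (k < 2L) {
    abort("logrank_test() needs at least two groups.",
          class = "androdyn_data_error")
  }
  if (!any(records$event)) {
    abort("logrank_test() needs at least one death event.",
          class = "androdyn_data_error")
  }
  g <- match(records$group, groups)

  death_times <- sort(unique(records$day[records$event]))
  # n_at_risk[j, i]: group i animals with day >= t_j; d[j, i]: deaths at t_j
  n_at_risk <- vapply(groups, function(gr) {
    vapply(death_times, function(t) sum(records$day >= t & records$group == gr),
           numeric(1))
  }, numeric(length(death_times)))
  n_at_risk <- matrix(n_at_risk, nrow = length(death_times), ncol = k)
  d <- vapply(groups, function(gr) {
    vapply(death_times,
           function(t) sum(records$day == t & records$event & records$group == gr),
           numeric(1))
  }, numeric(length(death_times)))
  d <- matrix(d, nrow = length(death_times), ncol = k)

  n_tot <- rowSums(n_at_risk)
  d_tot <- rowSums(d)
  observed <- colSums(d)
  expected <- colSums(d_tot * n_at_risk / n_tot)

  # hypergeometric covariance of the per-group death counts, summed over times
  V <- matrix(0, k, k)
  mult <- ifelse(n_tot > 1, d_tot * (n_tot - d_tot) / (n_tot - 1), 0)
  p <- n_at_risk / n_tot
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      V[i, j] <- sum(mult * p[, i] * ((i == j) - p[, j]))
    }
  }

  oe <- (observed - expected)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(crossprod(oe, solve(Vk, oe))),
                  error = function(e) 0)
  chi <- max(chi, 0)
  df <- k - 1L
  structure(
    list(
      chi_square = chi,
      df = df,
      p_value = pchisq(chi, df, lower.tail = FALSE),
      by_group = tibble(
        group = groups,
        n = as.integer(table(factor(records$group, levels = groups))),
        observed = observed,
        expected = expected
      )
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank (Mantel-Cox) test\n")
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  print(x$by_group)
  invisible(x)
}

#' Tidy a log-rank test
#'
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-group tibble of sample sizes and
#'   observed/expected deaths; `glance()` returns a one-row tibble with
#'   `statistic`, `df`, `p.value` and `method`.
#' @export
tidy.logrank_test <- function(x, ...) {
  x$by_group
}

#' @rdname tidy.logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$chi_square, df = x$df, p.value = x$p_value,
         method = "log-rank (Mantel-Cox)")
}
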