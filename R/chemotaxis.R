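#' Chemotaxis index per plate
#'
#' Computes the chemotaxis index for each plate of a counts table:
#' `(n_super - n_ctrl) / (n_total - n_origin)` — worms at the test
#' (supernatant) spot minus worms at the control spot, over all scored worms
#' that left the origin. Worms neither at a destination nor at the origin
#' ("elsewhere" on the plate) count in the denominator through `n_total`.
#' The index lies in \[-1, 1\]; +1 means every scoring worm chose the
#' supernatant.
#'
#' @param plates Data frame with one row per plate and columns `n_super`,
#'   `n_ctrl`, `n_origin`, `n_total` (all counts >= 0,
#'   `n_super + n_ctrl + n_origin <= n_total`).
#'
#' @return The input tibble with a `ci` column appended.
#' @seealso [aggregate_ci()], [compare_ci()]
#' @export
#' @examples
#' plate <- tibble::tibble(n_super = 5, n_ctrl = 3, n_origin = 2, n_total = 10)
#' chemotaxis_index(plate)   # ci = 0.25
chemotaxis_index <- function(plates) {
  plates <- check_plates(plates)
  denom <- plates$n_total - plates$n_origin
  if (any(denom <= 0)) {
    abort("Chemotaxis index undefined: all worms remained at the origin on some plate.",
          class = "androdyn_undefined_index_error")
  }
  mutate(as_tibble(plates), ci = (.data$n_super - .data$n_ctrl) / denom)
}

check_plates <- function(plates) {
  needed <- c("n_super", "n_ctrl", "n_origin", "n_total")
  if (!is.data.frame(plates) || nrow(plates) == 0L ||
      !all(needed %in% names(plates))) {
    abort("`plates` must be a non-empty data frame with columns n_super, n_ctrl, n_origin, n_total.",
          class = "androdyn_data_error")
  }
  counts <- as.matrix(plates[needed])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Plate counts must be non-negative integers.",
          class = "androdyn_data_error")
  }
  if (any(plates$n_super + plates$n_ctrl + plates$n_origin > plates$n_total)) {
    abort("n_super + n_ctrl + n_origin cannot exceed n_total.",
          class = "androdyn_data_error")
  }
  plates
}

#' Aggregate chemotaxis indices across plates
#'
#' Mean chemotaxis index with its standard error across plates, the "CI =
#' mean +/- SEM, n plates" presentation used for assay results. The mean is
#' unweighted (each plate is one replicate regardless of worm count). For a
#' single plate the SEM is reported as 0 with a warning so pipelines remain
#' total.
#'
#' @param plates A plate counts table ([chemotaxis_index()] is applied if
#'   the `ci` column is absent).
#'
#' @return A one-row tibble: `mean_ci`, `sem`, `n_plates`.
#' @export
#' @examples
#' plates <- gen_chemotaxis_plates(12, 30, 0.5, 0.2, 0.1, seed = 3)
#' aggregate_ci(plates)
aggregate_ci <- function(plates) {
  if (!is.data.frame(plates) || nrow(plates) == 0L) {
    abort("`plates` must contain at least one plate.",
          class = "androdyn_data_error")
  }
  if (!"ci" %in% names(plates)) {
    plates <- chemotaxis_index(plates)
  }
  n <- nrow(plates)
  sem <- if (n == 1L) {
    warn("SEM of a single plate is undefined; reporting 0.")
    0
  } else {
    sd(plates$ci) / sqrt(n)
  }
  tibble(mean_ci = mean(plates$ci), sem = sem, n_plates = n)
}

#' Compare chemotaxis indices between two groups
#'
#' Two-sided comparison of per-plate chemotaxis indices between two groups,
#' either by unpaired t-test (see [unpaired_t_test()]) or by a label
#' permutation test on the difference of group means. The permutation test
#' enumerates all relabellings exactly when the total number of plates is at
#' most `exact_limit` (default 12); otherwise it samples `n_resamples`
#' random relabellings and reports the add-one p-value
#' `(1 + #{|diff*| >= |diff|}) / (1 + n_resamples)`.
#'
#' @param plates_a,plates_b Plate tables for the two groups (>= 2 plates
#'   each); `ci` is computed if absent.
#' @param method `"t"` or `"permutation"`.
#' @param n_resamples Random relabellings when not enumerating (default
#'   10000).
#' @param seed Integer RNG seed (required for the sampled permutation path).
#' @param exact_limit Enumerate exactly when
#'   `nrow(plates_a) + nrow(plates_b) <= exact_limit`.
#' @param welch Passed to [unpaired_t_test()] when `method = "t"`.
#'
#' @return A one-row tibble: `estimate` (mean CI difference, a minus b),
#'   `p_value`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' a <- gen_chemotaxis_plates(6, 30, 0.5, 0.2, 0.1, seed = 1, group = "a")
#' b <- gen_chemotaxis_plates(6, 30, 0.3, 0.3, 0.1, seed = 2, group = "b")
#' compare_ci(a, b, method = "permutation", seed = 9)
compare_ci <- function(plates_a, plates_b, method = c("t", "permutation"),
                       n_resamples = 10000, seed = NULL, exact_limit = 12,
                       welch = FALSE) {
  method <- match.arg(method)
  if (!"ci" %in% names(plates_a)) plates_a <- chemotaxis_index(plates_a)
  if (!"ci" %in% names(plates_b)) plates_b <- chemotaxis_index(plates_b)
  ci_a <- plates_a$ci
  ci_b <- plates_b$ci
  if (length(ci_a) < 2L || length(ci_b) < 2L) {
    abort("Each group needs at least two plates.",
          class = "androdyn_data_error")
  }
  est <- mean(ci_a) - mean(ci_b)
  if (method == "t") {
    fit <- unpaired_t_test(ci_a, ci_b, welch = welch)
    p <- fit$p_value
    used <- fit$method
  } else {
    res <- permutation_mean_diff(ci_a, ci_b, n_resamples, seed, exact_limit)
    p <- res$p_value
    used <- res$method
  }
  tibble(estimate = est, p_value = p, method = used,
         n_a = length(ci_a), n_b = length(ci_b))
}

permutation_mean_diff <- function(a, b, n_resamples, seed, exact_limit) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-12 * max(1, obs)
  if (n <= exact_limit) {
    idx <- combn(n, na)
    diffs <- apply(idx, 2L, function(i) {
      abs(mean(pooled[i]) - mean(pooled[-i]))
    })
    p <- mean(diffs >= obs - tol)
    return(list(p_value = p, method = "exact permutation"))
  }
  if (is.null(seed)) {
    abort("A `seed` is required for the sampled permutation test.",
          class = "androdyn_parameter_error")
  }
  diffs <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    take <- sample.int(n, na)
    abs(mean(pooled[take]) - mean(pooled[-take]))
  }, numeric(1)))
  p <- (1 + sum(diffs >= obs - tol)) / (1 + n_resamples)
  list(p_value = p, method = "sampled permutation")
}
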