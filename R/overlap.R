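#' Hypergeometric gene-list overlap test
#'
#' Tests whether two gene lists drawn from a common universe share more
#' members than expected by chance. Under the null that list B is a uniform
#' draw of `size_b` genes from the universe, the overlap with a fixed list A
#' of `size_a` genes is hypergeometric; the reported p-value is the upper
#' tail `P(X >= overlap)`.
#'
#' @param universe Number of genes in the universe.
#' @param size_a,size_b Sizes of the two lists (each <= `universe`).
#' @param overlap Observed shared count (<= `min(size_a, size_b)`).
#'
#' @return A one-row tibble: `universe`, `size_a`, `size_b`, `overlap`,
#'   `expected` (the null mean `size_a * size_b / universe`) and `p_value`.
#' @export
#' @examples
#' hypergeometric_overlap(universe = 4, size_a = 2, size_b = 2, overlap = 2)
#' # p = 1/6
hypergeometric_overlap <- function(universe, size_a, size_b, overlap) {
  universe <- check_count(universe, "universe", min = 1L)
  size_a <- check_count(size_a, "size_a")
  size_b <- check_count(size_b, "size_b")
  overlap <- check_count(overlap, "overlap")
  if (size_a > universe || size_b > universe) {
    abort("List sizes cannot exceed the universe.",
          class = "androdyn_parameter_error")
  }
  if (overlap > min(size_a, size_b)) {
    abort("`overlap` cannot exceed the smaller list size.",
          class = "androdyn_parameter_error")
  }
  if (overlap < size_a + size_b - universe) {
    abort("`overlap` is below the minimum forced by the list sizes.",
          class = "androdyn_parameter_error")
  }
  p <- phyper(overlap - 1, size_a, universe - size_a, size_b,
              lower.tail = FALSE)
  tibble(universe = universe, size_a = size_a, size_b = size_b,
         overlap = overlap, expected = size_a * size_b / universe,
         p_value = p)
}

#' Two-sample unpaired t-test
#'
#' Two-sided Student t-test for two independent groups, pooled-variance by
#' default with the Welch unequal-variance variant available (useful when
#' replicate-level variances differ). Results come as a one-row tidy tibble.
#'
#' Degenerate inputs are made total rather than erroring: when both groups
#' have zero variance, equal means give `statistic = 0, p_value = 1` and
#' unequal means give an infinite statistic with `p_value = 0`, each with a
#' warning.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch unequal-variance test instead of pooled
#'   variance? Default `FALSE` (pooled, df = n1 + n2 - 2).
#'
#' @return A one-row tibble: `estimate` (mean of `a` minus mean of `b`),
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' unpaired_t_test(rnorm(10), rnorm(10))
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least two values.",
          class = "androdyn_data_error")
  }
  method <- if (welch) "Welch two-sample t-test" else "pooled two-sample t-test"
  est <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) {
    if (est == 0) {
      warn("Zero variance in both groups with equal means; returning p = 1.")
      return(tibble(estimate = 0, statistic = 0,
                    df = length(a) + length(b) - 2, p_value = 1,
                    method = method))
    }
    warn("Zero variance in both groups with unequal means; returning p = 0.")
    return(tibble(estimate = est, statistic = sign(est) * Inf,
                  df = length(a) + length(b) - 2, p_value = 0,
                  method = method))
  }
  fit <- t.test(a, b, var.equal = !welch)
  tibble(estimate = est,
         statistic = unname(fit$statistic),
         df = unname(fit$parameter),
         p_value = fit$p.value,
         method = method)
}
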