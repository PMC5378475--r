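# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementations they check.

# Log-rank by explicit 2x2 (group x died/survived) tables at each death time;
# two groups only, chi-square from (O - E)^2 / V of the first group.
oracle_logrank_2g <- function(day_a, day_b, event_a = NULL, event_b = NULL) {
  event_a <- event_a %||% rep(TRUE, length(day_a))
  event_b <- event_b %||% rep(TRUE, length(day_b))
  times <- sort(unique(c(day_a[event_a], day_b[event_b])))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n_a <- sum(day_a >= t)
    n_b <- sum(day_b >= t)
    n <- n_a + n_b
    d_a <- sum(day_a == t & event_a)
    d_b <- sum(day_b == t & event_b)
    d <- d_a + d_b
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) {
      v <- v + d * (n - d) / (n - 1) * (n_a / n) * (1 - n_a / n)
    }
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# choose(universe, size_b) draws of list B; feasible for universe <= 12.
oracle_overlap_enum <- function(universe, size_a, size_b, k) {
  genes <- seq_len(universe)
  list_a <- seq_len(size_a)
  draws <- utils::combn(universe, size_b)
  overlaps <- apply(draws, 2L, function(b) length(intersect(b, list_a)))
  mean(overlaps >= k)
}

# Two-sided permutation p for a difference in means by bitmask enumeration of
# all subsets of the pooled values with |subset| = length(a).
oracle_perm_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  total <- 0L
  for (s in 0:(2^n - 1)) {
    members <- which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
    if (length(members) != na) next
    total <- total + 1L
    d <- abs(mean(pooled[members]) - mean(pooled[-members]))
    if (d >= obs - 1e-12 * max(1, obs)) hits <- hits + 1L
  }
  hits / total
}

# Mean lifespan under hazard a*exp(b*t) by quadrature on the survival
# function, written independently of the package's internals.
oracle_gompertz_mean <- function(a, b) {
  if (b == 0) return(1 / a)
  stats::integrate(function(t) exp(-(a / b) * expm1(b * t)), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Small uncensored cohort for reuse across tests.
make_records <- function(days, group = "g", event = TRUE) {
  tibble::tibble(group = group, day = days,
                 event = rep_len(event, length(days)))
}
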