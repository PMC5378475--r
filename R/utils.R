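# internal helpers shared across modules

# Run `code` under a private RNG stream; the caller's .Random.seed is untouched.
# seed must be a single finite integerish value.
with_seed <- function(seed, code) {
  check_seed(seed)
  withr::with_seed(as.integer(seed), code)
}

check_seed <- function(seed) {
  if (!rlang::is_scalar_integerish(seed) || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "androdyn_parameter_error")
  }
  invisible(seed)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    bounds <- paste0(if (strict_min) "(" else "[", min, ", ", max,
                     if (strict_max) ")" else "]")
    abort(sprintf("`%s` must be a single finite number in %s.", name, bounds),
          class = "androdyn_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!rlang::is_scalar_integerish(x) || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "androdyn_parameter_error")
  }
  invisible(as.integer(x))
}

check_survival_records <- function(records, arg = "records") {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort(sprintf("`%s` must be a non-empty data frame of survival records.", arg),
          class = "androdyn_data_error")
  }
  needed <- c("group", "day", "event")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing columns: %s.", arg,
                  paste(missing_cols, collapse = ", ")),
          class = "androdyn_data_error")
  }
  if (any(!is.finite(records$day)) || any(records$day <= 0)) {
    abort("`day` must be finite and > 0 (Day 1 is the first adult day).",
          class = "androdyn_data_error")
  }
  if (!is.logical(records$event) && !all(records$event %in% c(0, 1))) {
    abort("`event` must be logical or 0/1 (1 = death, 0 = censored).",
          class = "androdyn_data_error")
  }
  records$event <- as.logical(records$event)
  records
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, returned as
# 8 hex digits. Used to fingerprint run configurations; not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) {
    h <- (h * 257 + b + 1) %% 2147483647
  }
  sprintf("%08x", h)
}
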