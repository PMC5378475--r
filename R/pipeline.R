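#' Validate a run configuration
#'
#' Checks a pipeline configuration (a list, or a path to a JSON file) against
#' the schema used by [run_pipeline()] and returns every violation found,
#' as a tibble with one row per issue. An empty tibble means the
#' configuration is valid.
#'
#' The schema (version 1) is a JSON object with fields `version`, `seed`
#' (integer; required whenever a stochastic stage is configured) and
#' `stages`, an object with any of:
#' \describe{
#'   \item{`survival`}{`cohorts`: array of `{group, n, target_mean,
#'     aging_rate}`; cohorts are generated, Kaplan-Meier estimated, log-rank
#'     tested and summarised, and the percent lifespan reduction of every
#'     cohort against the first (the control) is reported.}
#'   \item{`demography`}{`r`: array of relative progeny factors (one
#'     trajectory each; 1 = control), `m0`, `generations`, `threshold`,
#'     `days_per_generation`.}
#'   \item{`chemotaxis`}{`groups`: array of `{group, n_plates, n_worms,
#'     p_super, p_ctrl, p_origin}`; plates are generated and aggregated, and
#'     the first two groups compared with the configured `method`.}
#' }
#'
#' @param config A named list, or a path to a JSON configuration file.
#'
#' @return A tibble with columns `field` and `issue`; zero rows when valid.
#' @export
#' @examples
#' cfg <- system.file("extdata", "default_config.json", package = "androdyn")
#' validate_config(cfg)   # 0 issues
validate_config <- function(config) {
  config <- load_config(config)
  issues <- list()
  note <- function(field, issue) {
    issues[[length(issues) + 1L]] <<- tibble(field = field, issue = issue)
  }
  bad_number <- function(x, lo = -Inf, hi = Inf) {
    !is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi
  }

  stages <- config$stages
  if (is.null(stages) || !is.list(stages) || length(stages) == 0L) {
    note("stages", "at least one stage must be configured")
    stages <- list()
  }
  unknown <- setdiff(names(stages), c("survival", "demography", "chemotaxis"))
  for (s in unknown) note(paste0("stages.", s), "unknown stage name")

  stochastic <- any(c("survival", "chemotaxis") %in% names(stages))
  if (stochastic &&
      (is.null(config$seed) || !rlang::is_scalar_integerish(config$seed))) {
    note("seed", "an integer seed is required for stochastic stages")
  }

  surv <- stages$survival
  if (!is.null(surv)) {
    cohorts <- surv$cohorts
    if (is.null(cohorts) || length(cohorts) < 1L) {
      note("stages.survival.cohorts", "at least one cohort is required")
    } else {
      for (i in seq_along(cohorts)) {
        co <- cohorts[[i]]
        at <- function(f) sprintf("stages.survival.cohorts[%d].%s", i, f)
        if (is.null(co$group)) note(at("group"), "missing group label")
        if (is.null(co$n) || bad_number(co$n, lo = 1)) {
          note(at("n"), "n must be an integer >= 1")
        }
        if (is.null(co$target_mean) || bad_number(co$target_mean) ||
            co$target_mean <= 0) {
          note(at("target_mean"), "target_mean must be > 0 days")
        }
        if (!is.null(co$aging_rate) && bad_number(co$aging_rate, lo = 0)) {
          note(at("aging_rate"), "aging_rate must be >= 0")
        }
      }
    }
  }

  demo <- stages$demography
  if (!is.null(demo)) {
    if (is.null(demo$r) || !is.numeric(unlist(demo$r)) ||
        any(unlist(demo$r) <= 0 | unlist(demo$r) > 1)) {
      note("stages.demography.r", "each r must lie in (0, 1]")
    }
    if (!is.null(demo$m0) && bad_number(demo$m0, lo = 0, hi = 1)) {
      note("stages.demography.m0", "m0 must lie in [0, 1]")
    }
    if (!is.null(demo$threshold) && bad_number(demo$threshold, lo = 0, hi = 1)) {
      note("stages.demography.threshold", "threshold must lie in [0, 1]")
    }
    if (!is.null(demo$generations) && bad_number(demo$generations, lo = 0)) {
      note("stages.demography.generations", "generations must be >= 0")
    }
  }

  chem <- stages$chemotaxis
  if (!is.null(chem)) {
    grps <- chem$groups
    if (is.null(grps) || length(grps) < 1L) {
      note("stages.chemotaxis.groups", "at least one group is required")
    } else {
      for (i in seq_along(grps)) {
        gr <- grps[[i]]
        at <- function(f) sprintf("stages.chemotaxis.groups[%d].%s", i, f)
        if (is.null(gr$n_plates) || bad_number(gr$n_plates, lo = 1)) {
          note(at("n_plates"), "n_plates must be an integer >= 1")
        }
        if (is.null(gr$n_worms) || bad_number(gr$n_worms, lo = 0)) {
          note(at("n_worms"), "n_worms must be an integer >= 0")
        }
        probs <- c(gr$p_super, gr$p_ctrl, gr$p_origin)
        if (length(probs) != 3L || any(vapply(probs, bad_number, logical(1),
                                              lo = 0, hi = 1))) {
          note(at("p_*"), "p_super, p_ctrl, p_origin must each lie in [0, 1]")
        } else if (sum(unlist(probs)) > 1) {
          note(at("p_*"), "p_super + p_ctrl + p_origin must not exceed 1")
        }
      }
    }
  }

  if (length(issues) == 0L) {
    tibble(field = character(), issue = character())
  } else {
    bind_rows(issues)
  }
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file '%s' does not exist.", config),
            class = "androdyn_config_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config)) {
    abort("`config` must be a named list or a path to a JSON file.",
          class = "androdyn_config_error")
  }
  config
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages in order — synthetic survival cohorts with
#' Kaplan-Meier/log-rank/summary statistics, deterministic male-fraction
#' trajectories with threshold crossing, and chemotaxis plate generation
#' with group comparison — and returns a report that carries its own
#' provenance (the configuration, its hash, the seed and package version).
#' Identical configurations produce identical reports: every stochastic
#' stage derives its stream from the configured seed.
#'
#' @param config A named list or path to a JSON file; see
#'   [validate_config()] for the schema.
#'
#' @return An object of class `run_report`: a list with `config`,
#'   `config_hash`, `seed`, `package_version` and `results` (one element
#'   per executed stage). [glance()] gives a one-row provenance summary.
#' @export
#' @examples
#' cfg <- system.file("extdata", "default_config.json", package = "androdyn")
#' report <- run_pipeline(cfg)
#' names(report$results)
run_pipeline <- function(config) {
  config <- load_config(config)
  issues <- validate_config(config)
  if (nrow(issues) > 0L) {
    abort(paste0("Invalid configuration:\n",
                 paste0("  - ", issues$field, ": ", issues$issue,
                        collapse = "\n")),
          class = "androdyn_config_error")
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else NA_integer_
  hash <- config_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  results <- list()

  surv <- config$stages$survival
  if (!is.null(surv)) {
    results$survival <- run_survival_stage(surv, seed)
  }
  demo <- config$stages$demography
  if (!is.null(demo)) {
    results$demography <- run_demography_stage(demo)
  }
  chem <- config$stages$chemotaxis
  if (!is.null(chem)) {
    results$chemotaxis <- run_chemotaxis_stage(chem, seed)
  }

  structure(
    list(config = config, config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("androdyn")),
         results = results),
    class = "run_report"
  )
}

run_survival_stage <- function(stage, seed) {
  cohorts <- stage$cohorts
  records <- bind_rows(imap(cohorts, function(co, i) {
    hz <- calibrate_hazard(co$target_mean, co$aging_rate %||% 0)
    gen_survival_cohort(co$n, hz, group = co$group, seed = seed + i)
  }))
  summaries <- mean_lifespan(records)
  ctrl_label <- cohorts[[1L]]$group
  others <- setdiff(vapply(cohorts, `[[`, character(1), "group"), ctrl_label)
  reductions <- bind_rows(map(others, function(gr) {
    tibble(ctrl = ctrl_label, trt = gr,
           percent_reduction = percent_reduction(summaries, gr,
                                                 ctrl_group = ctrl_label))
  }))
  list(
    records = records,
    km = km_estimate(records),
    logrank = if (length(cohorts) > 1L) logrank_test(records) else NULL,
    summaries = summaries,
    reductions = reductions
  )
}

run_demography_stage <- function(stage) {
  rs <- unlist(stage$r)
  m0 <- stage$m0 %||% 0.5
  generations <- stage$generations %||% 20
  threshold <- stage$threshold %||% 0.01
  dpg <- stage$days_per_generation %||% 3
  trajectories <- bind_rows(map(rs, function(r) {
    mutate(male_fraction_trajectory(r, generations, m0), r = r,
           .before = 1L)
  }))
  benchmarks <- bind_rows(map(rs, function(r) {
    traj <- male_fraction_trajectory(r, generations, m0)
    mutate(compare_to_benchmark(traj, threshold, dpg), r = r, .before = 1L)
  }))
  list(trajectories = trajectories, benchmarks = benchmarks,
       threshold = threshold, days_per_generation = dpg)
}

run_chemotaxis_stage <- function(stage, seed) {
  grps <- stage$groups
  plates <- bind_rows(imap(grps, function(gr, i) {
    gen_chemotaxis_plates(gr$n_plates, gr$n_worms, gr$p_super, gr$p_ctrl,
                          gr$p_origin, seed = seed + 1000L + i,
                          group = gr$group %||% paste0("group", i))
  }))
  plates <- chemotaxis_index(plates)
  by_group <- plates |>
    group_by(group = .data$group) |>
    summarise(mean_ci = mean(.data$ci),
              sem = if (dplyr::n() > 1L) sd(.data$ci) / sqrt(dplyr::n()) else 0,
              n_plates = dplyr::n(), .groups = "drop")
  comparison <- NULL
  if (length(grps) >= 2L) {
    labels <- unique(plates$group)
    comparison <- compare_ci(plates[plates$group == labels[[1L]], ],
                             plates[plates$group == labels[[2L]], ],
                             method = stage$method %||% "t",
                             seed = seed + 2000L)
  }
  list(plates = plates, by_group = by_group, comparison = comparison)
}

#' @export
print.run_report <- function(x, ...) {
  cat("androdyn run report\n")
  cat(sprintf("  config hash: %s | seed: %s | package %s\n",
              x$config_hash, x$seed, x$package_version))
  cat(sprintf("  stages run: %s\n", paste(names(x$results), collapse = ", ")))
  invisible(x)
}

#' Provenance summary of a run report
#'
#' @param x A `run_report` object.
#' @param ... Unused.
#' @return A one-row tibble: `config_hash`, `seed`, `package_version`,
#'   `stages`.
#' @export
glance.run_report <- function(x, ...) {
  tibble(config_hash = x$config_hash, seed = x$seed,
         package_version = x$package_version,
         stages = paste(names(x$results), collapse = ","))
}
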