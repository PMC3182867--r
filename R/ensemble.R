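#' Run an ensemble of independently seeded simulations
#'
#' Per-run seeds are `base_seed + round - 1`, so extending an ensemble with
#' more rounds reproduces the earlier runs exactly. Trajectories are not
#' stored; summary statistics are accumulated online per run.
#'
#' @param config A [simulation_config()] object.
#' @param n_rounds Number of independent runs.
#' @param base_seed Integer base seed.
#' @return A `swarm_ensemble`: list with `$runs` (one [summarize_run()] row
#'   per run, plus a `round` column) and `$config`. [tidy()] returns the
#'   runs, [glance()] the aggregate means/standard errors.
#' @export
run_ensemble <- function(config, n_rounds = 100, base_seed = 1) {
  stopifnot(inherits(config, "simulation_config"), n_rounds >= 1)
  runs <- purrr::map_dfr(seq_len(n_rounds), function(k) {
    traj <- run_simulation(config, seed = base_seed + k - 1L, record = FALSE)
    mutate(summarize_run(traj), round = k, .before = 1)
  })
  structure(list(runs = runs, config = config, base_seed = base_seed),
            class = "swarm_ensemble")
}

#' @export
print.swarm_ensemble <- function(x, ...) {
  cat(sprintf("<swarm_ensemble> %d run(s), mechanism = %s\n",
              nrow(x$runs), x$config$policy$mode))
  print(glance(x))
  invisible(x)
}

#' @method tidy swarm_ensemble
#' @export
tidy.swarm_ensemble <- function(x, ...) x$runs

#' Aggregate statistics of an ensemble
#'
#' Means, medians and standard errors are computed over runs (not agents);
#' censored runs are counted separately and excluded from the path-length
#' aggregates.
#'
#' @param x A `swarm_ensemble`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance swarm_ensemble
#' @export
glance.swarm_ensemble <- function(x, ...) {
  aggregate_runs(x$runs)
}

aggregate_runs <- function(runs) {
  se <- function(v) { v <- v[!is.na(v)]; if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v)) }
  summarise(runs,
    n_rounds = n(),
    n_censored = sum(.data$censored),
    mean_median_path = mean(.data$median_path_length, na.rm = TRUE),
    se_median_path = se(.data$median_path_length),
    median_median_path = median(.data$median_path_length, na.rm = TRUE),
    var_median_path = stats::var(.data$median_path_length[!is.na(.data$median_path_length)]),
    mean_error_fraction = mean(.data$error_fraction, na.rm = TRUE),
    se_error_fraction = se(.data$error_fraction),
    mean_alignment = mean(.data$alignment, na.rm = TRUE),
    se_alignment = se(.data$alignment),
    mean_n_clusters = mean(.data$n_clusters),
    mean_weight = mean(.data$mean_weight, na.rm = TRUE))
}

#' Sweep one parameter over an ensemble grid
#'
#' Runs an ensemble at every value of the swept parameter with matched seeds
#' across values (the same per-round seeds are reused at each value, a
#' variance-reduction pairing). Output is long format: one row per run.
#'
#' Sweepable parameters: `"fixed_w"` (constant interaction weight; forces the
#' fixed policy), `"n_agents"`, `"sigma_eta"` (internal noise), `"radii"`
#' (`values` must be a data frame with columns `orientation`, `attraction`),
#' and `"tau_range"` (`values` a data frame with columns `tau_min`,
#' `tau_max`).
#'
#' @param config Base [simulation_config()].
#' @param parameter Name of the swept parameter (see above).
#' @param values Vector (or data frame, see above) of values.
#' @param n_rounds Rounds per value.
#' @param base_seed Integer base seed (shared across values).
#' @return A `swarm_sweep`: `$runs` tibble with a `value` column (for grid
#'   sweeps, the individual columns as well), `$parameter`, `$config`.
#' @export
sweep_parameter <- function(config, parameter, values, n_rounds = 50,
                            base_seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  known <- c("fixed_w", "n_agents", "sigma_eta", "radii", "tau_range")
  if (!parameter %in% known)
    abort(paste0("unknown parameter '", parameter, "'; sweepable parameters: ",
                 paste(known, collapse = ", ")))
  with_value <- function(v) {
    cfg <- config
    if (parameter == "fixed_w") {
      cfg$policy <- weight_policy("fixed", fixed_w = v)
    } else if (parameter == "n_agents") {
      cfg$n_agents <- as.integer(v)
    } else if (parameter == "sigma_eta") {
      cfg$motion$internal_noise_sd <- v
    } else if (parameter == "radii") {
      cfg$zones <- interaction_zones(config$zones$repulsion,
                                     v$orientation, v$attraction,
                                     config$zones$alignment_attraction_ratio)
      cfg$goal_radius <- config$goal_radius
    } else if (parameter == "tau_range") {
      cfg$tau_range <- c(v$tau_min, v$tau_max)
    }
    validate_simconfig(cfg)
  }
  vlist <- if (is.data.frame(values)) split(values, seq_len(nrow(values)))
  else as.list(values)
  runs <- purrr::imap_dfr(vlist, function(v, k) {
    cfg <- with_value(v)
    ens <- run_ensemble(cfg, n_rounds = n_rounds, base_seed = base_seed)
    r <- ens$runs
    if (is.data.frame(values)) {
      for (nm in names(v)) r[[nm]] <- v[[nm]]
      r$value <- as.integer(k)
    } else {
      r$value <- as.numeric(v)
    }
    r
  })
  structure(list(runs = runs, parameter = parameter, config = config,
                 base_seed = base_seed),
            class = "swarm_sweep")
}

# re-run the constructor checks after a field surgery
validate_simconfig <- function(cfg) {
  simulation_config(terrain = cfg$terrain, motion = cfg$motion,
                    zones = cfg$zones, policy = cfg$policy,
                    n_agents = cfg$n_agents,
                    start_position = cfg$start_position,
                    init_radius = cfg$init_radius, max_steps = cfg$max_steps,
                    goal_radius = cfg$goal_radius, tau_range = cfg$tau_range)
}

#' @export
print.swarm_sweep <- function(x, ...) {
  cat(sprintf("<swarm_sweep> parameter '%s', %d run(s)\n",
              x$parameter, nrow(x$runs)))
  print(glance(x))
  invisible(x)
}

#' @method tidy swarm_sweep
#' @export
tidy.swarm_sweep <- function(x, ...) x$runs

#' @method glance swarm_sweep
#' @export
glance.swarm_sweep <- function(x, ...) {
  x$runs %>% group_by(.data$value) %>%
    dplyr::group_modify(~aggregate_runs(.x)) %>% ungroup()
}

#' Compare the three interaction mechanisms on matched seeds
#'
#' Runs the independent, fixed-weight and adaptive policies with identical
#' per-round seeds (so each round sees the same initial swarm geometry up to
#' the policy-dependent draws) and reports per-mechanism path-length
#' distributions plus Wilcoxon rank-sum tests of each pairwise ordering.
#' Censored runs enter the rank statistics as larger than every observed
#' path length.
#'
#' @param config Base [simulation_config()]; its policy section is replaced
#'   per mechanism.
#' @param n_rounds Rounds per mechanism.
#' @param base_seed Integer base seed.
#' @param fixed_w Constant weight for the fixed mechanism (default: the
#'   frozen default configuration's sweep-optimal value).
#' @param adaptive_levels `c(w_low, w_high)` for the adaptive mechanism.
#' @return A `mechanism_comparison`: `$runs` (3 x n_rounds records),
#'   `$tests` (pairwise one-sided rank-sum results), `$summary` (per-
#'   mechanism aggregates).
#' @export
mechanism_comparison <- function(config, n_rounds = 100, base_seed = 1,
                                 fixed_w = NULL, adaptive_levels = c(0, 0.5)) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(fixed_w)) fixed_w <- default_config("fixed")$policy$fixed_w
  policies <- list(
    independent = weight_policy("independent"),
    fixed = weight_policy("fixed", fixed_w = fixed_w),
    adaptive = weight_policy("adaptive", w_low = adaptive_levels[1],
                             w_high = adaptive_levels[2]))
  runs <- purrr::imap_dfr(policies, function(p, nm) {
    cfg <- config
    cfg$policy <- p
    run_ensemble(validate_simconfig(cfg), n_rounds = n_rounds,
                 base_seed = base_seed)$runs
  })
  path_of <- function(mech) {
    r <- filter(runs, .data$mechanism == mech)
    ifelse(r$censored, Inf, r$median_path_length)
  }
  pairs <- list(c("adaptive", "fixed"), c("fixed", "independent"),
                c("adaptive", "independent"))
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- path_of(pr[1]); b <- path_of(pr[2])
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "less", exact = FALSE))
    tibble(faster = pr[1], slower = pr[2],
           statistic = unname(wt$statistic), p_value = wt$p.value,
           median_faster = median(a), median_slower = median(b))
  })
  summary <- runs %>% group_by(.data$mechanism) %>%
    dplyr::group_modify(~aggregate_runs(.x)) %>% ungroup()
  structure(list(runs = runs, tests = tests, summary = summary,
                 config = config, base_seed = base_seed),
            class = "mechanism_comparison")
}

#' @export
print.mechanism_comparison <- function(x, ...) {
  cat("<mechanism_comparison>\n")
  print(x$summary)
  cat("\npairwise rank-sum tests (alternative: 'faster' has shorter paths):\n")
  print(x$tests)
  invisible(x)
}

#' @method tidy mechanism_comparison
#' @export
tidy.mechanism_comparison <- function(x, ...) x$runs

#' @method glance mechanism_comparison
#' @export
glance.mechanism_comparison <- function(x, ...) x$summary
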