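#' Initialise a swarm
#'
#' Positions are area-uniform over the disc of radius `init_radius` about the
#' start position (so the group starts cohesive, with every agent inside
#' every other's interaction range on the default geometry); headings are
#' uniform on \eqn{(-\pi, \pi]}; weights are the policy's initial weight;
#' per-agent run lengths are uniform over the integers of `tau_range` when
#' heterogeneous, else constant; tumble phases are uniform over
#' `{0, ..., tau_i - 1}` so the group does not tumble in lockstep. Draws use
#' the current RNG state; call `set.seed()` (or use [run_simulation()]'s
#' `seed`) for reproducibility.
#'
#' @param config A [simulation_config()] object.
#' @return Agent-state tibble with columns `agent, x, y, theta, w,
#'   steps_since_tumble, tau, last_conc, g, arrived`.
#' @export
init_swarm <- function(config) {
  n <- config$n_agents
  # draw order (kept fixed for reproducibility): radii, angles, headings,
  # run lengths (if heterogeneous), tumble phases
  r <- config$init_radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  x <- config$start_position[1] + r * cos(a)
  y <- config$start_position[2] + r * sin(a)
  theta <- wrap_angle(runif(n, 0, 2 * pi))
  tau <- if (is.null(config$tau_range)) rep(config$motion$run_length, n)
  else config$tau_range[1] +
    floor(runif(n) * (config$tau_range[2] - config$tau_range[1] + 1L))
  phase <- if (config$motion$tumble_phases == "staggered")
    floor(runif(n) * tau) else rep(0, n)
  cc <- conc_xy(x, y, config$terrain)
  arrived <- sqrt((x - config$terrain$target[1])^2 +
                  (y - config$terrain$target[2])^2) <= config$goal_radius
  tibble(agent = seq_len(n), x = x, y = y, theta = theta,
         w = rep(config$policy$initial_w, n),
         steps_since_tumble = as.integer(phase), tau = as.integer(tau),
         last_conc = cc, conc_at_tumble = cc, g = rep(0, n), arrived = arrived)
}

#' Run one seeded simulation
#'
#' Synchronous loop to `max_steps` or full absorption: each step, every
#' agent's group direction is computed from the time-t state, then all agents
#' advance together; adaptive weights are refreshed every step from each
#' agent's own concentration change. Agents within `goal_radius` of the
#' target are absorbed: frozen in place and invisible to the interaction
#' rules and metrics. The heavy loop runs in compiled code.
#'
#' @param config A [simulation_config()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param record Record the full per-step trajectory (default `TRUE`). Large
#'   ensembles switch this off; summary statistics are accumulated online
#'   either way.
#' @return An object of class `swarm_trajectory`: per-step state matrices
#'   (`(n_steps+1) x N`, when recorded), per-agent arrival steps (`NA` =
#'   censored), final state, online alignment and mean weight, and the
#'   configuration. Use [tidy()] for a long tibble, [summarize_run()] for the
#'   one-row summary.
#' @export
run_simulation <- function(config, seed = NULL, record = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  agents <- init_swarm(config)
  fl <- config_flat(config)
  res <- sim_core(agents$x, agents$y, agents$theta, agents$w,
                  agents$steps_since_tumble, agents$tau, agents$last_conc,
                  agents$conc_at_tumble, config$motion$run_length,
                  fl$terrain, fl$periodic_form, fl$motion, fl$gradient_mode,
                  fl$tumble_reference, fl$zones, fl$policy_mode, fl$policy,
                  config$goal_radius, config$max_steps, record)
  ns <- res$n_steps
  traj <- list(
    n_steps = ns,
    n_agents = config$n_agents,
    arrival_step = res$arrival_step,
    alignment = res$alignment,
    mean_weight = res$mean_weight,
    final = tibble(agent = agents$agent, x = res$x_final, y = res$y_final,
                   theta = res$theta_final, w = res$w_final,
                   arrived = res$arrived_final),
    config = config,
    seed = seed)
  if (record) {
    keep <- seq_len(ns + 1L)
    traj$x <- res$x[keep, , drop = FALSE]
    traj$y <- res$y[keep, , drop = FALSE]
    traj$theta <- res$theta[keep, , drop = FALSE]
    traj$w <- res$w[keep, , drop = FALSE]
    traj$arrived <- res$arrived[keep, , drop = FALSE]
  }
  structure(traj, class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  n_arr <- sum(!is.na(x$arrival_step))
  cat(sprintf("<swarm_trajectory> N = %d, %d step(s), %d/%d arrived, alignment %.3f\n",
              x$n_agents, x$n_steps, n_arr, x$n_agents, x$alignment))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `swarm_trajectory` with a recorded trajectory.
#' @param ... Unused.
#' @return Tibble with columns `t`, `agent`, `x`, `y`, `theta`, `w`,
#'   `arrived` (one row per agent per recorded step, `t = 0` is the initial
#'   state).
#' @method tidy swarm_trajectory
#' @export
tidy.swarm_trajectory <- function(x, ...) {
  if (is.null(x$x)) abort("trajectory was not recorded (record = FALSE)")
  nt <- nrow(x$x)
  xs <- as.vector(x$x); ys <- as.vector(x$y)
  ths <- as.vector(x$theta); ws <- as.vector(x$w)
  arr <- as.vector(x$arrived)
  tibble(t = rep(0:(nt - 1L), times = x$n_agents),
         agent = rep(seq_len(x$n_agents), each = nt),
         x = xs, y = ys, theta = ths, w = ws, arrived = arr)
}

#' @method glance swarm_trajectory
#' @export
glance.swarm_trajectory <- function(x, ...) summarize_run(x)
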