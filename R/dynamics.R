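#' Measured gradient along an agent's own path
#'
#' Swimming bacteria are too small to sense a spatial gradient across their
#' body; they compare the concentration now with the concentration a moment
#' ago. The measured gradient is that temporal difference per unit path
#' length.
#'
#' @param last_concentration,new_concentration Concentrations at the previous
#'   and current position (vectorised).
#' @param path_increment Path length travelled between the two measurements
#'   (> 0).
#' @return Numeric vector of measured gradients (concentration/length).
#' @export
measured_gradient <- function(last_concentration, new_concentration, path_increment) {
  if (any(path_increment <= 0)) abort("path_increment must be > 0")
  (new_concentration - last_concentration) / path_increment
}

#' Tumble-angle standard deviation as a function of measured gradient
#'
#' \eqn{\sigma^2(g) = \sigma_{min}^2 + (\sigma_{max}^2 - \sigma_{min}^2) /
#' (1 + e^{g/g_0})}: strictly decreasing in \eqn{g} and bounded in
#' \eqn{[\sigma_{min}, \sigma_{max}]}, so motion up-gradient keeps its
#' direction while motion down-gradient reorients almost uniformly.
#'
#' @param g Measured gradient (vectorised).
#' @param motion A [motion_params()] object.
#' @return Standard deviation in radians.
#' @export
tumble_sd <- function(g, motion) {
  s2 <- motion$tumble_sd_min^2 +
    (motion$tumble_sd_max^2 - motion$tumble_sd_min^2) /
    (1 + exp(g / motion$gradient_scale))
  sqrt(s2)
}

#' Draw new headings for tumbling agents
#'
#' The new heading is the old one deflected by a Gaussian angle with standard
#' deviation [tumble_sd()] evaluated at each agent's most recent measured
#' gradient; draws are taken in agent order, so results are reproducible
#' under a fixed seed.
#'
#' @param theta Current headings (radians, vectorised).
#' @param g Measured gradients, same length.
#' @param motion A [motion_params()] object.
#' @return New headings wrapped to \eqn{(-\pi, \pi]}.
#' @export
tumble <- function(theta, g, motion) {
  wrap_angle(theta + rnorm(length(theta), 0, tumble_sd(g, motion)))
}

#' Combine an agent's own heading with the group direction
#'
#' Returns the unit vector along \eqn{w\,\hat u(\theta) + (1-w)\,d_{group}}.
#' With no group direction (no neighbours in any zone, or independent agents)
#' the agent keeps its own heading; if the weighted sum cancels exactly the
#' own-heading fallback is used as well.
#'
#' @param theta Own heading (radians, scalar).
#' @param group_direction Unit 2-vector, or `NULL` for none.
#' @param w Weight in `[0, 1]`.
#' @return Unit 2-vector.
#' @export
combine_directions <- function(theta, group_direction, w) {
  if (w < 0 || w > 1) abort("w must be in [0, 1]")
  u <- c(cos(theta), sin(theta))
  if (is.null(group_direction)) return(u)
  v <- w * u + (1 - w) * group_direction
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) u else v / nv
}

#' Advance a swarm by one synchronous time step
#'
#' Reference step of the dynamics, operating on an agent-state tibble (see
#' [init_swarm()]). For each non-arrived agent: if its run is over it tumbles
#' about its current heading (group influence is skipped on tumble steps),
#' otherwise its new angle is the combined self/group direction; Gaussian
#' internal noise is added to the angle; the agent moves `speed * time_step`
#' along it; its measured concentration, gradient, and counters are updated.
#' Arrived agents are frozen.
#'
#' Random draws follow a fixed block order per step — tumble deflections for
#' tumbling agents in ascending index order, then internal noise for all
#' non-arrived agents — matching the compiled simulation core, so composing
#' this function step by step reproduces [run_simulation()] exactly.
#'
#' The interaction-weight column is not modified here; weight policies are
#' applied by the simulation loop via [update_weight()] using the returned
#' `dC` column.
#'
#' @param agents Agent-state tibble with columns `x, y, theta, w,
#'   steps_since_tumble, tau, last_conc, g, arrived`.
#' @param group_directions N x 2 matrix of unit group directions (`NA` rows
#'   where an agent has none), or `NULL` for independent agents.
#' @param terrain A [terrain_params()] object.
#' @param motion A [motion_params()] object.
#' @return The updated agent tibble, with a `dC` column holding each agent's
#'   concentration change over the step (0 for arrived agents).
#' @export
advance <- function(agents, group_directions, terrain, motion) {
  n <- nrow(agents)
  if (!all(is.finite(agents$x)) || !all(is.finite(agents$y)) ||
      !all(is.finite(agents$theta)))
    abort("non-finite agent state")
  live <- !agents$arrived
  tumbling <- live & agents$steps_since_tumble >= agents$tau

  step_len <- motion$speed * motion$time_step
  # block 1: tumble deflections, ascending index order
  delta <- rep(0, n)
  if (any(tumbling)) {
    g_tum <- if (motion$gradient_mode == "run")
      (agents$last_conc[tumbling] - agents$conc_at_tumble[tumbling]) /
        (step_len * motion$run_length)
    else agents$g[tumbling]
    agents$g[tumbling] <- g_tum
    delta[tumbling] <- rnorm(sum(tumbling), 0, tumble_sd(g_tum, motion))
    agents$conc_at_tumble[tumbling] <- agents$last_conc[tumbling]
  }
  # base direction: combined self/group direction (skipped on tumble steps
  # unless tumbles deflect about the combined direction)
  new_theta <- agents$theta
  steer <- which(live & (!tumbling | motion$tumble_reference == "combined"))
  for (i in steer) {
    gd <- if (is.null(group_directions) || anyNA(group_directions[i, ]))
      NULL else group_directions[i, ]
    d <- combine_directions(agents$theta[i], gd, agents$w[i])
    new_theta[i] <- atan2(d[2], d[1])
  }
  new_theta[tumbling] <- new_theta[tumbling] + delta[tumbling]
  # block 2: internal noise for all live agents, ascending index order
  eta <- rnorm(sum(live), 0, motion$internal_noise_sd)
  new_theta[live] <- wrap_angle(new_theta[live] + eta)

  agents$dC <- 0
  if (any(live)) {
    nx <- agents$x[live] + step_len * cos(new_theta[live])
    ny <- agents$y[live] + step_len * sin(new_theta[live])
    newc <- conc_xy(nx, ny, terrain)
    dC <- newc - agents$last_conc[live]
    agents$x[live] <- nx
    agents$y[live] <- ny
    agents$theta[live] <- new_theta[live]
    agents$last_conc[live] <- newc
    if (motion$gradient_mode == "temporal") {
      agents$g[live] <- dC / step_len
    } else if (motion$gradient_mode == "projected") {
      gr <- grad_xy(nx, ny, terrain)
      agents$g[live] <- gr[, 1] * cos(new_theta[live]) + gr[, 2] * sin(new_theta[live])
    }
    agents$dC[live] <- dC
    agents$steps_since_tumble[live] <-
      ifelse(tumbling[live], 1L, agents$steps_since_tumble[live] + 1L)
  }
  agents
}
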