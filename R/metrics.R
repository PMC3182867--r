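#' Per-agent arrival times
#'
#' The first step at which an agent is within the goal radius of the target
#' (0 if it starts there). Agents that never arrive within the simulation
#' length are censored (`NA` step).
#'
#' @param traj A `swarm_trajectory` from [run_simulation()].
#' @return Tibble with columns `agent`, `step` (`NA` if censored),
#'   `censored`.
#' @export
arrival_times <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  tibble(agent = seq_len(traj$n_agents),
         step = traj$arrival_step,
         censored = is.na(traj$arrival_step))
}

#' Median path length of a run
#'
#' The navigation time of the median-arriving agent times the speed: the
#' median is used rather than the mean so rare extremely long paths do not
#' bias the statistic. Censored (non-arriving) agents rank above every
#' arrival; if too few agents arrived for the median order statistic to be
#' observed (fewer than half), the run's median path length is itself
#' censored and reported as `NA`, never imputed.
#'
#' @param arrival_steps Integer vector of per-agent arrival steps, `NA` =
#'   censored.
#' @param v0,dt Speed and time step.
#' @return Length or `NA` (censored).
#' @export
median_path_length <- function(arrival_steps, v0, dt) {
  s <- sort(ifelse(is.na(arrival_steps), Inf, arrival_steps))
  m <- median(s)
  if (!is.finite(m)) NA_real_ else m * v0 * dt
}

#' Path-length order statistic
#'
#' The q-quantile of the per-agent path lengths via the ceiling order
#' statistic; censored when that order statistic is itself a non-arrival.
#'
#' @inheritParams median_path_length
#' @param q Quantile in (0, 1], e.g. 0.9 for the 90th percentile.
#' @return Length or `NA` (censored).
#' @export
percentile_path_length <- function(arrival_steps, v0, dt, q = 0.9) {
  stopifnot(q > 0, q <= 1)
  s <- sort(ifelse(is.na(arrival_steps), Inf, arrival_steps))
  k <- ceiling(q * length(s))
  if (!is.finite(s[k])) NA_real_ else s[k] * v0 * dt
}

#' Error fraction of a run
#'
#' Relative excess of the median path length over the straight-line
#' start-to-target distance: `(L - D) / D`. Zero means the median agent took
#' the straight line; 0.65 means its path was 65% longer. Censored medians
#' propagate to a censored (`NA`) error fraction.
#'
#' @param median_length Median path length (possibly `NA` = censored).
#' @param distance Straight-line start-to-target distance `D > 0`.
#' @return Dimensionless error fraction, or `NA`.
#' @export
error_fraction <- function(median_length, distance) {
  if (any(distance <= 0)) abort("distance must be > 0")
  (median_length - distance) / distance
}

#' Time-averaged group alignment (polar order)
#'
#' At each step the polar order parameter
#' \eqn{\| \frac{1}{N_t}\sum_i \hat u(\theta_i) \|} is computed over the
#' agents not yet absorbed; the run's alignment is its average over steps
#' (steps after full absorption are excluded; the randomly oriented initial
#' state is not counted). 1 means perfectly common heading throughout, 0 no
#' net direction. `method = "pairwise"` instead averages the mean pairwise
#' cosine of headings, an alternative reading of "average alignment between
#' individuals" (note it can be slightly negative for anti-aligned pairs).
#'
#' @param traj A recorded `swarm_trajectory`.
#' @param method `"polar"` (default) or `"pairwise"`.
#' @return Scalar alignment.
#' @export
group_alignment <- function(traj, method = c("polar", "pairwise")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "swarm_trajectory"))
  if (is.null(traj$theta)) {
    if (method == "polar") return(traj$alignment)
    abort("pairwise alignment needs a recorded trajectory")
  }
  nt <- nrow(traj$theta)
  if (nt < 2) return(NA_real_)
  vals <- numeric(0)
  for (t in 2:nt) {
    live <- !traj$arrived[t, ]
    if (!any(live)) next
    th <- traj$theta[t, live]
    if (method == "polar") {
      vals <- c(vals, sqrt(sum(cos(th))^2 + sum(sin(th))^2) / length(th))
    } else {
      if (length(th) < 2) next
      cs <- cos(th); sn <- sin(th)
      gram <- outer(cs, cs) + outer(sn, sn)
      vals <- c(vals, mean(gram[upper.tri(gram)]))
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Number of clusters in a point configuration
#'
#' Connected components of the graph joining agents closer than the
#' attraction radius; a group whose interaction graph is connected is one
#' cluster.
#'
#' @param positions Data frame with columns `x`, `y`.
#' @param attraction_radius Edge threshold (the outer interaction radius).
#' @return Integer number of clusters.
#' @export
count_clusters <- function(positions, attraction_radius) {
  check_points(positions)
  n <- nrow(positions)
  if (n <= 1) return(n)
  d <- as.matrix(stats::dist(cbind(positions$x, positions$y)))
  adj <- d < attraction_radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

#' Time- and agent-averaged interaction weight
#'
#' Averaged over non-absorbed agents across all steps after the initial
#' state. For the adaptive policy with `w_low = 0` this equals `w_high`
#' times the average fraction of agents whose last step increased their
#' measured concentration.
#'
#' @param traj A `swarm_trajectory`.
#' @return Scalar mean weight.
#' @export
mean_weight <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  if (is.null(traj$w)) return(traj$mean_weight)
  nt <- nrow(traj$w)
  if (nt < 2) return(NA_real_)
  sel <- !traj$arrived[2:nt, , drop = FALSE]
  ww <- traj$w[2:nt, , drop = FALSE]
  if (!any(sel)) NA_real_ else mean(ww[sel])
}

#' One-row summary of a run
#'
#' The per-run record used throughout the ensemble experiments.
#'
#' @param traj A `swarm_trajectory`.
#' @return One-row tibble with columns `mechanism`, `seed`, `n_agents`,
#'   `n_arrived`, `median_path_length`, `censored`, `error_fraction`,
#'   `alignment`, `n_clusters`, `mean_weight`, `p90_path_length`.
#' @export
summarize_run <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  cfg <- traj$config
  v0 <- cfg$motion$speed; dt <- cfg$motion$time_step
  D <- sqrt(sum((cfg$start_position - cfg$terrain$target)^2))
  L <- median_path_length(traj$arrival_step, v0, dt)
  # absorbed agents are invisible to the interaction rules; for the cohesion
  # statistic they count as one cluster sitting at the target
  live <- !traj$final$arrived
  ncl <- as.integer(any(!live)) +
    if (any(live)) count_clusters(traj$final[live, ], cfg$zones$attraction) else 0L
  tibble(
    mechanism = cfg$policy$mode,
    seed = if (is.null(traj$seed)) NA_integer_ else as.integer(traj$seed),
    n_agents = cfg$n_agents,
    n_arrived = sum(!is.na(traj$arrival_step)),
    median_path_length = L,
    censored = is.na(L),
    error_fraction = error_fraction(L, D),
    alignment = traj$alignment,
    n_clusters = ncl,
    mean_weight = traj$mean_weight,
    p90_path_length = percentile_path_length(traj$arrival_step, v0, dt, 0.9))
}
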