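#' Zonal neighbour sets of one agent
#'
#' Classifies all other non-arrived agents into the three half-open distance
#' bands of [interaction_zones()]: repulsion `0 < d < R_r`, orientation
#' `R_r <= d < R_o`, attraction `R_o <= d < R_a` (lower-inclusive, so a
#' neighbour exactly at `R_r` aligns rather than repels). Coincident agents
#' (`d == 0`) are placed in the repulsion set.
#'
#' @param agents Agent tibble with columns `x`, `y` (and optionally
#'   `arrived`; arrived agents are invisible to all interaction rules).
#' @param i Focal agent index.
#' @param zones An [interaction_zones()] object.
#' @return List with integer-vector elements `repulsion`, `orientation`,
#'   `attraction`.
#' @export
neighbor_sets <- function(agents, i, zones) {
  n <- nrow(agents)
  if (i < 1 || i > n) abort("invalid agent index")
  d <- sqrt((agents$x - agents$x[i])^2 + (agents$y - agents$y[i])^2)
  vis <- if ("arrived" %in% names(agents)) !agents$arrived else rep(TRUE, n)
  vis[i] <- FALSE
  idx <- which(vis)
  dd <- d[idx]
  list(repulsion   = idx[dd < zones$repulsion],
       orientation = idx[dd >= zones$repulsion & dd < zones$orientation],
       attraction  = idx[dd >= zones$orientation & dd < zones$attraction])
}

#' Collision-avoidance direction
#'
#' Direction away from the repulsion-zone neighbours: the normalised negative
#' sum of unit vectors toward each of them. Exact cancellation returns `NULL`
#' (the caller falls back to the previous heading); a coincident neighbour
#' contributes a random unit direction.
#'
#' @inheritParams neighbor_sets
#' @param repulsion_set Integer indices from [neighbor_sets()].
#' @return Unit 2-vector, or `NULL` on cancellation.
#' @export
repulsion_direction <- function(agents, i, repulsion_set) {
  s <- c(0, 0)
  for (j in repulsion_set) {
    dx <- agents$x[j] - agents$x[i]
    dy <- agents$y[j] - agents$y[i]
    d <- sqrt(dx * dx + dy * dy)
    if (d == 0) {
      a <- runif(1, 0, 2 * pi)
      s <- s + c(cos(a), sin(a))
    } else s <- s + c(dx, dy) / d
  }
  s <- -s
  ns <- sqrt(sum(s^2))
  if (ns < 1e-12) NULL else s / ns
}

#' Alignment/attraction direction
#'
#' Used only when the repulsion set is empty: the normalised sum of the
#' orientation-zone neighbours' heading unit vectors (scaled by the
#' configured alignment:attraction ratio) and the unit vectors toward the
#' attraction-zone neighbours.
#'
#' @inheritParams repulsion_direction
#' @param orientation_set,attraction_set Integer indices from
#'   [neighbor_sets()].
#' @param zones An [interaction_zones()] object (for the ratio).
#' @return Unit 2-vector, or `NULL` if both sets are empty or the sum
#'   cancels.
#' @export
align_attract_direction <- function(agents, i, orientation_set, attraction_set,
                                    zones = interaction_zones()) {
  if (length(orientation_set) + length(attraction_set) == 0) return(NULL)
  s <- c(0, 0)
  for (j in orientation_set)
    s <- s + zones$alignment_attraction_ratio *
      c(cos(agents$theta[j]), sin(agents$theta[j]))
  for (j in attraction_set) {
    dx <- agents$x[j] - agents$x[i]
    dy <- agents$y[j] - agents$y[i]
    d <- sqrt(dx * dx + dy * dy)
    s <- s + c(dx, dy) / d
  }
  ns <- sqrt(sum(s^2))
  if (ns < 1e-12) NULL else s / ns
}

#' Group-derived direction of one agent
#'
#' Repulsion strictly preempts everything: if any neighbour is inside the
#' repulsion zone the result is [repulsion_direction()]; otherwise it is
#' [align_attract_direction()]. An isolated agent gets `NULL`.
#'
#' @inheritParams neighbor_sets
#' @return Unit 2-vector or `NULL`.
#' @export
group_direction <- function(agents, i, zones) {
  ns <- neighbor_sets(agents, i, zones)
  if (length(ns$repulsion) > 0) repulsion_direction(agents, i, ns$repulsion)
  else align_attract_direction(agents, i, ns$orientation, ns$attraction, zones)
}

#' Group directions for all agents
#'
#' @inheritParams neighbor_sets
#' @return N x 2 matrix of unit vectors, with `NA` rows where an agent has no
#'   neighbours in any zone (or is arrived).
#' @export
group_directions <- function(agents, zones) {
  n <- nrow(agents)
  out <- matrix(NA_real_, n, 2)
  live <- if ("arrived" %in% names(agents)) !agents$arrived else rep(TRUE, n)
  for (i in which(live)) {
    g <- group_direction(agents, i, zones)
    if (!is.null(g)) out[i, ] <- g
  }
  out
}

#' Update interaction weights after a step
#'
#' The adaptive policy is a hard-limit two-state rule: an agent whose
#' measured concentration increased over the step (`dC > 0`) sets its weight
#' to `w_high` and relies more on itself; otherwise (`dC <= 0`, including
#' ties) it sets `w_low` and follows the group. Fixed and independent
#' policies return their configured constant.
#'
#' @param w Current weights (vectorised; returned unchanged in shape).
#' @param dC Concentration change of each agent over the last step.
#' @param policy A [weight_policy()] object.
#' @return New weights.
#' @export
update_weight <- function(w, dC, policy) {
  switch(policy$mode,
         adaptive = ifelse(dC > 0, policy$w_high, policy$w_low),
         fixed = rep(policy$fixed_w, length(w)),
         independent = rep(policy$initial_w, length(w)))
}
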