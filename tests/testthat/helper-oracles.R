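# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature for the Bessel function, central
# finite differences for gradients, O(N^2) pairwise classification for the
# zonal sets, stack-based DFS for connected components, and a plain
# single-agent random-walk loop for the dynamics reduction.

# K0 via its integral representation, independent of besselK()
k0_quadrature <- function(z) {
  stats::integrate(function(t) exp(-z * cosh(t)), 0, 30,
                   rel.tol = 1e-10)$value
}

# central finite differences of the concentration field
fd_gradient <- function(x, y, terrain, h) {
  cxp <- concentration(data.frame(x = x + h, y = y), terrain)$concentration
  cxm <- concentration(data.frame(x = x - h, y = y), terrain)$concentration
  cyp <- concentration(data.frame(x = x, y = y + h), terrain)$concentration
  cym <- concentration(data.frame(x = x, y = y - h), terrain)$concentration
  cbind((cxp - cxm) / (2 * h), (cyp - cym) / (2 * h))
}

# finite-difference Hessian sign oracle for critical-point classification
fd_hessian_class <- function(x, y, terrain, h) {
  cc <- function(px, py) concentration(data.frame(x = px, y = py), terrain)$concentration
  c0 <- cc(x, y)
  hxx <- (cc(x + h, y) - 2 * c0 + cc(x - h, y)) / h^2
  hyy <- (cc(x, y + h) - 2 * c0 + cc(x, y - h)) / h^2
  hxy <- (cc(x + h, y + h) - cc(x + h, y - h) - cc(x - h, y + h) + cc(x - h, y - h)) / (4 * h^2)
  ev <- eigen(matrix(c(hxx, hxy, hxy, hyy), 2), symmetric = TRUE, only.values = TRUE)$values
  if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
}

# brute-force zonal classification of neighbour j relative to i
brute_zones <- function(xy, i, zones, arrived = rep(FALSE, nrow(xy))) {
  res <- list(repulsion = integer(), orientation = integer(), attraction = integer())
  for (j in seq_len(nrow(xy))) {
    if (j == i || arrived[j]) next
    d <- sqrt((xy$x[j] - xy$x[i])^2 + (xy$y[j] - xy$y[i])^2)
    if (d < zones$repulsion) res$repulsion <- c(res$repulsion, j)
    else if (d < zones$orientation) res$orientation <- c(res$orientation, j)
    else if (d < zones$attraction) res$attraction <- c(res$attraction, j)
  }
  res
}

# connected components by explicit depth-first search
dfs_components <- function(xy, radius) {
  n <- nrow(xy)
  if (n == 0) return(0L)
  seen <- rep(FALSE, n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      d <- sqrt((xy$x - xy$x[v])^2 + (xy$y - xy$y[v])^2)
      nb <- which(d < radius & !seen)
      nb <- nb[nb != v]
      stack <- c(stack, nb)
    }
  }
  ncomp
}

# sorting-based median path length with censoring (Inf) on raw vectors
sort_median_path <- function(steps, v0, dt) {
  s <- sort(ifelse(is.na(steps), Inf, steps))
  m <- stats::median(s)
  if (is.finite(m)) m * v0 * dt else NA_real_
}

# Reference single-agent chemotaxis walker used by the reduction tests
# (N = 1, independent): a plain loop written without the package's
# advance()/compiled core, following the documented draw order.
reference_walk <- function(config, seed, n_steps) {
  set.seed(seed)
  tp <- config$terrain; mo <- config$motion
  step_len <- mo$speed * mo$time_step
  cxy <- function(px, py) concentration(data.frame(x = px, y = py), tp)$concentration
  # initialisation draws in the documented order
  r <- config$init_radius * sqrt(runif(1))
  a <- runif(1, 0, 2 * pi)
  x <- config$start_position[1] + r * cos(a)
  y <- config$start_position[2] + r * sin(a)
  theta <- runif(1, 0, 2 * pi)
  theta <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  if (theta <= -pi) theta <- theta + 2 * pi
  phase <- if (mo$tumble_phases == "staggered") floor(runif(1) * mo$run_length) else 0
  lastc <- cxy(x, y)
  ctum <- lastc
  g <- 0
  ssc <- phase
  out <- matrix(NA_real_, n_steps + 1, 3)
  out[1, ] <- c(x, y, theta)
  arrived <- sqrt((x - tp$target[1])^2 + (y - tp$target[2])^2) <= config$goal_radius
  for (t in seq_len(n_steps)) {
    if (arrived) { out[t + 1, ] <- c(x, y, theta); next }
    tumbling <- ssc >= mo$run_length
    if (tumbling) {
      if (mo$gradient_mode == "run") {
        g <- (lastc - ctum) / (step_len * mo$run_length)
        ctum <- lastc
      }
      sdv <- sqrt(mo$tumble_sd_min^2 + (mo$tumble_sd_max^2 - mo$tumble_sd_min^2) /
                    (1 + exp(g / mo$gradient_scale)))
      ang <- theta + rnorm(1, 0, sdv)
    } else ang <- theta
    ang <- ang + rnorm(1, 0, mo$internal_noise_sd)
    ang <- ang - 2 * pi * floor((ang + pi) / (2 * pi))
    if (ang <= -pi) ang <- ang + 2 * pi
    x <- x + step_len * cos(ang)
    y <- y + step_len * sin(ang)
    theta <- ang
    newc <- cxy(x, y)
    if (mo$gradient_mode == "temporal") g <- (newc - lastc) / step_len
    lastc <- newc
    ssc <- if (tumbling) 1 else ssc + 1
    if (sqrt((x - tp$target[1])^2 + (y - tp$target[2])^2) <= config$goal_radius)
      arrived <- TRUE
    out[t + 1, ] <- c(x, y, theta)
  }
  out
}

# Compose a full multi-agent simulation from the exported per-step surface
# (group_directions + advance + update_weight), for equality against the
# compiled loop.
compose_simulation <- function(config, seed, n_steps) {
  set.seed(seed)
  agents <- init_swarm(config)
  xs <- list(agents)
  for (t in seq_len(n_steps)) {
    if (all(agents$arrived)) break
    gd <- if (config$policy$mode == "independent") NULL
    else group_directions(agents, config$zones)
    live <- !agents$arrived
    agents <- advance(agents, gd, config$terrain, config$motion)
    agents$w[live] <- update_weight(agents$w[live], agents$dC[live], config$policy)
    d <- sqrt((agents$x - config$terrain$target[1])^2 +
              (agents$y - config$terrain$target[2])^2)
    agents$arrived <- agents$arrived | d <= config$goal_radius
    xs[[length(xs) + 1L]] <- agents
  }
  xs
}

# small scrambled configuration for quick tests
tiny_config <- function(mechanism = "adaptive", n = 5, ...) {
  default_config(mechanism, n_agents = n, max_steps = 50L, ...)
}
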