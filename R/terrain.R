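#' Terrain (concentration map) parameters
#'
#' The terrain is a static scalar concentration field
#' \deqn{C(x, y) = A_K K_0(\kappa \, \max(\|p - p_T\|, \epsilon)) + P(x, y)}
#' where \eqn{K_0} is the modified Bessel function of the second kind (the
#' radially symmetric steady solution of two-dimensional diffusion from a
#' point source), \eqn{p_T} is the target location, and \eqn{P} is a periodic
#' perturbation creating mountains (low concentration) and valleys (high
#' concentration). Two periodic forms are available: a product of sines
#' \eqn{A_p \sin(k_x x)\sin(k_y y)} (default) or a sum of cosines
#' \eqn{\tfrac{A_p}{2}(\cos(k_x x) + \cos(k_y y))}.
#'
#' \eqn{K_0} diverges at the origin, so the field is capped on a small ring of
#' radius `singularity_radius` around the target; the target remains the
#' global concentration maximum as long as \eqn{A_K K_0(\kappa\epsilon)}
#' exceeds the periodic range there (checked at construction).
#'
#' @param target Numeric length-2: target (maximum-concentration) location.
#' @param bessel_amplitude \eqn{A_K \ge 0}, amplitude of the diffusion bowl
#'   (concentration units).
#' @param bessel_decay \eqn{\kappa > 0}, inverse length scale of the bowl.
#' @param periodic_amplitude \eqn{A_p \ge 0}, amplitude of the periodic
#'   mountains/valleys.
#' @param wavenumbers Numeric length-2 \eqn{(k_x, k_y) > 0}, inverse length.
#' @param singularity_radius \eqn{\epsilon > 0}, cap radius; must be
#'   `< 1 / bessel_decay`.
#' @param domain Numeric length-4 `c(xmin, xmax, ymin, ymax)` bounding the
#'   region of interest; the target must lie inside.
#' @param periodic_form `"product_sines"` or `"sum_cosines"`.
#' @return An object of class `terrain_params`.
#' @examples
#' tp <- terrain_params()
#' concentration(data.frame(x = c(0, 5), y = c(0, 0)), tp)
#' @export
terrain_params <- function(target = c(0, 0),
                           bessel_amplitude = 8,
                           bessel_decay = 0.1,
                           periodic_amplitude = 0.028,
                           wavenumbers = c(4, 4),
                           singularity_radius = 0.01 / bessel_decay,
                           domain = c(-10, 40, -25, 25),
                           periodic_form = c("product_sines", "sum_cosines")) {
  periodic_form <- match.arg(periodic_form)
  stopifnot(length(target) == 2, is.finite(target),
            length(wavenumbers) == 2, length(domain) == 4)
  if (bessel_amplitude < 0 || periodic_amplitude < 0)
    abort("amplitudes must be non-negative", class = "swarmtaxis_config_error")
  if (bessel_amplitude == 0 && periodic_amplitude == 0)
    abort("terrain is identically flat: need bessel_amplitude > 0 or periodic_amplitude > 0",
          class = "swarmtaxis_config_error")
  if (bessel_decay <= 0 || any(wavenumbers <= 0) || singularity_radius <= 0)
    abort("bessel_decay, wavenumbers and singularity_radius must be strictly positive",
          class = "swarmtaxis_config_error")
  if (singularity_radius >= 1 / bessel_decay)
    abort("singularity_radius must be smaller than 1/bessel_decay",
          class = "swarmtaxis_config_error")
  if (target[1] < domain[1] || target[1] > domain[2] ||
      target[2] < domain[3] || target[2] > domain[4])
    abort("target must lie inside domain", class = "swarmtaxis_config_error")
  if (bessel_amplitude > 0) {
    peak <- bessel_amplitude * besselK(bessel_decay * singularity_radius, 0)
    if (peak <= 2 * periodic_amplitude)
      warn("capped peak does not dominate the periodic range: target may not be the global maximum")
  }
  structure(
    list(target = as.numeric(target),
         bessel_amplitude = bessel_amplitude,
         bessel_decay = bessel_decay,
         periodic_amplitude = periodic_amplitude,
         wavenumbers = as.numeric(wavenumbers),
         singularity_radius = singularity_radius,
         domain = as.numeric(domain),
         periodic_form = periodic_form),
    class = "terrain_params")
}

#' @export
print.terrain_params <- function(x, ...) {
  cat("<terrain_params>\n")
  cat(sprintf("  target (%.3g, %.3g); bowl A_K=%g kappa=%g; periodic A_p=%g k=(%g, %g) [%s]\n",
              x$target[1], x$target[2], x$bessel_amplitude, x$bessel_decay,
              x$periodic_amplitude, x$wavenumbers[1], x$wavenumbers[2],
              x$periodic_form))
  cat(sprintf("  cap radius %g; domain [%g, %g] x [%g, %g]\n",
              x$singularity_radius, x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  invisible(x)
}

# vectorised numeric kernels -------------------------------------------------

conc_xy <- function(x, y, tp) {
  dx <- x - tp$target[1]
  dy <- y - tp$target[2]
  r <- sqrt(dx * dx + dy * dy)
  rc <- pmax(r, tp$singularity_radius)
  bess <- if (tp$bessel_amplitude > 0)
    tp$bessel_amplitude * besselK(tp$bessel_decay * rc, 0) else 0
  per <- if (tp$periodic_form == "product_sines")
    tp$periodic_amplitude * sin(tp$wavenumbers[1] * x) * sin(tp$wavenumbers[2] * y)
  else
    tp$periodic_amplitude * 0.5 * (cos(tp$wavenumbers[1] * x) + cos(tp$wavenumbers[2] * y))
  bess + per
}

grad_xy <- function(x, y, tp) {
  dx <- x - tp$target[1]
  dy <- y - tp$target[2]
  r <- sqrt(dx * dx + dy * dy)
  rc <- pmax(r, tp$singularity_radius)
  gx <- gy <- numeric(length(x))
  if (tp$bessel_amplitude > 0) {
    # dK0(z)/dz = -K1(z); inside the cap the ring value is used radially
    mag <- -tp$bessel_amplitude * tp$bessel_decay * besselK(tp$bessel_decay * rc, 1)
    ok <- r > 0
    gx[ok] <- mag[ok] * dx[ok] / r[ok]
    gy[ok] <- mag[ok] * dy[ok] / r[ok]
  }
  kx <- tp$wavenumbers[1]; ky <- tp$wavenumbers[2]
  if (tp$periodic_amplitude > 0) {
    if (tp$periodic_form == "product_sines") {
      gx <- gx + tp$periodic_amplitude * kx * cos(kx * x) * sin(ky * y)
      gy <- gy + tp$periodic_amplitude * ky * sin(kx * x) * cos(ky * y)
    } else {
      gx <- gx - tp$periodic_amplitude * 0.5 * kx * sin(kx * x)
      gy <- gy - tp$periodic_amplitude * 0.5 * ky * sin(ky * y)
    }
  }
  cbind(gx, gy, deparse.level = 0)
}

# data-frame-first user surface ----------------------------------------------

check_points <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points)))
    abort("`points` must be a data frame with columns x and y")
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    abort("point coordinates must be finite")
  invisible(points)
}

#' Concentration at a set of points
#'
#' @param points Data frame with columns `x`, `y`.
#' @param terrain A [terrain_params()] object.
#' @return The input as a tibble with a `concentration` column appended.
#' @export
concentration <- function(points, terrain) {
  check_points(points)
  as_tibble(points) %>% mutate(concentration = conc_xy(.data$x, .data$y, terrain))
}

#' Analytic concentration gradient at a set of points
#'
#' Uses \eqn{dK_0(z)/dz = -K_1(z)} for the bowl term. Inside the singularity
#' cap the gradient is the value on the cap ring taken along the radial
#' direction (so it still points at the target); exactly at the target the
#' radial part is zero.
#'
#' @inheritParams concentration
#' @return The input as a tibble with `dC_dx`, `dC_dy` columns appended.
#' @export
concentration_gradient <- function(points, terrain) {
  check_points(points)
  g <- grad_xy(points$x, points$y, terrain)
  as_tibble(points) %>% mutate(dC_dx = g[, 1], dC_dy = g[, 2])
}

#' Terrain height along a straight segment
#'
#' Height is the negated concentration: mountains are low concentration,
#' valleys high concentration, and the target is the lowest point.
#'
#' @param start,end Numeric length-2 endpoints.
#' @param n_samples Number of evenly spaced samples (>= 2).
#' @param terrain A [terrain_params()] object.
#' @return Tibble with columns `s` (arc length from `start`), `x`, `y`,
#'   `height`.
#' @export
height_profile <- function(start, end, n_samples, terrain) {
  stopifnot(length(start) == 2, length(end) == 2, is.finite(start), is.finite(end))
  if (n_samples < 2) abort("n_samples must be >= 2")
  tt <- seq(0, 1, length.out = n_samples)
  x <- start[1] + tt * (end[1] - start[1])
  y <- start[2] + tt * (end[2] - start[2])
  tibble(s = tt * sqrt(sum((end - start)^2)), x = x, y = y,
         height = -conc_xy(x, y, terrain))
}

#' Regular grid of concentration values
#'
#' Convenience export for plotting or CSV dumps.
#'
#' @param terrain A [terrain_params()] object.
#' @param n Grid points per axis.
#' @return Tibble with columns `x`, `y`, `concentration`.
#' @export
terrain_grid <- function(terrain, n = 101) {
  d <- terrain$domain
  g <- tidyr::expand_grid(x = seq(d[1], d[2], length.out = n),
                          y = seq(d[3], d[4], length.out = n))
  concentration(g, terrain)
}

#' Locate and classify stationary points of the terrain
#'
#' Scans a regular grid for local minima of the gradient norm, polishes each
#' candidate with damped Newton iterations on \eqn{\nabla C = 0} (Jacobian by
#' central differences), deduplicates, and classifies by the signs of the
#' numerical Hessian eigenvalues. Eigenvalues smaller in magnitude than
#' `degenerate_tol` (default `1e-6` times the natural curvature scale
#' \eqn{A_p \max(k)^2 + A_K \kappa^2}) mark a point `degenerate`. The capped
#' peak at the target is reported as a maximum when it dominates a small
#' surrounding ring.
#'
#' @param terrain A [terrain_params()] object.
#' @param grid_resolution Grid spacing; must be below half the shortest
#'   periodic wavelength.
#' @param degenerate_tol Optional override of the degeneracy tolerance.
#' @return Tibble with columns `x`, `y`, `class`
#'   (`"minimum"`, `"maximum"`, `"saddle"`, `"degenerate"`).
#' @export
find_critical_points <- function(terrain, grid_resolution = NULL,
                                 degenerate_tol = NULL) {
  lam <- 2 * pi / max(terrain$wavenumbers)
  if (is.null(grid_resolution)) grid_resolution <- lam / 8
  if (terrain$periodic_amplitude > 0 && grid_resolution >= lam / 2)
    abort("grid_resolution must be below half the periodic wavelength")
  d <- terrain$domain
  xs <- seq(d[1], d[2], by = grid_resolution)
  ys <- seq(d[3], d[4], by = grid_resolution)
  nx <- length(xs); ny <- length(ys)
  gg <- grad_xy(rep(xs, times = ny), rep(ys, each = nx), terrain)
  gn <- matrix(sqrt(gg[, 1]^2 + gg[, 2]^2), nrow = nx)

  # local minima of |grad C| over the 8-neighbourhood (interior cells only)
  cand <- list()
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- gn[i, j]
    if (v <= min(gn[(i - 1):(i + 1), (j - 1):(j + 1)]))
      cand[[length(cand) + 1L]] <- c(xs[i], ys[j])
  }

  h <- grid_resolution / 50
  hess_scale <- terrain$periodic_amplitude * max(terrain$wavenumbers)^2 +
    terrain$bessel_amplitude * terrain$bessel_decay^2
  tol <- if (is.null(degenerate_tol)) 1e-6 * hess_scale else degenerate_tol

  polish <- function(p) {
    for (it in 1:50) {
      g <- drop(grad_xy(p[1], p[2], terrain))
      if (sqrt(sum(g^2)) < 1e-12 * hess_scale * grid_resolution) break
      H <- num_hessian(p, terrain, h)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      if (sqrt(sum(step^2)) > grid_resolution) # stay near the candidate cell
        step <- step * grid_resolution / sqrt(sum(step^2))
      p <- p - step
    }
    g <- drop(grad_xy(p[1], p[2], terrain))
    if (sqrt(sum(g^2)) > 1e-6 * hess_scale * grid_resolution) NULL else p
  }

  pts <- list()
  eps <- terrain$singularity_radius
  for (p in cand) {
    if (sqrt(sum((p - terrain$target)^2)) < 2 * eps + grid_resolution &&
        terrain$bessel_amplitude > 0) next  # handled by the cap special case
    q <- polish(p)
    if (is.null(q)) next
    if (q[1] < d[1] || q[1] > d[2] || q[2] < d[3] || q[2] > d[4]) next
    pts[[length(pts) + 1L]] <- q
  }
  # deduplicate
  keep <- list()
  for (p in pts) {
    dup <- any(vapply(keep, function(q) sqrt(sum((p - q)^2)) < grid_resolution / 2,
                      logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- p
  }
  classify <- function(p) {
    ev <- eigen(num_hessian(p, terrain, h), symmetric = TRUE, only.values = TRUE)$values
    if (any(abs(ev) < tol)) "degenerate"
    else if (all(ev < 0)) "maximum"
    else if (all(ev > 0)) "minimum"
    else "saddle"
  }
  out <- if (length(keep))
    tibble(x = vapply(keep, `[`, numeric(1), 1),
           y = vapply(keep, `[`, numeric(1), 2),
           class = vapply(keep, classify, character(1)))
  else tibble(x = numeric(), y = numeric(), class = character())

  if (terrain$bessel_amplitude > 0) {
    tg <- terrain$target
    ring <- 2 * eps
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    c0 <- conc_xy(tg[1], tg[2], terrain)
    cr <- conc_xy(tg[1] + ring * cos(ang), tg[2] + ring * sin(ang), terrain)
    if (all(c0 > cr))
      out <- bind_rows(tibble(x = tg[1], y = tg[2], class = "maximum"), out)
  }
  arrange(out, .data$x, .data$y)
}

num_hessian <- function(p, terrain, h) {
  gxp <- grad_xy(p[1] + h, p[2], terrain); gxm <- grad_xy(p[1] - h, p[2], terrain)
  gyp <- grad_xy(p[1], p[2] + h, terrain); gym <- grad_xy(p[1], p[2] - h, terrain)
  H <- cbind(drop(gxp - gxm), drop(gyp - gym)) / (2 * h)
  (H + t(H)) / 2
}
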