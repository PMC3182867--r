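test_that("arrival times are first-entry steps with censoring", {
  cfg <- default_config("adaptive", max_steps = 400L)
  tr <- run_simulation(cfg, seed = 3, record = TRUE)
  at <- arrival_times(tr)
  expect_equal(nrow(at), cfg$n_agents)
  tgt <- cfg$terrain$target
  for (i in which(!at$censored)) {
    s <- at$step[i]
    d <- sqrt((tr$x[, i] - tgt[1])^2 + (tr$y[, i] - tgt[2])^2)
    expect_lte(d[s + 1], cfg$goal_radius)
    if (s > 0) expect_true(all(d[seq_len(s)] > cfg$goal_radius))
  }
  # an agent starting inside the goal radius arrives at time 0
  cfg0 <- default_config("independent", start_position = c(2.2, 0),
                         init_radius = 2, goal_radius = 1.4)
  tr0 <- run_simulation(cfg0, seed = 5)
  started_in <- sqrt(tr0$x[1, ]^2 + tr0$y[1, ]^2) <= 1.4
  expect_true(all(tr0$arrival_step[started_in] == 0))
})

test_that("noiseless straight-line arrival lands at the kinematic step count", {
  tp <- terrain_params(periodic_amplitude = 0)
  mo <- motion_params(internal_noise_sd = 0, run_length = 10000L)
  cfg <- default_config("independent", terrain = tp, motion = mo,
                        n_agents = 1L, start_position = c(10, 0),
                        init_radius = 1e-9, max_steps = 500L, goal_radius = 1)
  step <- mo$speed * mo$time_step
  for (seed in 1:10) {
    tr <- run_simulation(cfg, seed = seed, record = TRUE)
    # kinematic oracle: the agent runs straight along its initial heading
    p0 <- c(tr$x[1, 1], tr$y[1, 1]); th <- tr$theta[1, 1]
    d <- vapply(0:500, function(t)
      sqrt(sum((p0 + t * step * c(cos(th), sin(th)))^2)), numeric(1))
    hit <- which(d <= cfg$goal_radius)
    expected <- if (length(hit)) hit[1] - 1L else NA_integer_
    expect_identical(tr$arrival_step[1], expected)
  }
})

test_that("median path length handles censoring per the order-statistics oracle", {
  expect_equal(median_path_length(c(10, 20, NA), 1, 1), 20)
  expect_true(is.na(median_path_length(c(NA, NA, NA), 1, 1)))
  expect_true(is.na(median_path_length(c(5, NA, NA), 1, 1)))
  set.seed(41)
  for (case in 1:200) {
    n <- sample(1:9, 1)
    steps <- sample(1:50, n, replace = TRUE)
    steps[runif(n) < 0.3] <- NA
    expect_equal(median_path_length(steps, 0.1, 1),
                 sort_median_path(steps, 0.1, 1))
  }
})

test_that("error fraction is the relative path excess and propagates censoring", {
  expect_equal(error_fraction(30, 30), 0)
  expect_equal(error_fraction(1.65 * 30, 30), 0.65)
  expect_equal(error_fraction(1.5 * 30, 30), 0.5)
  expect_true(is.na(error_fraction(NA_real_, 30)))
  expect_error(error_fraction(10, 0))
})

test_that("the dynamics are invariant under a common rescaling of all lengths", {
  # the system is chaotic over long horizons, so invariance is checked on the
  # trajectory itself over a short window: positions divided by the scale
  # factor must coincide
  trs <- lapply(c(1, 3.7), function(f) {
    tp <- terrain_params(bessel_decay = 0.1 / f, periodic_amplitude = 0.028,
                         wavenumbers = c(4, 4) / f,
                         domain = c(-10, 40, -25, 25) * f)
    mo <- motion_params(speed = 0.1 * f, gradient_scale = 0.005 / f)
    cfg <- default_config("fixed", terrain = tp, motion = mo,
                          zones = interaction_zones(0.75 * f, 4.5 * f, 8 * f),
                          start_position = c(30 * f, 0), init_radius = 2 * f,
                          goal_radius = 1.4 * f, max_steps = 60L)
    tidy(run_simulation(cfg, seed = 17, record = TRUE))$x / f
  })
  expect_equal(trs[[1]], trs[[2]], tolerance = 1e-6)
})

test_that("group alignment is the time-averaged polar order in [0, 1]", {
  # hand-built trajectories
  mk_traj <- function(theta_mat, arrived = NULL) {
    nt <- nrow(theta_mat); n <- ncol(theta_mat)
    if (is.null(arrived)) arrived <- matrix(FALSE, nt, n)
    structure(list(theta = theta_mat, arrived = arrived, n_agents = n,
                   n_steps = nt - 1L,
                   alignment = NA_real_), class = "swarm_trajectory")
  }
  same <- mk_traj(matrix(0.7, 5, 4))
  expect_equal(group_alignment(same), 1)
  opp <- mk_traj(matrix(rep(c(0, pi), each = 5), 5, 2))
  expect_equal(group_alignment(opp), 0, tolerance = 1e-12)
  quad <- mk_traj(matrix(rep(c(0, pi / 2, pi, -pi / 2), each = 3), 3, 4))
  expect_equal(group_alignment(quad), 0, tolerance = 1e-12)
  set.seed(43)
  rnd <- mk_traj(matrix(runif(60, -pi, pi), 6, 10))
  a <- group_alignment(rnd)
  expect_gte(a, 0); expect_lte(a, 1)
  # pairwise variant is bounded by [-1, 1] and equals 1 for identical headings
  expect_equal(group_alignment(same, method = "pairwise"), 1)
})

test_that("recorded-trajectory alignment matches the online accumulator", {
  cfg <- default_config("fixed", max_steps = 300L)
  tr <- run_simulation(cfg, seed = 23, record = TRUE)
  expect_equal(group_alignment(tr), tr$alignment, tolerance = 1e-12)
  expect_equal(mean_weight(tr), tr$mean_weight, tolerance = 1e-12)
})

test_that("cluster counting equals the DFS oracle and is monotone in the radius", {
  one <- data.frame(x = c(0, 0.5, 1), y = 0)
  expect_equal(count_clusters(one, 2), 1L)
  expect_equal(count_clusters(one, 0.4), 3L)
  chain <- data.frame(x = cumsum(rep(0.9, 6)), y = 0)
  expect_equal(count_clusters(chain, 1), 1L)
  set.seed(47)
  for (case in 1:200) {
    n <- sample(1:12, 1)
    xy <- data.frame(x = runif(n, 0, 5), y = runif(n, 0, 5))
    r <- runif(1, 0.3, 3)
    expect_equal(count_clusters(xy, r), dfs_components(xy, r))
  }
  xy <- data.frame(x = runif(15, 0, 6), y = runif(15, 0, 6))
  radii <- seq(0.2, 4, by = 0.2)
  counts <- vapply(radii, function(r) count_clusters(xy, r), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mean weight averages over time and non-arrived agents", {
  w <- matrix(c(0.5, 0.5, 0.5,
                0.0, 0.5, 0.0,
                0.5, 0.0, 0.0), 3, 3, byrow = FALSE)
  arr <- matrix(FALSE, 3, 3); arr[3, 3] <- TRUE
  tr <- structure(list(w = w, arrived = arr, n_agents = 3, n_steps = 2,
                       mean_weight = NA_real_), class = "swarm_trajectory")
  # rows 2..3, excluding the arrived (3,3) entry
  expect_equal(mean_weight(tr), mean(c(0.5, 0.5, 0.5, 0.0, 0.0)))
  # fixed policy keeps the mean weight at the constant exactly
  cfg <- default_config("fixed", max_steps = 200L)
  tr2 <- run_simulation(cfg, seed = 29, record = FALSE)
  expect_equal(tr2$mean_weight, cfg$policy$fixed_w)
})

test_that("run summaries have the documented schema and internal consistency", {
  cfg <- default_config("adaptive", max_steps = 500L)
  tr <- run_simulation(cfg, seed = 31)
  s <- summarize_run(tr)
  expect_named(s, c("mechanism", "seed", "n_agents", "n_arrived",
                    "median_path_length", "censored", "error_fraction",
                    "alignment", "n_clusters", "mean_weight", "p90_path_length"))
  expect_equal(s$mechanism, "adaptive")
  expect_gte(s$n_clusters, 1L)
  expect_lte(s$n_clusters, cfg$n_agents)
  expect_equal(s$censored, is.na(s$median_path_length))
  if (!s$censored) {
    D <- sqrt(sum(cfg$start_position^2))
    expect_equal(s$error_fraction, (s$median_path_length - D) / D)
  }
})
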