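test_that("initial swarms are uniform on the disc with uniform headings", {
  cfg <- default_config("adaptive")
  set.seed(51)
  draws <- do.call(rbind, lapply(1:500, function(i) {
    ag <- init_swarm(cfg)
    cbind(ag$x, ag$y)
  }))
  d <- sqrt((draws[, 1] - cfg$start_position[1])^2 +
            (draws[, 2] - cfg$start_position[2])^2)
  expect_true(all(d <= cfg$init_radius + 1e-12))
  # area-uniformity: mean position is the centre within 3 standard errors
  n <- nrow(draws)
  se <- cfg$init_radius / 2 / sqrt(n)  # sd of one coordinate is R/2
  expect_lt(abs(mean(draws[, 1]) - cfg$start_position[1]), 3 * se)
  expect_lt(abs(mean(draws[, 2]) - cfg$start_position[2]), 3 * se)
  # fixed seed reproduces the swarm exactly
  set.seed(52); a <- init_swarm(cfg)
  set.seed(52); b <- init_swarm(cfg)
  expect_identical(a, b)
})

test_that("heterogeneous run lengths are uniform over the configured integers", {
  cfg <- default_config("adaptive", tau_range = c(2L, 6L))
  set.seed(53)
  taus <- unlist(lapply(1:400, function(i) init_swarm(cfg)$tau))
  expect_setequal(sort(unique(taus)), 2:6)
  expect_true(all(table(taus) > 0.15 * length(taus) / 5))
  # tumble phases stay below each agent's tau
  set.seed(54)
  ag <- init_swarm(cfg)
  expect_true(all(ag$steps_since_tumble >= 0 & ag$steps_since_tumble < ag$tau))
})

test_that("configuration invariants produce field-level errors", {
  expect_error(default_config("fixed", n_agents = 0), class = "swarmtaxis_config_error")
  expect_error(default_config("fixed", init_radius = 40), class = "swarmtaxis_config_error")
  expect_error(default_config("fixed", tau_range = c(5, 2)), class = "swarmtaxis_config_error")
  expect_error(simulation_config(policy = weight_policy("fixed", fixed_w = 2)),
               class = "swarmtaxis_config_error")
})

test_that("the compiled loop equals the composed R-level pipeline step by step", {
  for (mech in c("independent", "fixed", "adaptive")) {
    cfg <- tiny_config(mech, n = 5)
    ref <- compose_simulation(cfg, seed = 61, n_steps = cfg$max_steps)
    tr <- run_simulation(cfg, seed = 61, record = TRUE)
    nt <- length(ref)
    expect_equal(nrow(tr$x), nt)
    last <- ref[[nt]]
    expect_equal(tr$x[nt, ], last$x, tolerance = 1e-12)
    expect_equal(tr$y[nt, ], last$y, tolerance = 1e-12)
    expect_equal(tr$theta[nt, ], last$theta, tolerance = 1e-12)
    expect_equal(tr$w[nt, ], last$w, tolerance = 1e-12)
    mid <- ref[[ceiling(nt / 2)]]
    expect_equal(tr$x[ceiling(nt / 2), ], mid$x, tolerance = 1e-12)
  }
})

test_that("a single independent agent reduces to the reference chemotaxis walk", {
  cfg <- default_config("independent", n_agents = 1L, max_steps = 200L)
  ref <- reference_walk(cfg, seed = 63, n_steps = 200L)
  tr <- run_simulation(cfg, seed = 63, record = TRUE)
  nt <- min(nrow(ref), nrow(tr$x))
  expect_equal(tr$x[1:nt, 1], ref[1:nt, 1], tolerance = 1e-12)
  expect_equal(tr$y[1:nt, 1], ref[1:nt, 2], tolerance = 1e-12)
  expect_equal(tr$theta[1:nt, 1], ref[1:nt, 3], tolerance = 1e-12)
})

test_that("full self-weight with vanishing interaction radii reproduces independent motion", {
  zo <- interaction_zones(1e-12, 2e-12, 3e-12)
  fx <- default_config("fixed", zones = zo, goal_radius = 1.4, max_steps = 300L)
  fx$policy <- weight_policy("fixed", fixed_w = 1)
  ind <- default_config("independent", zones = zo, goal_radius = 1.4, max_steps = 300L)
  a <- run_simulation(fx, seed = 65, record = TRUE)
  b <- run_simulation(ind, seed = 65, record = TRUE)
  expect_identical(a$x, b$x)
  expect_identical(a$theta, b$theta)
  expect_identical(a$arrival_step, b$arrival_step)
})

test_that("ensembles derive per-run seeds so extensions reproduce earlier runs", {
  cfg <- tiny_config("fixed", n = 4)
  e1 <- run_ensemble(cfg, n_rounds = 4, base_seed = 71)
  e2 <- run_ensemble(cfg, n_rounds = 8, base_seed = 71)
  expect_equal(e1$runs, e2$runs[1:4, ])
  g <- glance(e1)
  expect_equal(g$n_rounds, 4L)
  paths <- e1$runs$median_path_length
  if (sum(!is.na(paths)) > 1)
    expect_equal(g$se_median_path, sd(paths, na.rm = TRUE) / sqrt(sum(!is.na(paths))))
  # single-round aggregate equals the run itself
  e3 <- run_ensemble(cfg, n_rounds = 1, base_seed = 71)
  expect_equal(e3$runs$median_path_length[1], e1$runs$median_path_length[1])
  # arrivals + censored agents account for the whole group
  expect_true(all(e1$runs$n_arrived <= cfg$n_agents))
})

test_that("sweeps produce long-format matched-seed tables and validate values", {
  cfg <- tiny_config("fixed", n = 4)
  sw <- sweep_parameter(cfg, "fixed_w", c(0.2, 0.8), n_rounds = 3, base_seed = 81)
  expect_equal(nrow(sw$runs), 6L)
  expect_equal(sort(unique(sw$runs$value)), c(0.2, 0.8))
  expect_equal(unname(table(sw$runs$value)), c(3L, 3L), ignore_attr = TRUE)
  # sweeping a single value reproduces run_ensemble exactly
  one <- sweep_parameter(cfg, "sigma_eta", 0.1, n_rounds = 3, base_seed = 81)
  ens <- run_ensemble(cfg, n_rounds = 3, base_seed = 81)
  expect_equal(one$runs$median_path_length, ens$runs$median_path_length)
  # invalid entries rejected
  expect_error(sweep_parameter(cfg, "speed", 1), "sweepable")
  bad <- data.frame(orientation = 5, attraction = 4)
  expect_error(sweep_parameter(cfg, "radii", bad), class = "swarmtaxis_config_error")
})

test_that("mechanism comparison runs matched seeds and degenerates to equality without interactions", {
  zo <- interaction_zones(1e-12, 2e-12, 3e-12)
  cfg <- default_config("fixed", zones = zo, goal_radius = 1.4, max_steps = 400L)
  mc <- mechanism_comparison(cfg, n_rounds = 30, base_seed = 91, fixed_w = 1)
  expect_equal(nrow(mc$runs), 90L)
  # with no interactions the fixed(w=1) and independent distributions coincide
  pf <- with(dplyr::filter(mc$runs, mechanism == "fixed"), median_path_length)
  pi_ <- with(dplyr::filter(mc$runs, mechanism == "independent"), median_path_length)
  expect_equal(pf, pi_)
  p <- mc$tests$p_value[mc$tests$faster == "fixed" & mc$tests$slower == "independent"]
  expect_gt(p, 0.01)
})

test_that("config validation diagnoses run length and repulsion radius against the terrain", {
  ok <- validate_config(default_config("fixed"))
  expect_true(all(ok$status == "ok"))
  lam <- attr(ok, "characteristic_length")
  expect_equal(lam, 2 * pi / 4)
  # runs much longer than the wavelength
  mo <- motion_params(run_length = 200L)
  long <- validate_config(default_config("fixed", motion = mo))
  expect_true(any(long$status == "warning" & grepl("too long", long$message)))
  # runs far below the detectable scale
  tiny_mo <- motion_params(speed = 1e-4)
  short <- validate_config(default_config("fixed", motion = tiny_mo))
  expect_true(any(short$status == "warning" & grepl("too short", short$message)))
  # repulsion radius comparable to the wavelength
  zo <- interaction_zones(1.5, 4.5, 8)
  wide <- validate_config(default_config("fixed", zones = zo, goal_radius = 1.4))
  expect_true(any(wide$status == "warning" & grepl("repulsion", wide$message)))
})

test_that("configurations round-trip through JSON and unknown keys are rejected", {
  cfg <- default_config("adaptive", tau_range = c(2L, 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$terrain, cfg$terrain)
  expect_equal(back$motion, cfg$motion)
  expect_equal(back$zones, cfg$zones)
  expect_equal(back$policy, cfg$policy)
  expect_equal(back$tau_range, cfg$tau_range)
  expect_equal(back$goal_radius, cfg$goal_radius)
  # same seed, same config file -> identical run records
  r1 <- summarize_run(run_simulation(cfg, seed = 7, record = FALSE))
  r2 <- summarize_run(run_simulation(back, seed = 7, record = FALSE))
  expect_equal(r1, r2)
  # unknown key rejection
  obj <- jsonlite::read_json(path)
  obj$terrain$unknown_knob <- 1
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, auto_unbox = TRUE)
  expect_error(read_config(path2), "unknown key")
})

test_that("tidy() output of a trajectory is time-aligned long format", {
  cfg <- tiny_config("adaptive", n = 3)
  tr <- run_simulation(cfg, seed = 15, record = TRUE)
  td <- tidy(tr)
  expect_equal(nrow(td), (tr$n_steps + 1) * 3)
  expect_equal(unique(td$agent), 1:3)
  a1 <- dplyr::filter(td, agent == 1)
  expect_equal(a1$x, tr$x[, 1])
  # arrived flags never revert
  for (i in 1:3) {
    fl <- dplyr::filter(td, agent == i)$arrived
    expect_true(all(diff(as.integer(fl)) >= 0))
  }
})
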