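test_that("seeding is uniform in the configured slab with unit orientations", {
  cfg <- simulation_config(n_microbes = 1e4, seed = 1)
  ens <- seed_microbes(cfg)
  expect_true(all(ens$X[, 3] >= 0.15 & ens$X[, 3] <= 0.3))
  expect_true(all(ens$X[, 1] >= 0 & ens$X[, 1] <= 0.6))
  expect_equal(max(abs(rowSums(ens$P^2) - 1)), 0, tolerance = 1e-12)
  # orientation components have mean 0 within 3 sigma for a uniform sphere
  sigma <- 1 / sqrt(3 * 1e4)
  expect_true(all(abs(colMeans(ens$P)) < 3 * sigma))

  # N = 1 and determinism
  ens1 <- seed_microbes(simulation_config(n_microbes = 1, seed = 5))
  expect_equal(sum(ens1$P^2), 1, tolerance = 1e-14)
  expect_identical(seed_microbes(cfg), seed_microbes(cfg))

  expect_error(simulation_config(seed_z_range = c(0.2, 0.2)), "range")
})

test_that("vertical orientation is a fixed point and relaxation follows the closed form", {
  mot <- motility_params("gyrotactic", B = 1, v_swim = 1e-4)
  p <- c(0, 0, 1)
  expect_equal(orientation_step(p, c(0, 0, 0), mot, 0.01), p)

  # horizontal start, no vorticity: theta(t) = 2 atan(tan(theta0/2) e^(-t/2B))
  p <- c(1, 0, 0)
  dt <- 1e-4
  for (s in seq_len(2 / dt)) p <- orientation_step(p, c(0, 0, 0), mot, dt)
  theta <- acos(p[3])
  expect_equal(theta, relaxation_theta(pi / 2, 1, 2), tolerance = 1e-3)

  # corrupted input rejected
  expect_error(orientation_step(c(1, 0, 1), c(0, 0, 0), mot, dt), "unit")
})

test_that("steady vorticity tilts swimmers to sin(theta_eq) = B|omega|, or tumbles them", {
  # stationary tilt across a (B, omega) grid with B|omega| <= 0.9
  for (case in list(c(1, 0.4), c(3, 0.2), c(5, 0.12), c(2, 0.45))) {
    B <- case[1]; wy <- case[2]
    mot <- motility_params("gyrotactic", B = B, v_swim = 0)
    p <- c(0.05, 0, sqrt(1 - 0.05^2))
    dt <- 1e-3
    for (s in seq_len(round(60 * B / dt))) p <- orientation_step(p, c(0, wy, 0), mot, dt)
    expect_equal(sin(acos(p[3])), B * wy, tolerance = 1e-3)
  }

  # B|omega| > 1: no fixed point, the swimmer tumbles through theta = pi
  res <- integrate_orientation_fine(c(0, 0, 1), c(0, 0.5, 0), B = 5,
                                    t_end = 100, dt = 1e-4)
  expect_lt(res$min_pz, -0.9)
  mot <- motility_params("gyrotactic", B = 5, v_swim = 0)
  p <- c(0, 0, 1)
  minpz <- 1
  dt <- 1e-3
  for (s in seq_len(1e5)) {
    p <- orientation_step(p, c(0, 0.5, 0), mot, dt)
    minpz <- min(minpz, p[3])
  }
  expect_lt(minpz, -0.9)
})

test_that("non-gyrotactic orientations rotate with vorticity only", {
  mot <- motility_params("non_gyrotactic_motile", v_swim = 1e-4)
  # solid rotation omega about y: p precesses, no drift toward vertical
  p <- c(1, 0, 0)
  dt <- 1e-3
  for (s in seq_len(1000)) p <- orientation_step(p, c(0, 2 * pi, 0), mot, dt)
  # after 1 s at rotation rate omega/2 = pi rad/s the vector has turned half
  # a revolution: p ~ (-1, 0, 0)
  expect_equal(p[1], -1, tolerance = 1e-2)
  expect_equal(sum(p^2), 1, tolerance = 1e-12)
})

test_that("RK4 position updates are exact for constant motion and 4th order on vortices", {
  dom <- flow_domain()
  still <- make_uniform_flow(c(0, 0, 0))
  mot <- motility_params("gyrotactic", B = 1, v_swim = 100e-6)
  X <- c(0.3, 0.3, 0.2)
  for (s in 1:1000) X <- position_step(X, c(0, 0, 1), mot, still, 0, 0.01)
  expect_equal(unname(X[3]) - 0.2, 1e-3, tolerance = 1e-9)

  uni <- make_uniform_flow(c(0.01, 0, 0))
  passive <- motility_params("non_motile")
  X <- c(0.1, 0.3, 0.2)
  for (s in 1:100) X <- position_step(X, c(0, 0, 1), passive, uni, 0, 0.01)
  expect_equal(unname(X[1]) - 0.1, 0.01, tolerance = 1e-9)

  # Richardson convergence on a Taylor-Green vortex
  tg <- make_taylor_green(U = 0.05, kappa = 2 * pi / 0.6)
  integrate_to <- function(dt, t_end = 1) {
    X <- c(0.21, 0.3, 0.17)
    for (s in seq_len(round(t_end / dt)))
      X <- position_step(X, c(0, 0, 1), passive, tg, (s - 1) * dt, dt)
    X
  }
  ref <- integrate_to(1e-4)
  errs <- vapply(c(0.08, 0.04, 0.02), function(dt)
    sqrt(sum((integrate_to(dt) - ref)^2)), 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("boundaries wrap horizontally and reflect vertically", {
  dom <- flow_domain()
  expect_equal(apply_boundaries(c(0.61, -0.01, 0.305), dom), c(0.01, 0.59, 0.295))
  expect_equal(apply_boundaries(c(0.2, 0.3, 0.1), dom), c(0.2, 0.3, 0.1))
  expect_equal(apply_boundaries(c(0.2, 0.3, 0.3), dom), c(0.2, 0.3, 0.3))
  expect_equal(apply_boundaries(c(0.2, 0.3, -0.02), dom)[3], 0.02)
  expect_error(apply_boundaries(c(0.2, 0.3, 0.95), dom), "timestep")
})

test_that("simulations are deterministic and respect motility modes", {
  tg <- make_taylor_green(U = 0.01, kappa = 2 * pi / 0.6)
  cfg <- simulation_config(n_microbes = 40, dt = 0.01, total_time = 2,
                           output_interval = 0.5, seed = 7)
  tr1 <- run_simulation(cfg, tg, motility_params("gyrotactic", B = 1, v_swim = 5e-4))
  tr2 <- run_simulation(cfg, tg, motility_params("gyrotactic", B = 1, v_swim = 5e-4))
  expect_identical(tr1$X, tr2$X)
  expect_identical(tr1$P, tr2$P)

  # unit norm preserved at every record
  expect_lt(max(abs(sqrt(rowSums(matrix(tr1$P, ncol = 3)^2)) - 1)), 1e-12)

  # non-motile microbes never change orientation
  trn <- run_simulation(cfg, tg, motility_params("non_motile"))
  for (i in seq_along(trn$times))
    expect_identical(trn$P[i, , ], trn$P[1, , ])

  # record times and the initial condition
  expect_equal(tr1$times, seq(0, 2, by = 0.5))
  expect_identical(tr1$X[1, , ], seed_microbes(cfg)$X)
})

test_that("gyrotactic microbes in still fluid align upright and ascend at v_swim", {
  still <- make_uniform_flow(c(0, 0, 0))
  cfg <- simulation_config(n_microbes = 30, dt = 0.01, total_time = 20,
                           output_interval = 1, seed = 3,
                           seed_z_range = c(0.15, 0.2))
  tr <- run_simulation(cfg, still, motility_params("gyrotactic", B = 1, v_swim = 1e-4))
  theta_end <- acos(tr$P[length(tr$times), , 3])
  expect_lt(max(theta_end) * 180 / pi, 1)  # all upright within 1 degree

  # after alignment (~5 s) the climb rate is v_swim
  z10 <- tr$X[which(tr$times == 10), , 3]
  z20 <- tr$X[which(tr$times == 20), , 3]
  expect_equal(z20 - z10, rep(1e-3, 30), tolerance = 1e-3)
})

test_that("trajectory netCDF round trip preserves state and metadata", {
  tg <- make_taylor_green()
  cfg <- simulation_config(n_microbes = 10, dt = 0.01, total_time = 1,
                           output_interval = 0.5, seed = 2)
  tr <- run_simulation(cfg, tg, motility_params("gyrotactic", B = 3, v_swim = 1e-4))
  path <- withr::local_tempfile(fileext = ".nc")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$X, tr$X, tolerance = 1e-14)
  expect_equal(tr2$P, tr$P, tolerance = 1e-14)
  expect_equal(tr2$motility$B, 3)
  expect_equal(tr2$motility$v_swim, 1e-4)
  expect_equal(tr2$times, tr$times)
})
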