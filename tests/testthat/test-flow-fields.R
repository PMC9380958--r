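test_that("Taylor-Green field is divergence-free with exact closed-form vorticity", {
  tg <- make_taylor_green(U = 0.01, kappa = 2 * pi / 0.6)
  set.seed(11)
  X <- runif_positions(100)
  divs <- vapply(seq_len(100), function(i) fd_divergence(tg, X[i, ], 0), 0)
  expect_lt(max(abs(divs)), 1e-9)

  # stagnation point at a vortex corner
  expect_equal(evaluate_velocity(tg, c(0, 0.123, 0), 0), c(u = 0, v = 0, w = 0))

  # closed-form curl vs centred finite differences
  for (i in 1:25) {
    num <- fd_curl(tg, X[i, ], 0)
    ana <- evaluate_vorticity(tg, X[i, ], 0)
    expect_lt(max(abs(num - ana)) / max(max(abs(ana)), 1e-8), 1e-6)
  }

  # non-tiling wavenumber rejected
  expect_error(make_taylor_green(U = 0.01, kappa = 7), "tile")
})

test_that("analytic fields return the expected velocities and vorticities", {
  uni <- make_uniform_flow(c(0.01, 0, 0))
  expect_equal(evaluate_velocity(uni, c(0.5, 0.1, 0.2), 3),
               c(u = 0.01, v = 0, w = 0))
  expect_equal(unname(evaluate_vorticity(uni, c(0.5, 0.1, 0.2), 0)), c(0, 0, 0))

  sbr <- make_solid_body_rotation(Omega = c(0, 0.4, 0))
  set.seed(2)
  X <- runif_positions(10)
  W <- evaluate_vorticity(sbr, X, 0)
  expect_equal(unname(W), matrix(rep(c(0, 0.8, 0), each = 10), 10))

  sh <- make_simple_shear(dudz = 2)
  expect_equal(unname(evaluate_velocity(sh, c(0.1, 0.1, 0.25), 0)), c(0.5, 0, 0))
  expect_equal(unname(evaluate_vorticity(sh, c(0.1, 0.1, 0.25), 0)), c(0, 2, 0))
})

test_that("kinematic turbulence is solenoidal, isotropic at the surface, and calibrated", {
  kf <- make_kinematic_turbulence(n_modes = 64, seed = 1)
  set.seed(5)
  X <- runif_positions(200)
  ts <- runif(5, 0, 10)
  # |div u| small relative to u_rms over the smallest resolved scale
  eta <- 2 * pi / max(kf$modes$k)
  tol <- 1e-6 * kf$u_rms / eta
  divs <- unlist(lapply(ts, function(tt)
    vapply(1:40, function(i) fd_divergence(kf, X[i, ], tt, h = 1e-5), 0)))
  expect_lt(max(abs(divs)), tol)

  # closed-form vorticity agrees with finite-difference curl (sampled in
  # the turbulent layer; the deep water is exactly quiescent)
  Xt <- cbind(X[1:25, 1:2], runif(25, 0.18, 0.3))
  for (i in 1:25) {
    num <- fd_curl(kf, Xt[i, ], 0.7, h = 1e-5)
    ana <- evaluate_vorticity(kf, Xt[i, ], 0.7)
    expect_lt(max(abs(num - ana)) / max(abs(ana)), 1e-4)
  }

  # surface plane is a material boundary: w vanishes identically there and
  # its variance is carried by the horizontal components, whose summed
  # variance matches the calibrated u_rms^2 within 10%
  set.seed(31)
  Xs <- cbind(runif(1e4, 0, 0.6), runif(1e4, 0, 0.6), 0.3)
  us <- evaluate_velocity(kf, Xs, 0)
  expect_lt(max(abs(us[, 3])), 1e-12 * kf$u_rms)
  expect_equal(var(us[, 1]) + var(us[, 2]), kf$u_rms^2, tolerance = 0.1)

  # interior: every component carries an order-one share of the variance
  # (residual anisotropy from the surface blocking is bounded)
  Xi <- cbind(runif(1e4, 0, 0.6), runif(1e4, 0, 0.6), 0.2)
  vi <- apply(evaluate_velocity(kf, Xi, 0.7), 2, var)
  expect_true(all(vi > 0.4 * mean(vi) & vi < 1.6 * mean(vi)))

  # envelope: below the interface the fluid is quiescent
  Xd <- cbind(runif(500, 0, 0.6), runif(500, 0, 0.6), 0.05)
  rms_deep <- sqrt(mean(rowSums(evaluate_velocity(kf, Xd, 0)^2)))
  rms_surf <- sqrt(mean(rowSums(us^2)))
  expect_lt(rms_deep, 0.01 * rms_surf)

  # determinism: same seed, bit-identical coefficients
  kf2 <- make_kinematic_turbulence(n_modes = 64, seed = 1)
  expect_identical(kf$C, kf2$C)
  expect_identical(kf$omega, kf2$omega)

  # prescribed spectrum recovered from the mode energies
  m <- unique(kf$modes[, c("k", "energy")])
  slope <- coef(lm(log(energy) ~ log(k), data = m))[[2]]
  expect_equal(slope, -5 / 3, tolerance = 0.1)

  # degenerate band and missing seed rejected
  expect_error(make_kinematic_turbulence(k_min = 10, k_max = 10), "degenerate")
  expect_error(make_kinematic_turbulence(n_modes = 4), "n_modes")
})

test_that("turbulence profile recovers k and epsilon depth structure", {
  # quiescent flow: k = 0, epsilon = 0 everywhere
  still <- make_uniform_flow(c(0, 0, 0))
  pr0 <- turbulence_profile(still, z_levels = c(0.05, 0.2), nu = 5e-6,
                            n_samples = 200)
  expect_equal(pr0$k, c(0, 0))
  expect_equal(pr0$epsilon, c(0, 0))

  kf <- make_kinematic_turbulence(n_modes = 64, seed = 1)
  pr <- turbulence_profile(kf, z_levels = seq(0.1, 0.3, by = 0.02), nu = 5e-6,
                           n_samples = 2000, t_window = c(0, 5), seed = 1)
  # k at the envelope peak ~ u_rms^2 / 2 within 10%
  expect_equal(pr$k[pr$z == 0.3], kf$u_rms^2 / 2, tolerance = 0.1)
  # monotone decay of k with depth
  expect_gt(cor(pr$k, pr$z, method = "spearman"), 0.9)
  expect_true(all(pr$epsilon >= 0))
})

test_that("gridded fields interpolate exactly at nodes and for linear fields", {
  nx <- 8; ny <- 8; nz <- 8; nt <- 3
  x <- (seq_len(nx) - 0.5) * 0.6 / nx
  y <- (seq_len(ny) - 0.5) * 0.6 / ny
  z <- (seq_len(nz) - 0.5) * 0.3 / nz
  times <- c(0, 1, 2)
  set.seed(3)
  mk <- function() array(rnorm(nx * ny * nz * nt), c(nx, ny, nz, nt))
  u <- mk(); v <- mk(); w <- mk()
  f <- make_gridded_field(u, v, w, x, y, z, times)

  # write-then-read round trip: node values recovered exactly
  path <- withr::local_tempfile(fileext = ".nc")
  write_gridded_field(f, path)
  f2 <- load_gridded_field(path)
  for (it in seq_len(nt)) for (k in c(1, 4, 8)) for (j in c(1, 5)) for (i in c(2, 8)) {
    got <- evaluate_velocity(f2, c(x[i], y[j], z[k]), times[it])
    expect_equal(unname(got), c(u[i, j, k, it], v[i, j, k, it], w[i, j, k, it]),
                 tolerance = 1e-12)
  }

  # globally linear field reproduced exactly at arbitrary interior points
  cgrad <- 0.37
  ul <- array(rep(cgrad * x, ny * nz * nt), c(nx, ny, nz, nt))
  zl <- array(0, c(nx, ny, nz, nt))
  fl <- make_gridded_field(ul, zl, zl, x, y, z, times)
  set.seed(4)
  for (q in 1:20) {
    xq <- c(runif(1, x[1], x[nx]), runif(1, y[1], y[ny]), runif(1, z[1], z[nz]))
    expect_equal(evaluate_velocity(fl, xq, 0.5)[[1]], cgrad * xq[1],
                 tolerance = 1e-12)
  }

  # linear interpolation in time between snapshot values 0 and 1
  u0 <- array(0, c(nx, ny, nz, 2)); u0[, , , 2] <- 1
  z0 <- array(0, c(nx, ny, nz, 2))
  ft <- make_gridded_field(u0, z0, z0, x, y, z, c(0, 1))
  expect_equal(evaluate_velocity(ft, c(x[3], y[3], z[3]), 0.5)[[1]], 0.5)
  expect_error(evaluate_velocity(ft, c(x[3], y[3], z[3]), 2), "span")

  # malformed files are rejected with the offending name
  nc <- ncdf4::nc_open(path, write = TRUE)
  ncdf4::nc_close(nc)
  path2 <- withr::local_tempfile(fileext = ".nc")
  d1 <- ncdf4::ncdim_def("x", "m", x); d2 <- ncdf4::ncdim_def("y", "m", y)
  d3 <- ncdf4::ncdim_def("z", "m", z); d4 <- ncdf4::ncdim_def("t", "s", times)
  vv <- ncdf4::ncvar_def("u", "m s-1", list(d1, d2, d3, d4))
  nc2 <- ncdf4::nc_create(path2, list(vv))
  ncdf4::ncvar_put(nc2, vv, u)
  ncdf4::nc_close(nc2)
  expect_error(load_gridded_field(path2), "`v`")
})

test_that("grid bookkeeping matches a published header", {
  gs <- grid_spec(720, 720, 360, domain = flow_domain(0.6, 0.6, 0.3))
  expect_equal(n_cells(gs), 186624000)
  expect_equal(gs$dx_m, 0.6 / 720)
})

test_that("out-of-range vertical queries clamp to the nearest plane", {
  nx <- 4
  x <- (seq_len(nx) - 0.5) * 0.6 / nx
  z <- (seq_len(nx) - 0.5) * 0.3 / nx
  u <- array(rep(z, each = nx * nx), c(nx, nx, nx, 1))  # u = z at nodes
  zero <- array(0, c(nx, nx, nx, 1))
  f <- make_gridded_field(u, zero, zero, x, x, z, 0)
  top <- evaluate_velocity(f, c(0.3, 0.3, 0.31), 0)[[1]]
  expect_equal(top, z[nx])
  bottom <- evaluate_velocity(f, c(0.3, 0.3, 0.0), 0)[[1]]
  expect_equal(bottom, z[1])
})
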