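#' Motility parameters
#'
#' Describes a microbe population's swimming behaviour. Gyrotactic swimmers
#' are bottom-heavy spheres that reorient toward the upward vertical on a
#' timescale `B` while being overturned by fluid vorticity; non-gyrotactic
#' motile microbes swim at `v_swim` but have no restoring torque (their
#' orientation is rotated by vorticity only); non-motile microbes are
#' passive tracers.
#'
#' @param mode One of `"gyrotactic"`, `"non_gyrotactic_motile"`,
#'   `"non_motile"`.
#' @param B Gyrotactic reorientation timescale (s); required for (and only
#'   for) gyrotactic mode.
#' @param v_swim Swim speed (m/s); must be 0 for non-motile microbes.
#' @return A `gp_motility`.
#' @examples
#' motility_params("gyrotactic", B = 1, v_swim = 500e-6)
#' motility_params("non_motile")
#' @export
motility_params <- function(mode = c("gyrotactic", "non_gyrotactic_motile", "non_motile"),
                            B = NULL, v_swim = 0) {
  mode <- match.arg(mode)
  stopifnot_scalar(v_swim, "v_swim", nonneg = TRUE)
  if (mode == "gyrotactic") {
    if (is.null(B)) abort("gyrotactic motility requires the reorientation timescale `B` (s)")
    stopifnot_scalar(B, "B", positive = TRUE)
  } else {
    if (!is.null(B)) abort(sprintf("`B` is only meaningful for gyrotactic microbes (mode = \"%s\")", mode))
  }
  if (mode == "non_motile" && v_swim != 0)
    abort("non-motile microbes must have v_swim = 0")
  structure(list(mode = mode, B = B, v_swim = v_swim), class = "gp_motility")
}

#' @export
print.gp_motility <- function(x, ...) {
  cat(sprintf("<motility: %s%s, v_swim = %g um/s>\n", x$mode,
              if (!is.null(x$B)) sprintf(", B = %g s", x$B) else "",
              x$v_swim * 1e6))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects the numerical parameters of a Lagrangian microbe run. Defaults
#' follow the standard protocol for a 60 s convective mixed-layer
#' experiment: timestep 0.01 s, state recorded every 0.1 s, microbes seeded
#' uniformly in the upper half of the water column (`z >= 0.15` m) with
#' uniformly random swimming directions.
#'
#' @param n_microbes Number of agents.
#' @param dt Timestep (s).
#' @param total_time Simulated duration (s).
#' @param output_interval Recording cadence (s); must be an integer multiple
#'   of `dt`.
#' @param seed_z_range Length-2 vertical seeding range (m).
#' @param seed Integer RNG seed; positions are drawn first, then
#'   orientations, each microbe-major, so runs are reproducible.
#' @param domain A [flow_domain()].
#' @return A `gp_sim_config`.
#' @export
simulation_config <- function(n_microbes = 1000L, dt = 0.01, total_time = 60,
                              output_interval = 0.1,
                              seed_z_range = c(0.15, 0.3), seed = 1L,
                              domain = flow_domain()) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(total_time, "total_time", positive = TRUE)
  if (n_microbes < 1) abort("`n_microbes` must be >= 1")
  ratio <- output_interval / dt
  if (abs(ratio - round(ratio)) > 1e-8)
    abort("`output_interval` must be an integer multiple of `dt`")
  if (length(seed_z_range) != 2L || seed_z_range[2] <= seed_z_range[1])
    abort("`seed_z_range` must be an increasing (z_min, z_max) pair; an empty range is not seedable")
  if (seed_z_range[1] < 0 || seed_z_range[2] > domain$Lz)
    abort("`seed_z_range` must lie within [0, Lz]")
  structure(list(n_microbes = as.integer(n_microbes), dt = dt,
                 total_time = total_time, output_interval = output_interval,
                 seed_z_range = seed_z_range, seed = as.integer(seed),
                 domain = domain),
            class = "gp_sim_config")
}

#' Seed a microbe ensemble
#'
#' Draws initial positions uniformly in the horizontal extent of the domain
#' and the configured vertical range, and initial swimming directions
#' uniformly on the unit sphere. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `gp_ensemble` with `X` (N x 3 positions, m) and `P` (N x 3 unit
#'   orientations).
#' @export
seed_microbes <- function(config) {
  n <- config$n_microbes
  dom <- config$domain
  with_local_seed(config$seed, {
    X <- matrix(runif(3 * n), ncol = 3, byrow = TRUE)
    X[, 1] <- X[, 1] * dom$Lx
    X[, 2] <- X[, 2] * dom$Ly
    X[, 3] <- config$seed_z_range[1] +
      X[, 3] * diff(config$seed_z_range)
    P <- matrix(rnorm(3 * n), ncol = 3, byrow = TRUE)
    P <- P / row_norms(P)
    structure(list(X = X, P = P), class = "gp_ensemble")
  })
}

#' One forward-Euler step of the swimming-direction dynamics
#'
#' Advances unit orientation vectors `p` by one explicit Euler step of
#' `dp/dt = (1 / 2B) * (k - (k . p) p) + (omega x p) / 2` for gyrotactic
#' microbes (restoring torque toward the vertical `k = (0, 0, 1)` plus
#' vorticity-driven overturning), or of `dp/dt = (omega x p) / 2` for
#' non-gyrotactic motile microbes, followed by renormalisation to unit
#' length. Non-motile microbes are returned unchanged (they carry no
#' orientation dynamics).
#'
#' @param p Unit orientation(s): length-3 vector or N x 3 matrix.
#' @param omega Vorticity (rad/s), same shape as `p`.
#' @param motility A [motility_params()].
#' @param dt Timestep (s).
#' @return Updated unit orientation(s), same shape as `p`.
#' @export
orientation_step <- function(p, omega, motility, dt) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  P <- as_points(p)
  if (motility$mode == "non_motile") return(p)
  nrm <- row_norms(P)
  if (any(abs(nrm - 1) > 1e-6))
    abort("orientation vectors are not unit length (deviation > 1e-6): integrator state is corrupt")
  W <- as_points(omega)
  if (nrow(W) == 1L && nrow(P) > 1L) W <- W[rep(1L, nrow(P)), , drop = FALSE]
  dp <- 0.5 * cross3(W, P)
  if (motility$mode == "gyrotactic") {
    khat <- matrix(c(0, 0, 1), nrow(P), 3, byrow = TRUE)
    dp <- dp + (khat - P * P[, 3]) / (2 * motility$B)
  }
  Pn <- P + dt * dp
  Pn <- Pn / row_norms(Pn)
  shape_like(Pn, p)
}

#' One RK4 step of the position dynamics
#'
#' Advances positions by one classical 4-stage Runge-Kutta step of
#' `dX/dt = v_swim * p + u(X, t)`, the superposition of swimming along the
#' (frozen) orientation and advection by the flow. Returns the raw new
#' position; boundary conditions are applied separately with
#' [apply_boundaries()].
#'
#' @param X Position(s), length-3 vector or N x 3 matrix (m).
#' @param p Orientation(s), same shape as `X` (ignored when `v_swim = 0`).
#' @param motility A [motility_params()].
#' @param field A flow field.
#' @param t Time at the start of the step (s).
#' @param dt Timestep (s).
#' @return New position(s), same shape as `X`.
#' @export
position_step <- function(X, p, motility, field, t, dt) {
  Xm <- as_points(X)
  swim <- if (motility$v_swim > 0) motility$v_swim * as_points(p) else 0
  f <- function(Xq, tq) {
    u <- evaluate_velocity(field, Xq, tq)
    if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
    u + swim
  }
  k1 <- f(Xm, t)
  k2 <- f(Xm + dt / 2 * k1, t + dt / 2)
  k3 <- f(Xm + dt / 2 * k2, t + dt / 2)
  k4 <- f(Xm + dt * k3, t + dt)
  shape_like(Xm + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), X)
}

#' Apply domain boundary conditions
#'
#' Wraps x and y periodically and reflects z at the surface (`z = Lz`) and
#' bottom (`z = 0`). Orientations are untouched by reflection. A position
#' more than one full reflection beyond a wall signals a timestep too large
#' for the flow and raises an error.
#'
#' @param X Position(s), length-3 vector or N x 3 matrix (m).
#' @param domain A [flow_domain()].
#' @return Position(s) inside the domain, same shape as `X`.
#' @export
apply_boundaries <- function(X, domain) {
  Xm <- as_points(X)
  Lz <- domain$Lz
  if (any(Xm[, 3] > 2 * Lz | Xm[, 3] < -Lz))
    abort("position beyond one full vertical reflection: timestep too large for this flow")
  if (domain$periodic_x) Xm[, 1] <- Xm[, 1] %% domain$Lx
  if (domain$periodic_y) Xm[, 2] <- Xm[, 2] %% domain$Ly
  z <- Xm[, 3]
  z <- ifelse(z < 0, -z, z)
  z <- ifelse(z > Lz, 2 * Lz - z, z)
  Xm[, 3] <- z
  shape_like(Xm, X)
}

#' Run a microbe simulation
#'
#' Integrates an ensemble of microbes through a flow: each timestep the
#' swimming directions take one Euler step driven by the vorticity at the
#' pre-step positions, then the positions take one RK4 step with the updated
#' (frozen) orientation, then boundary conditions are applied. State is
#' recorded every `output_interval`. The run is fully deterministic given
#' the config seed; initialisation is the only source of randomness.
#'
#' @param config A [simulation_config()].
#' @param field A flow field spanning `[0, total_time]`.
#' @param motility A [motility_params()].
#' @param engine `"compiled"` uses the C++ stepping kernel (available for
#'   uniform, Taylor-Green and kinematic flows), `"reference"` the pure-R
#'   scheme; `"auto"` picks the compiled kernel when available. Both
#'   implement the identical scheme.
#' @return A `gp_trajectory`: recorded `times`, position array `X`
#'   (time x microbe x 3), orientation array `P`, and metadata.
#' @examples
#' cfg <- simulation_config(n_microbes = 50, total_time = 1, output_interval = 0.5)
#' tr <- run_simulation(cfg, make_taylor_green(), motility_params("non_motile"))
#' dim(tr$X)
#' @export
run_simulation <- function(config, field, motility,
                           engine = c("auto", "compiled", "reference")) {
  engine <- match.arg(engine)
  fast_spec <- compiled_field_spec(field)
  if (engine == "auto") engine <- if (is.null(fast_spec)) "reference" else "compiled"
  if (engine == "compiled" && is.null(fast_spec))
    abort("no compiled kernel for this field type; use engine = \"reference\"")

  ens <- seed_microbes(config)
  n <- config$n_microbes
  dt <- config$dt
  n_steps <- round(config$total_time / dt)
  out_every <- round(config$output_interval / dt)
  n_out <- floor(n_steps / out_every) + 1L
  times <- (0:(n_out - 1L)) * config$output_interval

  Xrec <- array(NA_real_, c(n_out, n, 3))
  Prec <- array(NA_real_, c(n_out, n, 3))
  X <- ens$X; P <- ens$P
  Xrec[1, , ] <- X; Prec[1, , ] <- P
  kin <- inherits(field, "gp_kinematic_field")
  needs_vort <- motility$mode != "non_motile"
  rec <- 1L

  if (engine == "compiled") {
    mode_code <- match(motility$mode,
                       c("non_motile", "gyrotactic", "non_gyrotactic_motile")) - 1L
    dom <- config$domain
    for (chunk in seq_len(n_out - 1L)) {
      res <- step_ensemble_cpp(X, P, fast_spec$type, fast_spec$params,
                               mode_code,
                               if (is.null(motility$B)) 1 else motility$B,
                               motility$v_swim,
                               (chunk - 1L) * out_every * dt, dt, out_every,
                               dom$Lx, dom$Ly, dom$Lz)
      X <- res$X; P <- res$P
      Xrec[chunk + 1L, , ] <- X
      Prec[chunk + 1L, , ] <- P
    }
    # leftover steps past the last record are not simulated (total_time is
    # an integer multiple of output_interval in all standard protocols)
    return(structure(list(times = times, X = Xrec, P = Prec,
                          motility = motility, config = config,
                          seed = config$seed, domain = config$domain),
                     class = "gp_trajectory"))
  }

  for (s in seq_len(n_steps)) {
    t <- (s - 1L) * dt
    if (needs_vort) {
      if (kin) {
        ev <- kin_eval_both(field, X, t)
        omega <- ev$w
      } else {
        omega <- evaluate_vorticity(field, X, t)
        if (is.null(dim(omega))) omega <- matrix(omega, nrow = 1L)
      }
      P <- orientation_step(P, omega, motility, dt)
      if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    }
    X <- position_step(X, P, motility, field, t, dt)
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    X <- apply_boundaries(X, config$domain)
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    if (anyNA(X) || anyNA(P)) {
      bad <- which(!stats::complete.cases(cbind(X, P)))[1]
      abort(sprintf("non-finite state at step %d (t = %.3f s), microbe %d", s, t + dt, bad))
    }
    if (s %% out_every == 0L) {
      rec <- rec + 1L
      Xrec[rec, , ] <- X
      Prec[rec, , ] <- P
    }
  }
  structure(list(times = times, X = Xrec, P = Prec, motility = motility,
                 config = config, seed = config$seed, domain = config$domain),
            class = "gp_trajectory")
}

# parameter bundle for the C++ stepping kernel, or NULL if unsupported
compiled_field_spec <- function(field) {
  if (inherits(field, "gp_kinematic_field")) {
    return(list(type = 2L, params = list(
      K = field$K, C = field$C, D = field$D, KxC = field$KxC, KxD = field$KxD,
      k2 = field$k2, kz = field$kz, omega = field$omega, chi = field$chi,
      z_lo = field$z_lo, z_hi = field$z_hi, beta = field$beta,
      Lz = field$domain$Lz)))
  }
  if (inherits(field, "gp_analytic_field")) {
    if (field$kind == "uniform")
      return(list(type = 0L, params = list(U = field$params$U)))
    if (field$kind == "taylor_green")
      return(list(type = 1L, params = list(U = field$params$U,
                                           kappa = field$params$kappa)))
  }
  NULL
}

#' @export
print.gp_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d microbes, %d records over %.3g s (every %.3g s), mode %s>\n",
              dim(x$X)[2], length(x$times), max(x$times),
              x$config$output_interval, x$motility$mode))
  invisible(x)
}

# positions / orientations at the recorded time nearest to `time`
traj_index <- function(traj, time) {
  i <- which.min(abs(traj$times - time))
  if (abs(traj$times[i] - time) > 1e-6)
    abort(sprintf("time %.4g s is not a recorded output time", time))
  i
}

#' Extract a trajectory snapshot
#'
#' @param traj A `gp_trajectory`.
#' @param time A recorded output time (s).
#' @return N x 3 matrix of positions (or orientations).
#' @export
trajectory_positions <- function(traj, time) {
  traj$X[traj_index(traj, time), , , drop = TRUE]
}

#' @rdname trajectory_positions
#' @export
trajectory_orientations <- function(traj, time) {
  traj$P[traj_index(traj, time), , , drop = TRUE]
}

#' @describeIn run_simulation Tidy a trajectory into a long tibble
#'   (`time`, `id`, `x`, `y`, `z`, `px`, `py`, `pz`). Intended for modest
#'   ensemble sizes.
#' @param x A `gp_trajectory`.
#' @param ... Unused.
#' @export
tidy.gp_trajectory <- function(x, ...) {
  nt <- length(x$times); n <- dim(x$X)[2]
  tibble(time = rep(x$times, each = n),
         id = rep(seq_len(n), nt),
         x = as.vector(t(x$X[, , 1])), y = as.vector(t(x$X[, , 2])),
         z = as.vector(t(x$X[, , 3])),
         px = as.vector(t(x$P[, , 1])), py = as.vector(t(x$P[, , 2])),
         pz = as.vector(t(x$P[, , 3])))
}

#' Write / read trajectories as netCDF
#'
#' Dims `(time, microbe)`, variables `x`, `y`, `z` (m) and `px`, `py`, `pz`;
#' global attributes record the motility mode, `B`, `v_swim`, seed and
#' timestep.
#'
#' @param traj A `gp_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  dm <- ncdf4::ncdim_def("microbe", "", seq_len(dim(traj$X)[2]))
  dt <- ncdf4::ncdim_def("time", "s", traj$times)
  mk <- function(nm, un) ncdf4::ncvar_def(nm, un, list(dm, dt), prec = "double")
  vars <- list(mk("x", "m"), mk("y", "m"), mk("z", "m"),
               mk("px", ""), mk("py", ""), mk("pz", ""))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  comp <- list(traj$X[, , 1], traj$X[, , 2], traj$X[, , 3],
               traj$P[, , 1], traj$P[, , 2], traj$P[, , 3])
  for (i in seq_along(vars)) ncdf4::ncvar_put(nc, vars[[i]], t(comp[[i]]))
  ncdf4::ncatt_put(nc, 0, "mode", traj$motility$mode)
  ncdf4::ncatt_put(nc, 0, "B_s", if (is.null(traj$motility$B)) -1 else traj$motility$B)
  ncdf4::ncatt_put(nc, 0, "v_swim_m_per_s", traj$motility$v_swim)
  ncdf4::ncatt_put(nc, 0, "seed", traj$seed)
  ncdf4::ncatt_put(nc, 0, "dt_s", traj$config$dt)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  times <- as.numeric(nc$dim$time$vals)
  n <- nc$dim$microbe$len
  nt <- length(times)
  get <- function(nm) t(matrix(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE), n, nt))
  X <- array(NA_real_, c(nt, n, 3)); P <- array(NA_real_, c(nt, n, 3))
  X[, , 1] <- get("x"); X[, , 2] <- get("y"); X[, , 3] <- get("z")
  P[, , 1] <- get("px"); P[, , 2] <- get("py"); P[, , 3] <- get("pz")
  att <- function(nm) ncdf4::ncatt_get(nc, 0, nm)$value
  B <- att("B_s"); if (is.numeric(B) && B < 0) B <- NULL
  mot <- motility_params(att("mode"), B = B, v_swim = att("v_swim_m_per_s"))
  dt <- att("dt_s")
  cfg <- simulation_config(n_microbes = n, dt = dt, total_time = max(times),
                           output_interval = if (nt > 1) times[2] - times[1] else dt,
                           seed = att("seed"))
  structure(list(times = times, X = X, P = P, motility = mot, config = cfg,
                 seed = att("seed"), domain = cfg$domain),
            class = "gp_trajectory")
}
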