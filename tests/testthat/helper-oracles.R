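# Independent numerical oracles used across the test files. These never call
# the code paths they are used to check.

# centred finite-difference divergence of a field at a point
fd_divergence <- function(field, x, t, h = 1e-6) {
  s <- 0
  for (d in 1:3) {
    xp <- x; xm <- x
    xp[d] <- xp[d] + h
    xm[d] <- xm[d] - h
    s <- s + (evaluate_velocity(field, xp, t)[d] -
              evaluate_velocity(field, xm, t)[d]) / (2 * h)
  }
  s
}

# centred finite-difference curl of a field at a point
fd_curl <- function(field, x, t, h = 1e-6) {
  J <- sapply(1:3, function(d) {
    xp <- x; xm <- x
    xp[d] <- xp[d] + h
    xm[d] <- xm[d] - h
    (evaluate_velocity(field, xp, t) - evaluate_velocity(field, xm, t)) / (2 * h)
  })  # J[i, d] = du_i / dx_d
  c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
}

# closed-form quiescent gyrotactic relaxation: polar angle at time t from
# dtheta/dt = -sin(theta) / (2B)
relaxation_theta <- function(theta0, B, t) 2 * atan(tan(theta0 / 2) * exp(-t / (2 * B)))

# reference Euler integration of the orientation equation at tiny dt
integrate_orientation_fine <- function(p0, omega, B, t_end, dt = 1e-4,
                                       mode = "gyrotactic") {
  p <- p0
  nst <- round(t_end / dt)
  traj_min_pz <- p[3]
  for (i in seq_len(nst)) {
    dp <- 0.5 * c(omega[2] * p[3] - omega[3] * p[2],
                  omega[3] * p[1] - omega[1] * p[3],
                  omega[1] * p[2] - omega[2] * p[1])
    if (mode == "gyrotactic")
      dp <- dp + (c(0, 0, 1) - p * p[3]) / (2 * B)
    p <- p + dt * dp
    p <- p / sqrt(sum(p^2))
    traj_min_pz <- min(traj_min_pz, p[3])
  }
  list(p = p, min_pz = traj_min_pz)
}

# grid-counting Voronoi volume oracle: nearest-generator assignment of grid
# cell centres under the periodic horizontal metric
voronoi_grid_oracle <- function(P, domain, n = 200L) {
  Lx <- domain$Lx; Ly <- domain$Ly; Lz <- domain$Lz
  xs <- (seq_len(n) - 0.5) * Lx / n
  ys <- (seq_len(n) - 0.5) * Ly / n
  zs <- (seq_len(n) - 0.5) * Lz / n
  best <- rep(Inf, n^3)
  who <- integer(n^3)
  for (i in seq_len(nrow(P))) {
    dx <- abs(xs - P[i, 1]); dx <- pmin(dx, Lx - dx)
    dy <- abs(ys - P[i, 2]); dy <- pmin(dy, Ly - dy)
    dz <- zs - P[i, 3]
    dxy2 <- outer(dx^2, dy^2, `+`)
    d2 <- rep(as.vector(dxy2), n) + rep(dz^2, each = n * n)
    hit <- d2 < best
    best[hit] <- d2[hit]
    who[hit] <- i
  }
  tabulate(who, nbins = nrow(P)) * (Lx * Ly * Lz / n^3)
}

# build a minimal single-snapshot trajectory from raw positions (and
# optional orientations) for analysis functions
snapshot_trajectory <- function(X, P = NULL, motility = motility_params("non_motile"),
                                times = 0, domain = flow_domain()) {
  nt <- length(times)
  n <- nrow(X)
  Xa <- array(NA_real_, c(nt, n, 3))
  Pa <- array(NA_real_, c(nt, n, 3))
  if (is.null(P)) P <- matrix(rep(c(0, 0, 1), each = n), n)
  for (i in seq_len(nt)) { Xa[i, , ] <- X; Pa[i, , ] <- P }
  cfg <- simulation_config(n_microbes = n, dt = 0.01,
                           total_time = max(max(times), 0.01),
                           output_interval = if (nt > 1) times[2] - times[1] else 0.01,
                           domain = domain)
  structure(list(times = times, X = Xa, P = Pa, motility = motility,
                 config = cfg, seed = 0L, domain = domain),
            class = "gp_trajectory")
}

# uniform random positions in the box
runif_positions <- function(n, domain = flow_domain(), z_range = c(0, domain$Lz)) {
  cbind(runif(n, 0, domain$Lx), runif(n, 0, domain$Ly),
        runif(n, z_range[1], z_range[2]))
}
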