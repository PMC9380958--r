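#' Analytic test flows
#'
#' Closed-form velocity fields used as integration oracles and idealised
#' study flows: a uniform stream, solid-body rotation, simple vertical shear
#' and a steady Taylor-Green vortex array. All are exactly divergence-free
#' and carry closed-form vorticity.
#'
#' @name analytic_fields
NULL

new_analytic_field <- function(kind, params, domain) {
  structure(list(kind = kind, params = params, domain = domain),
            class = c("gp_analytic_field", "gp_field"))
}

#' @describeIn analytic_fields Spatially uniform flow with velocity `U`
#'   (length-3 vector, m/s).
#' @param U For [make_uniform_flow()] a length-3 velocity vector (m/s); for
#'   [make_taylor_green()] a scalar velocity amplitude (m/s).
#' @param domain A [flow_domain()].
#' @export
make_uniform_flow <- function(U = c(0, 0, 0), domain = flow_domain()) {
  if (length(U) != 3L) abort("`U` must be a length-3 velocity vector")
  new_analytic_field("uniform", list(U = as.numeric(U)), domain)
}

#' @describeIn analytic_fields Rigid rotation with rotation-rate vector
#'   `Omega` (rad/s) about `center`; vorticity is `2 * Omega` everywhere.
#' @param Omega Length-3 rotation-rate vector in rad/s.
#' @param center Length-3 rotation centre (m).
#' @export
make_solid_body_rotation <- function(Omega = c(0, 0, 1),
                                     center = c(0.3, 0.3, 0.15),
                                     domain = flow_domain()) {
  if (length(Omega) != 3L || length(center) != 3L)
    abort("`Omega` and `center` must be length-3 vectors")
  new_analytic_field("solid_body_rotation",
                     list(Omega = as.numeric(Omega), center = as.numeric(center)),
                     domain)
}

#' @describeIn analytic_fields Horizontal stream `u = dudz * z` with uniform
#'   vertical shear; vorticity `(0, dudz, 0)`.
#' @param dudz Shear rate in 1/s.
#' @export
make_simple_shear <- function(dudz = 1, domain = flow_domain()) {
  stopifnot_scalar(dudz, "dudz")
  new_analytic_field("simple_shear", list(dudz = dudz), domain)
}

#' @describeIn analytic_fields Steady 2D cellular vortex array in the x-z
#'   plane: `u = U sin(kx) cos(kz)`, `v = 0`, `w = -U cos(kx) sin(kz)`. The
#'   wavenumber `kappa` must tile the periodic domain (an integer multiple of
#'   `2 * pi / Lx`).
#' @param kappa Vortex wavenumber in rad/m.
#' @export
make_taylor_green <- function(U = 0.01, kappa = 2 * pi / 0.6,
                              domain = flow_domain()) {
  stopifnot_scalar(U, "U", positive = TRUE)
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  m <- kappa * domain$Lx / (2 * pi)
  if (abs(m - round(m)) > 1e-9)
    abort(sprintf(
      "`kappa` = %.6g does not tile the periodic domain: it must be an integer multiple of 2*pi/Lx = %.6g",
      kappa, 2 * pi / domain$Lx))
  new_analytic_field("taylor_green", list(U = U, kappa = kappa), domain)
}

#' Evaluate flow velocity
#'
#' Returns the fluid velocity `u(x, t)` of a flow field at one or many
#' positions. Positions may be a length-3 vector or an N x 3 matrix; the
#' result has the matching shape (columns u, v, w in m/s).
#'
#' @param field A flow field (analytic, kinematic or gridded).
#' @param x Position(s) in metres.
#' @param t Time in seconds (scalar).
#' @param ... Passed to methods.
#' @return Velocity with the same shape as `x`.
#' @export
evaluate_velocity <- function(field, x, t = 0, ...) UseMethod("evaluate_velocity")

#' Evaluate flow vorticity
#'
#' Returns the vorticity `omega = curl(u)` at one or many positions.
#' Analytic and kinematic fields use their exact closed-form curl; gridded
#' fields interpolate a finite-difference curl computed on the grid.
#'
#' @inheritParams evaluate_velocity
#' @return Vorticity (rad/s) with the same shape as `x`.
#' @export
evaluate_vorticity <- function(field, x, t = 0, ...) UseMethod("evaluate_vorticity")

#' @export
evaluate_velocity.gp_analytic_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  p <- field$params
  res <- switch(field$kind,
    uniform = matrix(p$U, nrow(X), 3, byrow = TRUE),
    solid_body_rotation = {
      r <- sweep(X, 2, p$center)
      cross3(matrix(p$Omega, nrow(X), 3, byrow = TRUE), r)
    },
    simple_shear = cbind(p$dudz * X[, 3], 0, 0),
    taylor_green = {
      kx <- p$kappa * X[, 1]; kz <- p$kappa * X[, 3]
      cbind(p$U * sin(kx) * cos(kz), 0, -p$U * cos(kx) * sin(kz))
    },
    abort("unknown analytic field kind"))
  colnames(res) <- c("u", "v", "w")
  shape_like(res, x)
}

#' @export
evaluate_vorticity.gp_analytic_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  p <- field$params
  res <- switch(field$kind,
    uniform = matrix(0, nrow(X), 3),
    solid_body_rotation = matrix(2 * p$Omega, nrow(X), 3, byrow = TRUE),
    simple_shear = cbind(0, rep(p$dudz, nrow(X)), 0),
    taylor_green = {
      kx <- p$kappa * X[, 1]; kz <- p$kappa * X[, 3]
      cbind(0, -2 * p$U * p$kappa * sin(kx) * sin(kz), 0)
    },
    abort("unknown analytic field kind"))
  colnames(res) <- c("wx", "wy", "wz")
  shape_like(res, x)
}

#' @export
print.gp_field <- function(x, ...) {
  cat(sprintf("<%s flow field (%s)>\n",
              if (inherits(x, "gp_kinematic_field")) "kinematic turbulence"
              else if (inherits(x, "gp_gridded_field")) "gridded"
              else x$kind,
              class(x)[1]))
  invisible(x)
}
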