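# run code with a temporary, restored RNG state so field construction and
# seeding never perturb the caller's random stream
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# directions in independently rotated tetrahedral quadruples: the second
# moment of a tetrahedron's vertex directions is exactly isotropic, so every
# 4-mode shell feeds all three velocity components equally no matter how
# steep the energy spectrum is
tetrad_directions <- function(n_shells) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  do.call(rbind, lapply(seq_len(n_shells), function(i) tet %*% t(random_rotation())))
}

#' Synthetic kinematic turbulence with a mixed-layer depth structure
#'
#' Builds an unsteady, multi-scale, exactly divergence-free velocity field as
#' a sum of random Fourier modes, modulated in depth so that turbulence peaks
#' at the surface and vanishes below a density-interface depth -- a
#' desk-scale surrogate for a surface-cooled convective mixed layer.
#'
#' The field is constructed as the curl of an enveloped vector potential,
#' `u = curl(g(z) A(x, t))`, so incompressibility is exact everywhere,
#' envelope included. Mode energies follow `E(k) ~ k^spectrum_exponent`
#' (default -5/3, the inertial-range slope) and each mode is advected with an
#' eddy-turnover frequency `omega_n = unsteadiness * sqrt(k_n^3 E_n)`. Modes
#' come in wavenumber shells of four, with directions forming an
#' independently rotated tetrahedron per shell (whose direction second
#' moment is exactly isotropic) and orthonormal in-plane amplitude pairs, so
#' the interior field is statistically isotropic for any seed even under a
#' steep spectrum. `n_modes` is rounded up to a multiple of 4.
#'
#' Every mode carries a z-mirrored partner phase-locked at the surface, so
#' the vertical velocity vanishes identically on `z = Lz`: the surface is a
#' material boundary, as in a real cooled tank. (Without this, advecting
#' wall-reflected tracers through a plane the flow penetrates folds fluid
#' volumes and manufactures spurious concentration caustics.) Near the
#' surface the vertical variance is consequently transferred into the
#' horizontal components -- the free-surface signature. The evaluated field
#' therefore holds `2 * n_modes` Fourier terms. Amplitudes are calibrated by Monte-Carlo sampling at construction so
#' that the root-mean-square speed at the surface matches `u_rms` within a
#' few percent.
#'
#' The depth envelope `g(z)` equals 1 at the surface, declines linearly by a
#' factor `envelope_beta` down to the top of the interface, then falls
#' smoothly (C2 quintic ramp) to exactly zero across
#' `[interface_z - interface_halfwidth, interface_z + interface_halfwidth]`:
#' deep water is exactly quiescent.
#'
#' @param n_modes Number of Fourier modes (>= 8; default 64).
#' @param k_min,k_max Wavenumber band in rad/m (geometrically spaced mode
#'   magnitudes).
#' @param u_rms Target rms speed at the envelope peak, m/s. Default 0.04,
#'   the order of the convective velocity scale `w*` of the emulated mixed
#'   layer.
#' @param spectrum_exponent Power-law exponent of mode energy vs wavenumber.
#' @param unsteadiness Dimensionless factor scaling the eddy-turnover
#'   frequencies; 0 gives a frozen field.
#' @param interface_z Centre of the density interface (m).
#' @param interface_halfwidth Half-width of the turbulent-to-quiescent
#'   transition (m).
#' @param envelope_beta Fractional linear decline of the envelope from the
#'   surface to the interface top (0 = flat plateau).
#' @param seed Integer seed; the field is deterministic given the seed.
#' @param domain A [flow_domain()].
#' @return A `gp_kinematic_field` usable with [evaluate_velocity()] and
#'   [evaluate_vorticity()]. The element `modes` is a tibble with per-mode
#'   wavenumber magnitude, energy and frequency.
#' @examples
#' f <- make_kinematic_turbulence(n_modes = 16, seed = 1)
#' evaluate_velocity(f, c(0.1, 0.2, 0.28), t = 0)
#' @export
make_kinematic_turbulence <- function(n_modes = 64,
                                      k_min = 2 * pi / 0.3,
                                      k_max = 2 * pi / 0.02,
                                      u_rms = 0.04,
                                      spectrum_exponent = -5 / 3,
                                      unsteadiness = 0.5,
                                      interface_z = 0.135,
                                      interface_halfwidth = 0.03,
                                      envelope_beta = 0.5,
                                      seed = 1L,
                                      domain = flow_domain()) {
  if (n_modes < 8) abort("`n_modes` must be at least 8")
  stopifnot_scalar(k_min, "k_min", positive = TRUE)
  stopifnot_scalar(k_max, "k_max", positive = TRUE)
  if (k_max <= k_min) abort("degenerate wavenumber band: need k_min < k_max")
  stopifnot_scalar(u_rms, "u_rms", positive = TRUE)
  if (is.null(seed)) abort("`seed` is mandatory: the field must be reproducible")

  n_modes <- 4L * ceiling(n_modes / 4)  # whole tetrahedral shells
  n_shells <- n_modes %/% 4L

  with_local_seed(seed, {
    kmag <- rep(exp(seq(log(k_min), log(k_max), length.out = n_shells)), each = 4L)
    khat <- tetrad_directions(n_shells)

    # orthonormal pair spanning the plane perpendicular to each khat
    ref <- ifelse(abs(khat[, 3]) < 0.9, 3L, 1L)
    e1 <- matrix(0, n_modes, 3)
    e1[cbind(seq_len(n_modes), ref)] <- 1
    e1 <- e1 - khat * rowSums(e1 * khat)
    e1 <- e1 / row_norms(e1)
    e2 <- cross3(khat, e1)
    psi <- runif(n_modes, 0, 2 * pi)
    chat <- cos(psi) * e1 + sin(psi) * e2
    dhat <- -sin(psi) * e1 + cos(psi) * e2

    # velocity amplitude per mode from the prescribed spectrum
    wgt <- kmag^spectrum_exponent
    A <- u_rms * sqrt(wgt / sum(wgt))
    chi <- runif(n_modes, 0, 2 * pi)

    K <- khat * kmag
    C <- chat * (A / kmag)
    D <- dhat * (A / kmag)

    # no-penetration at the cooled surface: add the z-mirror image of every
    # mode, phase-locked at z = Lz, so the vertical velocity vanishes
    # identically on the surface plane (as it does at the free surface of
    # the emulated convective tank); horizontal motion is enhanced there
    # instead, the free-surface signature. Without this, advecting
    # reflective tracers through a surface the flow crosses folds fluid
    # volumes and generates spurious caustic concentrations.
    Lz <- domain$Lz
    K2 <- cbind(K[, 1], K[, 2], -K[, 3])
    C2 <- cbind(-C[, 1], -C[, 2], C[, 3])
    D2 <- cbind(-D[, 1], -D[, 2], D[, 3])
    chi2 <- chi + 2 * K[, 3] * Lz
    K <- rbind(K, K2); C <- rbind(C, C2) / sqrt(2); D <- rbind(D, D2) / sqrt(2)
    chi <- c(chi, chi2)
    kmag <- c(kmag, kmag)
    A <- c(A, A) / sqrt(2)
    n_all <- 2L * n_modes

    field <- structure(
      list(K = K, C = C, D = D,
           KxC = cross3(K, C), KxD = cross3(K, D),
           k2 = kmag^2, kz = K[, 3],
           omega = rep(0, n_all), chi = chi,
           z_lo = interface_z - interface_halfwidth,
           z_hi = interface_z + interface_halfwidth,
           beta = envelope_beta,
           u_rms = u_rms, seed = seed,
           spectrum_exponent = spectrum_exponent,
           domain = domain,
           modes = tibble(k = kmag, energy = A^2, omega = rep(0, n_all))),
      class = c("gp_kinematic_field", "gp_field"))

    # Monte-Carlo calibration of the surface rms speed
    ncal <- 4096L
    Xcal <- cbind(runif(ncal, 0, domain$Lx), runif(ncal, 0, domain$Ly), domain$Lz)
    ucal <- kin_eval_cpp(Xcal, 0, field$K, field$C, field$D, field$KxC,
                         field$KxD, field$k2, field$kz, field$omega, field$chi,
                         field$z_lo, field$z_hi, field$beta, domain$Lz, FALSE)$u
    fac <- u_rms / sqrt(mean(rowSums(ucal^2)))
    field$C <- field$C * fac
    field$D <- field$D * fac
    field$KxC <- field$KxC * fac
    field$KxD <- field$KxD * fac
    field$modes$energy <- field$modes$energy * fac^2

    # eddy-turnover unsteadiness from the calibrated spectrum
    field$omega <- unsteadiness * sqrt(kmag^3 * field$modes$energy)
    field$modes$omega <- field$omega
    field
  })
}

#' @export
evaluate_velocity.gp_kinematic_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  res <- kin_eval_cpp(X, t, field$K, field$C, field$D, field$KxC, field$KxD,
                      field$k2, field$kz, field$omega, field$chi,
                      field$z_lo, field$z_hi, field$beta, field$domain$Lz,
                      FALSE)$u
  colnames(res) <- c("u", "v", "w")
  shape_like(res, x)
}

#' @export
evaluate_vorticity.gp_kinematic_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  res <- kin_eval_cpp(X, t, field$K, field$C, field$D, field$KxC, field$KxD,
                      field$k2, field$kz, field$omega, field$chi,
                      field$z_lo, field$z_hi, field$beta, field$domain$Lz,
                      TRUE)$w
  colnames(res) <- c("wx", "wy", "wz")
  shape_like(res, x)
}

# velocity and vorticity in one C++ pass (used by the integrator)
kin_eval_both <- function(field, X, t) {
  kin_eval_cpp(X, t, field$K, field$C, field$D, field$KxC, field$KxD,
               field$k2, field$kz, field$omega, field$chi,
               field$z_lo, field$z_hi, field$beta, field$domain$Lz, TRUE)
}
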