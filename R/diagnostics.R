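#' Kolmogorov microscales
#'
#' The smallest turbulent length, time and velocity scales set by the
#' kinematic viscosity `nu` and dissipation rate `epsilon`:
#' `eta_K = (nu^3 / epsilon)^(1/4)`, `tau_K = (nu / epsilon)^(1/2)`,
#' `u_K = (nu * epsilon)^(1/4)`. A quiescent fluid (`epsilon = 0`) is legal
#' and yields infinite length/time scales.
#'
#' @param nu Kinematic viscosity (m^2/s), > 0.
#' @param epsilon Dissipation rate (m^2/s^3), >= 0; vectorised.
#' @return A tibble with `nu`, `epsilon`, `eta_K` (m), `tau_K` (s),
#'   `u_K` (m/s).
#' @examples
#' kolmogorov_scales(5e-6, 2.66e-4)
#' @export
kolmogorov_scales <- function(nu, epsilon) {
  stopifnot_scalar(nu, "nu", positive = TRUE)
  if (any(epsilon < 0)) abort("`epsilon` must be >= 0")
  tibble(nu = nu, epsilon = epsilon,
         eta_K = ifelse(epsilon == 0, Inf, (nu^3 / epsilon)^(1 / 4)),
         tau_K = ifelse(epsilon == 0, Inf, sqrt(nu / epsilon)),
         u_K = (nu * epsilon)^(1 / 4))
}

#' Stability number
#'
#' `Psi = B * sqrt(epsilon / nu)`, the ratio of the gyrotactic reorientation
#' timescale `B` to the Kolmogorov timescale. `Psi ~ 1` marks the balance of
#' stabilising and overturning torques at which patchiness is expected to
#' peak; large `Psi` means the swimmer is easily overturned by shear.
#'
#' @param B Reorientation timescale (s), > 0.
#' @param epsilon Dissipation rate (m^2/s^3), >= 0; vectorised.
#' @param nu Kinematic viscosity (m^2/s), > 0.
#' @return Dimensionless Psi (0 when `epsilon = 0`).
#' @export
stability_number <- function(B, epsilon, nu) {
  stopifnot_scalar(B, "B", positive = TRUE)
  stopifnot_scalar(nu, "nu", positive = TRUE)
  if (any(epsilon < 0)) abort("`epsilon` must be >= 0")
  B * sqrt(epsilon / nu)
}

#' Swimming number
#'
#' `Phi = v_swim / (nu * epsilon)^(1/4)`, the swim speed relative to the
#' Kolmogorov velocity. In quiescent fluid (`epsilon = 0`) the Kolmogorov
#' velocity vanishes and Phi is undefined (returned as `NA`).
#'
#' @param v_swim Swim speed (m/s), >= 0.
#' @param nu Kinematic viscosity (m^2/s), > 0.
#' @param epsilon Dissipation rate (m^2/s^3), >= 0; vectorised.
#' @return Dimensionless Phi (`NA` where `epsilon = 0`, 0 when
#'   `v_swim = 0` in turbulent fluid).
#' @export
swimming_number <- function(v_swim, nu, epsilon) {
  stopifnot_scalar(v_swim, "v_swim", nonneg = TRUE)
  stopifnot_scalar(nu, "nu", positive = TRUE)
  if (any(epsilon < 0)) abort("`epsilon` must be >= 0")
  ifelse(epsilon == 0, NA_real_, v_swim / (nu * epsilon)^(1 / 4))
}

#' Convective mixed-layer scales
#'
#' From the surface buoyancy flux `F_b` and layer depth `h0`: the convective
#' (Deardorff) velocity scale `w* = (F_b * h0)^(1/3)`, the Reynolds number
#' `Re = w* * h0 / nu`, and (when the buoyancy jump `Delta_b` across the
#' interface is supplied) the bulk Richardson number
#' `Ri0 = h0 * Delta_b / w*^2`.
#'
#' @param F_b Surface buoyancy flux (m^2/s^3), > 0.
#' @param h0 Mixed-layer depth (m), > 0.
#' @param nu Kinematic viscosity (m^2/s), > 0.
#' @param Delta_b Optional buoyancy jump (m/s^2).
#' @return A tibble with `w_star` (m/s), `Re`, and `Ri0` when available.
#' @examples
#' mixed_layer_scales(F_b = 5e-4, h0 = 0.15, nu = 5e-6)
#' @export
mixed_layer_scales <- function(F_b, h0, nu, Delta_b = NULL) {
  stopifnot_scalar(F_b, "F_b", positive = TRUE)
  stopifnot_scalar(h0, "h0", positive = TRUE)
  stopifnot_scalar(nu, "nu", positive = TRUE)
  w_star <- (F_b * h0)^(1 / 3)
  out <- tibble(w_star = w_star, Re = w_star * h0 / nu)
  if (!is.null(Delta_b)) out$Ri0 <- h0 * Delta_b / w_star^2
  out
}

#' Full scale report for a flow/motility configuration
#'
#' Collects the Kolmogorov scales, stability and swimming numbers and
#' mixed-layer scales into one row.
#'
#' @inheritParams kolmogorov_scales
#' @inheritParams mixed_layer_scales
#' @param B Optional reorientation timescale (s).
#' @param v_swim Optional swim speed (m/s).
#' @return A `gp_scale_report` tibble row.
#' @examples
#' scale_report(nu = 5e-6, epsilon = 2.66e-4, B = 1, v_swim = 500e-6,
#'              F_b = 5e-4, h0 = 0.15)
#' @export
scale_report <- function(nu, epsilon, B = NULL, v_swim = NULL,
                         F_b = NULL, h0 = NULL, Delta_b = NULL) {
  out <- kolmogorov_scales(nu, epsilon)
  if (!is.null(B)) out$Psi <- stability_number(B, epsilon, nu)
  if (!is.null(v_swim)) out$Phi <- swimming_number(v_swim, nu, epsilon)
  if (!is.null(F_b) && !is.null(h0))
    out <- dplyr::bind_cols(out, mixed_layer_scales(F_b, h0, nu, Delta_b))
  class(out) <- c("gp_scale_report", class(out))
  out
}

#' @export
glance.gp_scale_report <- function(x, ...) as_tibble(x)

#' @describeIn scale_report Serialise a scale report to a flat
#'   `key = value` text file.
#' @param report A `gp_scale_report`.
#' @param path Output file.
#' @export
write_scale_report <- function(report, path) {
  lines <- sprintf("%s = %.10g", names(report), as.numeric(report[1, ]))
  writeLines(lines, path)
  invisible(path)
}

#' Effective velocity of microbes
#'
#' The effective velocity is the sum of the fluid velocity at the microbe's
#' position and its swimming velocity, `v_eff = u(X, t) + v_swim * p`,
#' expressed in spherical coordinates: magnitude (m/s), polar angle
#' `theta_eff` measured from the upward vertical (0 = straight up), and
#' azimuth `phi_eff = atan2(v_y, v_x)` in `[-pi, pi)`. A zero vector has
#' magnitude 0 and undefined (missing) angles.
#'
#' @param traj A `gp_trajectory`.
#' @param field The flow field the trajectory was run in.
#' @param cadence Sampling cadence (s).
#' @param window Optional length-2 time window (s); default all recorded
#'   times.
#' @param regions Optional [depth_regions()] to label each record.
#' @return A tibble with `time`, `id`, optional `region`, `speed`,
#'   `theta_eff`, `phi_eff`.
#' @export
effective_velocity <- function(traj, field, cadence = 1, window = NULL,
                               regions = NULL) {
  times <- traj$times[abs(traj$times / cadence - round(traj$times / cadence)) < 1e-9]
  if (!is.null(window))
    times <- times[times >= window[1] - 1e-9 & times <= window[2] + 1e-9]
  vs <- traj$motility$v_swim
  bind_rows(lapply(times, function(tt) {
    i <- traj_index(traj, tt)
    pos <- traj$X[i, , , drop = TRUE]
    if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
    v <- evaluate_velocity(field, pos, tt)
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    if (vs > 0) {
      p <- traj$P[i, , , drop = TRUE]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      v <- v + vs * p
    }
    spd <- row_norms(v)
    zero <- spd == 0
    theta <- ifelse(zero, NA_real_, acos(pmin(pmax(v[, 3] / pmax(spd, .Machine$double.xmin), -1), 1)))
    phi <- ifelse(zero, NA_real_, atan2(v[, 2], v[, 1]))
    phi <- ifelse(!is.na(phi) & phi >= pi, -pi, phi)
    out <- tibble(time = tt, id = seq_len(nrow(v)), speed = spd,
                  theta_eff = theta, phi_eff = phi)
    if (!is.null(regions)) out$region <- assign_regions(pos[, 3], regions)
    out
  }))
}

#' Polar-angle statistics of microbe orientations
#'
#' Pools the polar angle `theta = acos(p_z)` of the swimming direction over
#' a time window (0 = oriented straight up toward the surface) and returns
#' its normalised distribution and mean, optionally per depth region.
#' Non-motile microbes carry no orientation and are rejected.
#'
#' @param traj A `gp_trajectory` of motile microbes.
#' @param window Length-2 time window (s).
#' @param regions Optional [depth_regions()].
#' @param bins Number of histogram bins over `[0, pi]`.
#' @return A `gp_polar` list: `histogram` (tibble `region`, `theta_mid`,
#'   `density`) and `means` (tibble `region`, `mean_theta`, `n`).
#' @export
polar_angle_stats <- function(traj, window = range(traj$times),
                              regions = NULL, bins = 36L) {
  if (traj$motility$mode == "non_motile")
    abort("non-motile microbes have no orientation: polar angles are undefined")
  times <- traj$times[traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9]
  if (!length(times)) abort("`window` contains no recorded times")
  recs <- bind_rows(lapply(times, function(tt) {
    i <- traj_index(traj, tt)
    pz <- traj$P[i, , 3]
    out <- tibble(theta = acos(pmin(pmax(pz, -1), 1)))
    out$region <- if (is.null(regions)) factor("all")
                  else assign_regions(traj$X[i, , 3], regions)
    out
  }))
  recs <- recs[!is.na(recs$region), ]
  brk <- seq(0, pi, length.out = bins + 1L)
  hist_df <- recs %>%
    group_by(.data$region) %>%
    summarise(counts = list(graphics::hist(.data$theta, breaks = brk, plot = FALSE)),
              .groups = "drop")
  histogram <- bind_rows(lapply(seq_len(nrow(hist_df)), function(i) {
    h <- hist_df$counts[[i]]
    tibble(region = hist_df$region[i], theta_mid = h$mids, density = h$density)
  }))
  means <- recs %>%
    group_by(.data$region) %>%
    summarise(mean_theta = mean(.data$theta), n = n(), .groups = "drop")
  structure(list(histogram = histogram, means = means), class = "gp_polar")
}

#' @export
print.gp_polar <- function(x, ...) {
  cat("<polar-angle distribution>\n")
  print(x$means)
  invisible(x)
}

#' @export
autoplot.gp_polar <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$theta_mid * 180 / pi, y = .data$density)) +
    ggplot2::geom_col(width = 180 / max(1, length(unique(object$histogram$theta_mid)))) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "polar angle (degrees from vertical)", y = "density")
}

#' Fluid velocity sampled at microbe positions
#'
#' Empirical CDF of one fluid-velocity component evaluated at the microbes'
#' positions, per depth region -- the flow conditions microbes actually
#' experience.
#'
#' @param traj A `gp_trajectory`.
#' @param field The flow field.
#' @param component One of `"u"`, `"v"`, `"w"`.
#' @param regions A [depth_regions()] (or `NULL` for a single pooled
#'   region).
#' @param cadence Sampling cadence (s).
#' @param window Optional time window (s).
#' @return A tibble with `region`, `value` (m/s) and empirical CDF `p`,
#'   sorted by value within region.
#' @export
fluid_velocity_at_microbes <- function(traj, field, component = c("w", "u", "v"),
                                       regions = depth_regions(), cadence = 1,
                                       window = NULL) {
  component <- match.arg(component)
  ci <- match(component, c("u", "v", "w"))
  times <- traj$times[abs(traj$times / cadence - round(traj$times / cadence)) < 1e-9]
  if (!is.null(window))
    times <- times[times >= window[1] - 1e-9 & times <= window[2] + 1e-9]
  samples <- bind_rows(lapply(times, function(tt) {
    pos <- trajectory_positions(traj, tt)
    if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
    v <- evaluate_velocity(field, pos, tt)
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    out <- tibble(value = v[, ci])
    out$region <- if (is.null(regions)) factor("all")
                  else assign_regions(pos[, 3], regions)
    out
  }))
  samples <- samples[!is.na(samples$region), ]
  samples %>%
    group_by(.data$region) %>%
    arrange(.data$value, .by_group = TRUE) %>%
    mutate(p = seq_len(n()) / n()) %>%
    ungroup()
}
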