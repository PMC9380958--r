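#' Depth profiles of turbulent kinetic energy and dissipation
#'
#' Samples a flow field at random horizontal positions and times to estimate
#' the turbulent kinetic energy `k(z) = (var u + var v + var w) / 2` and the
#' dissipation-rate surrogate `epsilon(z) = nu * <sum_ij (du_i/dx_j)^2>`
#' (velocity gradients by centred finite differences) at a set of depths.
#' This is the depth structure a convective mixed layer is characterised by:
#' turbulence peaks near the cooled surface and dies out below the density
#' interface.
#'
#' @param field A flow field.
#' @param z_levels Depths (m) at which to evaluate the profile.
#' @param nu Kinematic viscosity (m^2/s) used to scale the dissipation.
#' @param n_samples Sample points per depth (>= 1000 recommended).
#' @param t_window Length-2 time window (s) to sample over.
#' @param n_times Number of distinct sample times within the window.
#' @param h Finite-difference step (m) for the velocity gradients.
#' @param seed Integer seed for the sampling.
#' @return A tibble (`gp_depth_profile`) with columns `z`, `k` (m^2/s^2) and
#'   `epsilon` (m^2/s^3).
#' @examples
#' f <- make_kinematic_turbulence(n_modes = 16, seed = 1)
#' turbulence_profile(f, z_levels = c(0.05, 0.2, 0.3), nu = 5e-6,
#'                    n_samples = 1000)
#' @export
turbulence_profile <- function(field, z_levels, nu = 5e-6,
                               n_samples = 2000L, t_window = c(0, 5),
                               n_times = 8L, h = 1e-4, seed = 1L) {
  stopifnot_scalar(nu, "nu", positive = TRUE)
  if (length(t_window) != 2L || t_window[2] < t_window[1])
    abort("`t_window` must be an increasing length-2 window (s)")
  dom <- field$domain
  ts <- if (n_times == 1L) mean(t_window) else
    seq(t_window[1], t_window[2], length.out = n_times)
  per_t <- ceiling(n_samples / n_times)

  with_local_seed(seed, {
    rows <- lapply(z_levels, function(zl) {
      us <- NULL; grad2 <- 0; ng <- 0L
      for (tt in ts) {
        X <- cbind(runif(per_t, 0, dom$Lx), runif(per_t, 0, dom$Ly), zl)
        u0 <- evaluate_velocity(field, X, tt)
        us <- rbind(us, u0)
        # centred differences in the three directions
        for (d in 1:3) {
          Xp <- X; Xm <- X
          Xp[, d] <- Xp[, d] + h
          Xm[, d] <- Xm[, d] - h
          g <- (evaluate_velocity(field, Xp, tt) - evaluate_velocity(field, Xm, tt)) / (2 * h)
          grad2 <- grad2 + sum(g^2)
        }
        ng <- ng + per_t
      }
      k <- 0.5 * sum(apply(us, 2, var))
      eps <- nu * grad2 / ng
      tibble(z = zl, k = k, epsilon = eps)
    })
    out <- bind_rows(rows)
    class(out) <- c("gp_depth_profile", class(out))
    out
  })
}

#' @export
autoplot.gp_depth_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("k", "epsilon"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$z)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~quantity, scales = "free_x",
                        labeller = ggplot2::as_labeller(c(
                          k = "turbulent kinetic energy k (m² s⁻²)",
                          epsilon = "dissipation ε (m² s⁻³)"))) +
    ggplot2::labs(x = NULL, y = "z (m)")
}
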