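#' Voronoi cell volumes with horizontal periodicity
#'
#' Tessellates microbe positions into Voronoi cells under the same boundary
#' conditions as the simulations: periodic in x and y, planar walls at
#' `z = 0` and `z = Lz`. Each microbe's cell is the polyhedron of points
#' closer to it than to any other microbe (horizontal distances measured
#' with the minimal-image convention); the inverse cell volume is the local
#' number concentration. Cells tile the domain, so volumes sum to
#' `Lx * Ly * Lz`.
#'
#' @param positions N x 3 matrix of positions inside the domain (m).
#' @param domain A [flow_domain()].
#' @return A `gp_voronoi` tibble with columns `id` and `volume` (m^3);
#'   attribute `domain`.
#' @examples
#' dom <- flow_domain()
#' voronoi_volumes(matrix(c(0.3, 0.3, 0.15), 1), dom)  # whole box
#' @export
voronoi_volumes <- function(positions, domain = flow_domain()) {
  X <- as_points(positions)
  if (nrow(X) == 0L) abort("cannot tessellate an empty set of positions")
  if (any(X[, 1] < 0 | X[, 1] > domain$Lx | X[, 2] < 0 | X[, 2] > domain$Ly |
          X[, 3] < 0 | X[, 3] > domain$Lz))
    abort("all positions must lie inside the domain (wrap/reflect first)")
  vols <- voro_volumes_cpp(X, domain$Lx, domain$Ly, domain$Lz,
                           domain$periodic_x, domain$periodic_y)
  out <- tibble(id = seq_len(nrow(X)), volume = as.numeric(vols))
  attr(out, "domain") <- domain
  class(out) <- c("gp_voronoi", class(out))
  out
}

#' Local concentration from Voronoi volumes
#'
#' The inverse of a microbe's Voronoi cell volume estimates the local number
#' concentration around it.
#'
#' @param vr A `gp_voronoi` from [voronoi_volumes()].
#' @return The input tibble with a `concentration` column (1/m^3) added.
#' @export
local_concentration <- function(vr) {
  vr$concentration <- 1 / vr$volume
  vr
}

#' Select patch members
#'
#' Patches consist of the fraction `f` of microbes with the largest local
#' concentration (smallest Voronoi cells). Exactly `ceiling(f * N)` members
#' are selected; ties are broken by stable index order (the earlier index
#' wins).
#'
#' @param concentrations Numeric vector of local concentrations, or a
#'   tibble with a `concentration` column.
#' @param f Patch fraction in (0, 1].
#' @return Integer indices of the patch members.
#' @examples
#' select_patches(c(5, 1, 9, 7), f = 0.5)
#' @export
select_patches <- function(concentrations, f = 0.01) {
  if (is.data.frame(concentrations)) concentrations <- concentrations$concentration
  if (f <= 0 || f > 1) abort("`f` must be in (0, 1]")
  n <- length(concentrations)
  m <- ceiling(f * n)
  ord <- order(concentrations, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  sort(ord[seq_len(m)])
}

#' Patch concentration enhancement factor Q
#'
#' `Q = (C - C_P) / C_M`, where `C` is the median local concentration of
#' motile microbes inside patches, `C_P` the median among non-motile
#' particles inside their patches, and `C_M` the overall concentration
#' normalisation. Positive Q means motile microbes form denser patches than
#' passive tracers; negative Q is legal and means the opposite.
#'
#' @param motile_patch_conc,nonmotile_patch_conc Concentrations (1/m^3) of
#'   patch members from the motile and non-motile ensembles.
#' @param C_M Overall concentration normalisation (1/m^3), > 0.
#' @return Dimensionless Q, or `NA` when either input is empty.
#' @export
q_statistic <- function(motile_patch_conc, nonmotile_patch_conc, C_M) {
  stopifnot_scalar(C_M, "C_M", positive = TRUE)
  if (length(motile_patch_conc) == 0L || length(nonmotile_patch_conc) == 0L)
    return(NA_real_)
  (median(motile_patch_conc) - median(nonmotile_patch_conc)) / C_M
}

#' Depth regions of the water column
#'
#' The default regions split the seeded, turbulent part of the column into
#' `Shallow` (0.30 >= z >= 0.24 m), `Mid` (0.24 > z >= 0.17 m) and `Deep`
#' (0.17 > z >= 0.10 m); below 0.10 m the fluid is quiescent and microbes
#' are not seeded there.
#'
#' @param bins Named list of `c(z_min, z_max)` pairs (m), ordered from
#'   shallow to deep. The first (topmost) bin is closed at its upper edge;
#'   all others are half-open `[z_min, z_max)`.
#' @return A `gp_regions` tibble with columns `region`, `z_min`, `z_max`.
#' @examples
#' depth_regions()
#' depth_regions(list(All = c(0.10, 0.30)))
#' @export
depth_regions <- function(bins = list(Shallow = c(0.24, 0.30),
                                      Mid = c(0.17, 0.24),
                                      Deep = c(0.10, 0.17))) {
  out <- tibble(region = factor(names(bins), levels = names(bins)),
                z_min = vapply(bins, `[`, 0, 1),
                z_max = vapply(bins, `[`, 0, 2))
  if (any(out$z_max <= out$z_min)) abort("each region needs z_min < z_max")
  o <- order(out$z_max, decreasing = TRUE)
  if (!identical(o, seq_len(nrow(out)))) abort("regions must be ordered shallow to deep")
  if (nrow(out) > 1 && any(out$z_min[-nrow(out)] < out$z_max[-1] - 1e-12))
    abort("regions must not overlap")
  class(out) <- c("gp_regions", class(out))
  out
}

# region label for each z (NA outside all bins); top bin closed above
assign_regions <- function(z, regions) {
  lab <- rep(NA_character_, length(z))
  for (i in seq_len(nrow(regions))) {
    hi <- regions$z_max[i]
    inb <- if (i == 1L) z >= regions$z_min[i] & z <= hi
           else z >= regions$z_min[i] & z < hi
    lab[inb & is.na(lab)] <- as.character(regions$region[i])
  }
  factor(lab, levels = levels(regions$region))
}

default_z_excl <- function(domain) domain$Lz - domain$Lz / 360

#' Q time series by depth region
#'
#' For each analysis time: tessellates the motile and the non-motile
#' ensemble separately (excluding microbes in the top cell layer, above
#' `z_excl`), selects the `f`-fraction patches in each ensemble, attributes
#' patch members to depth regions, and computes Q per region with
#' `C_M = N / V_eff` (`V_eff` the domain volume below `z_excl`). A region
#' needs at least `min_members` patch members from both ensembles at a time
#' for a valid Q; otherwise the value is missing.
#'
#' @param motile,nonmotile `gp_trajectory` objects sharing output times and
#'   domain.
#' @param regions A [depth_regions()] tibble, or `NULL` to pool patch
#'   members across all depths into a single `all` series.
#' @param f Patch fraction (default 0.01, the 1% most aggregated cells).
#' @param cadence Analysis cadence in seconds (default 1 s; must be a
#'   multiple of the output interval).
#' @param z_excl Exclusion ceiling (m); defaults to the domain height minus
#'   one 1/360 cell layer.
#' @param selection `"global"` selects the f-fraction among all microbes and
#'   then attributes members to regions; `"per_region"` selects the
#'   f-fraction within each region separately.
#' @param min_members Minimum patch members per region per time.
#' @return A `gp_qseries` tibble with columns `time`, `region`, `Q`,
#'   `n_motile`, `n_nonmotile`; attributes `f`, `C_M`, `z_excl`.
#' @export
q_timeseries_by_region <- function(motile, nonmotile,
                                   regions = depth_regions(), f = 0.01,
                                   cadence = 1,
                                   z_excl = default_z_excl(motile$domain),
                                   selection = c("global", "per_region"),
                                   min_members = 5L) {
  selection <- match.arg(selection)
  if (!isTRUE(all.equal(motile$times, nonmotile$times)))
    abort("motile and non-motile trajectories must share output times")
  dom <- motile$domain
  step <- motile$config$output_interval
  if (cadence < step - 1e-9) abort("`cadence` must be >= the output interval")
  times <- motile$times[abs(motile$times / cadence - round(motile$times / cadence)) < 1e-9]
  pooled <- is.null(regions)
  if (pooled) regions <- depth_regions(list(all = c(0, z_excl)))

  V_eff <- dom$Lx * dom$Ly * z_excl
  n_tot <- dim(motile$X)[2]
  C_M <- n_tot / V_eff

  patch_conc_by_region <- function(traj, tt) {
    pos <- trajectory_positions(traj, tt)
    keep <- pos[, 3] <= z_excl
    pos <- pos[keep, , drop = FALSE]
    conc <- local_concentration(voronoi_volumes(pos, dom))$concentration
    reg <- assign_regions(pos[, 3], regions)
    if (selection == "global") {
      sel <- select_patches(conc, f)
      split(conc[sel], reg[sel])
    } else {
      out <- lapply(levels(regions$region), function(r) {
        idx <- which(!is.na(reg) & reg == r)
        if (!length(idx)) return(numeric())
        conc[idx][select_patches(conc[idx], f)]
      })
      setNames(out, levels(regions$region))
    }
  }

  rows <- lapply(times, function(tt) {
    cm <- patch_conc_by_region(motile, tt)
    cp <- patch_conc_by_region(nonmotile, tt)
    bind_rows(lapply(levels(regions$region), function(r) {
      a <- cm[[r]]; b <- cp[[r]]
      na <- length(a); nb <- length(b)
      q <- if (na >= min_members && nb >= min_members)
        q_statistic(a, b, C_M) else NA_real_
      tibble(time = tt, region = r, Q = q, n_motile = na, n_nonmotile = nb)
    }))
  })
  out <- bind_rows(rows)
  out$region <- factor(out$region, levels = levels(regions$region))
  attr(out, "f") <- f
  attr(out, "C_M") <- C_M
  attr(out, "z_excl") <- z_excl
  attr(out, "selection") <- selection
  class(out) <- c("gp_qseries", class(out))
  out
}

#' Time-mean Q
#'
#' Mean of the Q series per region, optionally truncated to times
#' `<= t_max` (robustness checks against the simulated duration).
#'
#' @param qs A `gp_qseries`.
#' @param t_max Truncation time (s); `Inf` uses the full series.
#' @return A tibble with `region` and `Q_mean`.
#' @export
q_mean <- function(qs, t_max = Inf) {
  qs %>%
    filter(.data$time <= t_max) %>%
    group_by(.data$region) %>%
    summarise(Q_mean = mean(.data$Q, na.rm = TRUE), .groups = "drop")
}

#' @export
glance.gp_qseries <- function(x, ...) {
  x %>%
    group_by(.data$region) %>%
    summarise(Q_mean = mean(.data$Q, na.rm = TRUE),
              Q_min = suppressWarnings(min(.data$Q, na.rm = TRUE)),
              Q_max = suppressWarnings(max(.data$Q, na.rm = TRUE)),
              n_valid = sum(!is.na(.data$Q)), .groups = "drop")
}

#' @export
tidy.gp_qseries <- function(x, ...) as_tibble(x)

#' @export
autoplot.gp_qseries <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$Q)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "patch concentration enhancement Q")
}

#' Absolute patch-concentration distributions
#'
#' Pools the absolute local concentrations of patch members per depth region
#' over a time window -- the complement of the relative Q statistic, showing
#' how concentrated patches actually are.
#'
#' @param traj A `gp_trajectory`.
#' @inheritParams q_timeseries_by_region
#' @param window Length-2 time window (s).
#' @return A `gp_patchdist` list with `samples` (tibble: `time`, `region`,
#'   `concentration`) and `summary` (per-region quantiles, mean and
#'   coefficient of variation). A window outside the trajectory span yields
#'   an all-missing summary.
#' @export
patch_concentration_distribution <- function(traj, regions = depth_regions(),
                                             f = 0.01, window,
                                             cadence = 1,
                                             z_excl = default_z_excl(traj$domain)) {
  dom <- traj$domain
  times <- traj$times[traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9]
  times <- times[abs(times / cadence - round(times / cadence)) < 1e-9]
  if (is.null(regions)) regions <- depth_regions(list(all = c(0, z_excl)))
  if (!length(times)) {
    out <- list(samples = tibble(time = numeric(), region = character(),
                                 concentration = numeric()),
                summary = tibble(region = levels(regions$region), n = 0L,
                                 q05 = NA_real_, q25 = NA_real_,
                                 median = NA_real_, q75 = NA_real_,
                                 q95 = NA_real_, mean = NA_real_, cv = NA_real_))
    class(out) <- "gp_patchdist"
    return(out)
  }
  samples <- bind_rows(lapply(times, function(tt) {
    pos <- trajectory_positions(traj, tt)
    pos <- pos[pos[, 3] <= z_excl, , drop = FALSE]
    conc <- local_concentration(voronoi_volumes(pos, dom))$concentration
    sel <- select_patches(conc, f)
    tibble(time = tt,
           region = as.character(assign_regions(pos[sel, 3], regions)),
           concentration = conc[sel])
  }))
  samples <- samples[!is.na(samples$region), ]
  summ <- samples %>%
    group_by(region = factor(.data$region, levels = levels(regions$region))) %>%
    summarise(n = n(),
              q05 = quantile(.data$concentration, 0.05),
              q25 = quantile(.data$concentration, 0.25),
              median = median(.data$concentration),
              q75 = quantile(.data$concentration, 0.75),
              q95 = quantile(.data$concentration, 0.95),
              mean = mean(.data$concentration),
              cv = sd(.data$concentration) / mean(.data$concentration),
              .groups = "drop") %>%
    tidyr::complete(region, fill = list(n = 0L))
  out <- list(samples = samples, summary = summ)
  class(out) <- "gp_patchdist"
  out
}

#' @export
print.gp_patchdist <- function(x, ...) {
  cat("<patch concentration distributions>\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.gp_patchdist <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$concentration)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~region, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(concentration ~ (m^-3)), y = "count")
}

#' Export a Q series to CSV
#'
#' Columns `time`, `region`, `Q`, `n_motile_members`, `n_nonmotile_members`.
#'
#' @param qs A `gp_qseries`.
#' @param path Output file.
#' @export
write_qseries_csv <- function(qs, path) {
  df <- as_tibble(qs)
  names(df) <- c("time", "region", "Q", "n_motile_members", "n_nonmotile_members")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
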