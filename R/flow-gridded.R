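#' Gridded velocity fields (netCDF)
#'
#' Time-resolved velocity snapshots on a regular grid, e.g. pre-computed
#' direct-numerical-simulation output. Queries use trilinear interpolation in
#' space and linear interpolation in time, with horizontal wrap-around at the
#' periodic x/y edges; vertical queries above the top node plane or below the
#' bottom plane clamp to the nearest plane (reflective walls can place
#' microbes between the wall and the outermost node). Vorticity is computed
#' once on the grid by centred finite differences (periodic in x/y,
#' one-sided at the z walls) and interpolated like the velocity.
#'
#' @param u,v,w Velocity component arrays, dim `(nx, ny, nz, nt)`, m/s.
#' @param x,y,z Node coordinates (m), uniformly spaced, increasing.
#' @param times Snapshot times (s), strictly increasing.
#' @param domain Optional [flow_domain()]; defaults to the grid extents
#'   (periodic spacing assumed in x and y, i.e. period `nx * dx`).
#' @return A `gp_gridded_field`.
#' @export
make_gridded_field <- function(u, v, w, x, y, z, times, domain = NULL) {
  dims <- c(length(x), length(y), length(z), length(times))
  for (nm in c("u", "v", "w")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims)))
      abort(sprintf("variable `%s` must have dim (nx, ny, nz, nt) = (%s)",
                    nm, paste(dims, collapse = ", ")))
  }
  check_uniform <- function(co, nm) {
    if (length(co) > 1) {
      d <- diff(co)
      if (any(d <= 0)) abort(sprintf("coordinate `%s` must be increasing", nm))
      if (nm != "t" && diff(range(d)) > 1e-8 * mean(d))
        abort(sprintf("coordinate `%s` is not uniformly spaced", nm))
    }
  }
  check_uniform(x, "x"); check_uniform(y, "y"); check_uniform(z, "z")
  if (length(times) > 1 && any(diff(times) <= 0))
    abort("coordinate `t` must be strictly increasing")
  dx <- if (length(x) > 1) x[2] - x[1] else 1
  dy <- if (length(y) > 1) y[2] - y[1] else 1
  dz <- if (length(z) > 1) z[2] - z[1] else 1
  if (is.null(domain))
    domain <- flow_domain(Lx = length(x) * dx, Ly = length(y) * dy,
                          Lz = max(z) + dz / 2)
  f <- structure(
    list(u = u, v = v, w = w, x = x, y = y, z = z, times = times,
         dx = dx, dy = dy, dz = dz, domain = domain),
    class = c("gp_gridded_field", "gp_field"))
  curl <- grid_curl(f)
  f$wx <- curl$wx; f$wy <- curl$wy; f$wz <- curl$wz
  f
}

#' @describeIn make_gridded_field Number of grid cells `nx * ny * nz`.
#' @param field A `gp_gridded_field` or a [grid_spec()].
#' @export
n_cells <- function(field) UseMethod("n_cells")

#' @export
n_cells.gp_gridded_field <- function(field)
  length(field$x) * length(field$y) * length(field$z)

#' @export
n_cells.gp_grid_spec <- function(field) field$n_cells

#' Grid bookkeeping from a header description
#'
#' Computes cell counts and cell side-lengths for a regular grid covering a
#' domain, without loading any data -- useful for checking the bookkeeping of
#' a simulation header (for example a 720 x 720 x 360 grid over a
#' 0.6 x 0.6 x 0.3 m box has 186,624,000 cubic cells of side ~0.83 mm).
#'
#' @param nx,ny,nz Grid cell counts.
#' @param domain A [flow_domain()] giving the extents.
#' @return A `gp_grid_spec` (also a tibble row) with `n_cells` and cell
#'   side-lengths `dx_m`, `dy_m`, `dz_m`.
#' @examples
#' grid_spec(720, 720, 360)
#' @export
grid_spec <- function(nx, ny, nz, domain = flow_domain()) {
  out <- tibble(nx = nx, ny = ny, nz = nz,
                n_cells = as.numeric(nx) * ny * nz,
                dx_m = domain$Lx / nx, dy_m = domain$Ly / ny,
                dz_m = domain$Lz / nz)
  class(out) <- c("gp_grid_spec", class(out))
  out
}

# centred-difference derivative of a (nx,ny,nz,nt) array along spatial dim d
grid_deriv <- function(a, d, h, periodic) {
  n <- dim(a)[d]
  idx <- function(shift) {
    i <- seq_len(n) + shift
    if (periodic) ((i - 1) %% n) + 1 else pmin(pmax(i, 1L), n)
  }
  slice <- function(i) {
    args <- rep(list(quote(expr = )), 4)
    args[[d]] <- i
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  up <- slice(idx(1L)); dn <- slice(idx(-1L))
  den <- array(2 * h, dim(a))
  if (!periodic && n > 1) {
    # one-sided at walls
    args <- rep(list(quote(expr = )), 4)
    args[[d]] <- c(1L, n)
    den_idx <- as.matrix(do.call(expand.grid, lapply(seq_len(4), function(k)
      if (k == d) c(1L, n) else seq_len(dim(a)[k]))))
    den[den_idx] <- h
  }
  (up - dn) / den
}

grid_curl <- function(f) {
  per <- c(f$domain$periodic_x, f$domain$periodic_y)
  dudy <- grid_deriv(f$u, 2, f$dy, per[2]); dudz <- grid_deriv(f$u, 3, f$dz, FALSE)
  dvdx <- grid_deriv(f$v, 1, f$dx, per[1]); dvdz <- grid_deriv(f$v, 3, f$dz, FALSE)
  dwdx <- grid_deriv(f$w, 1, f$dx, per[1]); dwdy <- grid_deriv(f$w, 2, f$dy, per[2])
  list(wx = dwdy - dvdz, wy = dudz - dwdx, wz = dvdx - dudy)
}

# trilinear + linear-time interpolation of one component array
interp_grid <- function(f, a, X, t) {
  nt <- length(f$times)
  if (t < f$times[1] - 1e-9 || t > f$times[nt] + 1e-9)
    abort(sprintf("time %.4g s is outside the field's span [%.4g, %.4g] s (no extrapolation)",
                  t, f$times[1], f$times[nt]))
  if (nt == 1) { it0 <- it1 <- 1L; ft <- 0 }
  else {
    it0 <- findInterval(t, f$times, rightmost.closed = TRUE)
    it0 <- min(max(it0, 1L), nt - 1L)
    it1 <- it0 + 1L
    ft <- (t - f$times[it0]) / (f$times[it1] - f$times[it0])
  }
  nx <- length(f$x); ny <- length(f$y); nz <- length(f$z)
  gx <- (X[, 1] - f$x[1]) / f$dx
  gy <- (X[, 2] - f$y[1]) / f$dy
  gz <- (X[, 3] - f$z[1]) / f$dz
  ix <- floor(gx); iy <- floor(gy); iz <- floor(gz)
  fx <- gx - ix; fy <- gy - iy; fz <- gz - iz
  # periodic wrap in x/y; clamp z to the node planes
  wrap <- function(i, n) as.integer(((i %% n) + n) %% n) + 1L
  clampz <- function(i) pmin(pmax(as.integer(i), 0L), nz - 1L) + 1L
  if (f$domain$periodic_x) { ix0 <- wrap(ix, nx); ix1 <- wrap(ix + 1, nx) }
  else { ix0 <- pmin(pmax(as.integer(ix), 0L), nx - 1L) + 1L
         ix1 <- pmin(ix0 + 1L, nx); fx <- pmin(pmax(fx, 0), 1) }
  if (f$domain$periodic_y) { iy0 <- wrap(iy, ny); iy1 <- wrap(iy + 1, ny) }
  else { iy0 <- pmin(pmax(as.integer(iy), 0L), ny - 1L) + 1L
         iy1 <- pmin(iy0 + 1L, ny); fy <- pmin(pmax(fy, 0), 1) }
  out_lo <- iz < 0; out_hi <- iz > nz - 2L
  iz0 <- clampz(iz); iz1 <- pmin(iz0 + 1L, nz)
  fz[out_lo] <- 0; fz[out_hi & iz0 == nz] <- 0
  fz[out_hi & iz0 == nz - 1L] <- 1
  fz <- pmin(pmax(fz, 0), 1)

  val_t <- function(it) {
    v <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wgt <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
             (if (cz) fz else 1 - fz)
      v <- v + wgt * a[cbind(if (cx) ix1 else ix0,
                             if (cy) iy1 else iy0,
                             if (cz) iz1 else iz0,
                             it)]
    }
    v
  }
  if (ft == 0) val_t(it0) else (1 - ft) * val_t(it0) + ft * val_t(it1)
}

#' @export
evaluate_velocity.gp_gridded_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  res <- cbind(u = interp_grid(field, field$u, X, t),
               v = interp_grid(field, field$v, X, t),
               w = interp_grid(field, field$w, X, t))
  shape_like(res, x)
}

#' @export
evaluate_vorticity.gp_gridded_field <- function(field, x, t = 0, ...) {
  X <- as_points(x)
  res <- cbind(wx = interp_grid(field, field$wx, X, t),
               wy = interp_grid(field, field$wy, X, t),
               wz = interp_grid(field, field$wz, X, t))
  shape_like(res, x)
}

#' Read and write gridded fields as netCDF
#'
#' Files use dims `(t, z, y, x)` and variables `u`, `v`, `w` in m/s, with
#' global attributes recording the grid spacing and domain extents.
#'
#' @param path File path.
#' @return [load_gridded_field()] returns a `gp_gridded_field`.
#' @export
load_gridded_field <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (vn in c("u", "v", "w"))
    if (is.null(nc$var[[vn]]))
      abort(sprintf("netCDF file is missing required variable `%s`", vn))
  getdim <- function(nm) {
    if (is.null(nc$dim[[nm]])) abort(sprintf("netCDF file is missing coordinate `%s`", nm))
    as.numeric(nc$dim[[nm]]$vals)
  }
  x <- getdim("x"); y <- getdim("y"); z <- getdim("z"); times <- getdim("t")
  u <- ncvar_get_4d(nc, "u", length(x), length(y), length(z), length(times))
  v <- ncvar_get_4d(nc, "v", length(x), length(y), length(z), length(times))
  w <- ncvar_get_4d(nc, "w", length(x), length(y), length(z), length(times))
  make_gridded_field(u, v, w, x, y, z, times)
}

ncvar_get_4d <- function(nc, vn, nx, ny, nz, nt) {
  a <- ncdf4::ncvar_get(nc, vn, collapse_degen = FALSE)
  array(a, dim = c(nx, ny, nz, nt))
}

#' @rdname load_gridded_field
#' @param field A `gp_gridded_field`.
#' @export
write_gridded_field <- function(field, path) {
  dx <- ncdf4::ncdim_def("x", "m", field$x)
  dy <- ncdf4::ncdim_def("y", "m", field$y)
  dz <- ncdf4::ncdim_def("z", "m", field$z)
  dt <- ncdf4::ncdim_def("t", "s", field$times, unlim = FALSE)
  mk <- function(nm) ncdf4::ncvar_def(nm, "m s-1", list(dx, dy, dz, dt), prec = "double")
  vu <- mk("u"); vv <- mk("v"); vw <- mk("w")
  nc <- ncdf4::nc_create(path, list(vu, vv, vw))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, field$u)
  ncdf4::ncvar_put(nc, vv, field$v)
  ncdf4::ncvar_put(nc, vw, field$w)
  ncdf4::ncatt_put(nc, 0, "dx_m", field$dx)
  ncdf4::ncatt_put(nc, 0, "Lx_m", field$domain$Lx)
  ncdf4::ncatt_put(nc, 0, "Ly_m", field$domain$Ly)
  ncdf4::ncatt_put(nc, 0, "Lz_m", field$domain$Lz)
  invisible(path)
}
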