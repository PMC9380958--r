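#' Simulation domain
#'
#' Defines the box in which flows are evaluated and microbes move. The
#' vertical coordinate increases upward: `z = 0` is the bottom and `z = Lz`
#' the (cooled) surface. The default extents, 0.6 x 0.6 x 0.3 m, are those of
#' a laboratory-scale convective mixed-layer tank with horizontal
#' periodicity.
#'
#' @param Lx,Ly,Lz Domain extents in metres; all must be positive.
#' @param periodic_x,periodic_y Horizontal periodicity flags.
#' @return An object of class `gp_domain`.
#' @examples
#' flow_domain()
#' flow_domain(Lx = 1, Ly = 1, Lz = 0.5)
#' @export
flow_domain <- function(Lx = 0.6, Ly = 0.6, Lz = 0.3,
                        periodic_x = TRUE, periodic_y = TRUE) {
  stopifnot_scalar(Lx, "Lx", positive = TRUE)
  stopifnot_scalar(Ly, "Ly", positive = TRUE)
  stopifnot_scalar(Lz, "Lz", positive = TRUE)
  structure(
    list(Lx = Lx, Ly = Ly, Lz = Lz,
         periodic_x = isTRUE(periodic_x), periodic_y = isTRUE(periodic_y)),
    class = "gp_domain"
  )
}

#' @export
print.gp_domain <- function(x, ...) {
  cat(sprintf("<domain %.3g x %.3g x %.3g m; periodic x:%s y:%s; z up, surface at z = %.3g m>\n",
              x$Lx, x$Ly, x$Lz, x$periodic_x, x$periodic_y, x$Lz))
  invisible(x)
}

domain_volume <- function(domain) domain$Lx * domain$Ly * domain$Lz
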