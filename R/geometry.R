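#' Conical nanopore geometry
#'
#' Bundles the dimensions of a conical track-etched nanopore. All lengths are
#' in metres (SI). The cone half-angle follows from the radius difference over
#' the pore length, `atan((d_b - d_t) / (2 L))`.
#'
#' @param d_t Tip diameter (m), the narrow sensing opening. Must be >= 0.
#' @param d_b Base diameter (m). Must be >= `d_t`.
#' @param L Membrane thickness / pore length (m). Must be > 0.
#'
#' @return An object of class `pore_geometry`: a list with elements `d_t`,
#'   `d_b`, `L` and the derived `alpha_deg` (cone half-angle, degrees).
#'
#' @examples
#' pore1 <- pore_geometry(d_t = 3e-9, d_b = 200e-9, L = 13e-6)
#' cone_half_angle(pore1) # ~0.43 degrees
#' @export
pore_geometry <- function(d_t, d_b, L) {
  stopifnot(is.numeric(d_t), is.numeric(d_b), is.numeric(L),
            length(d_t) == 1L, length(d_b) == 1L, length(L) == 1L)
  if (!is.finite(d_t) || d_t < 0) stop_domain("tip diameter d_t must be >= 0")
  if (!is.finite(d_b) || d_b < d_t) {
    stop_domain("base diameter d_b must be >= tip diameter d_t")
  }
  if (!is.finite(L) || L <= 0) stop_domain("pore length L must be > 0")
  geom <- structure(list(d_t = d_t, d_b = d_b, L = L), class = "pore_geometry")
  geom$alpha_deg <- cone_half_angle(geom)
  geom
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf(
    "Conical pore: d_t = %.3g nm, d_b = %.3g nm, L = %.3g um, alpha = %.2f deg\n",
    x$d_t * 1e9, x$d_b * 1e9, x$L * 1e6, x$alpha_deg))
  invisible(x)
}

#' Cone half-angle of a conical pore
#'
#' Half-angle of the cone, `atan((d_b - d_t) / (2 L))`, in degrees. A
#' cylindrical pore (`d_t == d_b`) has half-angle 0.
#'
#' @param geom A [pore_geometry()] object.
#' @return Half-angle in degrees.
#' @export
cone_half_angle <- function(geom) {
  stopifnot(inherits(geom, "pore_geometry"))
  atan2(geom$d_b - geom$d_t, 2 * geom$L) * 180 / pi
}

#' Conductance of a conical pore filled with bulk electrolyte
#'
#' Conductance of a conical channel assuming bulk-like ionic conductivity
#' inside the pore: `G = kappa * pi * d_t * d_b / (4 L)`. Linear in the
#' conductivity and in both diameters, inverse in the pore length.
#'
#' @param kappa Electrolyte conductivity (S/m). Must be > 0.
#' @param geom A [pore_geometry()] object.
#' @return Conductance in siemens.
#'
#' @examples
#' pore_conductance(10, pore_geometry(3e-9, 200e-9, 13e-6)) # 3.625e-10 S
#' @export
pore_conductance <- function(kappa, geom) {
  stopifnot(inherits(geom, "pore_geometry"))
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop_domain("electrolyte conductivity kappa must be a positive scalar")
  }
  kappa * pi * geom$d_t * geom$d_b / (4 * geom$L)
}

#' Tip diameter from a measured pore conductance
#'
#' Inverts the bulk conductance relation to estimate the tip opening from a
#' conductance measurement: `d_t = 4 G L / (kappa * pi * d_b)`. Exact inverse
#' of [pore_conductance()].
#'
#' @param G Measured conductance (S), >= 0.
#' @param kappa Electrolyte conductivity (S/m), > 0.
#' @param d_b Base diameter (m), > 0.
#' @param L Pore length (m), > 0.
#' @return Tip diameter in metres.
#' @export
tip_diameter_from_conductance <- function(G, kappa, d_b, L) {
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 0) {
    stop_domain("conductance G must be >= 0")
  }
  if (!is.finite(kappa) || kappa <= 0) stop_domain("kappa must be > 0")
  if (!is.finite(d_b) || d_b <= 0) stop_domain("base diameter d_b must be > 0")
  if (!is.finite(L) || L <= 0) stop_domain("pore length L must be > 0")
  4 * G * L / (kappa * pi * d_b)
}

#' Base diameter from total etch time
#'
#' The wide (base) opening of a track-etched conical pore grows linearly with
#' total etching time; the proportionality factor is a lab calibration
#' (default 2.5 nm per unit etch time).
#'
#' @param t_etch Total etch time (lab time units), >= 0.
#' @param factor Calibration factor, nm per unit etch time.
#' @return Base diameter in nanometres.
#'
#' @examples
#' base_diameter_from_etch_time(80)  # 200 nm
#' base_diameter_from_etch_time(140) # 350 nm
#' @export
base_diameter_from_etch_time <- function(t_etch, factor = 2.5) {
  if (!is.numeric(t_etch) || any(!is.finite(t_etch)) || any(t_etch < 0)) {
    stop_domain("etch time must be >= 0")
  }
  if (!is.numeric(factor) || factor <= 0) stop_domain("factor must be > 0")
  factor * t_etch
}
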