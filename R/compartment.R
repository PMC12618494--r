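#' Semi-open compartment geometry
#'
#' Describes the flat circular chamber (radius `R`, height `h`) flanked by a
#' thin exchange capillary (length `L`, width `W`) through which molecules
#' leave by diffusion. The second, constricted capillary that retains the cell
#' is geometrically recorded (`constriction_height_um`) but does not enter the
#' lifetime model: exchange is dominated by the open capillary.
#'
#' @param radius_um Chamber radius R in micrometres.
#' @param capillary_length_um Capillary length L in micrometres.
#' @param capillary_width_um Capillary width W in micrometres.
#' @param chamber_height_um Chamber height h in micrometres (default 1.5).
#' @param constriction_height_um Height of the constricted capillary in
#'   micrometres (default 0.4).
#'
#' @return An object of class `compartment_geometry`.
#' @examples
#' geom <- compartment_geometry(radius_um = 10, capillary_length_um = 40,
#'                              capillary_width_um = 1.5)
#' compartment_lifetime(geom, diffusion_um2_per_s = 10)
#' @export
compartment_geometry <- function(radius_um, capillary_length_um,
                                 capillary_width_um,
                                 chamber_height_um = 1.5,
                                 constriction_height_um = 0.4) {
  fields <- list(radius_um = radius_um,
                 capillary_length_um = capillary_length_um,
                 capillary_width_um = capillary_width_um,
                 chamber_height_um = chamber_height_um,
                 constriction_height_um = constriction_height_um)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("compartment_geometry: field '", nm,
           "' must be a single positive finite number", call. = FALSE)
  }
  if (capillary_width_um >= 2 * radius_um)
    stop("compartment_geometry: 'capillary_width_um' must be smaller than the chamber diameter",
         call. = FALSE)
  structure(fields, class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("Semi-open compartment: R = %g um, L = %g um, W = %g um, h = %g um\n",
              x$radius_um, x$capillary_length_um, x$capillary_width_um,
              x$chamber_height_um))
  invisible(x)
}

#' Diffusion lifetime of molecules in a semi-open compartment
#'
#' The mean residence time of a molecule with diffusion coefficient D in a
#' flat circular chamber that exchanges with the flow channels only through a
#' thin capillary is
#' \deqn{\tau = \frac{\pi R^2 L}{2 D W}}
#' with R the chamber radius and L, W the capillary length and width. Flow in
#' the chamber is negligible (the capillary's hydrodynamic resistance is
#' high), so exchange is purely diffusive.
#'
#' @param geometry A [compartment_geometry()].
#' @param diffusion_um2_per_s Diffusion coefficient D in um^2/s.
#'
#' @return A `lifetime_result` with fields `lifetime_s`, `lifetime_min`,
#'   `diffusion_um2_per_s` and `geometry`.
#' @examples
#' geom <- compartment_geometry(10, 40, 1.5)
#' # an mRNA-like species (D ~ 10 um^2/s) resides about 7 minutes
#' compartment_lifetime(geom, 10)$lifetime_min
#' @export
compartment_lifetime <- function(geometry, diffusion_um2_per_s) {
  if (!inherits(geometry, "compartment_geometry"))
    stop("compartment_lifetime: 'geometry' must be a compartment_geometry", call. = FALSE)
  if (!is.numeric(diffusion_um2_per_s) || length(diffusion_um2_per_s) != 1L ||
      !is.finite(diffusion_um2_per_s) || diffusion_um2_per_s <= 0)
    stop("compartment_lifetime: 'diffusion_um2_per_s' must be positive", call. = FALSE)
  tau <- pi * geometry$radius_um^2 * geometry$capillary_length_um /
    (2 * diffusion_um2_per_s * geometry$capillary_width_um)
  structure(list(lifetime_s = tau,
                 lifetime_min = tau / 60,
                 diffusion_um2_per_s = diffusion_um2_per_s,
                 geometry = geometry),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("Compartment lifetime: %.1f s (%.1f min) at D = %g um^2/s\n",
              x$lifetime_s, x$lifetime_min, x$diffusion_um2_per_s))
  invisible(x)
}

#' Chamber radius needed for a target diffusion lifetime
#'
#' Inverts the lifetime model for the chamber radius at fixed capillary
#' dimensions: R = sqrt(2 D W tau / (pi L)). Useful when designing a layout
#' that must retain a species of known mobility for a prescribed time.
#'
#' @param target_lifetime_s Desired residence time in seconds.
#' @param diffusion_um2_per_s Diffusion coefficient in um^2/s.
#' @param capillary_length_um Capillary length L in micrometres.
#' @param capillary_width_um Capillary width W in micrometres.
#'
#' @return Radius R in micrometres.
#' @export
solve_radius_for_lifetime <- function(target_lifetime_s, diffusion_um2_per_s,
                                      capillary_length_um, capillary_width_um) {
  args <- list(target_lifetime_s = target_lifetime_s,
               diffusion_um2_per_s = diffusion_um2_per_s,
               capillary_length_um = capillary_length_um,
               capillary_width_um = capillary_width_um)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        (v == 0 && nm != "target_lifetime_s"))
      stop("solve_radius_for_lifetime: '", nm, "' must be positive", call. = FALSE)
  }
  sqrt(2 * diffusion_um2_per_s * capillary_width_um * target_lifetime_s /
         (pi * capillary_length_um))
}

#' Flat report row for a compartment design
#'
#' @param geometry A [compartment_geometry()].
#' @param diffusion_um2_per_s Diffusion coefficient in um^2/s.
#' @return A one-row data.frame with R, L, W, D, tau_s and tau_min.
#' @export
lifetime_report <- function(geometry, diffusion_um2_per_s) {
  res <- compartment_lifetime(geometry, diffusion_um2_per_s)
  data.frame(R_um = geometry$radius_um,
             L_um = geometry$capillary_length_um,
             W_um = geometry$capillary_width_um,
             D_um2_per_s = diffusion_um2_per_s,
             tau_s = res$lifetime_s,
             tau_min = res$lifetime_min)
}
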