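# Unit policy: user-facing geometry is mm (axial positions, radii),
# cm^2 (areas), cm^3 (volumes), matching clinical airway tables; the flow
# solver works in SI. Every conversion lives here so no other file
# multiplies by a bare power of ten.

#' @keywords internal
mm_to_m <- function(x) x * 1e-3

#' @keywords internal
m_to_mm <- function(x) x * 1e3

#' @keywords internal
cm2_to_mm2 <- function(x) x * 100

#' @keywords internal
mm2_to_cm2 <- function(x) x / 100

#' @keywords internal
cm3_to_mm3 <- function(x) x * 1000

#' @keywords internal
mm3_to_cm3 <- function(x) x / 1000

#' @keywords internal
cm2_to_m2 <- function(x) x * 1e-4

#' @keywords internal
mlps_to_m3ps <- function(x) x * 1e-6

#' Convert a volumetric flow and an area to a mean velocity
#'
#' Implements the plug-flow relation V = Q/A used to set the extraction
#' velocity at the hypopharyngeal inlet face: Q is the peak volumetric flow
#' rate and A the cross-sectional area of the bottom of the hypopharynx.
#'
#' @param q_mlps volumetric flow rate, mL/s
#' @param area_cm2 cross-sectional area, cm^2
#' @return velocity in m/s
#' @examples
#' inlet_velocity(471.24, 2) # ~2.356 m/s
#' @export
inlet_velocity <- function(q_mlps, area_cm2) {
  stopifnot(is.numeric(q_mlps), is.numeric(area_cm2))
  if (area_cm2 <= 0) {
    stop("inlet_velocity: inlet area must be strictly positive (got ",
         area_cm2, " cm^2)")
  }
  mlps_to_m3ps(q_mlps) / cm2_to_m2(area_cm2)
}
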