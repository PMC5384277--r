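# Outcome metrics: per-millimetre slice sweep and the pharyngeal
# pressure-drop / area / resistance parameters.

# linear interpolation with linear extrapolation at both ends
lin_interp <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

# area-weighted slice quantities at one axial station (z in mm)
slice_quantities <- function(phantom, field, z_mm, hydro_correct = TRUE) {
  g <- field$grid
  ann <- g$ann
  z_m <- mm_to_m(z_mm)
  zc <- g$zc; zf <- g$zf
  nr <- g$nr; nz <- g$nz
  pj <- vapply(seq_len(nr), function(j) lin_interp(zc, field$p[, j], z_m),
               numeric(1))
  if (hydro_correct && field$fluid$gravity_enabled) {
    pj <- pj - field$fluid$density * field$fluid$gravity * z_m
  }
  uj <- vapply(seq_len(nr), function(j) lin_interp(zf, field$u[, j], z_m),
               numeric(1))
  vcell <- (field$v[, 1:nr, drop = FALSE] +
            field$v[, 2:(nr + 1), drop = FALSE]) / 2
  vj <- vapply(seq_len(nr), function(j) lin_interp(zc, vcell[, j], z_m),
               numeric(1))
  w <- ann / sum(ann)
  list(mean_pressure = sum(pj * w),
       mean_velocity = sum(sqrt(uj^2 + vj^2) * w))
}

#' Slice quantities at a single axial station
#'
#' @param phantom an `airway_phantom`
#' @param field a converged `flow_field` on that phantom's grid
#' @param z_mm axial position, mm
#' @param hydro_correct subtract the hydrostatic head rho*g*z when gravity
#'   was enabled, so pressures reflect flow resistance only
#' @return list: `z`, `area` (cm^2), `mean_pressure` (Pa),
#'   `mean_velocity` (m/s)
#' @export
slice_at <- function(phantom, field, z_mm, hydro_correct = TRUE) {
  q <- slice_quantities(phantom, field, z_mm, hydro_correct)
  list(z = z_mm, area = mm2_to_cm2(phantom$area_fun(z_mm)),
       mean_pressure = q$mean_pressure, mean_velocity = q$mean_velocity)
}

#' Per-millimetre slice sweep from choana to hypopharynx bottom
#'
#' Extracts cross-sections every `spacing` mm along the z axis and computes
#' the slice area and the area-weighted average pressure and velocity
#' magnitude on each. The terminal station z = L is always included.
#'
#' @inheritParams slice_at
#' @param spacing slice spacing, mm (default 1)
#' @param force extract even from an unconverged field
#' @return a `slice_profiles` data.frame: z (mm), area (cm^2),
#'   mean_pressure (Pa), mean_velocity (m/s), region
#' @export
slice_sweep <- function(phantom, field, spacing = 1, hydro_correct = TRUE,
                        force = FALSE) {
  stopifnot(inherits(phantom, "airway_phantom"),
            inherits(field, "flow_field"))
  if (!field$converged && !force) {
    stop("slice_sweep: flow field is not converged (use force = TRUE to ",
         "extract anyway)")
  }
  L <- phantom$length
  z <- seq(0, L, by = spacing)
  if (z[length(z)] < L - 1e-9) z <- c(z, L)
  qs <- lapply(z, function(zz) slice_quantities(phantom, field, zz,
                                                hydro_correct))
  b <- phantom$boundaries
  region <- REGION_NAMES[findInterval(z, c(b[[1]], b[[2]]),
                                      left.open = TRUE) + 1L]
  out <- data.frame(
    z = z, area = mm2_to_cm2(phantom$area_fun(z)),
    mean_pressure = vapply(qs, `[[`, numeric(1), "mean_pressure"),
    mean_velocity = vapply(qs, `[[`, numeric(1), "mean_velocity"),
    region = region)
  attr(out, "boundaries") <- b
  attr(out, "q_peak") <- field$q_peak
  class(out) <- c("slice_profiles", "data.frame")
  out
}

#' Compute the pharyngeal outcome metrics from a slice sweep
#'
#' The headline pressure-drop metric is the area-averaged pressure drop
#' from the choana slice to the minimum-area slice (dP_max). Regional
#' pressure drops are max - min of the slice-mean pressure within each
#' region; regional resistance is dP / Q (pressure drop per unit flow; the
#' drop and the resistance move together at constant flow). Ties in the
#' minimum area resolve to the most superior slice.
#'
#' @param profiles a [slice_sweep()] result
#' @param boundaries region boundary positions, mm (default: taken from
#'   the profiles attribute)
#' @param q_mlps volumetric flow rate, mL/s (default: from the profiles)
#' @return an `airway_metrics` list: volumes (cm^3), A_min and its
#'   location/region, A_mean = V/L, a_ratio, dP_max and regional dP (Pa),
#'   regional resistance (Pa per L/s), extremum-location regions
#' @export
compute_metrics <- function(profiles, boundaries = NULL, q_mlps = NULL) {
  stopifnot(inherits(profiles, "slice_profiles") ||
              is.data.frame(profiles))
  if (is.null(boundaries)) boundaries <- attr(profiles, "boundaries")
  if (is.null(q_mlps)) q_mlps <- attr(profiles, "q_peak")
  stopifnot(!is.null(boundaries), !is.null(q_mlps))
  z <- profiles$z; area <- profiles$area; p <- profiles$mean_pressure
  vel <- profiles$mean_velocity
  b1 <- boundaries[[1]]; b2 <- boundaries[[2]]
  L <- max(z) - min(z)

  # region volumes by trapezoid with exact cuts at the boundary planes
  vol_between <- function(lo, hi) {
    zz <- sort(unique(c(lo, z[z > lo & z < hi], hi)))
    aa <- stats::approx(z, area, zz)$y
    sum((aa[-1] + aa[-length(aa)]) / 2 * diff(zz)) / 10  # cm^2*mm -> cm^3
  }
  v_na <- vol_between(min(z), b1)
  v_or <- vol_between(b1, b2)
  v_hy <- vol_between(b2, max(z))
  V <- v_na + v_or + v_hy

  imin <- which(area <= min(area) + 1e-12)[1]  # tie -> most superior
  a_min <- area[imin]
  a_mean <- V / (L / 10)                       # cm^3 / cm = cm^2
  region_of <- function(zz) {
    REGION_NAMES[findInterval(zz, c(b1, b2), left.open = TRUE) + 1L]
  }

  dp_max <- p[1] - p[imin]
  if (dp_max < 0) {
    warning("compute_metrics: dP_max negative (pressure at the minimum ",
            "area exceeds the choana slice); flooring at 0")
    dp_max <- 0
  }
  reg_dp <- function(lo, hi) {
    sel <- z >= lo - 1e-9 & z <= hi + 1e-9
    if (!any(sel)) return(0)
    max(p[sel]) - min(p[sel])
  }
  dp_na <- reg_dp(min(z), b1)
  dp_or <- reg_dp(b1, b2)
  dp_hy <- reg_dp(b2, max(z))
  q_lps <- q_mlps / 1000
  res <- if (q_lps > 0) c(dp_na, dp_or, dp_hy) / q_lps else c(0, 0, 0)

  structure(list(
    V = V, V_na = v_na, V_or = v_or, V_hy = v_hy,
    A_min = a_min, A_min_z = z[imin], A_min_region = region_of(z[imin]),
    A_mean = a_mean, a_ratio = a_min / a_mean,
    dP_max = dp_max, dP_na = dp_na, dP_or = dp_or, dP_hy = dp_hy,
    R_na = res[1], R_or = res[2], R_hy = res[3],
    min_pressure_z = z[which.min(p)],
    min_pressure_region = region_of(z[which.min(p)]),
    max_velocity_z = z[which.max(vel)],
    max_velocity_region = region_of(z[which.max(vel)]),
    Q = q_mlps,
    resistance_note = paste(
      "resistance computed as dP/Q (Pa per L/s); at constant flow the",
      "pressure drop tracks the resistance")
  ), class = "airway_metrics")
}

#' One-call metrics for a phantom
#'
#' Builds the grid, solves the steady peak-inspiration flow, sweeps slices
#' and computes the outcome metrics.
#'
#' @param phantom an `airway_phantom`
#' @param q_peak flow rate, mL/s
#' @param nz,nr,grading grid resolution
#' @param fluid,numerics solver settings
#' @param hydro_correct hydrostatic pressure correction flag
#' @param inlet_area inlet face area override, cm^2 (default: from the
#'   phantom's specification when available)
#' @param extension_mm straight outlet extension for the solve, mm; metric
#'   extraction stays confined to the anatomical column
#' @param retry on divergence or an unusable field, retry with a damped
#'   relaxation pair and finally with the first-order scheme before giving
#'   up (the usual manual rescue sequence for stiff steady solves)
#' @return list with `metrics`, `profiles`, `field`, `grid`
#' @export
phantom_metrics <- function(phantom, q_peak = peak_flow_rate(),
                            nz = 200, nr = 32, grading = 1.15,
                            fluid = fluid_props(),
                            numerics = numerics_config(),
                            hydro_correct = TRUE, inlet_area = NULL,
                            extension_mm = 30, retry = TRUE) {
  if (is.null(inlet_area) && !is.null(phantom$spec)) {
    inlet_area <- phantom$spec$inlet_area
  }
  grid <- generate_grid(phantom, nz = nz, nr = nr, grading = grading,
                        extension_mm = extension_mm)
  bc <- boundary_conditions(q_peak = q_peak, inlet_area = inlet_area)
  attempts <- list(numerics)
  if (retry) {
    attempts <- c(attempts, list(
      numerics_config(scheme = numerics$scheme, alpha_u = 0.4,
                      alpha_p = 0.2, tol = numerics$tol,
                      max_iter = 2L * numerics$max_iter,
                      avg_window = numerics$avg_window),
      numerics_config(scheme = "first_upwind", alpha_u = 0.3,
                      alpha_p = 0.15, tol = numerics$tol,
                      max_iter = 2L * numerics$max_iter,
                      avg_window = numerics$avg_window)))
  }
  field <- NULL
  for (k in seq_along(attempts)) {
    field <- tryCatch(solve_steady(grid, bc, fluid, attempts[[k]]),
                      pharynxflow_divergence = function(e) e)
    if (inherits(field, "flow_field") && field_usable(field)) break
    if (k == length(attempts) && !inherits(field, "flow_field")) {
      stop(field)
    }
  }
  profiles <- slice_sweep(phantom, field, hydro_correct = hydro_correct,
                          force = field_usable(field) || !field$converged)
  list(metrics = compute_metrics(profiles), profiles = profiles,
       field = field, grid = grid)
}

#' @export
print.airway_metrics <- function(x, ...) {
  cat("Airway outcome metrics\n")
  cat(sprintf("  V (cm^3): total %.2f = Na %.2f + Or %.2f + Hy %.2f\n",
              x$V, x$V_na, x$V_or, x$V_hy))
  cat(sprintf("  A_min %.3f cm^2 (%s, z = %.0f mm); A_mean %.3f; ratio %.2f\n",
              x$A_min, x$A_min_region, x$A_min_z, x$A_mean, x$a_ratio))
  cat(sprintf("  dP_max %.2f Pa; dP Na/Or/Hy %.2f / %.2f / %.2f Pa\n",
              x$dP_max, x$dP_na, x$dP_or, x$dP_hy))
  cat(sprintf("  min pressure in %s; max velocity in %s\n",
              x$min_pressure_region, x$max_velocity_region))
  invisible(x)
}
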