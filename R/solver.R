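# Steady laminar incompressible axisymmetric flow with SIMPLE coupling.
#
# Finite volumes on a staggered arrangement over the body-fitted (z, eta)
# grid: pressure at cell centers, axial velocity on constant-z faces,
# radial velocity on eta faces. Convection is first-order upwind implicit
# with a deferred second-order (linear-upwind axially, central radially)
# correction; diffusion is central. The compiled kernel lives in src/.

#' Fluid properties
#'
#' Defaults are standard air at 15 degrees C; temperature and humidity
#' effects are neglected. Gravity acts along +z (inferiorly, down the
#' airway column) and is included by default.
#'
#' @param density kg/m^3
#' @param viscosity dynamic viscosity, Pa s
#' @param gravity magnitude, m/s^2
#' @param gravity_enabled include the axial body force
#' @return a `fluid_props` list
#' @export
fluid_props <- function(density = 1.225, viscosity = 1.7894e-5,
                        gravity = 9.81, gravity_enabled = TRUE) {
  stopifnot(density > 0, viscosity > 0, gravity >= 0)
  structure(list(density = density, viscosity = viscosity,
                 gravity = gravity, gravity_enabled = gravity_enabled),
            class = "fluid_props")
}

#' Sinusoidal respiratory waveform
#'
#' Inspiration is modeled as a half-sine flow pulse Q(t) = Q_peak sin(w t)
#' whose integral over the inspiratory phase equals the tidal volume. With
#' the defaults (600 mL tidal volume, 4 s cycle, 1:1 I:E ratio) the
#' inspiratory phase lasts 2 s, w = pi/2 rad/s and Q_peak = 150 pi
#' (~471.24 mL/s).
#'
#' @param tidal_volume mL
#' @param period full respiratory cycle, s
#' @param ie_ratio inspiratory:expiratory time ratio
#' @return a `waveform` list with `q_peak` (mL/s), `omega` (rad/s),
#'   `t_insp` (s)
#' @export
respiratory_waveform <- function(tidal_volume = 600, period = 4,
                                 ie_ratio = 1) {
  stopifnot(tidal_volume >= 0, period > 0, ie_ratio > 0)
  t_insp <- period * ie_ratio / (1 + ie_ratio)
  omega <- pi / t_insp
  structure(list(tidal_volume = tidal_volume, period = period,
                 ie_ratio = ie_ratio, t_insp = t_insp, omega = omega,
                 q_peak = peak_flow_rate(tidal_volume, period, ie_ratio)),
            class = "waveform")
}

#' Peak inspiratory flow rate of the half-sine waveform
#'
#' Solves int_0^T_insp Q_peak sin(pi t / T_insp) dt = tidal_volume, giving
#' Q_peak = pi * tidal_volume / (2 T_insp).
#'
#' @inheritParams respiratory_waveform
#' @return peak flow, mL/s
#' @export
peak_flow_rate <- function(tidal_volume = 600, period = 4, ie_ratio = 1) {
  if (tidal_volume < 0 || period <= 0 || ie_ratio <= 0) {
    stop("peak_flow_rate: tidal_volume >= 0, period > 0, ie_ratio > 0")
  }
  t_insp <- period * ie_ratio / (1 + ie_ratio)
  pi * tidal_volume / (2 * t_insp)
}

#' Boundary conditions for the steady peak-flow solve
#'
#' Ambient static pressure at the choana (superior outlet in the imaging
#' convention); a uniform (or parabolic) extraction velocity at the bottom
#' of the hypopharynx drawing flow inferiorly at V = Q/A; no-slip walls.
#'
#' @param q_peak volumetric flow, mL/s
#' @param inlet_area area of the hypopharynx bottom face, cm^2; taken from
#'   the phantom when `NULL` at solve time
#' @param outlet_pressure gauge pressure at the choana, Pa
#' @param profile "uniform" or "parabolic" extraction velocity profile
#' @return a `boundary_conditions` list
#' @export
boundary_conditions <- function(q_peak = peak_flow_rate(),
                                inlet_area = NULL, outlet_pressure = 0,
                                profile = c("uniform", "parabolic")) {
  stopifnot(q_peak >= 0)
  profile <- match.arg(profile)
  structure(list(q_peak = q_peak, inlet_area = inlet_area,
                 outlet_pressure = outlet_pressure, profile = profile),
            class = "boundary_conditions")
}

#' Numerical settings for the SIMPLE solver
#'
#' @param scheme convection scheme: "second_upwind" (deferred-correction
#'   linear upwind, default), "first_upwind", or "central"
#' @param alpha_u,alpha_p velocity / pressure under-relaxation in (0, 1]
#' @param tol scaled-residual convergence tolerance
#' @param max_iter maximum outer iterations
#' @param re_warn throat Reynolds number above which a laminar-assumption
#'   warning is emitted
#' @param avg_window when a solve stalls above tolerance without diverging
#'   (a limit cycle, typical of transitional throat jets), iterate this
#'   many further steps and return the iterate-averaged fields — the desk
#'   equivalent of the time-mean flow; 0 disables averaging
#' @return a `numerics_config` list
#' @export
numerics_config <- function(scheme = c("second_upwind", "first_upwind",
                                       "central"),
                            alpha_u = 0.7, alpha_p = 0.3,
                            tol = 1e-4, max_iter = 1000L, re_warn = 2300,
                            avg_window = 600L) {
  scheme <- match.arg(scheme)
  stopifnot(alpha_u > 0, alpha_u <= 1, alpha_p > 0, alpha_p <= 1,
            tol > 0, max_iter >= 1, avg_window >= 0)
  structure(list(scheme = scheme, alpha_u = alpha_u, alpha_p = alpha_p,
                 tol = tol, max_iter = as.integer(max_iter),
                 re_warn = re_warn, avg_window = as.integer(avg_window)),
            class = "numerics_config")
}

#' Solve the steady laminar flow field on an axisymmetric grid
#'
#' SIMPLE pressure-velocity coupling iterated until the scaled residuals of
#' continuity and both momentum equations fall below the tolerance or the
#' iteration cap is reached. The converged pressure field is referenced so
#' that the area-weighted mean pressure of the choana plane equals the
#' prescribed outlet pressure. Residual growth over 50 consecutive
#' iterations aborts with the residual history attached.
#'
#' @param grid an [generate_grid()] result
#' @param bc a [boundary_conditions()]
#' @param fluid a [fluid_props()]
#' @param numerics a [numerics_config()]
#' @return a `flow_field`: `u` (axial, (nz+1) x nr), `v` (radial,
#'   nz x (nr+1)), `p` (nz x nr), `converged`, `residuals` (per-iteration
#'   scaled continuity/momentum), `re_throat`, `mass_imbalance`
#' @export
solve_steady <- function(grid, bc, fluid = fluid_props(),
                         numerics = numerics_config()) {
  stopifnot(inherits(grid, "axi_grid"), inherits(bc, "boundary_conditions"))
  area_in_cm2 <- if (is.null(bc$inlet_area)) {
    mm2_to_cm2(pi * m_to_mm(grid$Rf[grid$nz + 1])^2)
  } else bc$inlet_area
  q_m3ps <- mlps_to_m3ps(bc$q_peak)
  # V = Q/A at the hypopharynx bottom is the reported inlet velocity; the
  # velocity actually applied on the (possibly extended) end face uses
  # that face's own area so the volumetric flux is exactly Q
  v_qa <- inlet_velocity(bc$q_peak, area_in_cm2)
  uin <- q_m3ps / (pi * grid$Rf[grid$nz + 1]^2)

  if (bc$q_peak == 0) {
    field <- list(u = matrix(0, grid$nz + 1, grid$nr),
                  v = matrix(0, grid$nz, grid$nr + 1),
                  p = matrix(bc$outlet_pressure, grid$nz, grid$nr),
                  converged = TRUE, oscillatory = FALSE, iterations = 0L,
                  residuals = data.frame(continuity = numeric(0),
                                         u_mom = numeric(0),
                                         v_mom = numeric(0)),
                  re_throat = 0, mass_imbalance = 0)
  } else {
    profile_code <- if (bc$profile == "parabolic") 1L else 0L
    scheme_code <- switch(numerics$scheme,
                          first_upwind = 0L, second_upwind = 1L,
                          central = 2L)
    gz <- if (fluid$gravity_enabled) fluid$gravity else 0
    sol <- simple_solve_cpp(
      grid$zf, grid$etaf, grid$Rf, grid$Rc, grid$Rpf, grid$Rpc,
      fluid$density, fluid$viscosity, gz, uin, profile_code,
      numerics$alpha_u, numerics$alpha_p, numerics$tol,
      numerics$max_iter, scheme_code, numerics$avg_window)
    res <- data.frame(continuity = sol$res_c, u_mom = sol$res_u,
                      v_mom = sol$res_v)
    if (sol$diverged) {
      err <- structure(
        class = c("pharynxflow_divergence", "error", "condition"),
        list(message = paste0("solve_steady: residual growth over 50 ",
                              "consecutive iterations (diverged)"),
             call = sys.call(), residuals = res))
      stop(err)
    }
    # reference pressure: choana-plane mean = outlet pressure
    ann <- grid$ann
    p_plane <- extrapolate_to_z0(grid, sol$p)
    shift <- bc$outlet_pressure - sum(p_plane * ann) / sum(ann)
    field <- list(u = sol$u, v = sol$v, p = sol$p + shift,
                  converged = as.logical(sol$converged),
                  oscillatory = as.logical(sol$oscillatory),
                  iterations = sol$iterations, residuals = res,
                  re_throat = NA_real_, mass_imbalance = NA_real_)
  }
  # throat Reynolds number from the minimum grid radius
  rmin <- min(grid$Rf)
  v_throat <- q_m3ps / (pi * rmin^2)
  field$re_throat <- fluid$density * v_throat * 2 * rmin / fluid$viscosity
  if (field$re_throat > numerics$re_warn) {
    warning(sprintf(
      paste0("solve_steady: throat Reynolds number %.0f exceeds %.0f; ",
             "the steady laminar assumption (no fully developed ",
             "turbulence below ~30 L/min) may be strained"),
      field$re_throat, numerics$re_warn))
  }
  field$q_peak <- bc$q_peak
  field$inlet_velocity <- v_qa
  field$fluid <- fluid
  field$grid <- grid
  field$outlet_pressure <- bc$outlet_pressure
  if (bc$q_peak > 0) field$mass_imbalance <- mass_imbalance(field)
  class(field) <- "flow_field"
  field
}

# linear extrapolation of cell-center pressures to the z = 0 plane
extrapolate_to_z0 <- function(grid, p) {
  z1 <- grid$zc[1]; z2 <- grid$zc[2]
  p[1, ] + (p[1, ] - p[2, ]) * z1 / (z2 - z1)
}

#' Worst relative slice-flux deviation of a converged field
#'
#' Volumetric flux through every constant-z face column compared with the
#' prescribed flow rate; returns max |Q(z) - Q_in| / Q_in.
#' @param field a `flow_field`
#' @return dimensionless imbalance
#' @export
mass_imbalance <- function(field) {
  g <- field$grid
  q_target <- mlps_to_m3ps(field$q_peak) / (2 * pi)  # per radian
  qz <- as.numeric(field$u %*% g$ann) * g$Rf^2 / g$Rf^2
  qz <- vapply(seq_len(g$nz + 1), function(i) {
    sum(field$u[i, ] * g$ann * g$Rf[i]^2)
  }, numeric(1))
  max(abs(qz - q_target)) / q_target
}

#' Is a flow field usable for metric extraction?
#'
#' A field is usable when the solve converged to tolerance, or when it
#' stalled in a small limit cycle (marginally unsteady throat jet) and the
#' returned iterate-averaged mean field still conserves mass to within
#' `max_imbalance`. Mirrors the study protocol of accepting plateaued
#' steady solves at a recorded residual level.
#'
#' @param field a `flow_field`
#' @param max_imbalance worst slice-flux deviation tolerated for
#'   oscillatory-averaged fields (default 2%)
#' @return logical
#' @export
field_usable <- function(field, max_imbalance = 0.02) {
  isTRUE(field$converged) ||
    (isTRUE(field$oscillatory) &&
       is.finite(field$mass_imbalance) &&
       field$mass_imbalance <= max_imbalance)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "Flow field: %s after %d iterations; Re_throat %.0f; mass imbalance %.2e\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$re_throat, x$mass_imbalance))
  invisible(x)
}
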