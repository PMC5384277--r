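# Structured body-fitted axisymmetric grids.
#
# The computational grid lives on the rectangle (z, eta) with eta = r/R(z)
# in [0, 1]: axial grid lines are flat annular faces at constant z, radial
# grid lines follow the wall. Radial spacing is geometrically graded toward
# the wall to resolve the laminar boundary layer. All areas and volumes
# below are per radian; multiply by 2*pi for physical values.

#' Generate a body-fitted axisymmetric grid on a phantom
#'
#' With `extension_mm > 0` a straight outlet extension is appended beyond
#' the hypopharynx bottom (wall slope blended smoothly to zero over
#' `blend_mm`), the standard upper-airway CFD practice that moves the
#' extraction boundary away from any separated flow at the last
#' constriction. Cells in the extension are flagged and excluded from
#' metric extraction, which only ever samples z in \[0, L\].
#'
#' @param phantom an `airway_phantom`
#' @param nz number of axial cells over the anatomical column (>= 8)
#' @param nr number of radial cells (>= 4)
#' @param grading radial spacing ratio toward the wall (>= 1; 1 = uniform,
#'   default 1.15 refines toward the wall)
#' @param extension_mm straight outlet extension length, mm (default 0)
#' @param blend_mm wall-slope blending length of the extension, mm
#' @return an `axi_grid` with face coordinates (SI), wall radius and slope
#'   at faces/centers, and per-radian cell volumes
#' @export
generate_grid <- function(phantom, nz = 200, nr = 32, grading = 1.15,
                          extension_mm = 0, blend_mm = 10) {
  stopifnot(inherits(phantom, "axi_grid") == FALSE,
            inherits(phantom, "airway_phantom"))
  if (nz < 8 || nr < 4) stop("generate_grid: need nz >= 8 and nr >= 4")
  if (grading < 1) stop("generate_grid: grading must be >= 1")
  L_mm <- phantom$length
  dz_mm <- L_mm / nz
  nz_ext <- if (extension_mm > 0) max(2L, ceiling(extension_mm / dz_mm))
            else 0L
  radius_mm <- function(z) {
    z <- pmin(z, L_mm + extension_mm)
    base <- phantom$radius_fun(pmin(z, L_mm))
    t <- pmax(z - L_mm, 0)
    rl <- phantom$radius_fun(L_mm)
    sl <- phantom$dradius_fun(L_mm)
    ext <- ifelse(t < blend_mm, rl + sl * (t - t^2 / (2 * blend_mm)),
                  rl + sl * blend_mm / 2)
    # a steep end slope must not pinch the extension shut
    ext <- pmax(ext, 0.5 * rl)
    ifelse(z <= L_mm, base, ext)
  }
  dradius_mm <- function(z) {
    t <- pmax(z - L_mm, 0)
    sl <- phantom$dradius_fun(L_mm)
    ifelse(z <= L_mm, phantom$dradius_fun(pmin(z, L_mm)),
           ifelse(t < blend_mm, sl * (1 - t / blend_mm), 0))
  }
  nz_tot <- nz + nz_ext
  L <- mm_to_m(L_mm + nz_ext * dz_mm)
  nz <- nz_tot
  zf <- seq(0, L, length.out = nz + 1)
  if (grading == 1) {
    etaf <- seq(0, 1, length.out = nr + 1)
  } else {
    d0 <- (1 - 1 / grading) / (1 - grading^(-nr))
    etaf <- c(0, cumsum(d0 * grading^(-(seq_len(nr) - 1))))
    etaf[nr + 1] <- 1
  }
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  z_mm_f <- m_to_mm(zf); z_mm_c <- m_to_mm(zc)
  Rf <- mm_to_m(radius_mm(z_mm_f))
  Rc <- mm_to_m(radius_mm(z_mm_c))
  Rpf <- dradius_mm(z_mm_f)              # dR/dz, dimensionless
  Rpc <- dradius_mm(z_mm_c)
  if (min(Rf) < 2 * min(diff(etaf)) * max(Rf) * 1e-3) {
    stop("generate_grid: phantom radius degenerate relative to the ",
         "radial resolution")
  }
  ann <- (etaf[-1]^2 - etaf[-(nr + 1)]^2) / 2   # per-radian annulus / R^2
  dz <- diff(zf)
  # per-radian cell volumes, Simpson in z for the R^2 factor
  R2s <- (Rf[-(nz + 1)]^2 + 4 * Rc^2 + Rf[-1]^2) / 6
  vol <- outer(R2s * dz, ann)                   # nz x nr
  structure(list(
    nz = nz, nr = nr, zf = zf, zc = zc, etaf = etaf,
    etac = (etaf[-1] + etaf[-(nr + 1)]) / 2,
    Rf = Rf, Rc = Rc, Rpf = Rpf, Rpc = Rpc,
    ann = ann, dz = dz, vol = vol, phantom = phantom,
    nz_anat = nz - nz_ext, extension_mm = nz_ext * dz_mm
  ), class = "axi_grid")
}

#' Total grid volume, cm^3 (sums per-radian cell volumes times 2*pi)
#' @param grid an `axi_grid`
#' @return volume, cm^3
#' @export
grid_volume <- function(grid) {
  2 * pi * sum(grid$vol) * 1e6 / 1e0   # m^3 -> cm^3 is 1e6
}

#' Build a refinement series of grids
#'
#' @param phantom an `airway_phantom`
#' @param nz,nr resolution of the middle (reference) level
#' @param levels number of levels (default 5)
#' @param ratio linear refinement ratio between consecutive levels
#'   (default sqrt(2))
#' @param grading radial grading factor
#' @param extension_mm outlet extension passed to [generate_grid()]
#' @return a `grid_series`: list of `axi_grid` at increasing resolution
#' @export
grid_series <- function(phantom, nz = 200, nr = 32, levels = 5,
                        ratio = sqrt(2), grading = 1.15,
                        extension_mm = 0) {
  mid <- (levels + 1) / 2
  grids <- lapply(seq_len(levels), function(k) {
    f <- ratio^(k - mid)
    generate_grid(phantom, nz = max(8L, as.integer(round(nz * f))),
                  nr = max(4L, as.integer(round(nr * f))),
                  grading = grading, extension_mm = extension_mm)
  })
  structure(list(grids = grids, ratio = ratio), class = "grid_series")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric grid: %d x %d cells (%d total), volume %.2f cm^3\n",
              x$nz, x$nr, x$nz * x$nr, grid_volume(x)))
  invisible(x)
}

#' Grid-independence study
#'
#' Solves the flow on every level of a refinement series and monitors the
#' area-weighted mean pressure and mean velocity magnitude on the probe
#' plane. The chosen level is the coarsest whose monitored quantities both
#' change by less than `threshold_pct` relative to the next finer level;
#' if no level qualifies the finest is returned with a warning flag.
#'
#' @param series a [grid_series()]
#' @param bc a [boundary_conditions()]
#' @param fluid a [fluid_props()]
#' @param numerics a [numerics_config()]
#' @param probe_z probe plane position, mm; default the minimum-area station
#' @param threshold_pct acceptance threshold, percent (default 1)
#' @return list: `chosen` (level index), `criterion_met` (flag), `table`
#'   (data.frame: level, cells, mean_p, mean_v, dp_pct, dv_pct)
#' @export
grid_independence <- function(series, bc, fluid = fluid_props(),
                              numerics = numerics_config(),
                              probe_z = NULL, threshold_pct = 1) {
  stopifnot(inherits(series, "grid_series"))
  grids <- series$grids
  phantom <- grids[[1]]$phantom
  if (is.null(probe_z)) probe_z <- phantom$z[which.min(phantom$area)]
  nlev <- length(grids)
  mean_p <- mean_v <- cells <- numeric(nlev)
  for (k in seq_len(nlev)) {
    field <- solve_steady(grids[[k]], bc, fluid, numerics)
    if (!field$converged) {
      stop("grid_independence: solver failed to converge on level ", k)
    }
    pr <- slice_at(phantom, field, probe_z)
    mean_p[k] <- pr$mean_pressure
    mean_v[k] <- pr$mean_velocity
    cells[k] <- grids[[k]]$nz * grids[[k]]$nr
  }
  rel <- function(x) c(abs(diff(x)) / pmax(abs(x[-1]), 1e-300) * 100, NA)
  dp <- rel(mean_p); dv <- rel(mean_v)
  ok <- which(dp[-nlev] < threshold_pct & dv[-nlev] < threshold_pct)
  criterion_met <- length(ok) > 0
  chosen <- if (criterion_met) min(ok) else nlev
  if (!criterion_met) {
    warning("grid_independence: <", threshold_pct,
            "% criterion never met; returning the finest level")
  }
  list(chosen = chosen, criterion_met = criterion_met,
       table = data.frame(level = seq_len(nlev), cells = cells,
                          mean_p = mean_p, mean_v = mean_v,
                          dp_pct = dp, dv_pct = dv))
}
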