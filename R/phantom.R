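# Parametric pharyngeal phantoms.
#
# The airway column from choana (z = 0 mm) to the bottom of the hypopharynx
# (z = L mm) is idealized as an axisymmetric tube with a smoothly varying
# circular cross-section A(z). Three anatomical regions (nasopharynx,
# oropharynx, hypopharynx) are stacked axially; the two landmark planes that
# separate them in imaging studies are abstracted to fixed axial positions.
# The profile is a per-region cubic spline through region-mean areas plus a
# C1 cosine-squared constriction bump whose depth is solved so the global
# minimum slice area equals the prescribed A_min.

REGION_NAMES <- c("nasopharynx", "oropharynx", "hypopharynx")

#' Specify one pharyngeal region
#'
#' @param name one of "nasopharynx", "oropharynx", "hypopharynx"
#' @param length axial extent, mm
#' @param volume target region volume, cm^3
#' @return a `region_spec` list
#' @export
region_spec <- function(name, length, volume) {
  name <- match.arg(name, REGION_NAMES)
  if (!is.numeric(length) || length <= 0) {
    stop("region_spec: length must be > 0 (", name, ")")
  }
  if (!is.numeric(volume) || volume <= 0) {
    stop("region_spec: volume must be > 0 (", name, ")")
  }
  structure(list(name = name, length = length, volume = volume),
            class = "region_spec")
}

#' Specify a complete pharyngeal phantom
#'
#' A phantom is defined by its three stacked regions (nasopharynx at the
#' top), the global minimum cross-sectional area `a_min` with the region and
#' fractional axial position of the constriction, and the area of the
#' hypopharyngeal inlet face where the extraction velocity is applied.
#'
#' @param regions list of three [region_spec()] in superior-to-inferior
#'   order: nasopharynx, oropharynx, hypopharynx
#' @param a_min target minimum cross-sectional area, cm^2
#' @param a_min_region region containing the constriction
#' @param a_min_frac fractional axial position of the constriction within
#'   its region, in \[0, 1\]
#' @param inlet_area cross-sectional area at the bottom of the hypopharynx,
#'   cm^2
#' @param constr_halfwidth half-width of the constriction bump, mm;
#'   default 0.4 x the constriction region's length, floored at 12 mm
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(regions, a_min, a_min_region = "hypopharynx",
                         a_min_frac = 0.5, inlet_area = 2.5,
                         constr_halfwidth = NULL) {
  stopifnot(is.list(regions), length(regions) == 3)
  nm <- vapply(regions, function(r) r$name, character(1))
  if (!identical(nm, REGION_NAMES)) {
    stop("phantom_spec: regions must be nasopharynx, oropharynx, ",
         "hypopharynx in superior-to-inferior order")
  }
  a_min_region <- match.arg(a_min_region, REGION_NAMES)
  if (a_min <= 0) stop("phantom_spec: a_min must be > 0")
  if (inlet_area <= 0) stop("phantom_spec: inlet_area must be > 0")
  if (a_min_frac < 0 || a_min_frac > 1) {
    stop("phantom_spec: a_min_frac must lie in [0, 1]")
  }
  reg_len <- vapply(regions, function(r) r$length, numeric(1))
  if (is.null(constr_halfwidth)) {
    # floor keeps the throat walls from steepening into unphysical cones
    # when a region is short
    constr_halfwidth <- max(12, 0.4 * reg_len[match(a_min_region,
                                                    REGION_NAMES)])
  }
  structure(list(regions = regions, a_min = a_min,
                 a_min_region = a_min_region, a_min_frac = a_min_frac,
                 inlet_area = inlet_area,
                 constr_halfwidth = constr_halfwidth),
            class = "phantom_spec")
}

#' Default region lengths, mm
#'
#' Chosen so that the whole-pharynx mean area V/L of the reference
#' pre-treatment anatomy equals A_min / 0.69 (the reported A_min/A_mean
#' ratio), with a clinically plausible split: a short nasopharynx, a long
#' oropharynx, and an intermediate hypopharynx.
#' @return named numeric vector of lengths, mm
#' @export
default_region_lengths <- function() {
  c(nasopharynx = 18, oropharynx = 62, hypopharynx = 29.31)
}

#' Reference pre-treatment phantom specification
#'
#' Region volumes 5.68 / 20.83 / 8.50 cm^3, A_min 2.21 cm^2 located in the
#' hypopharynx: the cohort-mean pre-treatment anatomy.
#' @param inlet_area inlet face area, cm^2
#' @return a [phantom_spec()]
#' @export
reference_pre_spec <- function(inlet_area = 2.5) {
  len <- default_region_lengths()
  phantom_spec(
    regions = list(
      region_spec("nasopharynx", len[["nasopharynx"]], 5.68),
      region_spec("oropharynx", len[["oropharynx"]], 20.83),
      region_spec("hypopharynx", len[["hypopharynx"]], 8.50)),
    a_min = 2.21, a_min_region = "hypopharynx", a_min_frac = 0.5,
    inlet_area = inlet_area)
}

#' Reference post-treatment phantom specification
#'
#' Region volumes 5.37 / 15.64 / 6.04 cm^3, A_min 1.51 cm^2 relocated to
#' the oropharynx (tongue-base level): the cohort-mean post-treatment
#' anatomy.
#' @param inlet_area inlet face area, cm^2
#' @return a [phantom_spec()]
#' @export
reference_post_spec <- function(inlet_area = 2.5) {
  len <- default_region_lengths()
  phantom_spec(
    regions = list(
      region_spec("nasopharynx", len[["nasopharynx"]], 5.37),
      region_spec("oropharynx", len[["oropharynx"]], 15.64),
      region_spec("hypopharynx", len[["hypopharynx"]], 6.04)),
    a_min = 1.51, a_min_region = "oropharynx", a_min_frac = 0.85,
    inlet_area = inlet_area,
    constr_halfwidth = 0.55 * len[["oropharynx"]])
}

# cos^2 window, C1 at its edges: w(z_c) = 1, w = 0 outside |z - z_c| > h
constriction_window <- function(z, z_c, h) {
  w <- numeric(length(z))
  inside <- abs(z - z_c) < h
  w[inside] <- cos(pi * (z[inside] - z_c) / (2 * h))^2
  w
}

#' Build an axisymmetric airway phantom from a specification
#'
#' Constructs a C1-smooth axial area profile A(z) (mm^2) whose per-region
#' integrals match the specified region volumes within 0.5%, whose global
#' minimum equals `a_min` within 0.5%, and whose area at the inferior end
#' equals `inlet_area` within 0.5%. The base profile is a shape-preserving
#' cubic interpolant (Fritsch-Carlson) through region-mean areas at region
#' midpoints — chosen over an ordinary cubic spline because it cannot
#' overshoot between controls, which would silently relocate the area
#' minimum on strongly contrasting anatomies; a cosine-squared
#' constriction bump is superposed and its depth solved by bisection;
#' region volumes are then re-normalized and the two steps iterated to
#' joint convergence.
#'
#' @param spec a [phantom_spec()]
#' @param axial_resolution samples per mm for the stored profile (>= 1)
#' @return an `airway_phantom` with fields `z` (mm), `radius` (mm), `area`
#'   (mm^2), `boundaries` (mm), plus smooth evaluator closures `area_fun`,
#'   `radius_fun`, `dradius_fun` used by the mesher
#' @export
build_phantom <- function(spec, axial_resolution = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (axial_resolution < 1) {
    stop("build_phantom: axial_resolution must be >= 1 per mm")
  }
  reg_len <- vapply(spec$regions, function(r) r$length, numeric(1))
  reg_vol_mm3 <- cm3_to_mm3(vapply(spec$regions, function(r) r$volume,
                                   numeric(1)))
  L <- sum(reg_len)
  b1 <- reg_len[1]
  b2 <- reg_len[1] + reg_len[2]
  reg_start <- c(0, b1, b2)
  reg_end <- c(b1, b2, L)
  ireg <- match(spec$a_min_region, REGION_NAMES)
  z_c <- reg_start[ireg] + spec$a_min_frac * reg_len[ireg]
  # keep the bump window inside the column so the inlet/choana areas hold
  h <- min(spec$constr_halfwidth, max(z_c - 0, 1), max(L - z_c, 1))
  a_min_mm2 <- cm2_to_mm2(spec$a_min)
  inlet_mm2 <- cm2_to_mm2(spec$inlet_area)

  # spline knots: choana, three region midpoints, inlet end
  zk <- c(0, reg_start + reg_len / 2, L)
  ctrl <- c(reg_vol_mm3[1] / reg_len[1], reg_vol_mm3 / reg_len, inlet_mm2)

  nfine <- max(2001L, as.integer(L * 8) + 1L)
  zfine <- seq(0, L, length.out = nfine)
  wfine <- constriction_window(zfine, z_c, h)
  depth <- 0
  base_fun <- NULL

  area_of <- function(base, D) base * (1 - D * wfine)
  region_idx <- findInterval(zfine, c(b1, b2)) + 1L

  solve_depth <- function(basef) {
    base <- basef(zfine)
    if (any(base <= 0)) {
      stop("build_phantom: infeasible spec: base area profile is not ",
           "positive; region volumes/lengths or inlet area are ",
           "inconsistent")
    }
    f <- function(D) min(area_of(base, D)) - a_min_mm2
    if (f(0) < -1e-9 * a_min_mm2) {
      stop("build_phantom: infeasible spec: a_min (", spec$a_min,
           " cm^2) exceeds the area the profile attains away from the ",
           "constriction (min ", signif(mm2_to_cm2(min(base)), 4),
           " cm^2); a_min would not be the global minimum")
    }
    if (f(0) <= 0) return(0)
    upper <- 1 - 1e-9
    if (f(upper) > 0) {
      stop("build_phantom: infeasible spec: constriction cannot reach ",
           "a_min within its window")
    }
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }

  for (iter in seq_len(60)) {
    # shape-preserving C1 interpolant: no overshoot between region
    # controls, so the base minimum equals the smallest control value and
    # the feasibility guarantees of the sampler hold pointwise
    base_fun <- stats::splinefun(zk, ctrl, method = "monoH.FC")
    depth <- solve_depth(base_fun)
    area <- area_of(base_fun(zfine), depth)
    # per-region volumes by trapezoid on the fine grid, exact boundary cuts
    vols <- numeric(3)
    for (k in 1:3) {
      zs <- seq(reg_start[k], reg_end[k], length.out = 801)
      as <- base_fun(zs) * (1 - depth * constriction_window(zs, z_c, h))
      vols[k] <- sum((as[-1] + as[-length(as)]) / 2 * diff(zs))
    }
    fac <- reg_vol_mm3 / vols
    if (max(abs(fac - 1)) < 5e-5) break
    ctrl[1] <- ctrl[1] * fac[1]
    ctrl[2] <- ctrl[2] * fac[1]
    ctrl[3] <- ctrl[3] * fac[2]
    ctrl[4] <- ctrl[4] * fac[3]
    # endpoint control stays pinned at the inlet area; interior controls
    # may not sink below a_min or the constriction stops being the global
    # minimum (the final volume check below catches genuine conflicts)
    ctrl[1:4] <- pmax(ctrl[1:4], 1.02 * a_min_mm2)
  }
  vol_err <- max(abs(fac - 1))
  if (vol_err > 5e-3) {
    stop("build_phantom: infeasible spec: region volumes cannot be ",
         "matched (worst error ", signif(100 * vol_err, 3),
         "%) while a_min stays the global minimum")
  }

  w_fun <- function(z) constriction_window(z, z_c, h)
  dfinal <- depth
  bf <- base_fun
  area_fun <- function(z) bf(z) * (1 - dfinal * w_fun(z))
  darea_fun <- function(z) {
    dw <- numeric(length(z))
    inside <- abs(z - z_c) < h
    x <- pi * (z[inside] - z_c) / (2 * h)
    dw[inside] <- -sin(2 * x) * pi / (2 * h)
    bf(z, deriv = 1) * (1 - dfinal * w_fun(z)) - bf(z) * dfinal * dw
  }
  radius_fun <- function(z) sqrt(pmax(area_fun(z), 1e-12) / pi)
  dradius_fun <- function(z) darea_fun(z) / (2 * pi * radius_fun(z))

  z <- seq(0, L, by = 1 / axial_resolution)
  if (z[length(z)] < L) z <- c(z, L)
  area <- area_fun(z)
  if (any(area <= 0)) {
    stop("build_phantom: infeasible spec: non-positive cross-section area")
  }
  structure(list(
    z = z, radius = radius_fun(z), area = area,
    boundaries = c(nasopharynx_oropharynx = unname(b1),
                   oropharynx_hypopharynx = unname(b2)),
    length = L, spec = spec, constriction = c(z = z_c, halfwidth = h),
    depth = depth,
    area_fun = area_fun, radius_fun = radius_fun, dradius_fun = dradius_fun
  ), class = "airway_phantom")
}

#' Straight-tube phantom
#'
#' Constant-radius tube, used for analytic Hagen-Poiseuille validation.
#' Region boundaries split the length in three equal parts.
#'
#' @param radius_mm tube radius, mm
#' @param length_mm tube length, mm
#' @return an `airway_phantom`
#' @export
tube_phantom <- function(radius_mm, length_mm) {
  stopifnot(radius_mm > 0, length_mm > 0)
  area_fun <- function(z) rep(pi * radius_mm^2, length(z))
  radius_fun <- function(z) rep(radius_mm, length(z))
  dradius_fun <- function(z) rep(0, length(z))
  z <- seq(0, length_mm, length.out = 257)
  structure(list(
    z = z, radius = radius_fun(z), area = area_fun(z),
    boundaries = c(nasopharynx_oropharynx = length_mm / 3,
                   oropharynx_hypopharynx = 2 * length_mm / 3),
    length = length_mm, spec = NULL,
    constriction = c(z = NA_real_, halfwidth = NA_real_), depth = 0,
    area_fun = area_fun, radius_fun = radius_fun, dradius_fun = dradius_fun
  ), class = "airway_phantom")
}

#' Phantom from an explicit smooth area profile
#'
#' Builds an `airway_phantom` from samples of A(z); the profile is
#' interpolated with a natural cubic spline. Useful for bespoke test
#' geometries such as venturi tubes.
#'
#' @param z axial samples, mm, increasing from 0
#' @param area_mm2 cross-sectional areas at `z`, mm^2
#' @param boundaries the two region boundary positions, mm; default equal
#'   thirds
#' @return an `airway_phantom`
#' @export
profile_phantom <- function(z, area_mm2, boundaries = NULL) {
  stopifnot(length(z) == length(area_mm2), all(diff(z) > 0),
            all(area_mm2 > 0), z[1] == 0)
  L <- z[length(z)]
  if (is.null(boundaries)) boundaries <- c(L / 3, 2 * L / 3)
  af <- stats::splinefun(z, area_mm2, method = "natural")
  area_fun <- function(zz) af(zz)
  radius_fun <- function(zz) sqrt(pmax(af(zz), 1e-12) / pi)
  dradius_fun <- function(zz) af(zz, deriv = 1) / (2 * pi * radius_fun(zz))
  zs <- seq(0, L, length.out = 513)
  structure(list(
    z = zs, radius = radius_fun(zs), area = area_fun(zs),
    boundaries = c(nasopharynx_oropharynx = boundaries[1],
                   oropharynx_hypopharynx = boundaries[2]),
    length = L, spec = NULL,
    constriction = c(z = NA_real_, halfwidth = NA_real_), depth = 0,
    area_fun = area_fun, radius_fun = radius_fun, dradius_fun = dradius_fun
  ), class = "airway_phantom")
}

#' Analytic phantom volume, cm^3
#'
#' High-resolution quadrature of the area profile; the oracle against which
#' voxelized and meshed volumes are checked.
#' @param phantom an `airway_phantom`
#' @param from,to axial bounds, mm; defaults to the whole column
#' @return volume, cm^3
#' @export
phantom_volume <- function(phantom, from = 0, to = phantom$length) {
  v <- stats::integrate(phantom$area_fun, from, to, subdivisions = 2000L,
                        rel.tol = 1e-9)$value
  mm3_to_cm3(v)
}

#' Per-region phantom volumes, cm^3
#' @param phantom an `airway_phantom`
#' @return named numeric vector (nasopharynx, oropharynx, hypopharynx)
#' @export
phantom_region_volumes <- function(phantom) {
  b <- phantom$boundaries
  c(nasopharynx = phantom_volume(phantom, 0, b[[1]]),
    oropharynx = phantom_volume(phantom, b[[1]], b[[2]]),
    hypopharynx = phantom_volume(phantom, b[[2]], phantom$length))
}

#' @export
print.airway_phantom <- function(x, ...) {
  vols <- phantom_region_volumes(x)
  cat("Axisymmetric airway phantom\n")
  cat(sprintf("  length: %.1f mm, boundaries at %.1f / %.1f mm\n",
              x$length, x$boundaries[[1]], x$boundaries[[2]]))
  cat(sprintf("  region volumes (cm^3): Na %.2f, Or %.2f, Hy %.2f\n",
              vols[[1]], vols[[2]], vols[[3]]))
  cat(sprintf("  A_min: %.3f cm^2 at z = %.1f mm\n",
              mm2_to_cm2(min(x$area)), x$z[which.min(x$area)]))
  invisible(x)
}
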