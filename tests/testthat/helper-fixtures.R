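# Shared fixtures: everything is generated in code, nothing on disk.

air_still <- function() fluid_props(gravity_enabled = FALSE)

coarse_numerics <- function(max_iter = 2000, ...) {
  numerics_config(max_iter = max_iter, ...)
}

# straight tube sized for a Reynolds-100, L/D = 30 Poiseuille benchmark
poiseuille_case <- function(radius_mm = 4, length_mm = 240, re = 100,
                            fluid = air_still()) {
  v <- re * fluid$viscosity / (fluid$density * 2 * mm_to_m_(radius_mm))
  q_mlps <- v * pi * mm_to_m_(radius_mm)^2 * 1e6
  list(phantom = tube_phantom(radius_mm, length_mm), q_mlps = q_mlps,
       area_cm2 = pi * radius_mm^2 / 100, fluid = fluid,
       dp_analytic = function(length_m) {
         8 * fluid$viscosity * length_m * (q_mlps / 1e6) /
           (pi * mm_to_m_(radius_mm)^4)
       })
}

mm_to_m_ <- function(x) x / 1000

# smooth venturi with an off-centre throat (asymmetric on purpose)
venturi_phantom <- function(center = 50, depth = 140, width = 12) {
  z <- seq(0, 100, by = 1)
  profile_phantom(z, 300 - depth * exp(-((z - center) / width)^2))
}

solve_on <- function(phantom, q_mlps, nz = 120, nr = 16, ext = 0,
                     fluid = air_still(), max_iter = 3000, ...) {
  g <- generate_grid(phantom, nz, nr, extension_mm = ext)
  suppressWarnings(solve_steady(g, boundary_conditions(q_mlps),
                                fluid, coarse_numerics(max_iter, ...)))
}
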