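# fabricate a flow field on a grid from closed-form p/u (for tests that
# need exact fields rather than solver output)
fake_field <- function(grid, p_const = 5, u_const = 1) {
  structure(list(
    u = matrix(u_const, grid$nz + 1, grid$nr),
    v = matrix(0, grid$nz, grid$nr + 1),
    p = matrix(p_const, grid$nz, grid$nr),
    converged = TRUE, oscillatory = FALSE,
    fluid = air_still(), grid = grid, q_peak = 100,
    mass_imbalance = 0), class = "flow_field")
}

test_that("uniform fields sweep to uniform slice quantities", {
  ph <- tube_phantom(5, 60)
  g <- generate_grid(ph, 30, 8)
  pr <- slice_sweep(ph, fake_field(g))
  expect_equal(pr$mean_pressure, rep(5, nrow(pr)))
  expect_equal(pr$mean_velocity, rep(1, nrow(pr)))
  expect_equal(pr$area, rep(pi * 25 / 100, nrow(pr)), tolerance = 1e-9)
  expect_equal(pr$z, c(0:60))
})

test_that("unconverged fields are refused unless forced", {
  ph <- tube_phantom(5, 60)
  g <- generate_grid(ph, 30, 8)
  f <- fake_field(g)
  f$converged <- FALSE
  expect_error(slice_sweep(ph, f), "not converged")
  expect_s3_class(slice_sweep(ph, f, force = TRUE), "data.frame")
})

test_that("Poiseuille slice pressures are linear in the developed region", {
  pc <- poiseuille_case()
  f <- solve_on(pc$phantom, pc$q_mlps, fluid = pc$fluid)
  pr <- slice_sweep(pc$phantom, f)
  dev <- pr[pr$z >= 120 & pr$z <= 216, ]
  fit <- stats::lm(mean_pressure ~ z, data = dev)
  expect_gt(summary(fit)$r.squared, 0.9999)
  # slice-average speed times area reproduces the flow rate everywhere
  q_slice <- dev$mean_velocity * dev$area * 1e2 # m/s * cm^2 -> mL/s
  expect_equal(q_slice / pc$q_mlps, rep(1, nrow(dev)), tolerance = 5e-3)
})

test_that("zero-flow metrics are all zero", {
  ph <- tube_phantom(5, 60)
  g <- generate_grid(ph, 30, 8)
  f <- fake_field(g, p_const = 0, u_const = 0)
  f$q_peak <- 0
  m <- compute_metrics(slice_sweep(ph, f))
  expect_equal(m$dP_max, 0)
  expect_equal(c(m$dP_na, m$dP_or, m$dP_hy), c(0, 0, 0))
  expect_equal(c(m$R_na, m$R_or, m$R_hy), c(0, 0, 0))
})

test_that("A_min ties resolve to the most superior slice", {
  profiles <- data.frame(z = 0:30, area = rep(3, 31),
                         mean_pressure = seq(0, -3, length.out = 31),
                         mean_velocity = rep(1, 31),
                         region = c(rep("nasopharynx", 11),
                                    rep("oropharynx", 10),
                                    rep("hypopharynx", 10)))
  class(profiles) <- c("slice_profiles", "data.frame")
  m <- compute_metrics(profiles, boundaries = c(10, 20), q_mlps = 100)
  expect_equal(m$A_min_z, 0)
})

test_that("metrics recover the built A_min and additive region volumes", {
  for (sp in list(reference_pre_spec(), reference_post_spec())) {
    ph <- build_phantom(sp)
    g <- generate_grid(ph, 100, 12)
    pr <- slice_sweep(ph, fake_field(g))
    m <- compute_metrics(pr)
    expect_equal(m$A_min, sp$a_min, tolerance = 0.01)
    expect_equal(m$V, m$V_na + m$V_or + m$V_hy, tolerance = 5e-3)
    expect_equal(m$V, sum(vapply(sp$regions, function(r) r$volume,
                                 numeric(1))), tolerance = 0.01)
    expect_equal(m$A_mean, m$V / (ph$length / 10), tolerance = 1e-9)
  }
})

test_that("dP_max grows with flow rate on fixed geometry", {
  ph <- venturi_phantom()
  g <- generate_grid(ph, 100, 16, extension_mm = 20)
  dp <- vapply(c(100, 250, 471.24), function(q) {
    f <- suppressWarnings(solve_steady(g, boundary_conditions(q),
                                       air_still(), coarse_numerics()))
    compute_metrics(slice_sweep(ph, f, force = TRUE))$dP_max
  }, numeric(1))
  expect_true(all(diff(dp) > 0))
})

test_that("the minimum-pressure location tracks the constriction region", {
  len <- default_region_lengths()
  mk <- function(region, frac) phantom_spec(
    regions = list(region_spec("nasopharynx", len[[1]], 5.68),
                   region_spec("oropharynx", len[[2]], 20.83),
                   region_spec("hypopharynx", len[[3]], 8.50)),
    a_min = 1.8, a_min_region = region, a_min_frac = frac,
    inlet_area = 2.5)
  out <- lapply(list(c("hypopharynx", 0.5), c("oropharynx", 0.5)),
                function(spec) {
    r <- suppressWarnings(phantom_metrics(
      build_phantom(mk(spec[1], as.numeric(spec[2]))),
      q_peak = 250, nz = 96, nr = 14,
      numerics = coarse_numerics()))
    r$metrics
  })
  expect_equal(out[[1]]$min_pressure_region, "hypopharynx")
  expect_equal(out[[2]]$min_pressure_region, "oropharynx")
  # the minimum moved superiorly with the constriction
  expect_lt(out[[2]]$min_pressure_z, out[[1]]$min_pressure_z)
})
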