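test_that("peak flow closes the half-sine waveform on the tidal volume", {
  expect_equal(peak_flow_rate(0, 4, 1), 0)
  expect_equal(peak_flow_rate(600, 4, 1), 150 * pi)
  wf <- respiratory_waveform(600, 4, 1)
  expect_equal(wf$omega, pi / 2)
  vol <- stats::integrate(function(t) wf$q_peak * sin(wf$omega * t),
                          0, wf$t_insp)$value
  expect_equal(vol, 600, tolerance = 1e-8)
  # a 1:2 I:E ratio shortens inspiration and raises the peak
  wf2 <- respiratory_waveform(600, 4, 1 / 2)
  expect_equal(wf2$t_insp, 4 / 3)
  expect_equal(stats::integrate(function(t) wf2$q_peak *
                                  sin(wf2$omega * t),
                                0, wf2$t_insp)$value, 600,
               tolerance = 1e-8)
  expect_error(peak_flow_rate(600, 0, 1), "period")
})

test_that("inlet velocity is Q/A in SI units", {
  expect_equal(inlet_velocity(0, 2), 0)
  expect_equal(inlet_velocity(471.24, 2), 2.3562, tolerance = 1e-4)
  expect_equal(inlet_velocity(471.24, 1), 2 * inlet_velocity(471.24, 2))
  expect_error(inlet_velocity(100, 0), "positive")
})

test_that("steady solve reproduces Hagen-Poiseuille within 3%", {
  pc <- poiseuille_case()
  f <- solve_on(pc$phantom, pc$q_mlps, fluid = pc$fluid)
  expect_true(f$converged)
  pr <- slice_sweep(pc$phantom, f)
  dpn <- pr$mean_pressure[pr$z == 120] - pr$mean_pressure[pr$z == 216]
  expect_equal(dpn, pc$dp_analytic(0.096), tolerance = 0.03)
  # fully developed centreline velocity tends to 2 x mean
  v_mean <- (pc$q_mlps / 1e6) / (pi * 0.004^2)
  expect_equal(max(f$u), 2 * v_mean, tolerance = 0.02)
})

test_that("converged runs conserve mass at every axial station", {
  pc <- poiseuille_case()
  f <- solve_on(pc$phantom, pc$q_mlps, fluid = pc$fluid)
  expect_lt(f$mass_imbalance, 1e-3)
  fv <- solve_on(venturi_phantom(), 300, ext = 20)
  expect_true(f$converged && fv$converged)
  expect_lt(fv$mass_imbalance, 1e-3)
})

test_that("venturi pressure minimum sits at the throat and exceeds Bernoulli", {
  ph <- venturi_phantom(center = 50)
  fl <- air_still()
  f <- solve_on(ph, 300, ext = 20, fluid = fl)
  pr <- slice_sweep(ph, f)
  expect_lt(abs(pr$z[which.min(pr$mean_pressure)] - 50), 5)
  a_th <- min(ph$area) * 1e-6
  a_in <- ph$area_fun(0) * 1e-6
  q <- 300e-6
  bern <- 0.5 * fl$density * ((q / a_th)^2 - (q / a_in)^2)
  dp <- pr$mean_pressure[1] - min(pr$mean_pressure)
  expect_gt(dp, bern)
})

test_that("pressure reference shifts with outlet pressure, velocities fixed", {
  ph <- venturi_phantom()
  g <- generate_grid(ph, 100, 16, extension_mm = 20)
  f0 <- solve_steady(g, boundary_conditions(300, outlet_pressure = 0),
                     air_still(), coarse_numerics())
  f1 <- solve_steady(g, boundary_conditions(300, outlet_pressure = 10),
                     air_still(), coarse_numerics())
  expect_equal(f1$p, f0$p + 10, tolerance = 1e-10)
  expect_equal(f1$u, f0$u, tolerance = 1e-12)
})

test_that("mirrored geometry with reversed flow matches at low Reynolds", {
  ph <- venturi_phantom(center = 35, width = 10)
  z <- seq(0, 100, by = 1)
  phm <- profile_phantom(z, rev(ph$area_fun(z)))
  dps <- vapply(list(ph, phm), function(p) {
    f <- solve_on(p, 10, nz = 120, nr = 20, max_iter = 4000)
    pr <- slice_sweep(p, f)
    pr$mean_pressure[1] - pr$mean_pressure[nrow(pr)]
  }, numeric(1))
  expect_equal(dps[1], dps[2], tolerance = 0.01)
})

test_that("gravity adds a removable hydrostatic head only", {
  ph <- venturi_phantom()
  g <- generate_grid(ph, 100, 16, extension_mm = 20)
  f0 <- solve_steady(g, boundary_conditions(300), air_still(),
                     coarse_numerics())
  fg <- solve_steady(g, boundary_conditions(300), fluid_props(),
                     coarse_numerics())
  p0 <- slice_sweep(ph, f0)
  pg <- slice_sweep(ph, fg, hydro_correct = TRUE)
  expect_equal(pg$mean_pressure, p0$mean_pressure, tolerance = 1e-4)
  praw <- slice_sweep(ph, fg, hydro_correct = FALSE)
  head <- fluid_props()$density * 9.81 * 0.1
  expect_equal(praw$mean_pressure[nrow(praw)] -
                 pg$mean_pressure[nrow(pg)], head, tolerance = 1e-3)
})

test_that("the laminar-regime guard warns above the Reynolds threshold", {
  ph <- build_phantom(reference_pre_spec())
  g <- generate_grid(ph, 64, 10, extension_mm = 30)
  expect_warning(
    solve_steady(g, boundary_conditions(peak_flow_rate(),
                                        inlet_area = 2.5),
                 fluid_props(), coarse_numerics()),
    "Reynolds")
})

test_that("zero flow returns a quiescent converged field; solves are deterministic", {
  ph <- tube_phantom(5, 60)
  g <- generate_grid(ph, 30, 8)
  f <- solve_steady(g, boundary_conditions(q_peak = 0), air_still(),
                    coarse_numerics())
  expect_true(f$converged)
  expect_true(all(f$u == 0) && all(f$v == 0))
  pc <- poiseuille_case()
  f1 <- solve_on(pc$phantom, pc$q_mlps, fluid = pc$fluid)
  f2 <- solve_on(pc$phantom, pc$q_mlps, fluid = pc$fluid)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$u, f2$u)
})
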