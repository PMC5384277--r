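test_that("constant-radius phantom meshes to an orthogonal grid", {
  g <- generate_grid(tube_phantom(5, 60), nz = 30, nr = 8)
  expect_true(all(g$Rpf == 0) && all(g$Rpc == 0))
  expect_equal(diff(range(g$dz)), 0, tolerance = 1e-15)
  # per-radian annuli reconstruct the full cross-section exactly
  expect_equal(2 * pi * sum(g$ann) * g$Rf[1]^2, pi * g$Rf[1]^2,
               tolerance = 1e-12)
})

test_that("grid volume matches the analytic phantom volume", {
  ph <- build_phantom(reference_pre_spec())
  va <- phantom_volume(ph)
  errs <- vapply(list(c(60, 10), c(120, 20), c(240, 40)), function(res) {
    abs(grid_volume(generate_grid(ph, res[1], res[2])) - va) / va
  }, numeric(1))
  expect_lt(errs[2], 5e-3)      # default-scale resolution
  expect_true(all(diff(errs) < 0))
})

test_that("refinement arithmetic and grading behave", {
  ph <- tube_phantom(5, 60)
  g1 <- generate_grid(ph, 30, 8)
  g2 <- generate_grid(ph, 60, 16)
  expect_equal(g2$nz * g2$nr, 4 * g1$nz * g1$nr)
  expect_equal(max(g2$dz), max(g1$dz) / 2)
  # grading refines toward the wall
  gg <- generate_grid(ph, 30, 8, grading = 1.3)
  d <- diff(gg$etaf)
  expect_true(all(diff(d) < 0))
  expect_equal(gg$etaf[length(gg$etaf)], 1)
  expect_error(generate_grid(ph, 4, 8), "nz")
  expect_error(generate_grid(ph, 30, 8, grading = 0.5), "grading")
})

test_that("outlet extension appends a flagged straight section", {
  ph <- build_phantom(reference_pre_spec())
  g0 <- generate_grid(ph, 100, 12)
  g1 <- generate_grid(ph, 100, 12, extension_mm = 30)
  expect_gt(g1$nz, g0$nz)
  expect_equal(g1$nz_anat, 100)
  expect_gte(g1$extension_mm, 30)
  # wall slope vanishes at the far end of the blend
  expect_equal(g1$Rpf[g1$nz + 1], 0)
  # geometry over the anatomical column is untouched
  expect_equal(g1$Rf[1:101], g0$Rf[1:101])
})

test_that("grid series is monotone in resolution on shared geometry", {
  ph <- tube_phantom(5, 60)
  ser <- grid_series(ph, nz = 40, nr = 8, levels = 5)
  cells <- vapply(ser$grids, function(g) g$nz * g$nr, numeric(1))
  expect_true(all(diff(cells) > 0))
  expect_length(ser$grids, 5)
})

test_that("zero-flow grid independence trivially picks the coarsest level", {
  ph <- tube_phantom(5, 60)
  ser <- grid_series(ph, nz = 24, nr = 6, levels = 3)
  gi <- grid_independence(ser, boundary_conditions(q_peak = 0))
  expect_true(gi$criterion_met)
  expect_equal(gi$chosen, 1)
  expect_true(all(gi$table$dp_pct[1:2] == 0))
})

test_that("Poiseuille pressure drop approaches the closed form under refinement", {
  pc <- poiseuille_case()
  errs <- vapply(c(8, 12, 16), function(nr) {
    f <- solve_on(pc$phantom, pc$q_mlps, nz = 120, nr = nr,
                  fluid = pc$fluid)
    pr <- slice_sweep(pc$phantom, f)
    dpn <- pr$mean_pressure[pr$z == 120] - pr$mean_pressure[pr$z == 216]
    abs(dpn - pc$dp_analytic(0.096)) / pc$dp_analytic(0.096)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.03)
})
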