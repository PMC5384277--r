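test_that("uniform tube spec yields a constant-radius phantom", {
  a <- 2.5 # cm^2 everywhere
  sp <- phantom_spec(
    regions = list(region_spec("nasopharynx", 20, a * 2),
                   region_spec("oropharynx", 20, a * 2),
                   region_spec("hypopharynx", 20, a * 2)),
    a_min = a, inlet_area = a)
  ph <- build_phantom(sp)
  expect_equal(ph$area, rep(250, length(ph$z)), tolerance = 1e-6)
  expect_equal(ph$depth, 0, tolerance = 1e-9)
})

test_that("reference pre-treatment anatomy round-trips its targets", {
  ph <- build_phantom(reference_pre_spec())
  vols <- phantom_region_volumes(ph)
  expect_equal(unname(vols), c(5.68, 20.83, 8.50), tolerance = 5e-3)
  expect_equal(min(ph$area) / 100, 2.21, tolerance = 5e-3)
  expect_equal(ph$area_fun(ph$length) / 100, 2.5, tolerance = 5e-3)
  # the constriction must sit in the declared region
  z_min <- ph$z[which.min(ph$area)]
  expect_gt(z_min, ph$boundaries[[2]])
})

test_that("area solve is homogeneous: doubling volumes doubles A(z)", {
  len <- default_region_lengths()
  mk <- function(f) phantom_spec(
    regions = list(region_spec("nasopharynx", len[[1]], f * 5.68),
                   region_spec("oropharynx", len[[2]], f * 20.83),
                   region_spec("hypopharynx", len[[3]], f * 8.50)),
    a_min = f * 2.21, inlet_area = f * 2.5)
  p1 <- build_phantom(mk(1))
  p2 <- build_phantom(mk(2))
  expect_equal(p2$area, 2 * p1$area, tolerance = 1e-3)
})

test_that("infeasible specs fail with a named constraint", {
  len <- default_region_lengths()
  sp <- phantom_spec(
    regions = list(region_spec("nasopharynx", len[[1]], 5.68),
                   region_spec("oropharynx", len[[2]], 20.83),
                   region_spec("hypopharynx", len[[3]], 8.50)),
    a_min = 5.0, inlet_area = 2.5) # far above every mean area
  expect_error(build_phantom(sp), "infeasible")
  expect_error(region_spec("oropharynx", -1, 5), "length")
  expect_error(phantom_spec(list(region_spec("nasopharynx", 10, 5),
                                 region_spec("oropharynx", 10, 5),
                                 region_spec("hypopharynx", 10, 5)),
                            a_min = 0), "a_min")
})

test_that("volume conservation holds across randomized feasible specs", {
  set.seed(42)
  for (k in 1:5) {
    vols <- c(5.68, 20.83, 8.50) * runif(3, 0.7, 1.3)
    lens <- c(18, 62, 29.31) * runif(3, 0.85, 1.15)
    a_min <- 0.6 * min(10 * vols / lens)
    sp <- phantom_spec(
      regions = list(region_spec("nasopharynx", lens[1], vols[1]),
                     region_spec("oropharynx", lens[2], vols[2]),
                     region_spec("hypopharynx", lens[3], vols[3])),
      a_min = a_min, a_min_region = sample(c("oropharynx",
                                             "hypopharynx"), 1),
      inlet_area = max(2.5, 1.3 * a_min))
    ph <- build_phantom(sp, axial_resolution = 4)
    expect_equal(unname(phantom_region_volumes(ph)), vols,
                 tolerance = 5e-3)
    expect_equal(min(ph$area) / 100, a_min, tolerance = 5e-3)
    expect_true(all(ph$radius > 0))
  }
})
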