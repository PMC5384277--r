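test_that("all-tissue volume segments to nothing, with a warning", {
  vol <- structure(list(hu = array(40, c(6, 6, 6)), voxel_mm = 1,
                        origin = c(0, 0, 0)), class = "voxel_volume")
  expect_warning(seg <- segment_hu(vol), "zero")
  expect_equal(seg$volume_cm3, 0)
  expect_false(any(seg$mask))
})

test_that("straight tube segments to its analytic volume within 2%", {
  tb <- tube_phantom(5, 60)
  seg <- voxelize_and_segment(tb, voxel_mm = 0.4)
  expect_equal(seg$volume_cm3, pi * 25 * 60 / 1000, tolerance = 0.02)
})

test_that("the HU window selects air voxels only", {
  ph <- build_phantom(reference_pre_spec())
  vol <- voxelize_phantom(ph, voxel_mm = 0.8)
  seg <- segment_hu(vol, -1024, -480)
  expect_identical(sum(seg$mask), sum(vol$hu == -1000))
  expect_false(any(vol$hu[seg$mask] == 40))
  # shifting the window above air HU excludes everything
  expect_warning(none <- segment_hu(vol, -400, -100), "zero")
  expect_equal(none$volume_cm3, 0)
  expect_error(segment_hu(vol, -100, -400), "lo_hu < hi_hu")
})

test_that("segmented volume converges to the analytic phantom volume", {
  ph <- build_phantom(reference_pre_spec())
  va <- phantom_volume(ph)
  errs <- vapply(c(1.2, 0.6, 0.3), function(vm) {
    abs(voxelize_and_segment(ph, vm)$volume_cm3 - va) / va
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})
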