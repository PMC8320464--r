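test_that("layer generation hits the target solidity and trivial cases", {
  # zero target -> empty grid
  empty <- generate_layer(fiber_layer_spec(12, 0, 100), c(1e-4, 1e-4), 3e-6,
                          seed = 1)
  expect_equal(sum(empty$occupancy), 0)
  expect_equal(solidity(empty), 0)

  lay <- generate_layer(spunbond_spec(0.10), c(1.2e-4, 1.2e-4), 3e-6,
                        seed = 7)
  expect_lt(abs(solidity(lay) - 0.10), 0.01)
  # dims reproduce the requested physical size to voxel rounding
  expect_lt(abs(lay$dims[1] * lay$voxel_size - 1.2e-4), 1.5e-6)
  expect_lt(abs(lay$dims[3] * lay$voxel_size - 250e-6), 1.5e-6)
})

test_that("same seed gives a bit-identical web; different seeds differ", {
  a <- generate_layer(spunbond_spec(0.08), c(1e-4, 1e-4), 3e-6, seed = 11)
  b <- generate_layer(spunbond_spec(0.08), c(1e-4, 1e-4), 3e-6, seed = 11)
  c <- generate_layer(spunbond_spec(0.08), c(1e-4, 1e-4), 3e-6, seed = 12)
  expect_identical(a$occupancy, b$occupancy)
  expect_false(identical(a$occupancy, c$occupancy))
})

test_that("solidity tolerance holds across targets and resolutions", {
  for (tgt in c(0.04, 0.12, 0.25)) {
    lay <- generate_layer(fiber_layer_spec(12, tgt, 120), c(1e-4, 1e-4),
                          3e-6, seed = 3)
    expect_lt(abs(solidity(lay) - tgt), 0.01)
  }
  # doubling resolution moves achieved solidity by < 0.01
  s1 <- solidity(generate_layer(fiber_layer_spec(12, 0.10, 120),
                                c(1.2e-4, 1.2e-4), 4e-6, seed = 5))
  s2 <- solidity(generate_layer(fiber_layer_spec(12, 0.10, 120),
                                c(1.2e-4, 1.2e-4), 2e-6, seed = 5))
  expect_lt(abs(s1 - s2), 0.01)
})

test_that("generation guards: resolution, domain and convergence errors", {
  expect_error(generate_layer(spunbond_spec(0.1), c(1e-4, 1e-4), 5e-6,
                              seed = 1), "resolution")
  expect_error(generate_layer(spunbond_spec(0.1), c(2e-5, 2e-5), 3e-6,
                              seed = 1), "domain")
  expect_error(generate_layer(fiber_layer_spec(12, 0.3, 200), c(1e-4, 1e-4),
                              3e-6, seed = 1, max_fibers = 2), "convergence")
})

test_that("solidity is occupied fraction for constructed grids", {
  h <- 5e-6
  occ <- array(FALSE, c(4, 4, 10))
  expect_equal(solidity(mkstruct(occ, h)), 0)
  occ[] <- TRUE
  expect_equal(solidity(mkstruct(occ, h)), 1)
  occ[] <- FALSE
  occ[, , 1:5] <- TRUE
  expect_equal(solidity(mkstruct(occ, h)), 0.5)
})

test_that("stacking concatenates thickness and records boundaries", {
  sb <- generate_layer(spunbond_spec(0.08), c(1e-4, 1e-4), 3e-6, seed = 2)

  one <- stack_layers(list(sb))
  expect_identical(one$occupancy, sb$occupancy)
  expect_length(one$layer_boundaries, 1)

  # two 250 um spunbond layers give the 0.5 mm Type A media thickness
  # (to voxel rounding)
  two <- stack_layers(list(sb, sb))
  expect_lt(abs(thickness(two) - 0.0005), 2 * 3e-6)
  expect_length(two$layer_boundaries, 2)
  expect_equal(two$layer_boundaries[[2]], c(sb$dims[3] + 1L, 2L * sb$dims[3]))

  # 250 + 470 + 250 um gives the 0.97 mm Type B media thickness
  mid <- generate_layer(fiber_layer_spec(12, 0.08, 470), c(1e-4, 1e-4),
                        3e-6, seed = 3)
  three <- stack_layers(list(sb, mid, sb))
  expect_lt(abs(thickness(three) - 0.00097), 3 * 3e-6)

  other <- generate_layer(spunbond_spec(0.08), c(1.2e-4, 1.2e-4), 3e-6,
                          seed = 2)
  expect_error(stack_layers(list(sb, other)), "shape")
})

test_that("voxel structures round-trip through the text container", {
  lay <- generate_layer(meltblown_spec(0.06), c(2e-5, 2e-5), 0.75e-6,
                        seed = 9)
  path <- tempfile(fileext = ".json")
  write_voxel_structure(lay, path)
  back <- read_voxel_structure(path)
  expect_identical(back$occupancy, lay$occupancy)
  expect_equal(back$voxel_size, lay$voxel_size)
  expect_equal(back$dims, lay$dims)
  unlink(path)
})
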