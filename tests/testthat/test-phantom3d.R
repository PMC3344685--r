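test_that("empty phantom is pure stroma with unit stroma fraction", {
  vol <- build_phantom(phantom_spec(tubule_count = 0, voxel_size = 0.02))
  gt <- true_quantities(vol)
  expect_true(all(vol$labels == 3L))
  expect_identical(unname(gt$vv["stroma"]), 1)
  expect_identical(unname(gt$vv["lumen"]), 0)
  expect_equal(gt$lv, 0)
})

test_that("axis-aligned spanning cylinder matches closed-form vv and lv", {
  # one tubule along z spanning the whole 1 mm block: lumen volume
  # pi r^2 L, centerline length density exactly 1 mm / 1 mm^3
  vol <- build_phantom(phantom_spec(
    block_edge_lengths = c(1, 1, 1), voxel_size = 0.005,
    tubule_count = 1, tubule_lumen_radius = 0.05,
    epithelium_thickness = 0.02, tubule_length = 1,
    orientation = c(0, 0, 1), rng_seed = 3))
  gt <- true_quantities(vol)
  expect_equal(unname(gt$vv["lumen"]), pi * 0.05^2, tolerance = 0.02)
  expect_equal(gt$lv, 1.0, tolerance = 1e-9)
})

test_that("digital ball volume and surface oracles converge to closed forms", {
  vol <- ball_phantom(ball_count = 1, ball_radius = 0.2,
                      shell_thickness = 0.05, voxel_size = 0.004,
                      rng_seed = 2)
  gt <- true_quantities(vol)
  v_true <- 4 / 3 * pi * 0.2^3 / prod(vol$block)
  s_true <- 4 * pi * 0.2^2 / prod(vol$block)
  expect_equal(unname(gt$vv["lumen"]), v_true, tolerance = 0.02)
  # face counting corrected by the 3/2 digitization factor
  expect_equal(gt$sv, s_true, tolerance = 0.02)
})

test_that("label partition always sums to one", {
  for (seed in 1:3) {
    vol <- small_tubule_phantom(seed)
    expect_equal(sum(true_quantities(vol)$vv), 1, tolerance = 1e-9)
  }
})

test_that("phantoms are bit-for-bit reproducible under a seed", {
  spec <- phantom_spec(tubule_count = 5, voxel_size = 0.02, rng_seed = 42,
                       particle_density = c(mast_cell = 50, macrophage = 20))
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$particles, b$particles)
  c <- build_phantom(phantom_spec(tubule_count = 5, voxel_size = 0.02,
                                  rng_seed = 43))
  expect_false(identical(a$labels, c$labels))
})

test_that("particle seeding is Poisson with the requested mean", {
  # stroma-only block of 1.0 x 0.8 x 0.5 = 0.4 mm^3, intensity 200/mm^3
  vol <- build_phantom(phantom_spec(block_edge_lengths = c(1, 0.8, 0.5),
                                    voxel_size = 0.02, tubule_count = 0))
  counts <- vapply(1:500, function(s) {
    nrow(seed_particles(vol, c(mast_cell = 200), rng_seed = s)$particles)
  }, numeric(1))
  # mean 80, SE of the mean sqrt(80/500)
  expect_lt(abs(mean(counts) - 80), 3 * sqrt(80 / 500))
  expect_gt(var(counts) / mean(counts), 0.7)   # Poisson dispersion
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("zero density seeds no particles and classes are independent", {
  vol <- build_phantom(phantom_spec(block_edge_lengths = c(0.6, 0.6, 0.6),
                                    voxel_size = 0.02, tubule_count = 0))
  expect_identical(nrow(seed_particles(vol, c(mast_cell = 0),
                                       rng_seed = 1)$particles), 0L)
  two <- vapply(1:300, function(s) {
    p <- seed_particles(vol, c(mast_cell = 150, macrophage = 150),
                        rng_seed = s)$particles
    c(sum(p$class == "mast_cell"), sum(p$class == "macrophage"))
  }, numeric(2))
  expect_lt(abs(cor(two[1, ], two[2, ])), 0.17)  # ~3/sqrt(300)
})

test_that("particles always lie inside stroma voxels", {
  vol <- small_tubule_phantom(5, voxel = 0.01, count = 8)
  vol <- seed_particles(vol, c(mast_cell = 400), rng_seed = 3)
  p <- vol$particles
  idx <- cbind(floor(p$x / vol$voxel_size) + 1,
               floor(p$y / vol$voxel_size) + 1,
               floor(p$z / vol$voxel_size) + 1)
  expect_true(all(vol$labels[idx] == 3L))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(tubule_lumen_radius = 0.4,
                            epithelium_thickness = 0.2),
               "outer radius")
  expect_error(phantom_spec(voxel_size = 0),
               "voxel_size")
  # over-dense packing: tubule coverage beyond ~95% of the block
  expect_error(build_phantom(phantom_spec(
    tubule_count = 500, tubule_lumen_radius = 0.05,
    epithelium_thickness = 0.02, tubule_length = 2, voxel_size = 0.02)),
    "over-dense")
})
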