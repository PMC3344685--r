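test_that("IUR normals follow the uniform-hemisphere law", {
  normals <- t(vapply(1:10000, function(s)
    sample_iur_plane(rng_seed = s)$normal, numeric(3)))
  nz <- normals[, 3]
  # z-component ~ U(0,1): mean 1/2 within 3 SE
  expect_lt(abs(mean(abs(nz)) - 0.5), 3 * sqrt(1 / 12 / 10000))
  # chi-square goodness of fit on deciles of nz and of the azimuth
  gof <- function(u) {
    obs <- tabulate(pmin(10, floor(u * 10) + 1), nbins = 10)
    stats::chisq.test(obs)$p.value
  }
  expect_gt(gof(nz), 0.01)
  expect_gt(gof((atan2(normals[, 2], normals[, 1]) + pi) / (2 * pi)), 0.01)
})

test_that("offsets are uniform over the block support", {
  u <- vapply(1:5000, function(s) {
    pl <- sample_iur_plane(rng_seed = s)
    corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
    proj <- drop(corners %*% pl$normal) - sum(c(.5, .5, .5) * pl$normal)
    (pl$offset - min(proj)) / (max(proj) - min(proj))
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(u, "punif")$p.value), 0.01)
})

test_that("planes and sections are reproducible under a seed", {
  p1 <- sample_iur_plane(rng_seed = 99)
  p2 <- sample_iur_plane(rng_seed = 99)
  expect_identical(p1$normal, p2$normal)
  expect_identical(p1$offset, p2$offset)
  expect_true(abs(sum(p1$vertical_axis * p1$normal)) < 1e-12)
})

test_that("sections take voxel labels and reject non-intersecting planes", {
  vol <- build_phantom(phantom_spec(tubule_count = 0, voxel_size = 0.02))
  pl <- sample_iur_plane(vol, rng_seed = 5)
  sec <- extract_section(vol, pl)
  expect_true(all(sec$labels %in% c(0L, 3L)))
  expect_gt(sum(sec$labels == 3L), 0)
  far <- section_plane(c(0, 0, 1), offset = 2, block = vol$block)
  expect_error(extract_section(vol, far), "does not intersect")
})

test_that("axial section of a cylinder shows a lumen disc of the right radius", {
  vol <- build_phantom(phantom_spec(
    block_edge_lengths = c(1, 1, 1), voxel_size = 0.005,
    tubule_count = 1, tubule_lumen_radius = 0.08,
    epithelium_thickness = 0.03, tubule_length = 1,
    orientation = c(0, 0, 1), rng_seed = 3))
  pl <- section_plane(c(0, 0, 1), offset = 0, block = vol$block)
  sec <- extract_section(vol, pl)
  lumen_area <- sum(sec$labels == 1L) * sec$pixel_size^2
  expect_equal(lumen_area, pi * 0.08^2, tolerance = 0.05)
})

test_that("a full tiling covers the section exactly once", {
  vol <- small_tubule_phantom(9)
  sec <- extract_section(vol, sample_iur_plane(vol, rng_seed = 11))
  tiles <- systematic_fields(sec, field_edge = 0.22, rng_seed = 2,
                             keep_empty = TRUE)
  # every tissue pixel lands in exactly one tile (no overlap, no gap)
  for (lbl in 1:3) {
    expect_identical(sum(vapply(tiles, function(f) sum(f$labels == lbl),
                                integer(1))),
                     sum(sec$labels == lbl))
  }
})

test_that("tiled in-block pixel area matches the analytic section area", {
  vol <- build_phantom(phantom_spec(tubule_count = 0, voxel_size = 0.004))
  for (s in c(3, 17, 29)) {
    pl <- sample_iur_plane(vol, rng_seed = s)
    sec <- extract_section(vol, pl)
    pix_area <- sum(sec$labels != 0L) * sec$pixel_size^2
    expect_equal(pix_area, plane_block_area(pl), tolerance = 0.01)
  }
})

test_that("systematic fields: count, spread, reproducibility, failure", {
  vol <- small_tubule_phantom(9)
  sec <- extract_section(vol, section_plane(c(0, 0, 1), 0,
                                            block = vol$block))
  f22 <- systematic_fields(sec, 22, field_edge = 0.15, rng_seed = 4)
  expect_length(f22, 22)
  expect_identical(systematic_fields(sec, 22, 0.15, rng_seed = 4)[[7]]$labels,
                   f22[[7]]$labels)
  expect_gt(attr(f22, "n_available"), 22)
  # fields spread across the section, not clustered at one corner
  origins <- t(vapply(f22, function(f) f$origin, numeric(2)))
  expect_gt(diff(range(origins[, 1])), 0.5)
  expect_error(systematic_fields(sec, 5000, field_edge = 0.3, rng_seed = 1),
               "too small")
  expect_length(systematic_fields(sec, 5000, 0.3, rng_seed = 1,
                                  allow_fewer = TRUE),
                attr(systematic_fields(sec, 5000, 0.3, rng_seed = 1,
                                       allow_fewer = TRUE), "n_taken"))
})

test_that("disector stacks validate height and keep particle bookkeeping", {
  vol <- build_phantom(phantom_spec(tubule_count = 0, voxel_size = 0.02))
  pl <- section_plane(c(0, 0, 1), offset = -0.2, block = vol$block)
  expect_error(make_disector(vol, pl, 0), "h must be > 0")
  expect_error(make_disector(vol, pl, 5), "exceeds")
  stk0 <- make_disector(vol, pl, 0.1)
  expect_identical(nrow(stk0$particles), 0L)

  # particle exactly on the look-up plane is present but excluded
  h <- 0.1
  vol$particles <- data.frame(class = "mast_cell", x = 0.5, y = 0.5,
                              z = (0.5 - 0.2) + h,
                              stringsAsFactors = FALSE)
  stk <- make_disector(vol, pl, h)
  expect_identical(nrow(stk$particles), 1L)
  expect_false(stk$particles$inside[1])
  expect_equal(stk$particles$height[1], h)
  # nudged just below the look-up plane it is counted
  vol$particles$z <- vol$particles$z - 1e-6
  stk2 <- make_disector(vol, pl, h)
  expect_true(stk2$particles$inside[1])
})
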