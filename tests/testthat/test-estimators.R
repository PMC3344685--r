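test_that("organ volume follows the unit specific-gravity rule", {
  expect_identical(volume_from_weight(423.08), 423.08)
  expect_identical(volume_from_weight(87.60), 87.60)
  expect_identical(volume_from_weight(0), 0)
  expect_error(volume_from_weight(-1), "nonnegative")
})

test_that("area fractions pool by ratio of sums", {
  expect_identical(vv_area_fraction(uniform_field(1L), "lumen"), 1)
  half <- make_field(matrix(c(2L, 3L), 10, 10))  # alternating columns
  expect_identical(vv_area_fraction(half, "epithelium"), 0.5)
  # ratio-of-sums: a big stroma field and a small lumen field
  big <- uniform_field(3L, n = 30)
  small <- uniform_field(1L, n = 10)
  expect_equal(vv_area_fraction(list(big, small), "lumen"),
               100 / (900 + 100))
  empty <- uniform_field(0L)
  expect_error(vv_area_fraction(empty, "lumen"), "no tissue")
})

test_that("absolute volumes follow V = Vv * Vt / 100", {
  expect_equal(absolute_volume(19.49, 260.24), 50.720776)
  expect_lt(abs(absolute_volume(19.49, 260.24) - 50.74) / 50.74, 0.005)
  expect_identical(absolute_volume(0, 123), 0)
  expect_identical(absolute_volume(100, 123), 123)
  expect_error(absolute_volume(101, 1), "0, 100")
})

test_that("profile counting obeys the forbidden-line rule", {
  ps <- 0.01
  lab <- matrix(3L, 40, 40)
  disc <- function(lab, cx, cy, r) {
    d <- sqrt(outer((1:40) - cx, rep(1, 40))^2 +
                outer(rep(1, 40), (1:40) - cy)^2)
    lab[d <= r + 2] <- 2L
    lab[d <= r] <- 1L
    lab
  }
  empty <- make_field(matrix(3L, 40, 40), ps)
  fr <- counting_frame(c(0.10, 0.10), 0.20, 0.20)  # pixels 11..30
  expect_identical(profile_count(empty, fr), 0L)
  # profile well inside the frame
  inside <- make_field(disc(lab, 20, 20, 4), ps)
  expect_identical(profile_count(inside, fr), 1L)
  # profile overlapping the left (forbidden) edge is not counted
  left <- make_field(disc(lab, 10, 20, 4), ps)
  expect_identical(profile_count(left, fr), 0L)
  # profile overlapping the right (inclusion) edge is counted
  right <- make_field(disc(lab, 30, 20, 4), ps)
  expect_identical(profile_count(right, fr), 1L)
  # profile overlapping the lower (forbidden) edge is not counted
  lower <- make_field(disc(lab, 20, 10, 4), ps)
  expect_identical(profile_count(lower, fr), 0L)
  # the recognition threshold suppresses sub-threshold lumina
  expect_identical(profile_count(inside, fr,
                                 min_lumen_area = pi * (10 * ps)^2), 0L)
})

test_that("a contiguous frame tiling counts every profile exactly once", {
  for (seed in 1:4) {
    f <- blob_field(n = 200, n_blobs = 20, seed = seed)
    truth <- count_lumen_components_oracle(f)
    total <- 0L
    for (i0 in seq(1, 200, 50)) for (j0 in seq(1, 200, 50)) {
      fr <- counting_frame(c((i0 - 1) * f$pixel_size,
                             (j0 - 1) * f$pixel_size), 0.5, 0.5)
      total <- total + profile_count(f, fr)
    }
    expect_identical(total, truth)
  }
})

test_that("length density doubles the profile density", {
  expect_identical(lv_from_qa(13.55), 27.10)
  expect_identical(lv_from_qa(0), 0)
  expect_error(lv_from_qa(-1), "nonnegative")
})

test_that("total length honors the reporting scale", {
  expect_identical(total_length(2, 10), 20)
  l93 <- total_length(19.10, 423.08, paper_scale = TRUE)
  expect_lt(abs(l93 - 8.07) / 8.07, 0.005)
  l63 <- total_length(20.40, 231.00, paper_scale = TRUE)
  expect_lt(abs(l63 - 4.70) / 4.70, 0.005)
  expect_identical(total_length(1, 1000, paper_scale = TRUE),
                   total_length(1, 1000) / 1000)
})

test_that("cycloid grids tile the field with bounded arcs", {
  g <- cycloid_grid(1, 0.6, arc_radius = 0.05)
  expect_gt(g$total_length, 0)
  for (arc in g$arcs) {
    expect_true(all(arc$x >= 0 & arc$x <= 1))
    expect_true(all(arc$y >= 0 & arc$y <= 0.6))
  }
  # doubling the row density roughly doubles the test line length
  g2 <- cycloid_grid(1, 0.6, arc_radius = 0.05, spacing = 0.075)
  expect_equal(g2$total_length / g$total_length, 2, tolerance = 0.25)
})

test_that("cycloid intercepts count transversal boundary crossings", {
  ps <- 0.005
  r <- 0.05
  # vertical lumen|epithelium boundary at x = 0.15: a single arch's
  # horizontal coordinate is monotone, so it crosses exactly once
  n <- ceiling(2 * pi * r / ps) + 2
  m <- 2 * ceiling(2 * r / ps)
  lab <- matrix(2L, n, m)
  lab[seq_len(floor(0.15 / ps)), ] <- 1L
  f <- make_field(lab, ps)
  g <- cycloid_grid(2 * pi * r * 0.999, m * ps, arc_radius = r,
                    spacing = 10, step = 0.75 * ps)
  expect_identical(length(g$arcs), 1L)
  expect_identical(cycloid_intercepts(f, g), 1L)
  none <- make_field(matrix(2L, n, m), ps)
  expect_identical(cycloid_intercepts(none, g), 0L)
})

test_that("surface density follows Sv = 2I / L_T", {
  expect_identical(sv_from_intercepts(0, 10), 0)
  expect_identical(sv_from_intercepts(25, 10), 5)
  expect_identical(sv_from_intercepts(25, 20, reference_area_fraction = 0.5),
                   5)
  expect_error(sv_from_intercepts(1, 0), "zero")
})

test_that("total surface modes differ by exactly 100x", {
  expect_identical(epithelial_surface(0, 100), 0)
  expect_identical(epithelial_surface(2, 100, mode = "standard"),
                   100 * epithelial_surface(2, 100, mode = "paper"))
})

test_that("the disector counts points once and only once", {
  vol <- build_phantom(phantom_spec(block_edge_lengths = c(0.6, 0.6, 0.6),
                                    voxel_size = 0.01, tubule_count = 0))
  vol <- seed_particles(vol, c(mast_cell = 1200), rng_seed = 8)
  n_true <- nrow(vol$particles)
  expect_gt(n_true, 100)
  h <- 0.12
  total <- 0L
  vols <- 0
  for (k in 0:4) {
    pl <- section_plane(c(0, 0, 1), offset = -0.3 + k * h,
                        block = vol$block)
    stk <- make_disector(vol, pl, h)
    nv <- nv_optical_disector(stk, "mast_cell")
    total <- total + attr(nv, "count")
    vols <- vols + attr(nv, "volume")
  }
  expect_identical(total, n_true)          # exact conservation
  expect_equal(vols, 0.6^3, tolerance = 0.01)
  expect_identical(
    attr(nv_optical_disector(stk, "macrophage"), "count"), 0L)
})

test_that("estimate records reproduce their derived quantities exactly", {
  rec <- build_estimate_record(
    "A1", fresh_weight_mg = 423.08, body_weight_g = 3456,
    compartment_areas = c(lumen = 4, epithelium = 3.9, stroma = 2.1),
    profile_counts = c(count = 120, area = 10),
    intercepts = c(count = 300, length = 250),
    disector = list(mast_cell = list(count = 30, volume = 0.2),
                    macrophage = list(count = 10, volume = 0.2)))
  expect_equal(rec$relative_weight, 423.08 / 3456 * 100)
  expect_equal(rec$vt, 423.08)
  expect_equal(rec$v_lumen + rec$v_epithelium + rec$v_stroma, rec$vt,
               tolerance = 1e-9)
  expect_equal(rec$lv, 2 * 120 / 10)
  expect_equal(rec$l_total, rec$lv * rec$vt / 1000)
  expect_equal(rec$sv, 2 * 300 / 250)
  expect_equal(rec$s_total, rec$sv * rec$vt / 100)
  expect_equal(rec$nv_mast_cell, 150)
  expect_error(build_estimate_record(
    "A2", 100, 300, compartment_areas = c(lumen = 1),
    profile_counts = c(count = 1, area = 1),
    intercepts = c(count = 1, length = 1), disector = list()),
    "incomplete")
})

test_that("estimate records round-trip through CSV unchanged", {
  rec <- build_estimate_record(
    "A1", 100, 300,
    compartment_areas = c(lumen = 1, epithelium = 2, stroma = 1),
    profile_counts = c(count = 10, area = 2),
    intercepts = c(count = 20, length = 30),
    disector = list(mast_cell = list(count = 3, volume = 0.1)))
  path <- tempfile(fileext = ".csv")
  write_estimate_records(rec, path)
  back <- read_estimate_records(path)
  expect_equal(back$lv, rec$lv)
  expect_equal(back$s_total, rec$s_total)
  expect_identical(back$animal_id, "A1")
  expect_true(file.exists(paste0(path, ".json")))
})
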