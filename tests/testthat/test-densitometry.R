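test_that("optical density follows the Beer-Lambert white calibration", {
  expect_equal(od_map(255, 255), 0)
  expect_equal(od_map(25.5, 255), 1)
  m <- matrix(c(255, 25.5, 2.55, 255), 2, 2)
  expect_equal(od_map(m, 255), matrix(c(0, 1, 2, 0), 2, 2))
  # halving transmittance adds log10(2) everywhere
  expect_equal(od_map(m / 2, 255) - od_map(m, 255),
               matrix(log10(2), 2, 2), tolerance = 1e-12)
  # near-opaque pixels are capped (16-bit reference exceeds the cap)
  expect_equal(od_map(0, 65535, ceiling = 3), 3)
  expect_error(od_map(10, 0), "positive")
})

test_that("integrated OD sums the rectangle", {
  expect_equal(integrated_od(matrix(255, 10, 10), 255), 0)
  expect_equal(integrated_od(matrix(25.5, 10, 10), 255), 100)
})

test_that("IOD is scale equivariant and monotone in transmittance", {
  set.seed(4)
  px <- matrix(runif(400, 30, 250), 20, 20)
  expect_equal(integrated_od(px, 255), integrated_od(2.5 * px, 2.5 * 255),
               tolerance = 1e-12)
  # pixel-wise: brighter image, strictly smaller IOD
  expect_gt(integrated_od(px * 0.8, 255), integrated_od(px, 255))
})

test_that("rendered nuclei darken the background deterministically", {
  img <- render_nuclei_image(width = 128, height = 128, n_nuclei = 10,
                             transmittance = 0.3, rng_seed = 6)
  img2 <- render_nuclei_image(width = 128, height = 128, n_nuclei = 10,
                              transmittance = 0.3, rng_seed = 6)
  expect_identical(img$pixels, img2$pixels)
  expect_identical(nrow(img$centers), 10L)
  expect_lt(min(img$pixels), 0.6 * img$incident)
  expect_identical(max(img$pixels), img$incident)
})

test_that("nucleus sampling is exact, seeded and guarded", {
  imgs <- list(
    A = render_nuclei_image(256, 256, n_nuclei = 60, transmittance = 0.3,
                            rng_seed = 1),
    B = render_nuclei_image(256, 256, n_nuclei = 60, transmittance = 0.6,
                            rng_seed = 2))
  rois <- sample_nuclei(imgs, n_per_group = 50, rng_seed = 3)
  expect_length(rois, 100)
  expect_identical(vapply(rois, function(r) r$group, character(1)),
                   rep(c("A", "B"), each = 50))
  expect_identical(dim(rois[[1]]$pixels), c(16L, 16L))
  rois2 <- sample_nuclei(imgs, n_per_group = 50, rng_seed = 3)
  expect_identical(rois[[17]]$pixels, rois2[[17]]$pixels)
  expect_error(sample_nuclei(imgs, n_per_group = 100, rng_seed = 1),
               "fewer")
})

test_that("groups with doubled transmittance have lower mean IOD", {
  hits <- 0
  for (s in 1:20) {
    imgs <- list(
      dark = render_nuclei_image(192, 192, n_nuclei = 25,
                                 transmittance = 0.35, rng_seed = 2 * s),
      pale = render_nuclei_image(192, 192, n_nuclei = 25,
                                 transmittance = 0.70,
                                 rng_seed = 2 * s + 1))
    rois <- sample_nuclei(imgs, n_per_group = 20, rng_seed = s)
    tab <- iod_group_summary(rois)
    hits <- hits + (tab$mean_iod[tab$group == "pale"] <
                      tab$mean_iod[tab$group == "dark"])
  }
  expect_equal(hits, 20)
})
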