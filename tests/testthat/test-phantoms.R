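test_that("annulus ground truth follows from the geometry", {
  sp <- phantom_spec(plant_type = "hollow",
                     outer_semi_axes = c(300, 300),
                     inner_semi_axes = c(240, 240),
                     px_per_mm = 100, noise_sd = 4)
  ph <- make_phantom(sp, 1)
  expect_equal(ph$truth$true_rind_thickness, 0.60, tolerance = 1e-3)
  expect_equal(ph$truth$true_major_d, 6.00)
  expect_equal(ph$truth$true_minor_d, 6.00)
  expect_equal(ph$truth$true_whole_area, pi * 3^2, tolerance = 1e-10)
  expect_equal(ph$truth$true_bundle_count, 0)
})

test_that("ellipse major axis ground truth is rotation-invariant", {
  for (rot in c(0, 37, 90, 142)) {
    sp <- phantom_spec(plant_type = "hollow",
                       outer_semi_axes = c(300, 200),
                       inner_semi_axes = c(250, 150),
                       rotation = rot, px_per_mm = 100)
    ph <- make_phantom(sp, 5)
    expect_equal(ph$truth$true_major_d, 6.00)
    expect_equal(ph$truth$true_minor_d, 4.00)
  }
})

test_that("phantom generation is a pure function of (spec, seed)", {
  sp <- small_maize_spec(n_bundles = 8, speck_count = 5)
  a <- make_phantom(sp, 99)
  b <- make_phantom(sp, 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_equal(a$truth$true_bundle_centers, b$truth$true_bundle_centers)
  c <- make_phantom(sp, 100)
  expect_false(identical(a$image$pixels, c$image$pixels))
  # generation must not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(make_phantom(sp, 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("rasterized region areas match the analytic ellipse areas within 2%", {
  sp <- phantom_spec(plant_type = "pith-filled",
                     outer_semi_axes = c(220, 180),
                     inner_semi_axes = c(170, 130),
                     rotation = 33, noise_sd = 0, px_per_mm = 100)
  ph <- make_phantom(sp, 2)
  g <- to_grayscale(ph$image)$pixels
  rind_px <- sum(g == sp$rind_intensity)
  pith_px <- sum(g == sp$pith_intensity)
  expect_lt(abs(rind_px - pi * (220 * 180 - 170 * 130)) / (pi * (220 * 180 - 170 * 130)), 0.02)
  expect_lt(abs(pith_px - pi * 170 * 130) / (pi * 170 * 130), 0.02)
})

test_that("planted bundles respect the minimum separation and stay in the pith", {
  sp <- small_maize_spec(n_bundles = 15)
  ph <- make_phantom(sp, 7)
  ctrs <- ph$truth$true_bundle_centers
  expect_equal(nrow(ctrs), 15)
  d <- as.matrix(dist(ctrs))
  diag(d) <- Inf
  expect_gte(min(d), sp$bundle_min_separation)
  # all centers strictly inside the inner ellipse
  ctr <- c((dim(ph$image$pixels)[2] - 1) / 2, (dim(ph$image$pixels)[1] - 1) / 2)
  phi <- sp$rotation * pi / 180
  dx <- ctrs[, 1] - ctr[1]; dy <- ctrs[, 2] - ctr[2]
  u <- (dx * cos(phi) + dy * sin(phi)) / sp$inner_semi_axes[1]
  v <- (-dx * sin(phi) + dy * cos(phi)) / sp$inner_semi_axes[2]
  expect_true(all(u^2 + v^2 < 1))
})

test_that("invalid phantom specs are rejected with the violated constraint named", {
  expect_error(phantom_spec(outer_semi_axes = c(100, 120)), "a >= b")
  expect_error(phantom_spec(inner_semi_axes = c(400, 200)), "a_in < a")
  expect_error(phantom_spec(rind_intensity = 100, pith_intensity = 110,
                            noise_sd = 6), "4 \\* noise_sd")
  expect_error(phantom_spec(plant_type = "hollow", n_bundles = 3), "hollow")
  expect_error(phantom_spec(image_size = c(100, 100)), "margin")
})

test_that("impossible bundle placement raises instead of silently reducing the count", {
  sp <- phantom_spec(plant_type = "pith-filled",
                     outer_semi_axes = c(80, 80), inner_semi_axes = c(40, 40),
                     n_bundles = 60, bundle_radius_range = c(5, 6),
                     bundle_min_separation = 18, px_per_mm = 50)
  expect_error(make_phantom(sp, 1), "failed to place|do not fit")
})

test_that("a zero-jitter batch of one reproduces make_phantom at the derived seed", {
  sp <- small_maize_spec(n_bundles = 5)
  batch <- make_batch(sp, 1, list(), seed = 13)
  direct <- make_phantom(sp, stalkmorph:::derive_seed(13, 1))
  expect_identical(batch[[1]]$image$pixels, direct$image$pixels)
})

test_that("batches are reproducible and jitter spans the requested range", {
  sp <- phantom_spec(plant_type = "hollow",
                     outer_semi_axes = c(120, 100),
                     inner_semi_axes = c(90, 70),
                     noise_sd = 4, px_per_mm = 50)
  b1 <- make_batch(sp, 20, list(scale = c(0.8, 1.2)), seed = 7)
  b2 <- make_batch(sp, 20, list(scale = c(0.8, 1.2)), seed = 7)
  expect_identical(lapply(b1, function(x) x$image$pixels),
                   lapply(b2, function(x) x$image$pixels))
  majors <- vapply(b1, function(x) x$truth$true_major_d, numeric(1))
  base_major <- 2 * 120 / 50
  expect_length(unique(majors), 20)
  expect_true(all(majors >= 0.8 * base_major & majors <= 1.2 * base_major))
  expect_lt(min(majors), 0.9 * base_major)   # jitter actually explores the range
  expect_gt(max(majors), 1.1 * base_major)
  expect_error(make_batch(sp, 5, list(scale = c(1.2, 0.8)), seed = 1), "jitter")
  expect_error(make_batch(sp, 5, list(zoom = c(1, 2)), seed = 1), "unknown jitter")
})

test_that("phantom files round trip through TIFF with a JSON sidecar", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(small_hollow_spec(), 21)
  paths <- write_phantom(ph, dir, "test_phantom")
  img <- read_image(file.path(dir, "test_phantom.tif"), plant_type = "hollow")
  expect_identical(img$pixels, ph$image$pixels)
  truth <- jsonlite::read_json(file.path(dir, "test_phantom.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_major_d, ph$truth$true_major_d)
})
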