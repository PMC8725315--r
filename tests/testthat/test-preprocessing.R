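test_that("grayscale conversion uses the fixed luminance weights", {
  white <- section_image(array(255, c(40, 40, 3)))
  expect_true(all(to_grayscale(white)$pixels == 255L))
  green <- array(0, c(40, 40, 3)); green[, , 2] <- 255
  expect_true(all(to_grayscale(section_image(green))$pixels == 150L))
  # per-pixel oracle on random RGB
  set.seed(3)
  px <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), c(40, 40, 3))
  g <- to_grayscale(section_image(px))$pixels
  oracle <- floor(0.2989 * px[, , 1] + 0.5870 * px[, , 2] + 0.1140 * px[, , 3] + 0.5)
  expect_identical(g, matrix(as.integer(oracle), 40, 40))
  # replicated gray image maps to itself (weights sum to ~1)
  gray <- matrix(sample(0:255, 1600, replace = TRUE), 40, 40)
  expect_identical(to_grayscale(section_image(gray))$pixels, gray)
})

test_that("Otsu equals exhaustive within-class-variance minimization", {
  set.seed(17)
  for (i in 1:20) {
    vals <- as.integer(pmin(255, pmax(0,
      rnorm(64 * 64, sample(60:200, 1), sample(15:70, 1)))))
    if (length(unique(vals)) < 2) next
    counts <- tabulate(vals + 1L, nbins = 256)
    expect_identical(otsu_threshold(counts), otsu_brute_force(vals))
  }
})

test_that("Otsu separates a two-level image exactly, ties broken low", {
  vals <- c(rep(40L, 300), rep(200L, 700))
  g <- structure(list(pixels = matrix(vals[sample(1000)], 25, 40), id = "two"),
                 class = "gray_image")
  m <- binarize_otsu(g)
  expect_equal(m$threshold_used, 40)  # lowest threshold in the flat tie region
  expect_equal(mean(m$pixels), 0.30)
  expect_error(binarize_otsu(structure(
    list(pixels = matrix(7L, 10, 10), id = "flat"), class = "gray_image")),
    "degenerate")
})

test_that("binarization is idempotent on a rendered 0/255 mask", {
  sp <- small_hollow_spec()
  ph <- make_phantom(sp, 9)
  m1 <- binarize_otsu(to_grayscale(ph$image))
  rendered <- section_image((1 - m1$pixels) * 255)  # foreground drawn black
  m2 <- binarize_otsu(to_grayscale(rendered))
  expect_identical(m1$pixels, m2$pixels)
  m3 <- binarize_adaptive(to_grayscale(rendered))
  expect_identical(m1$pixels, m3$pixels)
})

test_that("Otsu recovers the rind ring of a hollow phantom", {
  sp <- small_hollow_spec(rotation = 15, noise_sd = 8)
  ph <- make_phantom(sp, 12)
  m <- binarize_otsu(to_grayscale(ph$image))
  # ground-truth rind raster from the noise-free twin
  sp0 <- sp; sp0$noise_sd <- 0
  g0 <- to_grayscale(make_phantom(sp0, 12)$image)$pixels
  truth <- g0 == sp$rind_intensity
  expect_gte(mean(m$pixels == truth), 0.99)
})

test_that("adaptive thresholding recovers a dark disk on uniform background", {
  side <- 200L
  g <- matrix(200L, side, side)
  truth <- disk_mask(side, c(99.5, 99.5), 30)
  g[truth] <- 50L
  m <- binarize_adaptive(structure(list(pixels = g, id = "disk"),
                                   class = "gray_image"))
  # exact away from a 1-px boundary band
  interior <- disk_mask(side, c(99.5, 99.5), 29)
  exterior <- !disk_mask(side, c(99.5, 99.5), 31)
  expect_true(all(m$pixels[interior]))
  expect_true(!any(m$pixels[exterior]))
})

test_that("window_fraction = 1 approximates global mean thresholding", {
  set.seed(5)
  g <- matrix(sample(c(60L, 190L), 65 * 65, replace = TRUE, prob = c(0.4, 0.6)),
              65, 65)
  m <- binarize_adaptive(structure(list(pixels = g, id = "bi"),
                                   class = "gray_image"),
                         window_fraction = 1, sensitivity = 0.5)
  global <- g <= mean(g) * 0.85
  expect_gte(mean(m$pixels == global), 0.99)
  expect_error(binarize_adaptive(structure(list(pixels = g, id = "bi"),
                                           class = "gray_image"),
                                 window_fraction = 0), "window_fraction")
  expect_error(binarize_adaptive(structure(list(pixels = g, id = "bi"),
                                           class = "gray_image"),
                                 sensitivity = 2), "sensitivity")
})

test_that("adaptive thresholding tolerates a mild illumination gradient", {
  sp <- small_maize_spec(n_bundles = 10, noise_sd = 5)
  ph <- make_phantom(sp, 8)
  m0 <- binarize_adaptive(to_grayscale(ph$image))
  shaded <- ph$image
  H <- dim(shaded$pixels)[1]; W <- dim(shaded$pixels)[2]
  grad <- matrix(seq(-10, 10, length.out = W), H, W, byrow = TRUE)
  px <- shaded$pixels
  for (k in 1:3) px[, , k] <- pmax(pmin(px[, , k] + grad, 255), 0)
  shaded <- section_image(round(px), id = "shaded", plant_type = "pith-filled")
  m1 <- binarize_adaptive(to_grayscale(shaded))
  expect_gte(mean(m0$pixels == m1$pixels), 0.98)
})
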