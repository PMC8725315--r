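ring_boundaries <- function(seed = 2, outer = c(150, 150), inner = c(120, 120),
                            rotation = 0, plant_type = "hollow") {
  sp <- if (plant_type == "hollow") {
    small_hollow_spec(outer = outer, inner = inner, rotation = rotation)
  } else {
    phantom_spec(plant_type = "pith-filled", outer_semi_axes = outer,
                 inner_semi_axes = inner, rotation = rotation, px_per_mm = 50)
  }
  ph <- make_phantom(sp, seed)
  m <- if (plant_type == "hollow") binarize_otsu(to_grayscale(ph$image)) else
    binarize_adaptive(to_grayscale(ph$image))
  list(b = trace_boundaries(segment_regions(m, plant_type)), ph = ph, sp = sp)
}

test_that("traced annulus contours stay within one pixel of the true radii", {
  rb <- ring_boundaries()
  ctr <- rb$b$centroid_px
  ro <- sqrt((rb$b$outer[, 1] - ctr[1])^2 + (rb$b$outer[, 2] - ctr[2])^2)
  ri <- sqrt((rb$b$inner[, 1] - ctr[1])^2 + (rb$b$inner[, 2] - ctr[2])^2)
  expect_lte(max(abs(ro - 150)), 1)
  expect_lte(max(abs(ri - 120)), 1)
  # closed, canonical orientation, enough vertices
  expect_true(all(rb$b$outer[1, ] == rb$b$outer[nrow(rb$b$outer), ]))
  expect_gt(polygon_area(rb$b$outer), 0)
  expect_gte(nrow(rb$b$outer), 8)
})

test_that("contour shoelace area matches the pixel count within 2%", {
  rb <- ring_boundaries()
  seg <- segment_regions(binarize_otsu(to_grayscale(rb$ph$image)), "hollow")
  a_poly <- polygon_area(rb$b$outer)
  expect_lt(abs(a_poly - sum(seg$whole_mask)) / sum(seg$whole_mask), 0.02)
})

test_that("orientation canonicalization restores a reversed contour", {
  rb <- ring_boundaries()
  poly <- rb$b$outer
  reversed <- poly[rev(seq_len(nrow(poly))), ]
  restored <- stalkmorph:::ensure_ccw(reversed)
  expect_equal(unname(restored), unname(poly))
  expect_error(trace_contour(disk_mask(64, c(30, 30), 0.5)), "fewer than 8")
})

test_that("axis diameters recover ellipse axes in axis-aligned orientation", {
  rb <- ring_boundaries(outer = c(150, 100), inner = c(120, 70))
  cal <- calibration(50)
  d <- axis_diameters(rb$b, cal)
  expect_equal(d$major_mm, 2 * 150 / 50, tolerance = 1 / 150)   # within 1 px
  expect_equal(d$minor_mm, 2 * 100 / 50, tolerance = 1 / 100)
  expect_gte(d$major_mm, d$minor_mm)
  # circle: both diameters equal within a pixel
  rbc <- ring_boundaries()
  dc <- axis_diameters(rbc$b, cal)
  expect_lt(abs(dc$major_mm - dc$minor_mm), 2 / 50)
  expect_equal(dc$major_mm, 6, tolerance = 1 / 150)
})

test_that("rotated ellipse: axis-endpoint chords shrink, Feret does not", {
  rb <- ring_boundaries(outer = c(150, 100), inner = c(120, 70), rotation = 45)
  cal <- calibration(50)
  d_axis <- axis_diameters(rb$b, cal)
  d_feret <- feret_diameters(rb$b, cal)
  # closed-form chord oracle through the centroid at 0 and 90 degrees
  r0 <- stalkmorph:::ellipse_radius_at(0, 150, 100, 45)
  r90 <- stalkmorph:::ellipse_radius_at(pi / 2, 150, 100, 45)
  expect_equal(d_axis$major_mm, 2 * max(r0, r90) / 50, tolerance = 0.01)
  expect_equal(d_axis$minor_mm, 2 * min(r0, r90) / 50, tolerance = 0.01)
  expect_lt(d_axis$major_mm, 6)
  expect_equal(d_feret$major_mm, 6, tolerance = 1 / 150)
  expect_gte(d_feret$major_mm, d_axis$major_mm)
})

test_that("Feret diameters of a square match the brute-force caliper oracle", {
  s <- 81  # filled square of side s pixels: corner-to-corner span s-1
  m <- matrix(FALSE, 121, 121); m[21:(20 + s), 21:(20 + s)] <- TRUE
  seg <- structure(list(whole_mask = m, inner_mask = disk_mask(121, c(60, 60), 15),
                        plant_type = "pith-filled",
                        areas_px = c(whole = sum(m), inner = 700)),
                   class = "segmented_section")
  b <- trace_boundaries(seg)
  d <- feret_diameters(b, calibration(1))
  side <- s - 1  # vertex-to-vertex extent of the pixel-center polygon
  expect_equal(d$major_mm, side * sqrt(2), tolerance = 1e-6)
  expect_equal(d$minor_mm, side, tolerance = 1e-6)
  # independent brute force over all boundary vertex pairs / support widths
  pts <- b$outer[-nrow(b$outer), ]
  dmax <- max(dist(pts))
  expect_equal(d$major_mm, dmax, tolerance = 1e-9)
})

test_that("rind thickness recovers the annulus gap and eccentric offsets", {
  rb <- ring_boundaries()
  cal <- calibration(50)
  rt <- rind_thickness(rb$b, cal)
  expect_equal(rt$mean_mm, 30 / 50, tolerance = 1 / 50)  # 1 px equivalent
  expect_equal(rt$mean_mm, mean(rt$per_point_mm))
  expect_true(all(rt$per_point_mm > 0))
  # eccentric annulus: inner circle shifted by d -> per-point span ~ gap +/- d
  side <- 301
  outer <- disk_mask(side, c(150, 150), 100)
  inner <- disk_mask(side, c(170, 150), 60)  # shifted 20 px
  seg <- structure(list(whole_mask = outer, inner_mask = inner,
                        plant_type = "pith-filled",
                        areas_px = c(whole = sum(outer), inner = sum(inner))),
                   class = "segmented_section")
  rt2 <- rind_thickness(trace_boundaries(seg), calibration(1))
  expect_equal(min(rt2$per_point_mm), 100 - 60 - 20, tolerance = 1.5)
  expect_equal(max(rt2$per_point_mm), 100 - 60 + 20, tolerance = 1.5)
})

test_that("elliptical ring thickness matches a dense numeric oracle", {
  rb <- ring_boundaries(outer = c(150, 110), inner = c(110, 80))
  cal <- calibration(50)
  rt <- rind_thickness(rb$b, cal)
  # independent oracle: min distance from traced outer vertices to a dense
  # cloud of points on the continuous inner ellipse
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  ctr <- rb$b$centroid_px
  ix <- ctr[1] + 110 * cos(th); iy <- ctr[2] + 80 * sin(th)
  outer_pts <- rb$b$outer[-nrow(rb$b$outer), ]
  dmin <- vapply(seq_len(nrow(outer_pts)), function(i) {
    sqrt(min((outer_pts[i, 1] - ix)^2 + (outer_pts[i, 2] - iy)^2))
  }, numeric(1))
  expect_equal(rt$mean_mm, mean(dmin) / 50, tolerance = 0.02 * mean(dmin) / 50)
})

test_that("boundaries and per-point thickness serialize to JSON", {
  rb <- ring_boundaries()
  rt <- rind_thickness(rb$b, calibration(50))
  p <- file.path(withr::local_tempdir(), "boundaries.json")
  write_boundaries(rb$b, rt, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(j$outer), nrow(rb$b$outer))
  expect_equal(j$rind_thickness_mm$mean_mm, rt$mean_mm)
  expect_length(j$rind_thickness_mm$per_point_mm, length(rt$per_point_mm))
})

test_that("areas scale with the inverse square of the calibration", {
  rb <- ring_boundaries()
  seg <- segment_regions(binarize_otsu(to_grayscale(rb$ph$image)), "hollow")
  a1 <- region_areas(seg, calibration(50))
  a2 <- region_areas(seg, calibration(100))
  expect_equal(a1[["whole_mm2"]], 4 * a2[["whole_mm2"]])
  expect_equal(a1[["inner_mm2"]], 4 * a2[["inner_mm2"]])
  expect_lt(a1[["inner_mm2"]], a1[["whole_mm2"]])
  expect_lt(abs(a1[["whole_mm2"]] - pi * 9) / (pi * 9), 0.02)
})
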