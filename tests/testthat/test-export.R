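world_fixture <- function(n_bundles = 10, seed = 19) {
  sp <- small_maize_spec(n_bundles = n_bundles)
  ph <- make_phantom(sp, seed)
  cfg <- default_config(sp)
  rec <- run_single(ph$image, cfg)
  geom <- to_world(attr(rec, "boundaries"), attr(rec, "bundles"),
                   calibration(sp$px_per_mm))
  list(geom = geom, rec = rec, sp = sp)
}

test_that("world coordinates are centered at the centroid with y up", {
  sp <- small_hollow_spec(outer = c(150, 150), inner = c(120, 120))
  ph <- make_phantom(sp, 3)
  rec <- run_single(ph$image, default_config(sp))
  b <- attr(rec, "boundaries")
  geom <- to_world(b, NULL, calibration(sp$px_per_mm))
  outer <- geom$splines[[1]]
  radii <- sqrt(outer[, 1]^2 + outer[, 2]^2)
  expect_lt(abs(mean(outer[, 1])), 0.05)   # centroid maps to the origin
  expect_lt(abs(mean(outer[, 2])), 0.05)
  expect_true(all(abs(radii - 3) < 0.03))  # R = 150 px at 50 px/mm
  # y-up: the top of the image (small pixel y) has positive world y
  top_px <- b$outer[which.min(b$outer[, 2]), ]
  expect_gt(geom$splines[[1]][which.min(b$outer[, 2]), 2], 0)
  # round trip back to pixel coordinates
  wcal <- calibration(sp$px_per_mm, origin_px = b$centroid_px, y_up = TRUE)
  expect_lt(max(abs(mm_to_px(outer, wcal) - b$outer)), 1e-9)
  expect_equal(geom$names[1:2], c("outer_rind", "inner_rind"))
  expect_gte(geom$sheet_size_mm,
             2 * sqrt(sum(apply(do.call(rbind, geom$splines), 2,
                                function(v) diff(range(v)))^2)))
  expect_error(to_world(b, NULL, NULL), "calibration")
})

test_that("boundary decimation respects its tolerance and preserves area", {
  th <- seq(0, 2 * pi, length.out = 1001)
  circle <- cbind(3 * cos(th), 3 * sin(th))  # 1000-vertex circle, r = 3 mm
  expect_equal(decimate_boundary(circle, 0), stalkmorph:::close_polyline(circle))
  dec <- decimate_boundary(circle, 0.01)
  expect_lt(nrow(dec), nrow(circle) / 10)
  radii <- sqrt(dec[, 1]^2 + dec[, 2]^2)
  expect_lte(max(abs(radii - 3)), 0.0100001)
  expect_lt(abs(polygon_area(dec) - polygon_area(circle)) /
              abs(polygon_area(circle)), 0.005)
  # max deviation of removed points from the simplified curve
  d <- stalkmorph:::dist_to_polyline_cpp(circle, dec[-nrow(dec), , drop = FALSE])
  expect_lte(max(d[, "dist"]), 0.01 + 1e-9)
})

test_that("the FE sketch script contains one spline and rename per region", {
  w <- world_fixture(n_bundles = 10)
  expect_length(w$geom$splines, 12)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sketch.py")
  emit_fe_script(w$geom, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("s\\.Spline\\(points=", lines)), 12)
  expect_equal(sum(grepl("changeKey", lines)), 12)
  expect_equal(sum(grepl("mdb\\.Model\\(", lines)), 1)
  expect_equal(sum(grepl("sheetSize=", lines)), 12)
})

test_that("the emitted script round-trips through the companion parser", {
  w <- world_fixture(n_bundles = 4)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sketch.py")
  emit_fe_script(w$geom, p)
  back <- parse_fe_script(p)
  expect_equal(back$names, w$geom$names)
  expect_equal(back$sheet_size_mm, w$geom$sheet_size_mm)
  for (i in seq_along(w$geom$splines)) {
    expect_lte(max(abs(back$splines[[i]] - w$geom$splines[[i]])), 5e-7)
  }
  # byte-identical on rerun
  p2 <- file.path(dir, "sketch2.py")
  emit_fe_script(w$geom, p2)
  expect_identical(readLines(p), readLines(p2))
  expect_error(emit_fe_script(structure(list(splines = list(), names = character(0),
                                             sheet_size_mm = 10),
                                        class = "world_geometry"), p),
               "empty")
})

test_that("neutral CSV export re-imports to the identical geometry", {
  w <- world_fixture(n_bundles = 3)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "geom.csv")
  export_neutral(w$geom, "csv", p)
  back <- read_neutral_csv(p)
  expect_equal(back$names, w$geom$names)
  expect_identical(lapply(back$splines, unname),
                   lapply(w$geom$splines, unname))
  expect_equal(back$sheet_size_mm, w$geom$sheet_size_mm)
})

test_that("GeoJSON export has one polygon per spline with consistent area", {
  w <- world_fixture(n_bundles = 5)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "geom.geojson")
  export_neutral(w$geom, "geojson", p)
  j <- jsonlite::read_json(p, simplifyVector = FALSE)
  expect_equal(length(j$features), length(w$geom$splines))
  outer <- do.call(rbind, lapply(j$features[[1]]$geometry$coordinates[[1]],
                                 function(pt) unlist(pt)))
  a_geo <- abs(polygon_area(outer))
  expect_lt(abs(a_geo - w$rec$whole_area_mm2) / w$rec$whole_area_mm2, 0.02)
  svg <- file.path(dir, "geom.svg")
  export_neutral(w$geom, "svg", svg)
  svg_lines <- readLines(svg)
  expect_equal(sum(grepl("<polygon", svg_lines)), length(w$geom$splines))
  expect_error(export_neutral(w$geom, "step", file.path(dir, "x")), "arg")
})
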