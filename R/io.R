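#' Construct a section image
#'
#' A `section_image` is the pipeline's input: an 8-bit RGB raster of a stained
#' stalk cross-section together with its identifier, plant-type declaration
#' and (optional) spatial calibration. Pixel values are integers in 0..255
#' stored as an H x W x 3 array.
#'
#' @param pixels H x W x 3 numeric array of 8-bit intensities, or an H x W
#'   matrix (replicated to three channels).
#' @param id source identifier (file path or name).
#' @param plant_type `"pith-filled"` or `"hollow"`.
#' @param calibration optional [calibration()].
#' @return object of class `section_image`.
#' @export
section_image <- function(pixels, id = "image", plant_type = "pith-filled",
                          calibration = NULL) {
  plant_type <- match_plant_type(plant_type)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("pixels must be an H x W x 3 array")
  if (d[1] < 32 || d[2] < 32) stop("image too small: both dimensions must be >= 32 px")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  if (!is.null(calibration)) stopifnot(inherits(calibration, "calibration"))
  structure(
    list(pixels = pixels, id = as.character(id), plant_type = plant_type,
         calibration = calibration),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_image> '%s' %d x %d px, %s%s\n", x$id, d[2], d[1],
              x$plant_type,
              if (is.null(x$calibration)) ", uncalibrated"
              else sprintf(", %.6g px/mm", x$calibration$px_per_mm)))
  invisible(x)
}

#' Read a cross-section image from TIFF or PNG
#'
#' Grayscale sources are replicated to three channels; 16-bit sources are
#' linearly rescaled to 8-bit. An alpha channel, if present, is dropped.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param plant_type `"pith-filled"` or `"hollow"`.
#' @param calibration optional [calibration()] attached to the image.
#' @return a [section_image()].
#' @export
read_image <- function(path, plant_type = "pith-filled", calibration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path),
                            error = function(e) stop("unreadable TIFF '", path, "': ",
                                                     conditionMessage(e))),
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("unreadable PNG '", path, "': ",
                                            conditionMessage(e))),
    stop("unsupported image format '.", ext, "' (TIFF or PNG expected): ", path)
  )
  if (length(raw) == 0) stop("zero-sized image: ", path)
  # readers return values in [0, 1] regardless of source bit depth, so the
  # 16-bit -> 8-bit linear rescale is round(v * 255)
  if (length(dim(raw)) == 2) {
    px <- round(raw * 255)
  } else {
    nc <- dim(raw)[3]
    if (nc >= 3) {
      px <- round(raw[, , 1:3, drop = FALSE] * 255)
    } else {
      px <- round(raw[, , 1] * 255)
    }
  }
  section_image(px, id = path, plant_type = plant_type, calibration = calibration)
}

#' Write a section image to TIFF or PNG (8-bit)
#'
#' @param img a [section_image()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "section_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    stop("unsupported output format '.", ext, "'")
  )
  invisible(path)
}

#' Assemble a phenotype record
#'
#' One row of the batch output: the four headline phenotypes (major and minor
#' diameter, mean rind thickness, vascular bundle count) plus the whole and
#' inner cross-sectional areas, all in millimeter units, with the measurement
#' conventions used.
#'
#' @param image_id source identifier.
#' @param major_d_mm,minor_d_mm diameters in mm.
#' @param rind_thickness_mm mean rind thickness in mm.
#' @param bundle_count integer vascular bundle count.
#' @param whole_area_mm2,inner_area_mm2 areas in mm^2.
#' @param diameter_convention `"axis-endpoint"` or `"feret"`.
#' @param threshold_method `"otsu"` or `"adaptive"`.
#' @return one-row `data.frame` of class `phenotype_record`.
#' @export
phenotype_record <- function(image_id, major_d_mm, minor_d_mm, rind_thickness_mm,
                             bundle_count, whole_area_mm2, inner_area_mm2,
                             diameter_convention = c("axis-endpoint", "feret"),
                             threshold_method = c("otsu", "adaptive")) {
  diameter_convention <- match.arg(diameter_convention)
  threshold_method <- match.arg(threshold_method)
  if (!all(c(major_d_mm, minor_d_mm, rind_thickness_mm) > 0)) {
    stop("all lengths must be > 0")
  }
  if (bundle_count < 0) stop("bundle_count must be >= 0")
  if (inner_area_mm2 >= whole_area_mm2) stop("inner area must be smaller than whole area")
  rec <- data.frame(
    image_id = as.character(image_id),
    major_d_mm = unname(major_d_mm), minor_d_mm = unname(minor_d_mm),
    rind_thickness_mm = unname(rind_thickness_mm),
    bundle_count = as.integer(bundle_count),
    whole_area_mm2 = unname(whole_area_mm2),
    inner_area_mm2 = unname(inner_area_mm2),
    diameter_convention = diameter_convention,
    threshold_method = threshold_method,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("phenotype_record", class(rec))
  rec
}

RESULT_COLUMNS <- c("image_id", "major_d_mm", "minor_d_mm", "rind_thickness_mm",
                    "bundle_count", "whole_area_mm2", "inner_area_mm2",
                    "diameter_convention", "threshold_method")

#' Write phenotype records to CSV
#'
#' Fixed column order; millimeter quantities are printed with 4 decimal
#' places. An empty record list yields a header-only file.
#'
#' @param records a `data.frame` of phenotype records (rows may be zero), or a
#'   list of [phenotype_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (is.null(records) || nrow(records) == 0) {
    writeLines(paste(RESULT_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  df <- records[, RESULT_COLUMNS]
  for (col in c("major_d_mm", "minor_d_mm", "rind_thickness_mm",
                "whole_area_mm2", "inner_area_mm2")) {
    df[[col]] <- sprintf("%.4f", df[[col]])
  }
  lines <- c(paste(RESULT_COLUMNS, collapse = ","),
             apply(df, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype-record CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return `data.frame` with one row per record.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) df$bundle_count <- as.integer(df$bundle_count)
  df
}

# draw a polyline onto an RGB [0,1] array; col is length-3 in [0,1]
draw_polyline <- function(arr, poly, col, close = TRUE) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  poly <- as_xy_matrix(poly)
  if (close) poly <- close_polyline(poly)
  for (i in seq_len(nrow(poly) - 1)) {
    p <- poly[i, ]; q <- poly[i + 1, ]
    n <- max(2L, ceiling(2 * sqrt(sum((q - p)^2))))
    t <- seq(0, 1, length.out = n)
    xs <- round(p[1] + t * (q[1] - p[1])) + 1L
    ys <- round(p[2] + t * (q[2] - p[2])) + 1L
    ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    for (ch in 1:3) arr[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  }
  arr
}

draw_circle <- function(arr, center, radius, col) {
  theta <- seq(0, 2 * pi, length.out = max(16, ceiling(4 * radius)))
  draw_polyline(arr, cbind(center[1] + radius * cos(theta),
                           center[2] + radius * sin(theta)), col, close = FALSE)
}

#' Write a quality-control overlay PNG
#'
#' Renders the grayscale image with the outer and inner rind boundaries, the
#' diameter segments, automatically traced bundle boundaries, and manually
#' added bundles drawn as circles (green, mirroring the interactive display
#' the workflow replaces).
#'
#' @param img a [section_image()].
#' @param boundaries a `rind_boundaries` object from [trace_boundaries()].
#' @param bundles optional `bundle_set` from [detect_bundles()].
#' @param diam_segments optional list of two-row (x, y) matrices (one per
#'   diameter) as produced by [axis_diameters()]/[feret_diameters()] in
#'   `$endpoints_px`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, boundaries, bundles = NULL, diam_segments = NULL,
                         path) {
  stopifnot(inherits(img, "section_image"))
  g <- to_grayscale(img)$pixels / 255
  arr <- array(rep(g, 3), dim = c(dim(g), 3))
  red <- c(1, 0.1, 0.1); blue <- c(0.15, 0.4, 1); yellow <- c(1, 0.9, 0.1)
  green <- c(0.1, 0.9, 0.2)
  if (!is.null(boundaries)) {
    arr <- draw_polyline(arr, boundaries$outer, red)
    arr <- draw_polyline(arr, boundaries$inner, blue)
  }
  if (!is.null(diam_segments)) {
    for (seg in diam_segments) arr <- draw_polyline(arr, seg, yellow, close = FALSE)
  }
  if (!is.null(bundles)) {
    for (b in bundles$bundles) {
      if (identical(b$provenance, "manual")) {
        arr <- draw_circle(arr, b$centroid_px, 8, green)
      } else if (!is.null(b$boundary)) {
        arr <- draw_polyline(arr, b$boundary, red)
      }
    }
  }
  png::writePNG(arr, path)
  invisible(path)
}
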