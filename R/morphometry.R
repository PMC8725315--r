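#' Trace the ordered boundary of a single-component mask
#'
#' Moore-neighbor tracing at pixel centers (0-based image coordinates).
#' The returned polyline is closed (first vertex repeated last) and
#' canonically oriented (positive shoelace area in image coordinates).
#'
#' @param mask logical matrix with a single 8-connected foreground component.
#' @return closed two-column (x, y) matrix of boundary pixel centers.
#' @export
trace_contour <- function(mask) {
  m <- mask_pixels(mask)
  pts <- moore_contour_cpp(m)
  if (nrow(unique(pts)) < 8) {
    stop("mask boundary has fewer than 8 pixels; region too small to trace")
  }
  close_polyline(ensure_ccw(pts))
}

#' Extract the outer and inner rind boundaries
#'
#' Traces the contour of the whole-section mask (outer rind boundary) and of
#' the pith/lumen mask (inner rind boundary). These boundary coordinates are
#' the basis for all diameter and rind-thickness measurements.
#'
#' @param seg a [segment_regions()] result.
#' @return object of class `rind_boundaries`: closed polylines `outer` and
#'   `inner` plus `centroid_px`, the whole-mask foreground centroid.
#' @export
trace_boundaries <- function(seg) {
  stopifnot(inherits(seg, "segmented_section"))
  outer <- trace_contour(seg$whole_mask)
  inner <- trace_contour(seg$inner_mask)
  idx <- which(seg$whole_mask)
  H <- nrow(seg$whole_mask)
  cy <- mean((idx - 1L) %% H)         # row - 1
  cx <- mean((idx - 1L) %/% H)        # col - 1
  structure(list(outer = outer, inner = inner, centroid_px = c(cx, cy)),
            class = "rind_boundaries")
}

#' @export
print.rind_boundaries <- function(x, ...) {
  cat(sprintf("<rind_boundaries> outer %d vertices, inner %d vertices, centroid (%.1f, %.1f) px\n",
              nrow(x$outer) - 1, nrow(x$inner) - 1,
              x$centroid_px[1], x$centroid_px[2]))
  invisible(x)
}

# x-coordinates where the polygon crosses the horizontal line y = y0
# (and symmetrically for vertical lines via swap)
line_crossings <- function(poly, y0, vertical = FALSE) {
  p <- poly
  if (vertical) p <- p[, c(2, 1)]
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  i <- seq_len(n - 1)
  x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
  out <- numeric(0)
  span <- (y1 - y0) * (y2 - y0) <= 0 & y1 != y2
  if (any(span)) {
    t <- (y0 - y1[span]) / (y2[span] - y1[span])
    out <- c(out, x1[span] + t * (x2[span] - x1[span]))
  }
  flat <- y1 == y0 & y2 == y0
  if (any(flat)) out <- c(out, x1[flat], x2[flat])
  out
}

new_diameter_result <- function(major_mm, minor_mm, major_seg, minor_seg,
                                convention) {
  stopifnot(major_mm >= minor_mm, minor_mm > 0)
  structure(list(major_mm = major_mm, minor_mm = minor_mm,
                 endpoints_px = list(major = major_seg, minor = minor_seg),
                 convention = convention),
            class = "diameter_result")
}

#' @export
print.diameter_result <- function(x, ...) {
  cat(sprintf("<diameter_result> %s: major %.4f mm, minor %.4f mm\n",
              x$convention, x$major_mm, x$minor_mm))
  invisible(x)
}

#' Axis-endpoint diameters
#'
#' Measures the two diameters as centroid-anchored chords along the image
#' axes: rays at 0/180 degrees (horizontal) and 90/270 degrees (vertical) are
#' intersected with the outer rind boundary, taking the outermost crossing on
#' each side. The larger chord is the major diameter. This reproduces the
#' axis-aligned measurement convention of the original workflow; the
#' caliper-style alternative is [feret_diameters()].
#'
#' @param b a [trace_boundaries()] result.
#' @param cal a [calibration()].
#' @return a `diameter_result` with lengths in mm and the chord endpoints in
#'   pixel coordinates (for overlays).
#' @export
axis_diameters <- function(b, cal) {
  stopifnot(inherits(b, "rind_boundaries"), inherits(cal, "calibration"))
  cx <- b$centroid_px[1]; cy <- b$centroid_px[2]
  xs <- line_crossings(b$outer, cy, vertical = FALSE)
  ys <- line_crossings(b$outer, cx, vertical = TRUE)
  if (length(xs) < 2 || min(xs) > cx || max(xs) < cx ||
      length(ys) < 2 || min(ys) > cy || max(ys) < cy) {
    stop("centroid ray failed to intersect the outer boundary on both sides; ",
         "the section outline is not star-shaped about its centroid")
  }
  hseg <- rbind(c(min(xs), cy), c(max(xs), cy))
  vseg <- rbind(c(cx, min(ys)), c(cx, max(ys)))
  hlen <- (max(xs) - min(xs)) / cal$px_per_mm
  vlen <- (max(ys) - min(ys)) / cal$px_per_mm
  if (hlen >= vlen) {
    new_diameter_result(hlen, vlen, hseg, vseg, "axis-endpoint")
  } else {
    new_diameter_result(vlen, hlen, vseg, hseg, "axis-endpoint")
  }
}

#' Feret (caliper) diameters
#'
#' Major diameter = maximum Feret diameter (the largest distance between two
#' parallel supporting lines, i.e. the caliper measurement); minor diameter =
#' minimum Feret width. Both are computed on the convex hull of the outer
#' boundary: the maximum over hull-vertex pairs and the minimum over
#' hull-edge support widths (rotating calipers). Rotation-invariant, unlike
#' [axis_diameters()].
#'
#' @inheritParams axis_diameters
#' @return a `diameter_result` (convention `"feret"`).
#' @export
feret_diameters <- function(b, cal) {
  stopifnot(inherits(b, "rind_boundaries"), inherits(cal, "calibration"))
  pts <- b$outer[-nrow(b$outer), , drop = FALSE]
  hull <- pts[chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3 || abs(polygon_area(hull)) < 1e-9) {
    stop("degenerate (collinear) convex hull; cannot measure Feret diameters")
  }
  # max Feret: brute force over hull vertex pairs (hull is small)
  d2 <- as.matrix(stats::dist(hull))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  major_px <- sqrt(max(d2))
  major_seg <- hull[c(ij[1], ij[2]), , drop = FALSE]
  # min Feret width: for each hull edge, the farthest vertex from its line
  best <- Inf; best_seg <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    h <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    k <- which.max(abs(h))
    w <- abs(h[k])
    if (w < best) {
      best <- w
      foot <- hull[k, ] - h[k] * nrm
      best_seg <- rbind(foot, hull[k, ])
    }
  }
  new_diameter_result(major_px / cal$px_per_mm, best / cal$px_per_mm,
                      major_seg, best_seg, "feret")
}

#' Mean rind thickness from boundary-to-boundary shortest distances
#'
#' For every vertex of the outer rind boundary, the shortest Euclidean
#' distance to the inner rind boundary is found (measured against the inner
#' polyline's segments, not only its vertices, to avoid vertex-density bias).
#' The rind thickness is the arithmetic mean of these per-vertex shortest
#' segments. The mean is directed (outer to inner).
#'
#' @inheritParams axis_diameters
#' @return object of class `rind_thickness_result`: `mean_mm`, the per-vertex
#'   distances `per_point_mm`, and `segments_px`, a list with the outer points
#'   and their nearest inner points (for overlay drawing).
#' @export
rind_thickness <- function(b, cal) {
  stopifnot(inherits(b, "rind_boundaries"), inherits(cal, "calibration"))
  outer <- b$outer[-nrow(b$outer), , drop = FALSE]
  inner <- b$inner[-nrow(b$inner), , drop = FALSE]
  d <- dist_to_polyline_cpp(outer, inner)
  if (any(d[, "dist"] <= 0)) {
    stop("outer and inner boundaries touch or intersect; segmentation is invalid")
  }
  per_point <- d[, "dist"] / cal$px_per_mm
  structure(list(mean_mm = mean(per_point),
                 per_point_mm = per_point,
                 segments_px = list(outer = outer,
                                    nearest_inner = d[, c("x", "y"), drop = FALSE])),
            class = "rind_thickness_result")
}

#' @export
print.rind_thickness_result <- function(x, ...) {
  cat(sprintf("<rind_thickness_result> mean %.4f mm over %d boundary points (range %.4f-%.4f)\n",
              x$mean_mm, length(x$per_point_mm),
              min(x$per_point_mm), max(x$per_point_mm)))
  invisible(x)
}

#' Serialize boundaries (and per-point thickness) to JSON
#'
#' @param b a [trace_boundaries()] result.
#' @param thickness optional [rind_thickness()] result; adds the per-point
#'   distances and nearest-point segments.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(b, thickness = NULL, path) {
  stopifnot(inherits(b, "rind_boundaries"))
  out <- list(outer = unname(b$outer), inner = unname(b$inner),
              centroid_px = as.numeric(b$centroid_px))
  if (!is.null(thickness)) {
    out$rind_thickness_mm <- list(
      mean_mm = thickness$mean_mm,
      per_point_mm = as.numeric(thickness$per_point_mm),
      nearest_inner_px = unname(thickness$segments_px$nearest_inner))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Whole-section and inner region areas in mm^2
#'
#' Pixel counts divided by the squared calibration factor.
#'
#' @param seg a [segment_regions()] result.
#' @param cal a [calibration()].
#' @return named numeric vector `c(whole_mm2, inner_mm2)`.
#' @export
region_areas <- function(seg, cal) {
  stopifnot(inherits(seg, "segmented_section"), inherits(cal, "calibration"))
  a <- seg$areas_px / cal$px_per_mm^2
  c(whole_mm2 = unname(a["whole"]), inner_mm2 = unname(a["inner"]))
}
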