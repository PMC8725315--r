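new_world_geometry <- function(splines, names, sheet_size_mm) {
  stopifnot(length(splines) == length(names))
  splines <- lapply(splines, function(s) close_polyline(as_xy_matrix(s)))
  for (s in splines) {
    if (!all(is.finite(s))) stop("world geometry coordinates must be finite")
  }
  structure(list(splines = splines, names = as.character(names),
                 sheet_size_mm = sheet_size_mm),
            class = "world_geometry")
}

#' @export
print.world_geometry <- function(x, ...) {
  cat(sprintf("<world_geometry> %d splines (%s), sheet size %g mm\n",
              length(x$splines),
              paste(head(x$names, 4), collapse = ", "),
              x$sheet_size_mm))
  invisible(x)
}

bbox_diagonal <- function(splines) {
  all_pts <- do.call(rbind, splines)
  rng_x <- range(all_pts[, 1]); rng_y <- range(all_pts[, 2])
  sqrt(diff(rng_x)^2 + diff(rng_y)^2)
}

# smallest power of 10 strictly exceeding 2x the bounding-box diagonal
sheet_size_for <- function(splines) {
  d <- 2 * bbox_diagonal(splines)
  10^ceiling(log10(d + 1e-12) + 1e-12)
}

#' Convert boundaries and bundles to world (mm) coordinates
#'
#' Applies the pixel-to-millimeter calibration with the world origin at the
#' section centroid and the y axis flipped to point up, the orientation of a
#' finite-element sketch plane. Splines are named deterministically
#' (`outer_rind`, `inner_rind`, `bundle_001`, ...); only automatically traced
#' bundles contribute splines (manual point bundles have no boundary).
#'
#' @param b a [trace_boundaries()] result.
#' @param bundles optional `bundle_set`.
#' @param cal a [calibration()]; its `px_per_mm` is used, with the origin
#'   replaced by the section centroid and `y_up` set.
#' @return a `world_geometry`: closed mm-coordinate splines, names, and a
#'   sheet size (smallest power of 10 exceeding twice the bounding-box
#'   diagonal).
#' @export
to_world <- function(b, bundles = NULL, cal = NULL) {
  stopifnot(inherits(b, "rind_boundaries"))
  if (is.null(cal)) stop("missing calibration")
  stopifnot(inherits(cal, "calibration"))
  wcal <- calibration(cal$px_per_mm, origin_px = b$centroid_px, y_up = TRUE)
  splines <- list(px_to_mm(b$outer, wcal), px_to_mm(b$inner, wcal))
  nms <- c("outer_rind", "inner_rind")
  if (!is.null(bundles)) {
    k <- 0L
    for (bd in bundles$bundles) {
      if (is.null(bd$boundary)) next
      k <- k + 1L
      splines[[length(splines) + 1L]] <- px_to_mm(bd$boundary, wcal)
      nms <- c(nms, sprintf("bundle_%03d", k))
    }
  }
  new_world_geometry(splines, nms, sheet_size_for(splines))
}

# Douglas-Peucker on an open chain, iterative; returns kept-vertex logical
dp_keep <- function(pts, tol) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  if (n <= 2) return(keep)
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    p <- pts[i, ]; q <- pts[j, ]
    mid <- (i + 1):(j - 1)
    e <- q - p
    len <- sqrt(sum(e^2))
    if (len == 0) {
      d <- sqrt((pts[mid, 1] - p[1])^2 + (pts[mid, 2] - p[2])^2)
    } else {
      d <- abs(e[1] * (p[2] - pts[mid, 2]) - e[2] * (p[1] - pts[mid, 1])) / len
    }
    k <- mid[which.max(d)]
    if (max(d) > tol) {
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  keep
}

#' Simplify a closed boundary spline (Douglas-Peucker)
#'
#' Reduces vertex count while guaranteeing that no removed point deviates
#' from the simplified curve by more than `tolerance_mm`. The closed polyline
#' is split at its two mutually farthest vertices and each half simplified;
#' tolerance 0 is the identity and closure is preserved.
#'
#' @param spline closed two-column (x, y) matrix (mm or px; the tolerance is
#'   in the same units).
#' @param tolerance_mm maximum allowed deviation (>= 0).
#' @return simplified closed matrix.
#' @export
decimate_boundary <- function(spline, tolerance_mm) {
  stopifnot(tolerance_mm >= 0)
  spline <- close_polyline(as_xy_matrix(spline))
  if (tolerance_mm == 0) return(spline)
  pts <- spline[-nrow(spline), , drop = FALSE]
  n <- nrow(pts)
  if (n <= 4) return(spline)
  hull <- chull(pts)
  d2 <- as.matrix(stats::dist(pts[hull, , drop = FALSE]))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i <- sort(c(hull[ij[1]], hull[ij[2]]))
  rot <- c(i[1]:n, seq_len(i[1] - 1))  # rotate so the first anchor is vertex 1
  pts <- pts[rot, , drop = FALSE]
  split_at <- which(rot == i[2])
  chain1 <- pts[1:split_at, , drop = FALSE]
  chain2 <- pts[c(split_at:n, 1), , drop = FALSE]
  k1 <- dp_keep(chain1, tolerance_mm)
  k2 <- dp_keep(chain2, tolerance_mm)
  out <- rbind(chain1[k1, , drop = FALSE],
               chain2[k2, , drop = FALSE][-1, , drop = FALSE])
  # last kept vertex of chain2 is the first vertex again: closed
  out
}

#' Simplify every spline of a world geometry
#'
#' @param geom a `world_geometry`.
#' @param tolerance_mm per-spline deviation tolerance for
#'   [decimate_boundary()].
#' @return a `world_geometry` with simplified splines.
#' @export
decimate_geometry <- function(geom, tolerance_mm) {
  stopifnot(inherits(geom, "world_geometry"))
  splines <- lapply(geom$splines, decimate_boundary, tolerance_mm = tolerance_mm)
  new_world_geometry(splines, geom$names, geom$sheet_size_mm)
}

#' Emit a finite-element preprocessor sketch script
#'
#' Writes a plain-text Python script in the Abaqus/CAE scripting dialect
#' containing, in order: a model-creation statement, one constrained-sketch
#' command per spline carrying the sheet size, the closed-spline command with
#' the full coordinate list at fixed 6-decimal precision, and a rename
#' statement per sketch. The output is byte-identical for identical input.
#' The script is validated by round trip through [parse_fe_script()], not by
#' execution in the commercial package.
#'
#' @param geom a `world_geometry`.
#' @param out_path output path for the script.
#' @return the script text (character vector of lines), invisibly.
#' @export
emit_fe_script <- function(geom, out_path) {
  stopifnot(inherits(geom, "world_geometry"))
  if (length(geom$splines) == 0) stop("empty geometry: nothing to emit")
  fmt <- function(v) sprintf("%.6f", v)
  lines <- c(
    "# Specimen-specific cross-section sketch (generated by stalkmorph)",
    "from abaqus import mdb",
    "from abaqusConstants import *",
    "mdb.Model(name='Model-1')"
  )
  for (i in seq_along(geom$splines)) {
    s <- geom$splines[[i]]
    sketch_id <- sprintf("sketch_%03d", i)
    pts <- paste(sprintf("(%s, %s)", fmt(s[, 1]), fmt(s[, 2])), collapse = ", ")
    lines <- c(lines,
      sprintf("s = mdb.models['Model-1'].ConstrainedSketch(name='%s', sheetSize=%s)",
              sketch_id, fmt(geom$sheet_size_mm)),
      sprintf("s.Spline(points=(%s))", pts),
      sprintf("mdb.models['Model-1'].sketches.changeKey(fromName='%s', toName='%s')",
              sketch_id, geom$names[i]))
  }
  writeLines(lines, out_path)
  invisible(lines)
}

#' Parse a sketch script emitted by [emit_fe_script()]
#'
#' Companion parser used to validate the emitted script: recovers every
#' spline's coordinates (to the printed 6-decimal precision), its name, and
#' the sheet size.
#'
#' @param path script path.
#' @return a `world_geometry`.
#' @export
parse_fe_script <- function(path) {
  lines <- readLines(path)
  sheet <- NA_real_
  splines <- list(); ids <- character(0); names <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("ConstrainedSketch\\(name='([^']+)', sheetSize=([0-9.eE+-]+)\\)", ln))[[1]]
    if (length(m) == 3) {
      sheet <- as.numeric(m[3])
      ids <- c(ids, m[2])
      next
    }
    m <- regmatches(ln, regexec("s\\.Spline\\(points=\\((.*)\\)\\)", ln))[[1]]
    if (length(m) == 2) {
      nums <- as.numeric(regmatches(m[2], gregexpr("-?[0-9]+\\.[0-9]+", m[2]))[[1]])
      splines[[length(splines) + 1L]] <- matrix(nums, ncol = 2, byrow = TRUE)
      next
    }
    m <- regmatches(ln, regexec("changeKey\\(fromName='([^']+)', toName='([^']+)'\\)", ln))[[1]]
    if (length(m) == 3) names <- c(names, m[3])
  }
  if (length(splines) == 0) stop("no spline commands found in script: ", path)
  if (length(names) != length(splines)) {
    stop("script has ", length(splines), " splines but ", length(names),
         " rename statements")
  }
  new_world_geometry(splines, names, sheet)
}

#' Export geometry in a neutral format
#'
#' `csv`: one row per vertex with its spline name and vertex index (exact
#' round trip via [read_neutral_csv()]). `geojson`: one polygon feature per
#' spline, coordinates in mm. `svg`: a scaled drawing for visual QC.
#'
#' @param geom a `world_geometry`.
#' @param format `"csv"`, `"geojson"` or `"svg"`.
#' @param out_path output path.
#' @return `out_path`, invisibly.
#' @export
export_neutral <- function(geom, format = c("csv", "geojson", "svg"), out_path) {
  stopifnot(inherits(geom, "world_geometry"))
  format <- match.arg(format)
  switch(format,
    csv = {
      rows <- lapply(seq_along(geom$splines), function(i) {
        s <- geom$splines[[i]]
        sprintf("%s,%d,%.17g,%.17g", geom$names[i], seq_len(nrow(s)),
                s[, 1], s[, 2])
      })
      writeLines(c("spline,vertex,x_mm,y_mm", unlist(rows)), out_path)
    },
    geojson = {
      features <- lapply(seq_along(geom$splines), function(i) {
        s <- geom$splines[[i]]
        list(type = "Feature",
             properties = list(name = geom$names[i]),
             geometry = list(type = "Polygon",
                             coordinates = list(unname(s))))
      })
      jsonlite::write_json(
        list(type = "FeatureCollection", features = features),
        out_path, auto_unbox = TRUE, digits = NA)
    },
    svg = {
      all_pts <- do.call(rbind, geom$splines)
      xr <- range(all_pts[, 1]); yr <- range(all_pts[, 2])
      pad <- 0.05 * max(diff(xr), diff(yr), 1e-9)
      polys <- vapply(geom$splines, function(s) {
        # flip y: world y-up -> svg y-down
        paste(sprintf("%.4f,%.4f", s[, 1], -s[, 2]), collapse = " ")
      }, character(1))
      lines <- c(
        sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.4f %.4f %.4f %.4f">',
                xr[1] - pad, -yr[2] - pad, diff(xr) + 2 * pad, diff(yr) + 2 * pad),
        sprintf('  <polygon points="%s" fill="none" stroke="black" stroke-width="%.4f"><title>%s</title></polygon>',
                polys, 0.01 * max(diff(xr), 1e-9), geom$names),
        "</svg>")
      writeLines(lines, out_path)
    })
  invisible(out_path)
}

#' Re-import a neutral CSV geometry export
#'
#' @param path CSV written by `export_neutral(..., format = "csv")`.
#' @return a `world_geometry` (sheet size recomputed deterministically).
#' @export
read_neutral_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nms <- unique(df$spline)
  splines <- lapply(nms, function(nm) {
    s <- df[df$spline == nm, ]
    s <- s[order(s$vertex), ]
    cbind(s$x_mm, s$y_mm)
  })
  new_world_geometry(splines, nms, sheet_size_for(
    lapply(splines, as_xy_matrix)))
}
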