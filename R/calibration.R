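#' Spatial calibration between pixel and world (mm) coordinates
#'
#' The calibration is a single isotropic scale factor (pixels per millimeter),
#' as obtained by imaging a scale rule at a fixed magnification, plus a world
#' origin and an axis-orientation flag. Image coordinates are 0-based with x
#' increasing rightward and y increasing downward (origin at the top-left
#' pixel center); with `y_up = TRUE` the world y axis increases upward, as in
#' a finite-element sketch plane.
#'
#' @param px_per_mm pixels per millimeter; must be a single positive number.
#'   Anisotropic (two-component) calibrations are rejected.
#' @param origin_px length-2 numeric, pixel coordinates of the world origin.
#' @param y_up logical; if `TRUE`, world y = -(image y - origin y) / px_per_mm.
#' @return an object of class `calibration`.
#' @examples
#' cal <- calibration(100)
#' px_to_mm(cbind(100, 0), cal)  # (1, 0) mm
#' @export
calibration <- function(px_per_mm, origin_px = c(0, 0), y_up = FALSE) {
  if (length(px_per_mm) != 1 || !is.finite(px_per_mm)) {
    stop("px_per_mm must be a single finite number (anisotropic calibration is not supported)")
  }
  if (px_per_mm <= 0) stop("px_per_mm must be > 0")
  stopifnot(length(origin_px) == 2, is.finite(origin_px))
  structure(
    list(px_per_mm = as.numeric(px_per_mm),
         origin_px = as.numeric(origin_px),
         y_up = isTRUE(y_up)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g px/mm, origin (%g, %g) px, y %s\n",
              x$px_per_mm, x$origin_px[1], x$origin_px[2],
              if (x$y_up) "up" else "down"))
  invisible(x)
}

#' Convert pixel coordinates to world millimeters
#'
#' Subtracts the calibration origin, divides by `px_per_mm`, and negates the
#' y component when the calibration declares a y-up world frame. Exactly
#' inverted by [mm_to_px()].
#'
#' @param points two-column matrix (or data frame) of (x, y) pixel coordinates.
#' @param cal a [calibration()].
#' @return matrix of (x, y) world coordinates in mm.
#' @export
px_to_mm <- function(points, cal) {
  stopifnot(inherits(cal, "calibration"))
  p <- as_xy_matrix(points)
  p[, 1] <- (p[, 1] - cal$origin_px[1]) / cal$px_per_mm
  p[, 2] <- (p[, 2] - cal$origin_px[2]) / cal$px_per_mm
  if (cal$y_up) p[, 2] <- -p[, 2]
  p
}

#' Convert world millimeters to pixel coordinates
#'
#' Inverse of [px_to_mm()].
#'
#' @inheritParams px_to_mm
#' @param points two-column matrix of (x, y) world coordinates in mm.
#' @return matrix of (x, y) pixel coordinates.
#' @export
mm_to_px <- function(points, cal) {
  stopifnot(inherits(cal, "calibration"))
  p <- as_xy_matrix(points)
  if (cal$y_up) p[, 2] <- -p[, 2]
  p[, 1] <- p[, 1] * cal$px_per_mm + cal$origin_px[1]
  p[, 2] <- p[, 2] * cal$px_per_mm + cal$origin_px[2]
  p
}
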