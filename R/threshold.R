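#' Convert an RGB section image to grayscale
#'
#' Per-pixel luminance with the standard ITU-R BT.601 weights
#' 0.2989 R + 0.5870 G + 0.1140 B, rounded half-up to 8-bit.
#'
#' @param img a [section_image()].
#' @return object of class `gray_image`: a list with `pixels` (H x W integer
#'   matrix) and `id`.
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "section_image"))
  px <- img$pixels
  g <- 0.2989 * px[, , 1] + 0.5870 * px[, , 2] + 0.1140 * px[, , 3]
  g <- floor(g + 0.5)  # round half-up, unlike round()'s round-half-even
  storage.mode(g) <- "integer"
  structure(list(pixels = g, id = img$id), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> '%s' %d x %d px\n", x$id, d[2], d[1]))
  invisible(x)
}

as_gray <- function(g) {
  if (inherits(g, "section_image")) g <- to_grayscale(g)
  if (is.matrix(g)) g <- structure(list(pixels = g, id = "gray"), class = "gray_image")
  stopifnot(inherits(g, "gray_image"))
  g
}

new_binary_mask <- function(mask, method, threshold) {
  structure(list(pixels = mask, method = method, threshold_used = threshold,
                 foreground = "dark (stained/lignified) tissue"),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<binary_mask> %d x %d px, method %s, %.3g%% foreground\n",
              d[2], d[1], x$method, 100 * mean(x$pixels)))
  invisible(x)
}

# accept binary_mask objects or plain logical matrices everywhere downstream
mask_pixels <- function(m) {
  if (inherits(m, "binary_mask")) m$pixels else m
}

#' Otsu threshold of an 8-bit histogram
#'
#' Selects the threshold `t` in 0..254 that maximizes the between-class
#' variance of the two classes `{<= t}` and `{> t}` (equivalently, minimizes
#' the within-class variance). Ties are broken toward the smaller threshold.
#'
#' @param counts integer vector of length 256: histogram of gray levels 0..255.
#' @return the threshold `t` (gray level, 0..254).
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256)
  total <- sum(counts)
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: image has fewer than 2 distinct gray levels")
  }
  p <- counts / total
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w0_ <- w0[1:255]
  mu_ <- mu[1:255]
  valid <- w0_ > 0 & w0_ < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0_[valid] - mu_[valid])^2 /
    (w0_[valid] * (1 - w0_[valid]))
  which.max(sigma_b) - 1L  # which.max returns the first (lowest) maximizer
}

#' Global Otsu binarization
#'
#' Binarizes a grayscale image at the Otsu threshold; the dark class (stained,
#' lignified tissue) becomes foreground. This is the default method for
#' hollow-type sections, whose histogram is cleanly bimodal.
#'
#' @param g a `gray_image` (or [section_image()], converted internally).
#' @return a `binary_mask` whose `pixels` are a logical matrix
#'   (`TRUE` = dark/stained tissue) and whose `threshold_used` records the
#'   chosen gray level.
#' @export
binarize_otsu <- function(g) {
  g <- as_gray(g)
  counts <- tabulate(as.vector(g$pixels) + 1L, nbins = 256)
  t_star <- otsu_threshold(counts)
  new_binary_mask(g$pixels <= t_star, "otsu", t_star)
}

# local mean over an odd square window with symmetric (reflective) padding,
# via a summed-area table
local_mean <- function(g, win) {
  H <- nrow(g); W <- ncol(g)
  h <- (win - 1L) %/% 2L
  ri <- c(h:1, 1:H, H:(H - h + 1L))
  ci <- c(h:1, 1:W, W:(W - h + 1L))
  gp <- g[ri, ci]
  sat <- apply(gp, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  sat <- rbind(0, cbind(0, sat))
  r1 <- 1:H; r2 <- r1 + win; c1 <- 1:W; c2 <- c1 + win
  s <- sat[r2, c2] - sat[r1, c2] - sat[r2, c1] + sat[r1, c1]
  s / (win * win)
}

#' Local adaptive binarization (pith-filled sections)
#'
#' Per-pixel thresholding against the local mean over a square window:
#' a pixel becomes foreground (dark tissue) when its value does not exceed
#' `local_mean * (1 - 0.3 * sensitivity)`. Borders are handled by reflective
#' padding. This follows the local-mean-with-offset behavior of the common
#' adaptive binarization in image-processing toolboxes; higher sensitivity
#' demands darker pixels (fewer foreground pixels), `sensitivity = 0`
#' degenerates to the plain local mean.
#'
#' The window must be wider than the rind: with a window that fits inside the
#' rind annulus, the local mean deep in the rind equals the rind intensity and
#' the interior would not be classified as tissue. The default of half the
#' image's short side is safe for sections that roughly fill the frame.
#'
#' @param g a `gray_image` (or [section_image()]).
#' @param window_fraction window side as a fraction of `min(H, W)`; the pixel
#'   window is `ceiling(window_fraction * min(H, W))`, forced odd. Must be in
#'   (0, 1] and yield a window of at least 3 px.
#' @param sensitivity threshold offset control in `[0, 1]`; see Details.
#' @return a `binary_mask` (`TRUE` = dark tissue); `threshold_used` records
#'   the mean of the per-pixel threshold map.
#' @export
binarize_adaptive <- function(g, window_fraction = 0.5, sensitivity = 0.5) {
  g <- as_gray(g)
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  px <- g$pixels
  win <- as.integer(ceiling(window_fraction * min(dim(px))))
  if (win %% 2L == 0L) win <- win + 1L
  if (win < 3L) stop("adaptive window smaller than 3 px; increase window_fraction")
  thr <- local_mean(px, win) * (1 - 0.3 * sensitivity)
  # <= (not <) so that re-thresholding an already 0/255-rendered mask is the
  # identity even deep inside large dark regions where the local mean is 0
  new_binary_mask(px <= thr, "adaptive", mean(thr))
}
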