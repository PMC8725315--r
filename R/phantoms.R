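#' Specification of a synthetic cross-section phantom
#'
#' A phantom emulates a stained stalk cross-section: a dark (lignified) rind
#' annulus between concentric, co-rotated outer and inner ellipses on a light
#' background, enclosing either a lighter pith carrying dark circular
#' vascular-bundle spots (pith-filled type) or a background-filled lumen
#' (hollow type). Speck clusters of the opposite intensity class (light
#' specks inside the rind, dark specks inside the pith) mimic the unwanted
#' pixel clusters that segmentation reveals in real images, and i.i.d.
#' Gaussian noise exercises the thresholding. Regions are rasterized with
#' hard edges (no anti-aliasing) so pixel-level ground truth is exact.
#'
#' @param plant_type `"pith-filled"` or `"hollow"`.
#' @param outer_semi_axes `c(a, b)` outer ellipse semi-axes in px, `a >= b > 0`.
#' @param inner_semi_axes `c(a_in, b_in)` inner ellipse semi-axes in px,
#'   componentwise smaller than the outer axes.
#' @param rotation ellipse rotation in degrees (counterclockwise in a y-up
#'   frame; the rasterizer works in image coordinates).
#' @param center `(x, y)` center in px; `NULL` = image center.
#' @param n_bundles number of bundle disks (pith-filled only; must be 0 for
#'   hollow phantoms).
#' @param bundle_radius_range `c(min, max)` bundle radius in px.
#' @param bundle_min_separation minimum center-to-center distance in px.
#' @param rind_intensity,pith_intensity,background_intensity,bundle_intensity
#'   mean gray levels (0-255) of the four classes; they must be pairwise
#'   separated by at least `4 * noise_sd` so thresholding is well-posed.
#' @param speck_count number of speck clusters per eligible region (light
#'   specks in the rind; dark specks in the pith for pith-filled phantoms).
#' @param speck_area_range `c(min, max)` speck area in px^2.
#' @param noise_sd standard deviation of the additive Gaussian noise (gray
#'   levels), applied per pixel per channel and clipped to [0, 255].
#' @param image_size `c(width, height)` in px; `NULL` = a square just
#'   containing the outer ellipse plus a 12 px margin.
#' @param px_per_mm spatial calibration carried by the generated image.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(plant_type = "pith-filled",
                         outer_semi_axes = c(300, 260),
                         inner_semi_axes = c(240, 200),
                         rotation = 0,
                         center = NULL,
                         n_bundles = 0,
                         bundle_radius_range = c(6, 9),
                         bundle_min_separation = 24,
                         rind_intensity = 70,
                         pith_intensity = 170,
                         background_intensity = 235,
                         bundle_intensity = 30,
                         speck_count = 0,
                         speck_area_range = c(4, 12),
                         noise_sd = 6,
                         image_size = NULL,
                         px_per_mm = 100) {
  spec <- structure(
    list(plant_type = match_plant_type(plant_type),
         outer_semi_axes = as.numeric(outer_semi_axes),
         inner_semi_axes = as.numeric(inner_semi_axes),
         rotation = as.numeric(rotation),
         center = if (!is.null(center)) as.numeric(center),
         n_bundles = as.integer(n_bundles),
         bundle_radius_range = as.numeric(bundle_radius_range),
         bundle_min_separation = as.numeric(bundle_min_separation),
         rind_intensity = rind_intensity,
         pith_intensity = pith_intensity,
         background_intensity = background_intensity,
         bundle_intensity = bundle_intensity,
         speck_count = as.integer(speck_count),
         speck_area_range = as.numeric(speck_area_range),
         noise_sd = noise_sd,
         image_size = if (!is.null(image_size)) as.integer(image_size),
         px_per_mm = px_per_mm),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  a <- spec$outer_semi_axes[1]; b <- spec$outer_semi_axes[2]
  ai <- spec$inner_semi_axes[1]; bi <- spec$inner_semi_axes[2]
  if (!(a >= b && b > 0)) {
    stop("invalid outer_semi_axes: requires a >= b > 0")
  }
  if (!(ai < a && bi < b && ai > 0 && bi > 0)) {
    stop("invalid inner_semi_axes: requires 0 < a_in < a and 0 < b_in < b")
  }
  ints <- c(rind = spec$rind_intensity, pith = spec$pith_intensity,
            background = spec$background_intensity,
            bundle = spec$bundle_intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  gap <- min(dist(ints))
  if (gap < 4 * spec$noise_sd) {
    stop(sprintf(paste0("class intensities are separated by only %.1f gray levels; ",
                        "need >= 4 * noise_sd = %.1f for well-posed thresholding"),
                 gap, 4 * spec$noise_sd))
  }
  if (spec$plant_type == "hollow" && spec$n_bundles > 0) {
    stop("hollow phantoms have no pith: n_bundles must be 0")
  }
  if (spec$n_bundles < 0) stop("n_bundles must be >= 0")
  if (spec$n_bundles > 0) {
    rr <- spec$bundle_radius_range
    if (!(rr[1] > 0 && rr[1] <= rr[2])) {
      stop("invalid bundle_radius_range: requires 0 < min <= max")
    }
    if (spec$bundle_min_separation <= 0) {
      stop("bundle_min_separation must be > 0")
    }
  }
  if (spec$speck_count > 0) {
    sr <- spec$speck_area_range
    if (!(sr[1] > 0 && sr[1] <= sr[2])) {
      stop("invalid speck_area_range: requires 0 < min <= max")
    }
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$px_per_mm <= 0) stop("px_per_mm must be > 0")
  if (!is.null(spec$image_size)) {
    need <- 2 * (a + 10)
    if (spec$image_size[1] < need || spec$image_size[2] < need) {
      stop(sprintf("image_size must contain the outer ellipse plus a 10 px margin (need >= %d px)",
                   ceiling(need)))
    }
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, outer (%g, %g) px, inner (%g, %g) px, rot %g deg, %d bundles\n",
              x$plant_type, x$outer_semi_axes[1], x$outer_semi_axes[2],
              x$inner_semi_axes[1], x$inner_semi_axes[2], x$rotation,
              x$n_bundles))
  invisible(x)
}

# pixel-center mask of a rotated ellipse (0-based coordinates)
ellipse_mask <- function(W, H, center, semi_axes, rotation_deg) {
  phi <- rotation_deg * pi / 180
  x <- (0:(W - 1)) - center[1]
  y <- (0:(H - 1)) - center[2]
  X <- matrix(x, nrow = H, ncol = W, byrow = TRUE)
  Y <- matrix(y, nrow = H, ncol = W)
  u <- (X * cos(phi) + Y * sin(phi)) / semi_axes[1]
  v <- (-X * sin(phi) + Y * cos(phi)) / semi_axes[2]
  u * u + v * v <= 1
}

# set a filled disk to TRUE, rasterizing only its local bounding box
stamp_disk <- function(mask, center, radius) {
  H <- nrow(mask); W <- ncol(mask)
  xs <- max(0, floor(center[1] - radius - 1)):min(W - 1, ceiling(center[1] + radius + 1))
  ys <- max(0, floor(center[2] - radius - 1)):min(H - 1, ceiling(center[2] + radius + 1))
  Xl <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - center[1]
  Yl <- matrix(ys, nrow = length(ys), ncol = length(xs)) - center[2]
  inside <- Xl * Xl + Yl * Yl <= radius * radius
  sub <- mask[ys + 1L, xs + 1L, drop = FALSE]
  sub[inside] <- TRUE
  mask[ys + 1L, xs + 1L] <- sub
  mask
}

# radius of a centered ellipse along direction theta (world angle), for the
# axis-endpoint diameter ground truth
ellipse_radius_at <- function(theta, a, b, rotation_deg) {
  d <- theta - rotation_deg * pi / 180
  1 / sqrt((cos(d) / a)^2 + (sin(d) / b)^2)
}

#' Mean gap between concentric ellipses (analytic ground truth)
#'
#' Numerically computes the mean over the outer ellipse (uniform in arc
#' length) of the shortest distance to the inner ellipse, by dense sampling
#' of the continuous curves. Used as the rind-thickness ground truth for
#' elliptical phantoms; for circles it reduces to `R_out - R_in`.
#'
#' @param a,b outer semi-axes (px).
#' @param a_in,b_in inner semi-axes (px).
#' @param n_outer,n_inner sample counts.
#' @return mean gap in px.
#' @export
ellipse_ring_mean_gap <- function(a, b, a_in, b_in,
                                  n_outer = 800, n_inner = 6000) {
  th <- seq(0, 2 * pi, length.out = 8 * n_outer + 1)[-1]
  px <- a * cos(th); py <- b * sin(th)
  seglen <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
  s <- cumsum(seglen)
  # resample uniformly in arc length
  target <- seq(0, s[length(s)], length.out = n_outer + 1)[-1]
  idx <- findInterval(target, s) + 1
  idx[idx > length(th)] <- length(th)
  ox <- px[idx]; oy <- py[idx]
  ti <- seq(0, 2 * pi, length.out = n_inner + 1)[-1]
  ix <- a_in * cos(ti); iy <- b_in * sin(ti)
  # min distance outer-sample -> inner-sample, chunked to bound memory
  out <- numeric(length(ox))
  chunk <- 100
  for (k in seq(1, length(ox), by = chunk)) {
    kk <- k:min(k + chunk - 1, length(ox))
    d2 <- outer(ox[kk], ix, "-")^2 + outer(oy[kk], iy, "-")^2
    out[kk] <- sqrt(apply(d2, 1, min))
  }
  mean(out)
}

# rejection-sample n points inside the placement ellipse with pairwise
# minimum separation; error after max_tries total draws
place_bundle_centers <- function(n, center, place_axes, rotation_deg, min_sep,
                                 max_tries = 10000) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  if (any(place_axes <= 0)) {
    stop("bundles do not fit: pith too small for the requested bundle radius")
  }
  phi <- rotation_deg * pi / 180
  pts <- matrix(NA_real_, nrow = n, ncol = 2)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(paste0("failed to place %d bundles with separation %.1f px ",
                          "after %d draws; reduce n_bundles or bundle_min_separation"),
                   n, min_sep, max_tries))
    }
    # uniform in the placement ellipse via unit-disk sampling
    r <- sqrt(runif(1)); t <- runif(1, 0, 2 * pi)
    u <- r * cos(t) * place_axes[1]; v <- r * sin(t) * place_axes[2]
    x <- center[1] + u * cos(phi) - v * sin(phi)
    y <- center[2] + u * sin(phi) + v * cos(phi)
    if (got > 0) {
      d2 <- (pts[seq_len(got), 1] - x)^2 + (pts[seq_len(got), 2] - y)^2
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- c(x, y)
  }
  pts
}

# draw one random small ellipse ("speck") entirely inside host_ok (a logical
# matrix of eligible pixels, already eroded so that specks cannot touch the
# host region's boundary); returns pixel indices or NULL if placement failed
sample_speck_pixels <- function(host_ok, area_range, max_tries = 200) {
  H <- nrow(host_ok); W <- ncol(host_ok)
  eligible <- which(host_ok)
  if (length(eligible) == 0) return(NULL)
  for (i in seq_len(max_tries)) {
    A <- runif(1, area_range[1], area_range[2])
    asp <- runif(1, 1, 2)
    s1 <- sqrt(A * asp / pi); s2 <- sqrt(A / (asp * pi))
    th <- runif(1, 0, pi)
    ctr_idx <- eligible[sample.int(length(eligible), 1)]
    cy <- (ctr_idx - 1L) %% H; cx <- (ctr_idx - 1L) %/% H
    ext <- ceiling(s1) + 1L
    xs <- max(0, cx - ext):min(W - 1, cx + ext)
    ys <- max(0, cy - ext):min(H - 1, cy + ext)
    Xl <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
    Yl <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
    u <- (Xl * cos(th) + Yl * sin(th)) / s1
    v <- (-Xl * sin(th) + Yl * cos(th)) / s2
    inside <- u * u + v * v <= 1
    if (!any(inside)) next
    rows <- (Yl + cy)[inside] + 1L
    cols <- (Xl + cx)[inside] + 1L
    lin <- rows + (cols - 1L) * H
    if (all(host_ok[lin])) return(lin)
  }
  NULL
}

# erode a logical mask by one pixel (8-neighborhood), cheaply in R
erode1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- p[2:(H + 1), 2:(W + 1)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & p[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  out
}

#' Generate a synthetic phantom with exact ground truth
#'
#' Rasterizes the phantom described by `spec` (see [phantom_spec()]) and
#' returns it together with the analytically known phenotypes. Identical
#' `(spec, seed)` pairs yield bit-identical images; the caller's RNG state is
#' left untouched.
#'
#' Ground truth: the Feret diameters of an ellipse are `2a` and `2b`
#' regardless of rotation; the axis-endpoint chord lengths follow from the
#' ellipse radius along the image axes; the rind thickness is the mean
#' shortest gap between the continuous outer and inner ellipses
#' ([ellipse_ring_mean_gap()]); areas are `pi * a * b`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with elements `image` (a [section_image()]) and `truth`
#'   (class `ground_truth`): `true_major_d`, `true_minor_d`,
#'   `true_axis_major_d`, `true_axis_minor_d`, `true_rind_thickness` (mm),
#'   `true_bundle_count`, `true_bundle_centers` (px), `true_whole_area`,
#'   `true_inner_area` (mm^2).
#' @export
make_phantom <- function(spec, seed) {
  validate_phantom_spec(spec)
  withr::with_seed(as.integer(seed), make_phantom_impl(spec, seed))
}

make_phantom_impl <- function(spec, seed) {
  a <- spec$outer_semi_axes[1]; b <- spec$outer_semi_axes[2]
  ai <- spec$inner_semi_axes[1]; bi <- spec$inner_semi_axes[2]
  size <- spec$image_size
  if (is.null(size)) {
    side <- as.integer(ceiling(2 * (a + 12)))
    size <- c(side, side)
  }
  W <- size[1]; H <- size[2]
  center <- spec$center
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)

  outer <- ellipse_mask(W, H, center, c(a, b), spec$rotation)
  inner <- ellipse_mask(W, H, center, c(ai, bi), spec$rotation)
  rind <- outer & !inner

  canvas <- matrix(spec$background_intensity, H, W)
  canvas[rind] <- spec$rind_intensity
  if (spec$plant_type == "pith-filled") {
    canvas[inner] <- spec$pith_intensity
  }  # hollow: lumen keeps the background intensity

  # vascular bundle disks, rejection-placed strictly inside the pith
  bundle_mask <- matrix(FALSE, H, W)
  centers <- matrix(numeric(0), ncol = 2)
  if (spec$n_bundles > 0) {
    rr <- spec$bundle_radius_range
    radii <- runif(spec$n_bundles, rr[1], rr[2])
    margin <- max(radii) + 2
    centers <- place_bundle_centers(
      spec$n_bundles, center, c(ai - margin, bi - margin), spec$rotation,
      spec$bundle_min_separation)
    for (i in seq_len(spec$n_bundles)) {
      bundle_mask <- stamp_disk(bundle_mask, centers[i, ], radii[i])
    }
    canvas[bundle_mask] <- spec$bundle_intensity
  }

  # speck clusters: light specks inside the rind and, for pith-filled
  # phantoms, dark specks inside the pith; specks are kept one pixel clear of
  # region boundaries and of bundles so they are exactly removable
  if (spec$speck_count > 0) {
    rind_ok <- erode1(rind)
    for (i in seq_len(spec$speck_count)) {
      lin <- sample_speck_pixels(rind_ok, spec$speck_area_range)
      if (!is.null(lin)) canvas[lin] <- spec$background_intensity
    }
    if (spec$plant_type == "pith-filled") {
      pith_ok <- erode1(inner & !bundle_mask)
      if (spec$n_bundles > 0) pith_ok <- pith_ok & !dilate1(bundle_mask)
      for (i in seq_len(spec$speck_count)) {
        lin <- sample_speck_pixels(pith_ok, spec$speck_area_range)
        if (!is.null(lin)) canvas[lin] <- spec$bundle_intensity
      }
    }
  }

  # per-channel noise, assembled channelwise to keep peak memory low
  px <- array(0L, dim = c(H, W, 3))
  for (k in 1:3) {
    ch <- if (spec$noise_sd > 0) canvas + rnorm(length(canvas), 0, spec$noise_sd) else canvas
    ch <- round(ch)
    ch[ch < 0] <- 0
    ch[ch > 255] <- 255
    px[, , k] <- ch
  }

  ppm <- spec$px_per_mm
  truth <- structure(list(
    true_major_d = 2 * a / ppm,
    true_minor_d = 2 * b / ppm,
    true_axis_major_d = NA_real_,
    true_axis_minor_d = NA_real_,
    true_rind_thickness = ellipse_ring_mean_gap(a, b, ai, bi) / ppm,
    true_bundle_count = spec$n_bundles,
    true_bundle_centers = centers,
    true_whole_area = pi * a * b / ppm^2,
    true_inner_area = pi * ai * bi / ppm^2,
    plant_type = spec$plant_type,
    px_per_mm = ppm,
    seed = as.integer(seed)
  ), class = "ground_truth")
  hx <- 2 * ellipse_radius_at(0, a, b, spec$rotation) / ppm
  vx <- 2 * ellipse_radius_at(pi / 2, a, b, spec$rotation) / ppm
  truth$true_axis_major_d <- max(hx, vx)
  truth$true_axis_minor_d <- min(hx, vx)

  img <- section_image(px, id = sprintf("phantom_seed%d", as.integer(seed)),
                       plant_type = spec$plant_type,
                       calibration = calibration(ppm))
  list(image = img, truth = truth)
}

dilate1 <- function(m) !erode1(!m)

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> major %.3f mm, minor %.3f mm, rind %.4f mm, %d bundles\n",
              x$true_major_d, x$true_minor_d, x$true_rind_thickness,
              x$true_bundle_count))
  invisible(x)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 31 + as.numeric(i) * 7919) %% 2147483647)
}

#' Generate a seeded batch of phantoms with parameter jitter
#'
#' Draws `n` phantom specs by jittering `base_spec` within the requested
#' ranges (uniformly, from a seeded generator) and renders each with a
#' deterministically derived sub-seed. With zero jitter and `n = 1` the
#' result is identical to `make_phantom(base_spec, derive_seed(seed, 1))`.
#'
#' Supported jitter entries (each a `c(lo, hi)` range):
#' \describe{
#'   \item{`scale`}{multiplies outer and inner semi-axes (and bundle radii
#'     and separation) jointly.}
#'   \item{`aspect`}{outer axis ratio `b/a`; inner axes are rebuilt to keep
#'     the rind thickness profile, via `rind_frac` if given, else scaled.}
#'   \item{`rind_frac`}{rind thickness as a fraction of the outer semi-minor
#'     axis; rebuilds the inner axes as `(a - f*b, b - f*b)`.}
#'   \item{`rotation`}{degrees.}
#'   \item{`n_bundles`}{integer range (inclusive).}
#'   \item{`noise_sd`}{gray levels.}
#' }
#'
#' @param base_spec a [phantom_spec()].
#' @param n number of phantoms (>= 1).
#' @param jitter named list of ranges, see Details; empty list = no jitter.
#' @param seed integer seed.
#' @return list of `n` elements, each a `list(image, truth, spec)`.
#' @export
make_batch <- function(base_spec, n, jitter = list(), seed) {
  stopifnot(inherits(base_spec, "phantom_spec"), n >= 1)
  known <- c("scale", "aspect", "rind_frac", "rotation", "n_bundles", "noise_sd")
  bad <- setdiff(names(jitter), known)
  if (length(bad) > 0) stop("unknown jitter entries: ", paste(bad, collapse = ", "))
  for (nm in names(jitter)) {
    r <- jitter[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("invalid jitter range for '", nm, "': need c(lo, hi) with lo <= hi")
    }
  }
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      sp <- base_spec
      draw <- function(nm) runif(1, jitter[[nm]][1], jitter[[nm]][2])
      if (!is.null(jitter$scale)) {
        s <- draw("scale")
        sp$outer_semi_axes <- sp$outer_semi_axes * s
        sp$inner_semi_axes <- sp$inner_semi_axes * s
        sp$bundle_radius_range <- sp$bundle_radius_range * s
        sp$bundle_min_separation <- sp$bundle_min_separation * s
        sp$image_size <- NULL
      }
      if (!is.null(jitter$aspect)) {
        asp <- draw("aspect")
        a <- sp$outer_semi_axes[1]
        ratio_in <- sp$inner_semi_axes[2] / sp$outer_semi_axes[2]
        sp$outer_semi_axes[2] <- a * asp
        sp$inner_semi_axes[2] <- sp$outer_semi_axes[2] * ratio_in
        sp$image_size <- NULL
      }
      if (!is.null(jitter$rind_frac)) {
        f <- draw("rind_frac")
        t <- f * sp$outer_semi_axes[2]
        sp$inner_semi_axes <- sp$outer_semi_axes - t
      }
      if (!is.null(jitter$rotation)) sp$rotation <- draw("rotation")
      if (!is.null(jitter$n_bundles)) {
        r <- jitter$n_bundles
        sp$n_bundles <- as.integer(r[1] + sample.int(r[2] - r[1] + 1L, 1) - 1L)
      }
      if (!is.null(jitter$noise_sd)) sp$noise_sd <- draw("noise_sd")
      validate_phantom_spec(sp)
      sp
    })
  })
  lapply(seq_len(n), function(i) {
    out <- make_phantom(specs[[i]], derive_seed(seed, i))
    out$spec <- specs[[i]]
    out
  })
}

#' Write a phantom image and its ground-truth sidecar
#'
#' The image goes to `<basename>.tif` (8-bit RGB TIFF) and the ground truth
#' to `<basename>.json`.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @param basename file basename without extension.
#' @return named character vector with the two paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, basename) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(basename, ".tif"))
  json_path <- file.path(dir, paste0(basename, ".json"))
  write_image(phantom$image, img_path)
  tr <- phantom$truth
  tr$true_bundle_centers <- unname(tr$true_bundle_centers)
  jsonlite::write_json(unclass(tr), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, truth = json_path))
}

#' Study-condition specs for the phantom recovery sweep
#'
#' Builds the seeded set of phantom specifications used to validate the whole
#' measurement pipeline: outer diameters spanning 2-20 mm at 80 px/mm, rind
#' thickness 10-35% of the semi-minor axis, aspect ratios 0.8-1, random
#' rotations, speck noise on, and bundle counts up to `max_bundles` for the
#' pith-filled fraction (capped by a packing-density bound so that rejection
#' placement at the required separation is well-posed). Bundle radii scale
#' with the section (4-5% of the outer semi-major axis, at least 4 px) and
#' the minimum separation is `2 * max_radius + 5` px, so planted bundles are
#' always resolvable as distinct components.
#'
#' @param n number of phantoms.
#' @param seed integer seed.
#' @param hollow_fraction fraction of hollow (bundle-free) phantoms.
#' @param max_bundles largest bundle count to draw.
#' @param px_per_mm calibration.
#' @return list of [phantom_spec()]s.
#' @export
phantom_sweep_specs <- function(n = 50, seed = 1, hollow_fraction = 0.3,
                                max_bundles = 40, px_per_mm = 80) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      hollow <- (i / n) <= hollow_fraction  # deterministic mix
      a <- runif(1, 1, 10) * px_per_mm  # semi-major axis 1..10 mm
      b <- a * runif(1, 0.8, 1)
      f <- runif(1, 0.10, 0.35)
      t <- f * b
      rot <- runif(1, 0, 180)
      r_max <- max(4, 0.05 * a); r_min <- max(4, 0.04 * a)
      sep <- 2 * r_max + 5
      nb <- 0L
      if (!hollow) {
        place <- pi * max(0, (a - t) - r_max - 2) * max(0, (b - t) - r_max - 2)
        cap <- floor(0.5 * place / sep^2)
        nb <- as.integer(sample.int(min(max_bundles, cap) + 1L, 1) - 1L)
      }
      phantom_spec(
        plant_type = if (hollow) "hollow" else "pith-filled",
        outer_semi_axes = c(a, b),
        inner_semi_axes = c(a - t, b - t),
        rotation = rot,
        n_bundles = nb,
        bundle_radius_range = c(r_min, r_max),
        bundle_min_separation = sep,
        speck_count = 15,
        px_per_mm = px_per_mm)
    })
  })
}
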