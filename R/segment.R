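#' Label connected components of a binary mask
#'
#' Deterministic flood-fill labeling; labels are assigned in raster order of
#' each component's first pixel. Foreground uses 8-connectivity and holes
#' (background components) 4-connectivity by convention throughout the
#' package, the standard complementary pairing.
#'
#' @param mask logical matrix or `binary_mask`.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- mask_pixels(mask)
  stopifnot(is.logical(m), connectivity %in% c(4, 8))
  cc_label_cpp(m, as.integer(connectivity))
}

# labels of background components that touch the image border
border_labels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  v <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  v[v != 0]
}

#' Fill enclosed holes up to a size limit
#'
#' Background components (4-connected) fully enclosed by foreground and with
#' area at most `max_area_px` become foreground. The size gate protects true
#' anatomy (the pith or lumen) while clearing the small bright speck clusters
#' that segmentation reveals inside the rind. Foreground never shrinks.
#'
#' @param mask logical matrix or `binary_mask`.
#' @param max_area_px fill holes of at most this many pixels; 0 is the
#'   identity, `Inf` fills every enclosed hole.
#' @return logical matrix.
#' @export
fill_holes <- function(mask, max_area_px) {
  m <- mask_pixels(mask)
  stopifnot(max_area_px >= 0)
  if (max_area_px == 0 || !any(m) || all(m)) return(m)
  lab <- cc_label_cpp(!m, 4L)
  nlab <- max(lab)
  if (nlab == 0) return(m)
  sizes <- tabulate(lab, nbins = nlab)
  fill <- rep(TRUE, nlab)
  fill[border_labels(lab)] <- FALSE
  fill[sizes > max_area_px] <- FALSE
  if (any(fill)) m[c(FALSE, fill)[lab + 1L]] <- TRUE  # label 0 = keep
  m
}

#' Remove small foreground specks
#'
#' Foreground components (8-connected) with area at most `max_area_px` are
#' cleared, removing the small dark speck clusters in the pith without
#' touching real structures. Foreground never grows.
#'
#' @inheritParams fill_holes
#' @param max_area_px remove components of at most this many pixels; 0 is the
#'   identity.
#' @return logical matrix.
#' @export
remove_specks <- function(mask, max_area_px) {
  m <- mask_pixels(mask)
  stopifnot(max_area_px >= 0)
  if (max_area_px == 0 || !any(m)) return(m)
  lab <- cc_label_cpp(m, 8L)
  sizes <- tabulate(lab, nbins = max(lab))
  drop <- sizes <= max_area_px
  if (any(drop)) m[c(FALSE, drop)[lab + 1L]] <- FALSE  # label 0 = keep
  m
}

#' Morphological opening by a disc
#'
#' Erosion followed by dilation with a disc structuring element of the given
#' radius; radius 0 is the identity. Off by default in the pipeline because
#' opening shrinks boundary detail and would bias diameters; area-gated speck
#' removal and hole filling preserve dimensions instead.
#'
#' @inheritParams fill_holes
#' @param radius_px disc radius in pixels (>= 0).
#' @return logical matrix.
#' @export
open_mask <- function(mask, radius_px) {
  m <- mask_pixels(mask)
  stopifnot(radius_px >= 0)
  if (radius_px == 0) return(m)
  kern <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  EBImage::opening(m * 1, kern) > 0.5
}

#' Smoothing parameters
#'
#' Speck and hole limits are fractions of the whole-section area so that the
#' same settings transfer across image resolutions.
#'
#' @param speck_area_frac maximum removed-speck area as a fraction of the
#'   whole-section area (in `[0, 0.05]`).
#' @param hole_area_frac maximum filled-hole area as a fraction of the
#'   whole-section area (in `[0, 0.05]`).
#' @param opening_radius disc radius in px for an optional final opening
#'   (0 = off, the default).
#' @return object of class `smoothing_params`.
#' @export
smoothing_params <- function(speck_area_frac = 0.001, hole_area_frac = 0.001,
                             opening_radius = 0) {
  if (speck_area_frac < 0 || speck_area_frac > 0.05 ||
      hole_area_frac < 0 || hole_area_frac > 0.05) {
    stop("area fractions must lie in [0, 0.05]")
  }
  if (opening_radius < 0) stop("opening_radius must be >= 0")
  structure(list(speck_area_frac = speck_area_frac,
                 hole_area_frac = hole_area_frac,
                 opening_radius = opening_radius),
            class = "smoothing_params")
}

#' Apply the full smoothing pipeline to a binary mask
#'
#' Converts the area fractions of `params` to pixel limits using
#' `reference_area_px` (by default the filled area of the largest foreground
#' component, a provisional estimate of the whole-section support), then
#' removes specks, fills small holes and optionally opens. Idempotent.
#'
#' @param mask logical matrix or `binary_mask`.
#' @param params a [smoothing_params()].
#' @param reference_area_px whole-section area in px used to scale the
#'   fractions; computed from the mask when `NULL`.
#' @return logical matrix.
#' @export
smooth_mask <- function(mask, params = smoothing_params(),
                        reference_area_px = NULL) {
  m <- mask_pixels(mask)
  if (is.null(reference_area_px)) {
    reference_area_px <- provisional_section_area(m)
  }
  m <- remove_specks(m, params$speck_area_frac * reference_area_px)
  m <- fill_holes(m, params$hole_area_frac * reference_area_px)
  if (params$opening_radius > 0) m <- open_mask(m, params$opening_radius)
  m
}

# filled area of the largest foreground component
provisional_section_area <- function(m) {
  lab <- cc_label_cpp(m, 8L)
  if (max(lab) == 0) return(0)
  sizes <- tabulate(lab, nbins = max(lab))
  big <- lab == which.max(sizes)
  sum(fill_holes(big, Inf))
}

#' Segment the whole-section and pith/lumen regions
#'
#' Splits a binarized section into its two regions. The whole cross-section
#' is the largest foreground component with all enclosed holes filled. The
#' inner region is the largest enclosed hole of that component: the pith
#' support for pith-filled sections (with dark bundle islands filled back in)
#' or the lumen for hollow sections. Both masks are single components.
#'
#' @param mask logical matrix or `binary_mask` (foreground = dark tissue).
#' @param plant_type `"pith-filled"` or `"hollow"`.
#' @return object of class `segmented_section` with elements `whole_mask`,
#'   `inner_mask` (logical matrices), `plant_type` and `areas_px`
#'   (named vector: whole, inner).
#' @export
segment_regions <- function(mask, plant_type = "pith-filled") {
  plant_type <- match_plant_type(plant_type)
  m <- mask_pixels(mask)
  lab <- cc_label_cpp(m, 8L)
  if (max(lab) == 0) stop("mask has no foreground component")
  sizes <- tabulate(lab, nbins = max(lab))
  main <- lab == which.max(sizes)
  bg <- cc_label_cpp(!main, 4L)
  hole_ids <- setdiff(seq_len(max(bg)), border_labels(bg))
  if (length(hole_ids) == 0) {
    stop("no enclosed pith/lumen hole found in the main component; ",
         "review the threshold settings (the ",
         if (plant_type == "hollow") "ring may be broken" else "pith may be merged with the rind",
         ")")
  }
  hole_sizes <- tabulate(bg, nbins = max(bg))[hole_ids]
  inner <- bg == hole_ids[which.max(hole_sizes)]
  # interpret the hole as the region support: fill enclosed islands
  # (vascular bundles inside the pith)
  inner <- fill_holes(inner, Inf)
  whole <- main | inner
  whole <- fill_holes(whole, Inf)  # also fill any smaller enclosed holes
  areas <- c(whole = sum(whole), inner = sum(inner))
  if (areas["inner"] <= 0 || areas["whole"] <= areas["inner"]) {
    stop("degenerate segmentation: whole area must exceed inner area > 0")
  }
  structure(list(whole_mask = whole, inner_mask = inner,
                 plant_type = plant_type, areas_px = areas),
            class = "segmented_section")
}

#' @export
print.segmented_section <- function(x, ...) {
  cat(sprintf("<segmented_section> %s: whole %d px, inner %d px (ratio %.3f)\n",
              x$plant_type, x$areas_px["whole"], x$areas_px["inner"],
              x$areas_px["inner"] / x$areas_px["whole"]))
  invisible(x)
}
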