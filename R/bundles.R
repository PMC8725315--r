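new_bundle_set <- function(bundles, merged_candidates = list(), pith_mask = NULL) {
  ids <- vapply(bundles, function(b) b$id, integer(1))
  if (anyDuplicated(ids)) stop("bundle ids must be unique")
  structure(list(bundles = bundles, count = length(bundles),
                 merged_candidates = merged_candidates, pith_mask = pith_mask),
            class = "bundle_set")
}

#' @export
print.bundle_set <- function(x, ...) {
  prov <- vapply(x$bundles, function(b) b$provenance, character(1))
  cat(sprintf("<bundle_set> %d bundles (%d auto, %d manual), %d merged-cluster candidates\n",
              x$count, sum(prov == "auto"), sum(prov == "manual"),
              length(x$merged_candidates)))
  invisible(x)
}

#' Detect vascular bundles inside the pith
#'
#' Vascular bundles appear as dark, roughly circular spots in the stained
#' pith. Foreground components of the binarized image restricted to the pith
#' are filtered by area and circularity (`4 * pi * A / P^2`); each accepted
#' component gets a traced boundary and centroid. Components that are large
#' or irregular enough to be several merged bundles (area above `max_area_px`
#' or circularity below `min_circularity`) are reported separately as
#' merged-cluster candidates for manual resolution via [apply_manual_edits()].
#'
#' @param mask binarized image (logical matrix or `binary_mask`,
#'   foreground = dark tissue), ideally after smoothing.
#' @param pith_mask logical matrix: the pith support from [segment_regions()]
#'   (`inner_mask`).
#' @param min_area_px smallest accepted component area (also the floor for
#'   merged candidates); default 25 px.
#' @param max_area_px largest accepted bundle area; defaults to 2% of the
#'   pith area.
#' @param min_circularity smallest accepted circularity in `[0, 1]`.
#' @return object of class `bundle_set`: `bundles` (list of id, centroid_px,
#'   boundary, area_px, provenance), `count`, `merged_candidates`, and the
#'   pith mask used (kept for validating manual additions).
#' @export
detect_bundles <- function(mask, pith_mask, min_area_px = 25,
                           max_area_px = NULL, min_circularity = 0.3) {
  m <- mask_pixels(mask)
  pith <- mask_pixels(pith_mask)
  if (!any(pith)) stop("empty pith mask")
  if (is.null(max_area_px)) max_area_px <- 0.02 * sum(pith)
  if (!(min_area_px > 0 && min_area_px < max_area_px)) {
    stop("need 0 < min_area_px < max_area_px")
  }
  if (min_circularity < 0 || min_circularity > 1) {
    stop("min_circularity must be in [0, 1]")
  }
  lab <- cc_label_cpp(m & pith, 8L)
  nlab <- max(lab)
  bundles <- list(); merged <- list()
  H <- nrow(m)
  next_id <- 1L
  if (nlab > 0) {
    sizes <- tabulate(lab, nbins = nlab)
    idx_all <- which(lab > 0L)
    lab_of <- lab[idx_all]
    rows_of <- (idx_all - 1L) %% H + 1L
    cols_of <- (idx_all - 1L) %/% H + 1L
    by_lab <- split(seq_along(idx_all), lab_of)
    for (k in seq_len(nlab)) {
      if (sizes[k] < min_area_px) next  # speck-scale, ignore
      sel <- by_lab[[as.character(k)]]
      rr <- rows_of[sel]; cc2 <- cols_of[sel]
      centroid <- c(mean(cc2) - 1, mean(rr) - 1)
      # trace on the cropped bounding box, then shift back to image coords
      r1 <- min(rr); c1 <- min(cc2)
      sub <- lab[r1:max(rr), c1:max(cc2), drop = FALSE] == k
      boundary <- tryCatch(trace_contour(sub), error = function(e) NULL)
      if (!is.null(boundary)) {
        boundary[, 1] <- boundary[, 1] + (c1 - 1L)
        boundary[, 2] <- boundary[, 2] + (r1 - 1L)
      }
      circ <- if (is.null(boundary)) 0 else {
        4 * pi * sizes[k] / polyline_length(boundary, closed = FALSE)^2
      }
      entry <- list(id = next_id, centroid_px = centroid, boundary = boundary,
                    area_px = sizes[k], circularity = circ, provenance = "auto")
      if (sizes[k] <= max_area_px && circ >= min_circularity) {
        bundles[[length(bundles) + 1L]] <- entry
        next_id <- next_id + 1L
      } else {
        entry$id <- NA_integer_
        merged[[length(merged) + 1L]] <- entry
      }
    }
  }
  new_bundle_set(bundles, merged, pith)
}

#' Manual bundle corrections
#'
#' The interactive re-selection step of the original workflow is replaced by
#' a scriptable edit list: bundle ids to remove (typically merged clusters
#' the detector could not resolve) and point locations to add.
#'
#' @param removals integer vector of bundle ids to delete.
#' @param additions two-column (x, y) matrix of pixel locations of manually
#'   identified bundles (may have zero rows).
#' @return object of class `edit_list`.
#' @export
edit_list <- function(removals = integer(0), additions = NULL) {
  if (is.null(additions)) additions <- matrix(numeric(0), ncol = 2)
  additions <- as_xy_matrix(additions)
  removals <- as.integer(removals)
  if (anyDuplicated(removals)) stop("duplicate removal ids")
  structure(list(removals = removals, additions = additions),
            class = "edit_list")
}

#' Read a manual-edit file
#'
#' Plain-text CSV with one edit per line: `remove,<id>` or `add,<x>,<y>`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return an [edit_list()].
#' @export
read_edit_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  removals <- integer(0); additions <- NULL
  for (ln in lines) {
    parts <- trimws(strsplit(ln, ",")[[1]])
    if (parts[1] == "remove" && length(parts) == 2) {
      removals <- c(removals, as.integer(parts[2]))
    } else if (parts[1] == "add" && length(parts) == 3) {
      additions <- rbind(additions, as.numeric(parts[2:3]))
    } else {
      stop("malformed edit line: '", ln, "'")
    }
  }
  edit_list(removals, additions)
}

#' Write a manual-edit file
#'
#' @param edits an [edit_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edit_list <- function(edits, path) {
  stopifnot(inherits(edits, "edit_list"))
  lines <- c(sprintf("remove,%d", edits$removals),
             sprintf("add,%g,%g", edits$additions[, 1], edits$additions[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Apply manual edits to a bundle set
#'
#' Removals are applied before additions; within each class the operation is
#' order-independent. Added bundles are points with provenance `"manual"` and
#' no boundary; they must fall inside the pith mask carried by the bundle
#' set. Unknown removal ids and out-of-pith additions are errors naming the
#' offending entry. The edit is deliberately not idempotent: re-applying the
#' same list fails on the already-removed ids.
#'
#' @param bs a `bundle_set`.
#' @param edits an [edit_list()].
#' @return the edited `bundle_set` with `count` updated.
#' @export
apply_manual_edits <- function(bs, edits) {
  stopifnot(inherits(bs, "bundle_set"), inherits(edits, "edit_list"))
  ids <- vapply(bs$bundles, function(b) b$id, integer(1))
  missing <- setdiff(edits$removals, ids)
  if (length(missing) > 0) {
    stop("removal id(s) not present in bundle set: ",
         paste(missing, collapse = ", "))
  }
  bundles <- bs$bundles[!(ids %in% edits$removals)]
  if (nrow(edits$additions) > 0 && !is.null(bs$pith_mask)) {
    H <- nrow(bs$pith_mask); W <- ncol(bs$pith_mask)
    for (i in seq_len(nrow(edits$additions))) {
      x <- edits$additions[i, 1]; y <- edits$additions[i, 2]
      r <- round(y) + 1L; cc <- round(x) + 1L
      inside <- r >= 1 && r <= H && cc >= 1 && cc <= W && bs$pith_mask[r, cc]
      if (!inside) {
        stop(sprintf("manual addition (%g, %g) lies outside the pith mask", x, y))
      }
    }
  }
  next_id <- if (length(bs$bundles) > 0) {
    max(vapply(bs$bundles, function(b) b$id, integer(1))) + 1L
  } else 1L
  for (i in seq_len(nrow(edits$additions))) {
    bundles[[length(bundles) + 1L]] <- list(
      id = next_id, centroid_px = edits$additions[i, ], boundary = NULL,
      area_px = NA_real_, circularity = NA_real_, provenance = "manual")
    next_id <- next_id + 1L
  }
  new_bundle_set(bundles, bs$merged_candidates, bs$pith_mask)
}

#' Serialize a bundle set to JSON
#'
#' @param bs a `bundle_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bundles <- function(bs, path) {
  stopifnot(inherits(bs, "bundle_set"))
  out <- list(
    count = bs$count,
    bundles = lapply(bs$bundles, function(b) {
      list(id = b$id, centroid_px = as.numeric(b$centroid_px),
           area_px = b$area_px, circularity = b$circularity,
           provenance = b$provenance,
           boundary = if (!is.null(b$boundary)) unname(b$boundary))
    }),
    merged_candidates = lapply(bs$merged_candidates, function(b) {
      list(centroid_px = as.numeric(b$centroid_px), area_px = b$area_px,
           circularity = b$circularity,
           boundary = if (!is.null(b$boundary)) unname(b$boundary))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
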