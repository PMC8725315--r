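#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. Thresholding defaults
#' to the plant-type dispatch of the underlying method (pith-filled sections
#' use local adaptive thresholding, hollow sections global Otsu), which can
#' be overridden explicitly.
#'
#' @param plant_type `"pith-filled"` or `"hollow"`.
#' @param px_per_mm spatial calibration (pixels per millimeter).
#' @param threshold `"auto"`, `"otsu"` or `"adaptive"`.
#' @param adaptive_window,adaptive_sensitivity parameters of
#'   [binarize_adaptive()].
#' @param speck_frac,hole_frac,opening_radius smoothing settings, see
#'   [smoothing_params()].
#' @param diameter_convention `"axis-endpoint"` or `"feret"`.
#' @param detect_bundles run automatic bundle detection (pith-filled only).
#' @param bundle_min_area,bundle_max_area_frac,bundle_min_circ detection
#'   filters, see [detect_bundles()]; `bundle_max_area_frac` is a fraction of
#'   the pith area.
#' @param decimation_tol decimation tolerance in mm for FE-script export.
#' @param output_dir where [run_batch()] writes results; `NULL` = no files.
#' @param write_overlay write a QC overlay PNG per image (batch mode).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(plant_type = "pith-filled",
                            px_per_mm,
                            threshold = c("auto", "otsu", "adaptive"),
                            adaptive_window = 0.5,
                            adaptive_sensitivity = 0.5,
                            speck_frac = 0.001,
                            hole_frac = 0.001,
                            opening_radius = 0,
                            diameter_convention = c("axis-endpoint", "feret"),
                            detect_bundles = TRUE,
                            bundle_min_area = 25,
                            bundle_max_area_frac = 0.02,
                            bundle_min_circ = 0.3,
                            decimation_tol = 0.01,
                            output_dir = NULL,
                            write_overlay = FALSE) {
  cfg <- list(plant_type = match_plant_type(plant_type),
              px_per_mm = px_per_mm,
              threshold = match.arg(threshold),
              adaptive_window = adaptive_window,
              adaptive_sensitivity = adaptive_sensitivity,
              smoothing = smoothing_params(speck_frac, hole_frac, opening_radius),
              diameter_convention = match.arg(diameter_convention),
              detect_bundles = isTRUE(detect_bundles),
              bundle_min_area = bundle_min_area,
              bundle_max_area_frac = bundle_max_area_frac,
              bundle_min_circ = bundle_min_circ,
              decimation_tol = decimation_tol,
              output_dir = output_dir,
              write_overlay = isTRUE(write_overlay))
  calibration(px_per_mm)  # validates
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s, %.6g px/mm, threshold %s, diameters %s\n",
              x$plant_type, x$px_per_mm, x$threshold, x$diameter_convention))
  invisible(x)
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value` (comments with `#`). Recognized keys match
#' the arguments of [pipeline_config()]; values are coerced to the proper
#' type. Keys supplied in `...` override the file.
#'
#' @param path config file path.
#' @param ... overrides passed straight to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_config <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (identical(val, "true") || identical(val, "TRUE")) val <- TRUE
    if (identical(val, "false") || identical(val, "FALSE")) val <- FALSE
    kv[[key]] <- val
  }
  overrides <- list(...)
  kv[names(overrides)] <- overrides
  do.call(pipeline_config, kv)
}

resolve_threshold_method <- function(cfg) {
  if (cfg$threshold != "auto") return(cfg$threshold)
  if (cfg$plant_type == "pith-filled") "adaptive" else "otsu"
}

#' Run the full measurement pipeline on one image
#'
#' Executes read, grayscale conversion, thresholding (dispatched on plant
#' type unless overridden), smoothing, whole/inner segmentation, boundary
#' tracing, diameter and rind-thickness measurement, area computation, bundle
#' detection and manual edits, and assembles a [phenotype_record()].
#' Deterministic for fixed inputs; the measurement path uses no randomness.
#'
#' @param image a file path or a [section_image()].
#' @param config a [pipeline_config()].
#' @param edits optional [edit_list()] of manual bundle corrections.
#' @return a [phenotype_record()] whose attributes `boundaries`, `bundles`,
#'   `segmentation`, `diameters` and `thickness` carry the intermediate
#'   objects for export and overlays.
#' @export
run_single <- function(image, config, edits = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "read"
  result <- tryCatch({
    img <- if (inherits(image, "section_image")) image else {
      read_image(image, plant_type = config$plant_type)
    }
    stage <- "grayscale"
    g <- to_grayscale(img)
    stage <- "threshold"
    method <- resolve_threshold_method(config)
    mask <- switch(method,
      otsu = binarize_otsu(g),
      adaptive = binarize_adaptive(g, config$adaptive_window,
                                   config$adaptive_sensitivity))
    stage <- "smoothing"
    ref_area <- provisional_section_area(mask$pixels)
    m <- smooth_mask(mask$pixels, config$smoothing, ref_area)
    stage <- "segmentation"
    seg <- segment_regions(m, config$plant_type)
    stage <- "boundaries"
    bnd <- trace_boundaries(seg)
    cal <- calibration(config$px_per_mm)
    stage <- "diameters"
    diam <- switch(config$diameter_convention,
      "axis-endpoint" = axis_diameters(bnd, cal),
      feret = feret_diameters(bnd, cal))
    stage <- "rind thickness"
    thick <- rind_thickness(bnd, cal)
    stage <- "areas"
    areas <- region_areas(seg, cal)
    stage <- "bundles"
    bundles <- if (config$plant_type == "pith-filled" && config$detect_bundles) {
      detect_bundles(m & seg$inner_mask, seg$inner_mask,
                     min_area_px = config$bundle_min_area,
                     max_area_px = config$bundle_max_area_frac * seg$areas_px["inner"],
                     min_circularity = config$bundle_min_circ)
    } else {
      # hollow sections: manual counting only; additions validated against
      # the whole-section support
      new_bundle_set(list(), pith_mask = seg$whole_mask)
    }
    if (!is.null(edits)) {
      stage <- "manual edits"
      bundles <- apply_manual_edits(bundles, edits)
    }
    stage <- "record"
    rec <- phenotype_record(
      image_id = img$id,
      major_d_mm = diam$major_mm, minor_d_mm = diam$minor_mm,
      rind_thickness_mm = thick$mean_mm,
      bundle_count = bundles$count,
      whole_area_mm2 = areas["whole_mm2"], inner_area_mm2 = areas["inner_mm2"],
      diameter_convention = config$diameter_convention,
      threshold_method = method)
    attr(rec, "boundaries") <- bnd
    attr(rec, "bundles") <- bundles
    attr(rec, "segmentation") <- seg
    attr(rec, "diameters") <- diam
    attr(rec, "thickness") <- thick
    attr(rec, "image") <- img
    rec
  }, error = function(e) {
    id <- if (inherits(image, "section_image")) image$id else as.character(image)
    stop(sprintf("[%s] stage '%s' failed: %s", id, stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

#' Run the pipeline over a directory of images
#'
#' Processes every TIFF/PNG in lexicographic order. Per-image failures are
#' recorded in the manifest and do not abort the batch. When
#' `config$output_dir` is set, writes `results.csv`, `manifest.json` and
#' (optionally) per-image overlay PNGs there.
#'
#' @param input_dir directory containing section images.
#' @param config a [pipeline_config()].
#' @return list with `results` (data.frame of phenotype records) and
#'   `manifest` (config echo, package version, per-image status).
#' @export
run_batch <- function(input_dir, config) {
  stopifnot(dir.exists(input_dir), inherits(config, "pipeline_config"))
  files <- sort(list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no TIFF/PNG images found in ", input_dir)
  records <- list(); status <- list()
  for (f in files) {
    rec <- tryCatch(run_single(f, config), error = function(e) e)
    if (inherits(rec, "error")) {
      status[[basename(f)]] <- list(status = "failed",
                                    reason = conditionMessage(rec))
    } else {
      status[[basename(f)]] <- list(status = "ok")
      records[[length(records) + 1L]] <- {
        r <- rec
        attributes(r)[c("boundaries", "bundles", "segmentation", "diameters",
                        "thickness", "image")] <- NULL
        r
      }
      if (!is.null(config$output_dir) && config$write_overlay) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        write_overlay(attr(rec, "image"), attr(rec, "boundaries"),
                      attr(rec, "bundles"),
                      attr(rec, "diameters")$endpoints_px,
                      file.path(config$output_dir,
                                paste0(tools::file_path_sans_ext(basename(f)),
                                       "_overlay.png")))
      }
    }
  }
  results <- if (length(records) > 0) do.call(rbind, records) else {
    as.data.frame(setNames(rep(list(character(0)), length(RESULT_COLUMNS)),
                           RESULT_COLUMNS))
  }
  rownames(results) <- NULL
  manifest <- list(
    software = "stalkmorph",
    version = as.character(utils::packageVersion("stalkmorph")),
    config = unclass_config(config),
    images = status)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(config$output_dir, "results.csv"))
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, manifest = manifest)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$smoothing <- unclass(out$smoothing)
  out
}

#' Phantom recovery sweep
#'
#' Renders the seeded study-condition phantoms ([phantom_sweep_specs()]),
#' measures each one with the full pipeline under both diameter conventions,
#' and tabulates measured values against ground truth. This is the package's
#' built-in validation benchmark: on synthetic sections it quantifies the
#' same agreement that caliper comparisons quantify on physical stalks.
#'
#' @param n number of phantoms.
#' @param seed integer seed for the phantom generator.
#' @param specs optional list of [phantom_spec()]s overriding the default
#'   sweep conditions.
#' @return data.frame with one row per phantom: measured and true axis and
#'   Feret diameters, rind thickness, bundle count, areas, and the px/mm
#'   calibration.
#' @export
phantom_recovery_sweep <- function(n = 50, seed = 1, specs = NULL) {
  if (is.null(specs)) specs <- phantom_sweep_specs(n = n, seed = seed)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    ph <- make_phantom(sp, derive_seed(seed, i))
    cfg_axis <- pipeline_config(plant_type = sp$plant_type,
                                px_per_mm = sp$px_per_mm)
    cfg_feret <- pipeline_config(plant_type = sp$plant_type,
                                 px_per_mm = sp$px_per_mm,
                                 diameter_convention = "feret")
    ra <- run_single(ph$image, cfg_axis)
    rf <- run_single(ph$image, cfg_feret)
    tr <- ph$truth
    data.frame(
      phantom = i, plant_type = sp$plant_type, px_per_mm = sp$px_per_mm,
      axis_major = ra$major_d_mm, axis_minor = ra$minor_d_mm,
      feret_major = rf$major_d_mm, feret_minor = rf$minor_d_mm,
      rind = ra$rind_thickness_mm, bundles = ra$bundle_count,
      whole_area = ra$whole_area_mm2, inner_area = ra$inner_area_mm2,
      true_axis_major = tr$true_axis_major_d,
      true_axis_minor = tr$true_axis_minor_d,
      true_feret_major = tr$true_major_d, true_feret_minor = tr$true_minor_d,
      true_rind = tr$true_rind_thickness, true_bundles = tr$true_bundle_count,
      true_whole_area = tr$true_whole_area, true_inner_area = tr$true_inner_area)
  })
  do.call(rbind, rows)
}

#' Export the extracted geometry of one image
#'
#' Runs the pipeline, converts the boundaries and bundles to world
#' coordinates and writes the requested formats.
#'
#' @param image file path or [section_image()].
#' @param config a [pipeline_config()].
#' @param fea,csv,geojson,svg output paths (NULL = skip). The FE script is
#'   decimated at `config$decimation_tol`; neutral formats are exported at
#'   full resolution.
#' @param edits optional [edit_list()].
#' @return the `world_geometry`, invisibly.
#' @export
export_geometry <- function(image, config, fea = NULL, csv = NULL,
                            geojson = NULL, svg = NULL, edits = NULL) {
  rec <- run_single(image, config, edits)
  geom <- to_world(attr(rec, "boundaries"), attr(rec, "bundles"),
                   calibration(config$px_per_mm))
  if (!is.null(fea)) {
    emit_fe_script(decimate_geometry(geom, config$decimation_tol), fea)
  }
  if (!is.null(csv)) export_neutral(geom, "csv", csv)
  if (!is.null(geojson)) export_neutral(geom, "geojson", geojson)
  if (!is.null(svg)) export_neutral(geom, "svg", svg)
  invisible(geom)
}
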