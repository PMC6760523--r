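#' Read and write single-channel grayscale images
#'
#' Lossless grayscale round-trip: TIFF at 8 or 16 bit (the pipeline's
#' native format; bit depth is carried in the file), PNG at 8 bit
#' (16-bit PNG can be read — depth is inferred from the sample values —
#' but not written). RGB or floating-point input is rejected.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth Bit depth override for PNG input (8 or 16).
#' @return `read_image()`: an integer-valued image matrix with a
#'   `bit_depth` attribute. `write_image()`: `path`, invisibly.
#' @export
read_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(img)) != 2)
      stop("unsupported format (expected single-channel grayscale): ", path)
    bd <- attr(img, "bits.per.sample") %||% bit_depth %||% 16L
    out <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2)
      stop("unsupported format (expected single-channel grayscale): ", path)
    bd <- bit_depth %||%
      (if (max(abs(img * 255 - round(img * 255))) < 1e-9) 8L else 16L)
    out <- round(img * (2^bd - 1))
  } else stop("unsupported image format '", ext, "': ", path)
  new_image(out, bd)
}

#' @rdname read_image
#' @param image Integer-valued image matrix (with a `bit_depth` attribute,
#'   else inferred from its range).
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) != 2) stop("only single-channel images are written")
  if (any(image != round(image)))
    stop("unsupported format: floating-point image (quantise first)")
  bd <- image_bit_depth(image)
  maxval <- 2^bd - 1
  if (min(image) < 0 || max(image) > maxval)
    stop("image values exceed the ", bd, "-bit range")
  ext <- tolower(tools::file_ext(path))
  norm <- unclass(image) / maxval
  attr(norm, "bit_depth") <- NULL
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(norm, path, bits.per.sample = bd)
  else if (ext == "png") {
    if (bd != 8L)
      stop("unsupported format: PNG output is 8-bit only; use TIFF for ",
           bd, "-bit images")
    png::writePNG(norm, path)
  } else stop("unsupported image format '", ext, "': ", path)
  invisible(path)
}

#' Read a snap's channel images from a directory
#'
#' Discovers per-channel files named `{snap_id}_{channel}.tif` (or
#' `.tiff`/`.png`) and assembles them into a [snap_set()].
#'
#' @param dir Directory containing the images.
#' @param snap_id Snap identifier (file-name prefix).
#' @param exposure_s Optional named per-channel exposures to record.
#' @return A [snap_set()].
#' @export
read_snap <- function(dir, snap_id, exposure_s = NULL) {
  imgs <- list()
  for (ch in CHANNELS) {
    for (ext in c("tif", "tiff", "png")) {
      p <- file.path(dir, sprintf("%s_%s.%s", snap_id, ch, ext))
      if (file.exists(p)) {
        imgs[[ch]] <- read_image(p)
        break
      }
    }
  }
  if (!length(imgs))
    stop("no channel images found for snap '", snap_id, "' in ", dir)
  snap_set(imgs, exposure_s, snap_id)
}

#' Write snap images to a directory
#'
#' One 16-bit (or 8-bit) grayscale TIFF per channel, named
#' `{snap_id}_{channel}.tif`.
#'
#' @param snap A [snap_set()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_snap <- function(snap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(snap$images))
    write_image(snap$images[[ch]],
                file.path(dir, sprintf("%s_%s.tif", snap$snap_id, ch)))
  invisible(dir)
}

#' Write a count report as CSV
#'
#' Writes `report.csv` (columns `snap_id`, `phenotype`, `count`) and
#' `cells.csv` (one row per detection: `cell_id`, `snap_id`, `phenotype`,
#' `x_px`, `y_px`, `area_px` and the per-channel mean intensities).
#'
#' @param report A [count_report()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "report.csv")
  write.csv(report$per_snap, p1, row.names = FALSE)
  cells <- report$cells
  out <- data.frame(cell_id = seq_len(NROW(cells)))
  if (NROW(cells)) {
    out$snap_id <- cells$snap_id
    out$phenotype <- cells$label
    out$x_px <- cells$centroid_x_px
    out$y_px <- cells$centroid_y_px
    out$area_px <- cells$area_px
    for (ch in CHANNELS) {
      col <- paste0("mean_", ch)
      if (col %in% names(cells)) out[[col]] <- cells[[col]]
    }
  } else {
    out <- data.frame(cell_id = integer(0), snap_id = character(0),
                      phenotype = character(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0))
  }
  p2 <- file.path(dir, "cells.csv")
  write.csv(out, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

rule_fields <- c("label", "required_channels", "excluded_channels",
                 "min_diameter_um", "priority")

#' Read / write phenotype rules as YAML
#'
#' The YAML schema is a top-level `phenotypes:` list whose entries carry
#' `label`, `required_channels`, `excluded_channels`, `min_diameter_um`
#' and `priority`. Unknown keys and duplicate labels are rejected.
#'
#' @param path YAML file path.
#' @return `read_rules()`: a list of [phenotype_rule()].
#' @export
read_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$phenotypes))
    stop("rules YAML error at 'phenotypes': key missing in ", path)
  extra <- setdiff(names(doc), "phenotypes")
  if (length(extra))
    stop("rules YAML error: unknown top-level key(s) ",
         paste(extra, collapse = ", "))
  rules <- lapply(seq_along(doc$phenotypes), function(i) {
    entry <- doc$phenotypes[[i]]
    bad <- setdiff(names(entry), rule_fields)
    if (length(bad))
      stop(sprintf("rules YAML error at 'phenotypes[%d].%s': unknown key",
                   i, bad[1]))
    for (f in c("label", "required_channels", "min_diameter_um"))
      if (is.null(entry[[f]]))
        stop(sprintf("rules YAML error at 'phenotypes[%d].%s': missing",
                     i, f))
    phenotype_rule(entry$label, unlist(entry$required_channels),
                   unlist(entry$excluded_channels) %||% character(),
                   entry$min_diameter_um, entry$priority %||% i)
  })
  labels <- vapply(rules, function(r) r$label, "")
  if (anyDuplicated(labels))
    stop("rules YAML error: duplicate phenotype label '",
         labels[duplicated(labels)][1], "'")
  rules
}

#' @rdname read_rules
#' @param rules List of [phenotype_rule()].
#' @export
write_rules <- function(rules, path) {
  doc <- list(phenotypes = lapply(rules, function(r)
    list(label = r$label,
         required_channels = as.list(r$required_channels),
         excluded_channels = as.list(r$excluded_channels),
         min_diameter_um = r$min_diameter_um, priority = r$priority)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

config_sections <- c("camera", "optics", "simulation", "pipeline",
                     "phenotypes", "autofocus", "mapping", "seed",
                     "output_dir")

#' Read a run configuration from YAML
#'
#' Top-level sections `camera:`, `optics:`, `simulation:`, `pipeline:`,
#' `phenotypes:`, `autofocus:`, `seed:`; unknown keys are rejected, and
#' every omitted value falls back to the instrument defaults (QE 0.79,
#' pixel 2.4 um, sigma 3.30 e-, 4x4 binning, FOV 818 x 547 um at
#' 1368 x 912 px).
#'
#' @param path YAML file path (or `NULL` for all defaults).
#' @return A list with `camera`, `optics`, `simulation`
#'   ([simulation_config()]), `pipeline` ([pipeline_config()]), `rules`,
#'   `autofocus` (a [focus_search_config()] or `NULL`) and `seed`.
#' @export
read_config <- function(path = NULL) {
  doc <- if (is.null(path)) list() else yaml::read_yaml(path)
  extra <- setdiff(names(doc), config_sections)
  if (length(extra))
    stop("config error: unknown top-level key(s) ",
         paste(extra, collapse = ", "))
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(doc[[section]]), allowed)
    if (length(bad))
      stop(sprintf("config error at '%s.%s': unknown key", section, bad[1]))
  }
  check_keys("camera", names(formals(camera_spec)))
  check_keys("optics", names(formals(optics_geometry)))
  check_keys("simulation", setdiff(names(formals(simulation_config)),
                                   c("camera", "optics")))
  check_keys("pipeline", names(formals(pipeline_config)))
  check_keys("autofocus", names(formals(focus_search_config)))
  camera <- do.call(camera_spec, doc$camera %||% list())
  optics_args <- doc$optics %||% list()
  for (f in c("fov_um", "resolution_px"))
    if (!is.null(optics_args[[f]])) optics_args[[f]] <- unlist(optics_args[[f]])
  optics <- do.call(optics_geometry, optics_args)
  sim_args <- doc$simulation %||% list()
  if (!is.null(sim_args$exposure_s)) sim_args$exposure_s <-
      unlist(sim_args$exposure_s)
  sim <- do.call(simulation_config,
                 c(list(camera = camera, optics = optics), sim_args))
  pipe <- do.call(pipeline_config, doc$pipeline %||% list())
  rules <- if (!is.null(doc$phenotypes))
    read_rules_list(doc$phenotypes) else default_rules()
  af <- if (!is.null(doc$autofocus))
    do.call(focus_search_config, doc$autofocus) else NULL
  list(camera = camera, optics = optics, simulation = sim, pipeline = pipe,
       rules = rules, autofocus = af, seed = doc$seed,
       output_dir = doc$output_dir)
}

# rules from an already-parsed YAML list (shared by read_config/read_rules)
read_rules_list <- function(entries) {
  rules <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    phenotype_rule(e$label, unlist(e$required_channels),
                   unlist(e$excluded_channels) %||% character(),
                   e$min_diameter_um, e$priority %||% i)
  })
  labels <- vapply(rules, function(r) r$label, "")
  if (anyDuplicated(labels))
    stop("config error: duplicate phenotype label")
  rules
}

#' Write a colorized panorama or snap overlay as PNG
#'
#' @param rgb H x W x 3 array in \[0, 1\] (from [merge_colorize()]).
#' @param path Output `.png` path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(clamp(rgb, 0, 1), path)
  invisible(path)
}
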