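#' Plan a contiguous tile grid over a sample extent
#'
#' Splits the requested extent into abutting camera fields of view:
#' `cols = ceiling(width / fov_w)`, `rows = ceiling(height / fov_h)`.
#' Stage targets are the tile centres; traversal is serpentine by default
#' (left-to-right on even rows, right-to-left on odd) to minimise stage
#' travel. An extent smaller than one field of view yields a single tile.
#'
#' @param extent_um Length-2 (width, height) of the area to map, um.
#' @param optics An [optics_geometry()].
#' @param origin_um Sample-frame position of the grid's top-left corner.
#' @param serpentine Use serpentine traversal order?
#' @return An object of class `tile_grid`.
#' @examples
#' plan_grid(c(10000, 10000), optics_geometry())  # 13 cols x 19 rows
#' @export
plan_grid <- function(extent_um, optics = optics_geometry(),
                      origin_um = c(0, 0), serpentine = TRUE) {
  stopifnot(length(extent_um) == 2, all(extent_um > 0))
  fov <- optics$fov_um
  cols <- max(1L, as.integer(ceiling(extent_um[1] / fov[1])))
  rows <- max(1L, as.integer(ceiling(extent_um[2] / fov[2])))
  structure(list(origin_um = as.numeric(origin_um), rows = rows, cols = cols,
                 tile_fov_um = fov, serpentine = isTRUE(serpentine)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d rows x %d cols of %.4g x %.4g um tiles%s\n",
              x$rows, x$cols, x$tile_fov_um[1], x$tile_fov_um[2],
              if (x$serpentine) " (serpentine)" else ""))
  invisible(x)
}

#' Stage targets of a tile grid, in traversal order
#'
#' @param grid A [tile_grid()].
#' @return Data frame with `row`, `col` (1-based) and the stage target
#'   `center_x_um`, `center_y_um` of each tile.
#' @export
tile_positions <- function(grid) {
  out <- do.call(rbind, lapply(seq_len(grid$rows), function(r) {
    cs <- seq_len(grid$cols)
    if (grid$serpentine && r %% 2 == 0) cs <- rev(cs)
    data.frame(row = r, col = cs)
  }))
  out$center_x_um <- grid$origin_um[1] + (out$col - 0.5) * grid$tile_fov_um[1]
  out$center_y_um <- grid$origin_um[2] + (out$row - 0.5) * grid$tile_fov_um[2]
  rownames(out) <- NULL
  out
}

#' Stitch grid-indexed tiles into a panorama
#'
#' Pure abutting placement (the instrument relies on stage repeatability,
#' not image registration): tile (r, c) lands at pixel offset
#' `((r-1) * tile_h, (c-1) * tile_w)`; there is no overlap or blending,
#' and the panorama is exactly `(rows * tile_h) x (cols * tile_w)` pixels.
#'
#' @param tiles List of image matrices with identical shape and bit depth;
#'   either named `"r_c"` (e.g. `"2_3"`) or in row-major order.
#' @param rows,cols Grid dimensions (inferred from names if omitted).
#' @param missing `"error"` (default) or `"zero"`-fill for absent tiles.
#' @return An object of class `panorama`: the stitched `image` plus a
#'   `provenance` data frame of tile placements.
#' @export
stitch <- function(tiles, rows = NULL, cols = NULL,
                   missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (is.null(names(tiles))) {
    if (is.null(rows) || is.null(cols))
      stop("unnamed tiles require 'rows' and 'cols'")
    if (length(tiles) != rows * cols && missing == "error")
      stop("expected ", rows * cols, " tiles, got ", length(tiles))
    names(tiles) <- paste(rep(seq_len(rows), each = cols),
                          rep(seq_len(cols), rows),
                          sep = "_")[seq_along(tiles)]
  }
  rc <- do.call(rbind, strsplit(names(tiles), "_"))
  r <- as.integer(rc[, 1]); c <- as.integer(rc[, 2])
  rows <- rows %||% max(r); cols <- cols %||% max(c)
  d <- dim(tiles[[1]])
  for (t in tiles)
    if (!identical(dim(t), d)) stop("inconsistent tile shapes")
  pano <- matrix(0, rows * d[1], cols * d[2])
  present <- matrix(FALSE, rows, cols)
  for (k in seq_along(tiles)) {
    pano[(r[k] - 1) * d[1] + seq_len(d[1]),
         (c[k] - 1) * d[2] + seq_len(d[2])] <- tiles[[k]]
    present[r[k], c[k]] <- TRUE
  }
  if (!all(present) && missing == "error")
    stop("missing tile(s): ",
         paste(apply(which(!present, arr.ind = TRUE), 1, paste,
                     collapse = "_"), collapse = ", "))
  prov <- data.frame(row = r, col = c,
                     y0_px = (r - 1) * d[1], x0_px = (c - 1) * d[2])
  structure(list(image = new_image(pano, image_bit_depth(tiles[[1]])),
                 rows = rows, cols = cols, tile_dim_px = d,
                 provenance = prov),
            class = "panorama")
}

#' @export
print.panorama <- function(x, ...) {
  cat(sprintf("<panorama> %d x %d tiles -> %d x %d px\n", x$rows, x$cols,
              ncol(x$image), nrow(x$image)))
  invisible(x)
}

#' Map a whole synthetic membrane: acquire, focus, classify, stitch
#'
#' Plans a tile grid over the scene, and for each tile optionally
#' autofocuses (brightness search on the blue channel), acquires all four
#' channels with the virtual microscope, and runs the classification
#' pipeline. Per-tile reports are aggregated into membrane totals and the
#' per-channel tiles are stitched into panoramas. Deterministic for a
#' fixed seed.
#'
#' @param scene A [synthetic_scene()].
#' @param rules List of [phenotype_rule()].
#' @param config A [simulation_config()].
#' @param pipeline A [pipeline_config()].
#' @param autofocus `NULL` to image at z = 0, or a [focus_search_config()]
#'   applied per tile.
#' @param noise Render with the camera noise model?
#' @param seed Base seed; per-tile/channel seeds are derived from it.
#' @return A list: `report` ([count_report()] over all tiles), `panorama`
#'   (named list of per-channel [stitch()]ed panoramas), `grid`, and `log`
#'   (one row per tile: position, chosen focus z, counts).
#' @export
run_mapping <- function(scene, rules, config = simulation_config(),
                        pipeline = pipeline_config(), autofocus = NULL,
                        noise = TRUE, seed = config$seed) {
  grid <- plan_grid(scene$extent_um, config$optics)
  pos <- tile_positions(grid)
  optics <- config$optics
  tiles <- lapply(CHANNELS, function(ch) list())
  names(tiles) <- CHANNELS
  report <- NULL
  logs <- NULL
  for (k in seq_len(nrow(pos))) {
    stage_xy <- c(pos$center_x_um[k], pos$center_y_um[k])
    tile_id <- sprintf("tile_%d_%d", pos$row[k], pos$col[k])
    tile_seed <- if (is.null(seed)) NULL else seed + 1000L * k
    z <- 0
    if (!is.null(autofocus)) {
      af_count <- 0L
      res <- autofocus_search(function(zq) {
        af_count <<- af_count + 1L
        virtual_acquire(scene, stage_xy, zq, "blue", config, noise,
                        seed = if (is.null(tile_seed)) NULL
                               else tile_seed + af_count,
                        allow_outside = TRUE)
      }, autofocus)
      z <- res$best_z_um
    }
    imgs <- lapply(seq_along(CHANNELS), function(i) {
      err <- function(e) stop(sprintf("tile (%d, %d), channel %s: %s",
                                      pos$row[k], pos$col[k], CHANNELS[i],
                                      conditionMessage(e)))
      tryCatch(virtual_acquire(scene, stage_xy, z, CHANNELS[i], config,
                               noise,
                               seed = if (is.null(tile_seed)) NULL
                                      else tile_seed + 100L + i,
                               allow_outside = TRUE),
               error = err)
    })
    names(imgs) <- CHANNELS
    snap <- snap_set(imgs, config$exposure_s, tile_id)
    rep_k <- classify_and_count(snap, rules, optics, pipeline)
    report <- if (is.null(report)) rep_k else combine_reports(report, rep_k)
    for (ch in CHANNELS)
      tiles[[ch]][[sprintf("%d_%d", pos$row[k], pos$col[k])]] <- imgs[[ch]]
    cnt <- vapply(names(rep_k$totals), function(p)
      as.integer(rep_k$totals[[p]]), 0L)
    logs <- rbind(logs, data.frame(
      tile = tile_id, row = pos$row[k], col = pos$col[k],
      center_x_um = stage_xy[1], center_y_um = stage_xy[2], focus_z_um = z,
      t(cnt)))
  }
  panos <- lapply(CHANNELS, function(ch)
    stitch(tiles[[ch]], rows = grid$rows, cols = grid$cols))
  names(panos) <- CHANNELS
  list(report = report, panorama = panos, grid = grid, log = logs)
}
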