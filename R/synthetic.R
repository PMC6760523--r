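#' Ground-truth cell for the synthetic membrane
#'
#' One simulated cell with a phenotype, position, diameter, per-channel peak
#' photon flux and the axial position of its focal plane. Emission must be
#' consistent with the phenotype: CTCs emit in blue, green and orange and
#' are dark in red (CD45-negative); WBCs emit in blue and red only; other
#' nucleated blood cells emit only in blue.
#'
#' @param phenotype One of `"CTC"`, `"WBC"`, `"NUCLEATED_OTHER"`.
#' @param center_um Length-2 (x, y) position in micrometres, sample frame
#'   (origin top-left, y downward).
#' @param diameter_um Cell diameter in micrometres (> 0).
#' @param emission Named numeric vector of peak photon flux
#'   (photons um^-2 s^-1) for channels blue, green, orange, red.
#' @param z_um Axial position of the cell's focal plane in micrometres.
#' @return An object of class `ground_truth_cell`.
#' @export
ground_truth_cell <- function(phenotype, center_um, diameter_um, emission,
                              z_um = 0) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  stopifnot(length(center_um) == 2, diameter_um > 0)
  em <- numeric(4); names(em) <- CHANNELS
  em[names(emission)] <- emission
  on_ch <- switch(phenotype,
                  CTC = c("blue", "green", "orange"),
                  WBC = c("blue", "red"),
                  NUCLEATED_OTHER = "blue")
  off_ch <- setdiff(CHANNELS, on_ch)
  if (any(em[on_ch] <= 0))
    stop(sprintf("%s must emit in channel(s): %s", phenotype,
                 paste(on_ch[em[on_ch] <= 0], collapse = ", ")))
  if (any(em[off_ch] != 0))
    stop(sprintf("%s must not emit in channel(s): %s", phenotype,
                 paste(off_ch[em[off_ch] != 0], collapse = ", ")))
  structure(list(phenotype = phenotype, center_um = as.numeric(center_um),
                 diameter_um = diameter_um, emission = em,
                 z_um = z_um),
            class = "ground_truth_cell")
}

# Default per-phenotype peak photon flux (photons um^-2 s^-1). With the
# default per-channel exposures these give peak cell signals of roughly
# 4000-4600 electrons, far above the few-photon noise floor, as for
# brightly immunostained cells.
DEFAULT_PEAK_FLUX <- list(
  CTC = c(blue = 20000, green = 8000, orange = 600, red = 0),
  WBC = c(blue = 20000, green = 0, orange = 0, red = 10000),
  NUCLEATED_OTHER = c(blue = 20000, green = 0, orange = 0, red = 0)
)

# Membrane autofluorescence background (photons um^-2 s^-1): ~9-10
# electrons per pixel at the default exposures.
DEFAULT_BACKGROUND_FLUX <- c(blue = 40, green = 20, orange = 1.5, red = 20)

# Diameter ranges (um) drawn uniformly per phenotype: CTCs are large
# (>= 8 um, retained by the filtration membrane); WBCs and other
# nucleated cells sit comfortably above the 2.5 um counting gate, since
# the recovery studies concern gateable cells, not marginal ones.
DEFAULT_DIAMETER_RANGE <- list(CTC = c(8, 16), WBC = c(6, 12),
                               NUCLEATED_OTHER = c(4, 8))

#' Synthetic membrane scene
#'
#' Container for a ground-truthed synthetic filtering membrane: its extent,
#' cell list and uniform background flux. Usually built with [make_scene()].
#'
#' @param cells List of [ground_truth_cell()] objects.
#' @param extent_um Length-2 (width, height) extent in micrometres.
#' @param background_flux Named per-channel background photon flux.
#' @param seed Seed recorded for provenance (may be `NULL`).
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(cells, extent_um,
                            background_flux = DEFAULT_BACKGROUND_FLUX,
                            seed = NULL) {
  stopifnot(length(extent_um) == 2, all(extent_um > 0))
  bg <- numeric(4); names(bg) <- CHANNELS
  bg[names(background_flux)] <- background_flux
  for (cl in cells) {
    if (any(cl$center_um < 0) || cl$center_um[1] > extent_um[1] ||
        cl$center_um[2] > extent_um[2])
      stop("cell centre outside scene extent")
  }
  structure(list(extent_um = as.numeric(extent_um), cells = cells,
                 background_flux = bg, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  ph <- vapply(x$cells, function(c) c$phenotype, "")
  cat(sprintf("<synthetic_scene> %.4g x %.4g um, %d cells", x$extent_um[1],
              x$extent_um[2], length(x$cells)))
  if (length(ph))
    cat(" (", paste(sprintf("%s: %d", PHENOTYPES,
                            tabulate(factor(ph, PHENOTYPES), 3)),
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Generate a random ground-truthed membrane scene
#'
#' Places the requested number of CTCs, WBCs and other nucleated cells
#' uniformly at random on the membrane, with optional minimum
#' centre-to-centre separation enforced by rejection sampling. Cell
#' diameters are drawn uniformly per phenotype (CTCs 8-16 um, WBCs
#' 5-12 um, others 3-8 um by default) and per-channel brightness varies
#' log-normally around the phenotype's peak flux.
#'
#' @param n_ctc,n_wbc,n_other Cell counts per phenotype (>= 0).
#' @param extent_um Membrane (width, height) in micrometres; defaults to
#'   one camera field of view.
#' @param seed Integer seed; fixed seed gives an identical scene.
#' @param min_sep_um Minimum centre-to-centre distance in micrometres.
#' @param edge_margin_um Margin kept free of cell centres along the border.
#' @param z_spread_um Cell focal planes drawn uniformly in
#'   `[-z_spread_um, z_spread_um]`.
#' @param peak_flux,diameter_range,background_flux Optional overrides of the
#'   per-phenotype defaults.
#' @param flux_sdlog Log-normal sd of per-cell brightness variation.
#' @param max_tries Rejection-sampling retries per cell before giving up.
#' @return A [synthetic_scene()].
#' @examples
#' sc <- make_scene(2, 10, 20, extent_um = c(200, 200), seed = 1)
#' sc
#' @export
make_scene <- function(n_ctc, n_wbc, n_other, extent_um = c(818, 547),
                       seed = NULL, min_sep_um = 0, edge_margin_um = 12,
                       z_spread_um = 0, peak_flux = DEFAULT_PEAK_FLUX,
                       diameter_range = DEFAULT_DIAMETER_RANGE,
                       background_flux = DEFAULT_BACKGROUND_FLUX,
                       flux_sdlog = 0.2, max_tries = 2000) {
  stopifnot(n_ctc >= 0, n_wbc >= 0, n_other >= 0)
  if (any(extent_um <= 2 * edge_margin_um) && (n_ctc + n_wbc + n_other) > 0)
    stop("extent too small for the requested edge margin")
  log_params("make_scene", n_ctc = n_ctc, n_wbc = n_wbc, n_other = n_other,
             extent_um = extent_um, seed = seed %||% NA,
             min_sep_um = min_sep_um)
  phenos <- rep(PHENOTYPES, times = c(n_ctc, n_wbc, n_other))
  with_seed(seed, {
    cells <- vector("list", length(phenos))
    placed <- matrix(numeric(0), ncol = 2)
    lo <- edge_margin_um
    hi <- extent_um - edge_margin_um
    for (k in seq_along(phenos)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        pos <- c(runif(1, lo, hi[1]), runif(1, lo, hi[2]))
        if (min_sep_um <= 0 || nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - pos[1])^2 + (placed[, 2] - pos[2])^2)) >
              min_sep_um) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "could not place cell %d with min_sep_um = %g after %d tries",
          k, min_sep_um, max_tries))
      placed <- rbind(placed, pos)
      ph <- phenos[k]
      dr <- diameter_range[[ph]]
      base <- peak_flux[[ph]]
      em <- base * ifelse(base > 0, exp(rnorm(4, 0, flux_sdlog)), 0)
      names(em) <- CHANNELS
      cells[[k]] <- ground_truth_cell(
        phenotype = ph, center_um = pos,
        diameter_um = runif(1, dr[1], dr[2]), emission = em,
        z_um = if (z_spread_um > 0) runif(1, -z_spread_um, z_spread_um) else 0)
    }
    synthetic_scene(cells, extent_um, background_flux, seed = seed)
  })
}

#' Simulation configuration for the virtual microscope
#'
#' Holds everything the renderer needs besides the scene itself: camera and
#' optics, per-channel exposure times, the defocus model and the stage
#' repeatability. Defocus blur grows linearly with distance from the cell's
#' focal plane: `sigma(z) = defocus_sigma0_um + defocus_slope * |z - z_cell|`.
#'
#' @param camera A [camera_spec()].
#' @param optics An [optics_geometry()].
#' @param exposure_s Named per-channel exposure times in seconds. Defaults
#'   are the four-color acquisition settings (blue 50 ms, green 100 ms,
#'   orange 1.5 s, red 100 ms).
#' @param defocus_sigma0_um In-focus blur sigma in micrometres (> 0).
#' @param defocus_slope Blur growth per micrometre of defocus (>= 0).
#' @param stage_jitter_um Stage positioning error bound per axis: each
#'   acquisition is displaced uniformly within +/- this value, modelling
#'   the stage's bi-directional repeatability (2.2 um for the reference
#'   instrument); 0 disables jitter.
#' @param seed Default seed for renders that are not given one.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(camera = camera_spec(),
                              optics = optics_geometry(),
                              exposure_s = c(blue = 0.05, green = 0.1,
                                             orange = 1.5, red = 0.1),
                              defocus_sigma0_um = 0.5, defocus_slope = 0.3,
                              stage_jitter_um = 0, seed = NULL) {
  stopifnot(defocus_sigma0_um > 0, defocus_slope >= 0, stage_jitter_um >= 0)
  ex <- c(blue = 0.05, green = 0.1, orange = 1.5, red = 0.1)
  ex[names(exposure_s)] <- exposure_s
  structure(list(camera = camera, optics = optics, exposure_s = ex,
                 defocus_sigma0_um = defocus_sigma0_um,
                 defocus_slope = defocus_slope,
                 stage_jitter_um = stage_jitter_um, seed = seed),
            class = "simulation_config")
}

# Normalised 1-D Gaussian kernel, half-width 4 sigma.
gauss_kernel <- function(sigma_px) {
  h <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- exp(-((-h:h)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Band (Toeplitz) convolution matrix of size n for kernel k; implies
# zero padding beyond the patch, which is negligible given the 4-sigma
# patch padding used by the renderer.
conv_band <- function(n, k) {
  h <- (length(k) - 1L) / 2L
  d <- outer(seq_len(n), seq_len(n), "-")
  m <- matrix(0, n, n)
  sel <- abs(d) <= h
  m[sel] <- k[d[sel] + h + 1L]
  m
}

# Noise-free expected-electron image of a window of the scene.
# origin_um is the sample-frame position of the window's top-left corner;
# pixel (row i, col j) (1-based) has its centre at
# origin + ((j - 0.5) * pitch_x, (i - 0.5) * pitch_y).
render_mean_electrons <- function(scene, channel, origin_um, size_px,
                                  pitch_um, z_stage_um, config) {
  cam <- config$camera
  expo <- config$exposure_s[[channel]]
  w <- size_px[1]; h <- size_px[2]
  bg_e <- expected_signal(scene$background_flux[[channel]], cam, expo)
  img <- matrix(bg_e, nrow = h, ncol = w)
  for (cl in scene$cells) {
    flux <- cl$emission[[channel]]
    if (flux <= 0) next
    sig_um <- config$defocus_sigma0_um +
      config$defocus_slope * abs(z_stage_um - cl$z_um)
    r_um <- cl$diameter_um / 2
    # cell centre in 0-based pixel-centre coordinates of this window
    cx <- (cl$center_um[1] - origin_um[1]) / pitch_um[1] - 0.5
    cy <- (cl$center_um[2] - origin_um[2]) / pitch_um[2] - 0.5
    # full (uncropped) patch around the cell, so the blur sees the whole
    # profile even when the window truncates it; cropped after convolving
    half <- ceiling((r_um + 4 * sig_um) / min(pitch_um)) + 2
    jlo <- as.integer(floor(cx)) - half; jhi <- as.integer(ceiling(cx)) + half
    ilo <- as.integer(floor(cy)) - half; ihi <- as.integer(ceiling(cy)) + half
    if (jhi < 0 || jlo > w - 1L || ihi < 0 || ilo > h - 1L) next
    xs <- (jlo:jhi - cx) * pitch_um[1]
    ys <- (ilo:ihi - cy) * pitch_um[2]
    rr2 <- outer(ys^2, xs^2, "+")
    # spherical cell: projected fluorophore column density (chord length)
    prof <- sqrt(pmax(1 - rr2 / r_um^2, 0))
    sig_px_x <- sig_um / pitch_um[1]
    sig_px_y <- sig_um / pitch_um[2]
    if (sig_px_x > 0.05) {
      by <- conv_band(nrow(prof), gauss_kernel(sig_px_y))
      bx <- conv_band(ncol(prof), gauss_kernel(sig_px_x))
      prof <- by %*% prof %*% bx
    }
    amp_e <- expected_signal(flux, cam, expo)
    jj <- max(0L, jlo):min(w - 1L, jhi)
    ii <- max(0L, ilo):min(h - 1L, ihi)
    img[ii + 1L, jj + 1L] <- img[ii + 1L, jj + 1L] +
      amp_e * prof[ii - ilo + 1L, jj - jlo + 1L, drop = FALSE]
  }
  img
}

# Shared sampling contract: Poisson photo-electron statistics (mean = the
# expected signal of the acquisition model) plus Gaussian read/dark noise,
# then gain conversion, rounding and clipping to the digitiser range.
quantize_render <- function(mean_e, config, noise, seed) {
  cam <- config$camera
  e <- if (noise) {
    with_seed(seed, {
      matrix(rpois(length(mean_e), mean_e) +
               rnorm(length(mean_e), 0, cam$camera_noise_e),
             nrow = nrow(mean_e))
    })
  } else mean_e
  new_image(electrons_to_dn(e, cam), cam$bit_depth)
}

#' Render one channel of a scene
#'
#' Renders the full scene extent as one grayscale frame at the optics'
#' object-space pixel pitch. Cells are drawn as spheres of their true
#' diameter projected to the image plane (chord-length radial profile)
#' and convolved with a Gaussian defocus blur whose width grows linearly
#' with the distance between the stage plane and the cell's focal plane;
#' pixel means follow the acquisition signal model, and (when
#' `noise = TRUE`) pixel values carry Poisson shot noise plus Gaussian
#' read/dark noise before quantisation.
#'
#' @param scene A [synthetic_scene()].
#' @param channel One of `"blue"`, `"green"`, `"orange"`, `"red"`.
#' @param config A [simulation_config()].
#' @param z_stage_um Stage axial position in micrometres.
#' @param noise Add shot + camera noise? (`FALSE` gives the quantised
#'   noise-free expectation.)
#' @param seed Seed for the noise draw; defaults to the config's seed.
#' @return An integer-valued image matrix with a `bit_depth` attribute.
#' @export
render_snap <- function(scene, channel, config = simulation_config(),
                        z_stage_um = 0, noise = TRUE, seed = config$seed) {
  channel <- match.arg(channel, CHANNELS)
  pitch <- config$optics$fov_um / config$optics$resolution_px
  size_px <- as.integer(round(scene$extent_um / pitch))
  mean_e <- render_mean_electrons(scene, channel, c(0, 0), size_px, pitch,
                                  z_stage_um, config)
  quantize_render(mean_e, config, noise, seed)
}

#' Render all four channels of a scene as a snap set
#'
#' @inheritParams render_snap
#' @param snap_id Identifier recorded in the resulting [snap_set()].
#' @return A [snap_set()] with one image per channel.
#' @export
render_snap_set <- function(scene, config = simulation_config(),
                            z_stage_um = 0, noise = TRUE,
                            seed = config$seed, snap_id = "snap") {
  imgs <- lapply(seq_along(CHANNELS), function(i)
    render_snap(scene, CHANNELS[i], config, z_stage_um, noise,
                seed = if (is.null(seed)) NULL else seed + i))
  names(imgs) <- CHANNELS
  snap_set(imgs, exposure_s = config$exposure_s, snap_id = snap_id)
}

#' Render a focal stack
#'
#' Renders one channel at `n_steps` equidistant stage positions spanning
#' `z_range_um` inclusive, as an autofocus routine would acquire them.
#'
#' @inheritParams render_snap
#' @param z_range_um Length-2 (z_min, z_max), z_min < z_max.
#' @param n_steps Number of planes (>= 2).
#' @return A list of images with attribute `z_um` giving the plane of each.
#' @export
render_focal_stack <- function(scene, channel, z_range_um, n_steps,
                               config = simulation_config(), noise = TRUE,
                               seed = config$seed) {
  stopifnot(length(z_range_um) == 2)
  if (n_steps < 2) stop("'n_steps' must be >= 2")
  if (z_range_um[2] <= z_range_um[1]) stop("empty z range")
  zs <- seq(z_range_um[1], z_range_um[2], length.out = n_steps)
  stack <- lapply(seq_along(zs), function(i)
    render_snap(scene, channel, config, zs[i], noise,
                seed = if (is.null(seed)) NULL else seed + i))
  attr(stack, "z_um") <- zs
  stack
}

#' Acquire one tile with the virtual microscope
#'
#' Returns the frame an instrument would capture with the stage centred at
#' `stage_xy_um`: a field-of-view-sized window of the scene, optionally
#' displaced by stage-positioning jitter drawn uniformly within
#' +/- `config$stage_jitter_um` per axis. A cell located exactly at the
#' stage position appears at the image centre.
#'
#' @inheritParams render_snap
#' @param stage_xy_um Length-2 stage target (x, y) in micrometres — the
#'   centre of the captured field of view.
#' @param z_um Stage axial position in micrometres.
#' @param allow_outside Permit tiles extending beyond the scene extent
#'   (the overhang images plain background).
#' @return An image matrix, `config$optics$resolution_px` in size.
#' @export
virtual_acquire <- function(scene, stage_xy_um, z_um, channel,
                            config = simulation_config(), noise = TRUE,
                            seed = config$seed, allow_outside = FALSE) {
  channel <- match.arg(channel, CHANNELS)
  fov <- config$optics$fov_um
  origin <- stage_xy_um - fov / 2
  eps <- 1e-9
  if (!allow_outside &&
      (any(origin < -eps) || any(origin + fov > scene$extent_um + eps)))
    stop(sprintf("tile at stage (%.6g, %.6g) extends outside the scene extent",
                 stage_xy_um[1], stage_xy_um[2]))
  pitch <- fov / config$optics$resolution_px
  render_with <- function(actual_origin, noise_seed) {
    mean_e <- render_mean_electrons(scene, channel, actual_origin,
                                    config$optics$resolution_px, pitch,
                                    z_um, config)
    quantize_render(mean_e, config, noise, noise_seed)
  }
  if (config$stage_jitter_um > 0) {
    with_seed(seed, {
      actual <- origin + runif(2, -config$stage_jitter_um,
                               config$stage_jitter_um)
      render_with(actual, NULL)  # inherits the seeded stream
    })
  } else {
    render_with(origin, seed)
  }
}

#' Write / read a scene's ground truth
#'
#' `write_scene()` serialises a scene as a plain-text pair: `scene.yaml`
#' (extent, background flux, seed) and `ground_truth.csv` (one row per
#' cell: id, phenotype, position, diameter, focal plane, per-channel flux).
#' `read_scene()` reconstructs the scene from such a directory.
#'
#' @param scene A [synthetic_scene()].
#' @param dir Directory to write into (created if missing) / read from.
#' @return `write_scene()` the directory invisibly; `read_scene()` a
#'   [synthetic_scene()].
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(extent_um = as.numeric(scene$extent_um),
              background_flux = as.list(scene$background_flux),
              seed = scene$seed)
  yaml::write_yaml(hdr, file.path(dir, "scene.yaml"))
  df <- ground_truth_table(scene)
  write.csv(df, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  df <- read.csv(file.path(dir, "ground_truth.csv"))
  cells <- lapply(seq_len(nrow(df)), function(i) {
    em <- c(blue = df$flux_blue[i], green = df$flux_green[i],
            orange = df$flux_orange[i], red = df$flux_red[i])
    ground_truth_cell(df$phenotype[i], c(df$x_um[i], df$y_um[i]),
                      df$diameter_um[i], em, df$z_um[i])
  })
  synthetic_scene(cells, unlist(hdr$extent_um),
                  unlist(hdr$background_flux), seed = hdr$seed)
}

#' Ground-truth table of a scene
#'
#' @param scene A [synthetic_scene()].
#' @return A data frame, one row per cell (id, phenotype, x_um, y_um,
#'   diameter_um, z_um, flux per channel).
#' @export
ground_truth_table <- function(scene) {
  n <- length(scene$cells)
  df <- data.frame(
    cell_id = seq_len(n),
    phenotype = vapply(scene$cells, function(c) c$phenotype, ""),
    x_um = vapply(scene$cells, function(c) c$center_um[1], 0),
    y_um = vapply(scene$cells, function(c) c$center_um[2], 0),
    diameter_um = vapply(scene$cells, function(c) c$diameter_um, 0),
    z_um = vapply(scene$cells, function(c) c$z_um, 0))
  for (ch in CHANNELS)
    df[[paste0("flux_", ch)]] <-
      vapply(scene$cells, function(c) c$emission[[ch]], 0)
  df
}
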