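#' Camera specification
#'
#' Bundles the sensor parameters of the acquisition chain: quantum
#' efficiency, pixel pitch, combined read/dark noise, digitisation depth,
#' on-sensor binning and conversion gain. Defaults are the parameters of
#' a 20 MP back-illuminated CMOS sensor (IMX183 class) operated with
#' 4x4 binning, as used for membrane-wide CTC scanning.
#'
#' @param qe Quantum efficiency, electrons generated per incident photon,
#'   in (0, 1].
#' @param pixel_size_um Sensor pixel pitch \eqn{\delta} in micrometres.
#' @param camera_noise_e Combined dark + read noise \eqn{\sigma_{camera}}
#'   in electrons (signal-independent, added in quadrature with shot noise).
#' @param bit_depth Digitiser depth in bits, 8 or 16.
#' @param binning Pixels combined per axis on the sensor (integer >= 1).
#' @param gain_e_per_dn Conversion gain, electrons per digital number.
#' @return An object of class `camera_spec`.
#' @examples
#' cam <- camera_spec()
#' total_noise(16, cam)
#' @export
camera_spec <- function(qe = 0.79, pixel_size_um = 2.4, camera_noise_e = 3.30,
                        bit_depth = 16L, binning = 4L, gain_e_per_dn = 1) {
  stopifnot(length(qe) == 1, length(pixel_size_um) == 1,
            length(camera_noise_e) == 1)
  if (!(qe > 0 && qe <= 1)) stop("'qe' must be in (0, 1]")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  if (camera_noise_e < 0) stop("'camera_noise_e' must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  if (binning < 1) stop("'binning' must be >= 1")
  if (gain_e_per_dn <= 0) stop("'gain_e_per_dn' must be positive")
  structure(list(qe = qe, pixel_size_um = pixel_size_um,
                 camera_noise_e = camera_noise_e,
                 bit_depth = as.integer(bit_depth),
                 binning = as.integer(binning),
                 gain_e_per_dn = gain_e_per_dn),
            class = "camera_spec")
}

#' @export
print.camera_spec <- function(x, ...) {
  cat("<camera_spec>\n")
  cat(sprintf("  QE %.3f | pixel %.2f um | sigma_camera %.2f e- | %d bit | %dx%d binning | gain %.3g e-/DN\n",
              x$qe, x$pixel_size_um, x$camera_noise_e, x$bit_depth,
              x$binning, x$binning, x$gain_e_per_dn))
  invisible(x)
}

#' Optics geometry: field of view and frame resolution
#'
#' Records the object-space extent of one captured frame and its pixel
#' resolution; all micrometre-to-pixel conversions derive from it. The
#' defaults are a 818 x 547 um field imaged at 1368 x 912 px.
#'
#' @param fov_um Numeric length-2, field-of-view (width, height) in um.
#' @param resolution_px Integer length-2, frame (width, height) in pixels.
#' @return An object of class `optics_geometry`.
#' @examples
#' opt <- optics_geometry()
#' circle_area_px(7, opt)
#' @export
optics_geometry <- function(fov_um = c(818, 547),
                            resolution_px = c(1368L, 912L)) {
  stopifnot(length(fov_um) == 2, length(resolution_px) == 2)
  if (any(fov_um <= 0) || any(resolution_px <= 0))
    stop("field of view and resolution entries must be positive")
  pitch <- fov_um / resolution_px
  if (abs(pitch[1] - pitch[2]) > 0.01 * max(pitch))
    stop("x and y pixel pitches disagree by more than 1%")
  structure(list(fov_um = as.numeric(fov_um),
                 resolution_px = as.integer(resolution_px)),
            class = "optics_geometry")
}

#' @export
print.optics_geometry <- function(x, ...) {
  cat(sprintf("<optics_geometry> FOV %.4g x %.4g um at %d x %d px (%.4f um2/px)\n",
              x$fov_um[1], x$fov_um[2], x$resolution_px[1], x$resolution_px[2],
              object_pixel_area_um2(x)))
  invisible(x)
}

#' Expected sensor signal for a photon flux
#'
#' The mean signal recorded by one pixel is
#' \eqn{S(t) = \gamma \delta^2 \mathrm{QE}\, t}: photon flux \eqn{\gamma}
#' times the pixel's collection area \eqn{\delta^2}, the quantum efficiency,
#' and the exposure time.
#'
#' @param photon_flux Photon flux in photons um^-2 s^-1 (vectorised).
#' @param camera A [camera_spec()].
#' @param exposure_s Exposure time in seconds.
#' @return Expected signal in electrons.
#' @export
expected_signal <- function(photon_flux, camera, exposure_s) {
  if (any(photon_flux < 0)) stop("'photon_flux' must be >= 0")
  if (any(exposure_s < 0)) stop("'exposure_s' must be >= 0")
  photon_flux * camera$pixel_size_um^2 * camera$qe * exposure_s
}

#' Total noise at a given signal level
#'
#' Uncorrelated noise sources add in quadrature: the camera's
#' signal-independent read/dark noise and the photon shot noise
#' \eqn{\sigma_{shot} = \sqrt{S}}, giving
#' \eqn{N = \sqrt{\sigma_{camera}^2 + S}} electrons.
#'
#' @param signal_e Signal in electrons (vectorised, >= 0).
#' @param camera A [camera_spec()].
#' @return Total noise in electrons.
#' @export
total_noise <- function(signal_e, camera) {
  if (any(signal_e < 0)) stop("'signal_e' must be >= 0")
  sqrt(camera$camera_noise_e^2 + signal_e)
}

#' Noise-equivalent photon floor
#'
#' The signal level at which the expected signal equals the total noise:
#' solving \eqn{S = \sqrt{\sigma_{camera}^2 + S}} gives the positive root
#' \eqn{S = (1 + \sqrt{1 + 4\sigma_{camera}^2})/2} electrons, converted to
#' photons by dividing by the quantum efficiency. It is the photon count
#' below which a pixel is noise-dominated.
#'
#' @param camera A [camera_spec()].
#' @return Photon count at unity signal-to-noise.
#' @export
noise_equivalent_photons <- function(camera) {
  if (camera$qe <= 0) stop("'qe' must be positive")
  s_e <- (1 + sqrt(1 + 4 * camera$camera_noise_e^2)) / 2
  s_e / camera$qe
}

#' Object-space area of one pixel
#'
#' @param optics An [optics_geometry()].
#' @return Area in um^2 covered by one pixel in the sample plane.
#' @export
object_pixel_area_um2 <- function(optics) {
  (optics$fov_um[1] / optics$resolution_px[1]) *
    (optics$fov_um[2] / optics$resolution_px[2])
}

#' Pixel area of a circle of given diameter
#'
#' Converts a cell diameter in micrometres to the pixel area of the
#' corresponding circle under the instrument's object-space pixel pitch,
#' rounded half away from zero to the nearest integer. Used as the
#' minimum-size gate of the classification rules.
#'
#' @param diameter_um Circle diameter in um (vectorised, > 0).
#' @param optics An [optics_geometry()].
#' @return Integer pixel area(s).
#' @examples
#' circle_area_px(c(2.5, 7), optics_geometry())  # 14 and 107 px
#' @export
circle_area_px <- function(diameter_um, optics) {
  if (any(diameter_um <= 0)) stop("'diameter_um' must be positive")
  area_um2 <- pi * (diameter_um / 2)^2
  as.integer(floor(area_um2 / object_pixel_area_um2(optics) + 0.5))
}

#' Convert electrons to digital numbers
#'
#' Electrons are divided by the conversion gain, rounded, and clipped to
#' the digitiser range \eqn{[0, 2^{bits} - 1]}.
#'
#' @param electrons Numeric vector/matrix of electron counts.
#' @param camera A [camera_spec()].
#' @return Same shape as `electrons`, integer-valued digital numbers.
#' @export
electrons_to_dn <- function(electrons, camera) {
  dn <- round(electrons / camera$gain_e_per_dn)
  pmin(pmax(dn, 0), 2^camera$bit_depth - 1)
}
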