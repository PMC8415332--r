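# Flat-detector beamline geometry and resolution conversions.

# hc in keV * Angstrom; fixes the energy <-> wavelength conversion.
HC_KEV_ANGSTROM <- 12.398419

#' X-ray wavelength from photon energy
#'
#' @param energy_kev Photon energy in keV. Must be positive.
#' @return Wavelength in Angstrom, `hc / E` with `hc = 12.398419` keV A.
#' @examples
#' wavelength_from_energy(12.398419)  # 1 A
#' wavelength_from_energy(9.28)
#' @export
wavelength_from_energy <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0)) {
    stop("photon energy must be a positive finite number (keV)")
  }
  HC_KEV_ANGSTROM / energy_kev
}

#' Flat-detector beamline geometry
#'
#' Describes a single flat detector panel normal to the beam: photon energy
#' (wavelength is derived), sample-to-detector distance, pixel pitch, beam
#' center and frame shape. Pixel coordinates are 0-based in (fast, slow)
#' order with pixel centers at integer coordinates; the beam center may be
#' fractional.
#'
#' The default geometry is synthetic: it emulates an 8x8-binned large-area
#' CCD (480 x 480 pixels of 354 um) at 100 mm, a configuration under which
#' the detector edge reaches about 2 A at 9.28 keV. No distance or pitch is
#' prescribed by any experiment; treat them as configuration.
#'
#' @param photon_energy_kev Photon energy in keV (default 9.28).
#' @param detector_distance_mm Sample-to-detector distance in mm.
#' @param pixel_pitch_um Pixel pitch in um.
#' @param beam_center (fast, slow) beam center in fractional pixels.
#' @param frame_shape (n_slow, n_fast) frame dimensions in pixels.
#' @param fel_rate_hz Pulse (frame) rate in Hz; 10 for the emulated beamline.
#' @return An object of class `beamline_geometry`.
#' @export
beamline_geometry <- function(photon_energy_kev = 9.28,
                              detector_distance_mm = 100,
                              pixel_pitch_um = 354,
                              beam_center = c(239.5, 239.5),
                              frame_shape = c(480L, 480L),
                              fel_rate_hz = 10) {
  stopifnot(length(beam_center) == 2L, length(frame_shape) == 2L)
  if (detector_distance_mm <= 0) stop("detector_distance_mm must be > 0")
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be > 0")
  if (fel_rate_hz <= 0) stop("fel_rate_hz must be > 0")
  g <- list(
    photon_energy_kev = photon_energy_kev,
    wavelength = wavelength_from_energy(photon_energy_kev),
    detector_distance_mm = detector_distance_mm,
    pixel_pitch_um = pixel_pitch_um,
    beam_center = as.numeric(beam_center),
    frame_shape = as.integer(frame_shape),
    fel_rate_hz = fel_rate_hz
  )
  class(g) <- "beamline_geometry"
  g
}

#' @export
print.beamline_geometry <- function(x, ...) {
  cat("Beamline geometry (flat detector, normal incidence)\n")
  cat(sprintf("  photon energy : %.4f keV (lambda %.5f A)\n",
              x$photon_energy_kev, x$wavelength))
  cat(sprintf("  distance      : %.2f mm, pixel pitch %.1f um\n",
              x$detector_distance_mm, x$pixel_pitch_um))
  cat(sprintf("  frame         : %d x %d px, beam center (%.2f, %.2f)\n",
              x$frame_shape[1], x$frame_shape[2],
              x$beam_center[1], x$beam_center[2]))
  cat(sprintf("  pulse rate    : %g Hz\n", x$fel_rate_hz))
  invisible(x)
}

#' Resolution (d-spacing) at a detector position
#'
#' Maps pixel positions to Bragg d-spacing through the standard flat-detector
#' construction: radial offset rho = pitch * |pos - beam_center|,
#' 2theta = atan(rho / distance), d = lambda / (2 sin theta). At the beam
#' center theta = 0 and the d-spacing diverges; `Inf` is returned there and
#' all shell-binning treats it as out of range.
#'
#' @param geom A [beamline_geometry()].
#' @param fast,slow Pixel coordinates (vectors of equal length).
#' @return d-spacings in Angstrom; strictly decreasing with radial distance.
#' @export
pixel_to_d <- function(geom, fast, slow) {
  stopifnot(inherits(geom, "beamline_geometry"))
  rho_mm <- geom$pixel_pitch_um * 1e-3 *
    sqrt((fast - geom$beam_center[1])^2 + (slow - geom$beam_center[2])^2)
  tth <- atan(rho_mm / geom$detector_distance_mm)
  d <- geom$wavelength / (2 * sin(tth / 2))
  d[rho_mm == 0] <- Inf
  d
}

#' Ring radius for a given d-spacing
#'
#' Inverse of [pixel_to_d()] along the radial coordinate:
#' `radius = D * tan(2 * asin(lambda / 2d)) / pitch`. Only reflections with
#' `d > lambda / 2` exist, and on a flat detector only scattering angles
#' below 90 degrees intersect the panel.
#'
#' @param geom A [beamline_geometry()].
#' @param d d-spacing(s) in Angstrom.
#' @return Ring radii in pixels from the beam center.
#' @export
d_to_ring_radius <- function(geom, d) {
  stopifnot(inherits(geom, "beamline_geometry"))
  if (any(!is.finite(d)) || any(d <= geom$wavelength / 2)) {
    stop("unreachable resolution: need finite d > lambda/2")
  }
  tth <- 2 * asin(geom$wavelength / (2 * d))
  if (any(tth >= pi / 2)) {
    stop("unreachable resolution: 2theta >= 90 degrees never intersects a flat detector")
  }
  geom$detector_distance_mm * tan(tth) / (geom$pixel_pitch_um * 1e-3)
}

#' Radial pixel distance map
#'
#' @param geom A [beamline_geometry()].
#' @return A matrix (slow x fast) of radial distances from the beam center
#'   in pixels, for every pixel of the frame.
#' @export
radius_map <- function(geom) {
  stopifnot(inherits(geom, "beamline_geometry"))
  ns <- geom$frame_shape[1]; nf <- geom$frame_shape[2]
  ds <- (seq_len(ns) - 1) - geom$beam_center[2]
  df <- (seq_len(nf) - 1) - geom$beam_center[1]
  sqrt(outer(ds^2, df^2, "+"))
}

#' Write / read geometry as JSON
#'
#' Geometry files carry explicit unit-suffixed keys
#' (`detector_distance_mm`, `pixel_pitch_um`, ...).
#'
#' @param geom A [beamline_geometry()].
#' @param path Output / input file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns a [beamline_geometry()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "beamline_geometry"))
  x <- unclass(geom)
  x$wavelength <- NULL  # derived; re-computed on read
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("photon_energy_kev", "detector_distance_mm", "pixel_pitch_um",
            "beam_center", "frame_shape", "fel_rate_hz")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("geometry file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  }
  beamline_geometry(
    photon_energy_kev = x$photon_energy_kev,
    detector_distance_mm = x$detector_distance_mm,
    pixel_pitch_um = x$pixel_pitch_um,
    beam_center = x$beam_center,
    frame_shape = x$frame_shape,
    fel_rate_hz = x$fel_rate_hz
  )
}
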