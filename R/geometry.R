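#' Imaging geometry for a tomographic acquisition
#'
#' Bundles the physical acquisition parameters of a full-view optical
#' tomography experiment. All lengths are expressed in detector pixels
#' (pixel pitch fixed at 1); the wavelength is therefore supplied in pixels.
#' Use [wavelengths_to_pixels()] to convert an object size quoted in vacuum
#' wavelengths into pixels.
#'
#' @param wavelength vacuum wavelength of the illumination, in pixels (> 0).
#' @param medium_index refractive index \eqn{n_m} of the immersion medium
#'   (>= 1); water is 1.333.
#' @param detector_distance distance \eqn{l_D} from the volume center to the
#'   detector plane along the propagation axis, in pixels. Defaults to 0,
#'   i.e. detector data numerically refocused to the center of the object.
#'
#' @return An object of class `imaging_geometry` with fields `wavelength`,
#'   `medium_index`, `pixel_size` (always 1) and `detector_distance`.
#' @examples
#' geo <- imaging_geometry(wavelength = 4, medium_index = 1.333)
#' wavenumbers(geo)
#' @export
imaging_geometry <- function(wavelength, medium_index = 1.333,
                             detector_distance = 0) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1,
            is.finite(wavelength))
  if (wavelength <= 0) stop("wavelength must be positive")
  stopifnot(is.numeric(medium_index), length(medium_index) == 1,
            is.finite(medium_index))
  if (medium_index < 1) stop("medium_index must be >= 1")
  stopifnot(is.numeric(detector_distance), length(detector_distance) == 1,
            is.finite(detector_distance))
  structure(
    list(wavelength = wavelength, medium_index = medium_index,
         pixel_size = 1, detector_distance = detector_distance),
    class = "imaging_geometry"
  )
}

#' Vacuum and medium wavenumbers of a geometry
#'
#' @param geometry an [imaging_geometry()].
#' @return Named numeric vector with `k0` \eqn{= 2\pi/\lambda} and
#'   `km` \eqn{= n_m k_0}, in radians per pixel.
#' @examples
#' wavenumbers(imaging_geometry(wavelength = 2 * pi, medium_index = 1.333))
#' @export
wavenumbers <- function(geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  k0 <- 2 * pi / geometry$wavelength
  c(k0 = k0, km = geometry$medium_index * k0)
}

#' Convert lengths in vacuum wavelengths to pixels
#'
#' @param x length(s) in units of the vacuum wavelength.
#' @param geometry an [imaging_geometry()] supplying the wavelength in pixels.
#' @return length(s) in pixels.
#' @export
wavelengths_to_pixels <- function(x, geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  x * geometry$wavelength
}

#' @export
print.imaging_geometry <- function(x, ...) {
  k <- wavenumbers(x)
  cat(sprintf(
    "<imaging_geometry> lambda = %g px, n_m = %g, l_D = %g px (k0 = %.4g, km = %.4g)\n",
    x$wavelength, x$medium_index, x$detector_distance, k[["k0"]], k[["km"]]))
  invisible(x)
}
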