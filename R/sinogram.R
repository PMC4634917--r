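#' Validate a complex-field sinogram
#'
#' A sinogram holds the background-normalized complex detector fields
#' \eqn{u/u_0} acquired while the specimen rotates through a full turn. The
#' reconstruction algorithms require projections distributed equally over
#' \eqn{[0, 2\pi)} with the rotation axis at the center of each projection;
#' this constructor enforces those preconditions once so every downstream
#' consumer can rely on them.
#'
#' @param fields complex matrix (2D data, `N_angles x Nx`) or 3D array
#'   (`N_angles x Ny x Nx`) of background-normalized detector fields.
#' @param angles numeric vector of projection angles in radians, strictly
#'   increasing, equally spaced, covering `[0, 2pi)` within `tol`.
#' @param geometry an [imaging_geometry()].
#' @param tol tolerance on the angular spacing test, radians.
#'
#' @return An object of class `complex_sinogram`: list with `fields`,
#'   `angles`, `geometry` and the recorded spacing `dphi = 2*pi/N_angles`.
#'   Validation is idempotent.
#' @examples
#' geo <- imaging_geometry(wavelength = 4)
#' ang <- full_turn_angles(8)
#' sg <- complex_sinogram(matrix(1 + 0i, 8, 16), ang, geo)
#' sg$dphi
#' @export
complex_sinogram <- function(fields, angles, geometry, tol = 1e-9) {
  if (inherits(fields, "complex_sinogram")) return(fields)
  stopifnot(inherits(geometry, "imaging_geometry"))
  if (!(is.matrix(fields) || (is.array(fields) && length(dim(fields)) == 3)))
    stop("fields must be a matrix (angles x Nx) or 3D array (angles x Ny x Nx)")
  if (!is.complex(fields)) fields <- fields + 0i
  if (any(!is.finite(Re(fields))) || any(!is.finite(Im(fields))))
    stop("fields contain non-finite values")
  n_ang <- dim(fields)[1]
  if (!is.numeric(angles) || !is.null(dim(angles)))
    stop("angles must be a 1-D numeric vector")
  if (length(angles) != n_ang)
    stop(sprintf("angle count (%d) does not match field count (%d)",
                 length(angles), n_ang))
  if (any(!is.finite(angles))) stop("angles contain non-finite values")
  if (n_ang < 1) stop("empty sinogram")
  dphi <- 2 * pi / n_ang
  expected <- angles[1] + dphi * (seq_len(n_ang) - 1)
  dev <- max(abs(angles - expected))
  if (dev > tol)
    stop(sprintf(
      "unequal spacing: angles must be equally spaced over [0, 2*pi); max deviation %.3g rad",
      dev))
  if (abs(angles[1]) > tol)
    stop("angles must start at 0 (full-view convention)")
  structure(
    list(fields = fields, angles = as.numeric(angles), geometry = geometry,
         dphi = dphi),
    class = "complex_sinogram"
  )
}

#' @rdname complex_sinogram
#' @export
validate_sinogram <- complex_sinogram

#' Equally spaced full-turn projection angles
#'
#' @param n number of projections.
#' @return `n` angles `(k-1) * 2*pi/n`, radians, covering `[0, 2pi)`.
#' @export
full_turn_angles <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  2 * pi * (seq_len(n) - 1) / n
}

#' @export
print.complex_sinogram <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf("<complex_sinogram> %s angles, detector %s px, dphi = 2*pi/%d\n",
              d[1], paste(d[-1], collapse = " x "), d[1]))
  invisible(x)
}

#' Scattering data ready for reconstruction
#'
#' Internal constructor wrapping per-angle detector data after the
#' approximation-specific filtering step: Born (`u/u0 - 1`), Rytov
#' (`log|u/u0| + i * unwrapped arg`), or Radon (real unwrapped phase).
#'
#' @param data complex matrix / 3D array shaped like sinogram fields.
#' @param angles projection angles, radians.
#' @param geometry an [imaging_geometry()].
#' @param approximation one of `"born"`, `"rytov"`, `"radon"`.
#' @return object of class `scattering_data`; the approximation tag is fixed
#'   at creation.
#' @keywords internal
scattering_data <- function(data, angles, geometry,
                            approximation = c("born", "rytov", "radon")) {
  approximation <- match.arg(approximation)
  stopifnot(inherits(geometry, "imaging_geometry"))
  n_ang <- dim(data)[1]
  stopifnot(length(angles) == n_ang)
  structure(
    list(data = data, angles = as.numeric(angles), geometry = geometry,
         approximation = approximation, dphi = 2 * pi / n_ang),
    class = "scattering_data"
  )
}

#' @export
print.scattering_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scattering_data[%s]> %s angles, detector %s px\n",
              x$approximation, d[1], paste(d[-1], collapse = " x ")))
  invisible(x)
}

# Shared grid checks for maps -------------------------------------------------

#' Refractive-index map on a square/cubic grid
#'
#' @param n real or complex array (`N x N` or `N x N x N`, rows = z,
#'   then y, then x for 3D); real part must be non-negative.
#' @param geometry an [imaging_geometry()].
#' @return object of class `ri_map` with fields `n` and `geometry`.
#' @export
ri_map <- function(n, geometry) {
  if (inherits(n, "ri_map")) return(n)
  stopifnot(inherits(geometry, "imaging_geometry"))
  d <- dim(n)
  if (is.null(d) || !(length(d) %in% c(2, 3)) || length(unique(d)) != 1)
    stop("refractive-index map must be on a square or cubic grid")
  if (min(Re(n)) < 0) stop("real part of the refractive index must be >= 0")
  structure(list(n = n, geometry = geometry), class = "ri_map")
}

#' Object-function (scattering potential) map
#'
#' Holds \eqn{f(r) = k_m^2 [(n/n_m)^2 - 1]} on the reconstruction grid.
#'
#' @param f complex array, square or cubic grid.
#' @param geometry an [imaging_geometry()].
#' @return object of class `object_map`.
#' @export
object_map <- function(f, geometry) {
  if (inherits(f, "object_map")) return(f)
  stopifnot(inherits(geometry, "imaging_geometry"))
  d <- dim(f)
  if (is.null(d) || !(length(d) %in% c(2, 3)) || length(unique(d)) != 1)
    stop("object-function map must be on a square or cubic grid")
  if (!is.complex(f)) f <- f + 0i
  structure(list(f = f, geometry = geometry), class = "object_map")
}

#' @export
print.ri_map <- function(x, ...) {
  cat(sprintf("<ri_map> grid %s, n in [%.4g, %.4g]\n",
              paste(dim(x$n), collapse = " x "),
              min(Re(x$n)), max(Re(x$n))))
  invisible(x)
}

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("<object_map> grid %s, max |f| = %.4g\n",
              paste(dim(x$f), collapse = " x "), max(Mod(x$f))))
  invisible(x)
}
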