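# Scalar forward models generating full-view sinograms of a refractive-index
# map: straight-ray phase integrals (Radon), first-order scattering via the
# Fourier diffraction theorem (Born), Rytov-consistent complex fields, and a
# brute-force Green's-function summation that serves as an independent oracle
# for the diffraction operator.
#
# The incident field is the plane wave u0 = exp(+i k_m z); for projection
# angle phi the object is rotated by -phi about the grid center (y axis in
# 3D) and illuminated along +z. Detector pixels coincide with the grid's x
# (and y) columns; the detector plane sits at z = l_D from the volume center.

#' Object function (scattering potential) from a refractive-index map
#'
#' Computes \eqn{f(r) = k_m^2 [(n(r)/n_m)^2 - 1]}, the quantity the
#' diffraction-tomography inverse problem recovers. Inverse of
#' [object_to_ri()].
#'
#' @param ri an [ri_map()] (or bare array with `geometry` supplied).
#' @param geometry an [imaging_geometry()]; defaults to the map's.
#' @return an [object_map()].
#' @export
object_from_ri <- function(ri, geometry = NULL) {
  if (inherits(ri, "ri_map")) {
    if (is.null(geometry)) geometry <- ri$geometry
    n <- ri$n
  } else n <- ri
  stopifnot(inherits(geometry, "imaging_geometry"))
  km <- wavenumbers(geometry)[["km"]]
  nm <- geometry$medium_index
  object_map(km^2 * ((n / nm)^2 - 1), geometry)
}

# guard against spatially aliased wave propagation on the grid
check_nyquist <- function(geometry) {
  km <- wavenumbers(geometry)[["km"]]
  if (km > pi)
    stop(sprintf(paste0(
      "wavelength too small for the grid: k_m = %.3g > pi rad/px. ",
      "Use wavelength >= %.3g px (two pixels per wavelength in the medium) ",
      "or resample the object."), km, 2 * geometry$medium_index))
  invisible(TRUE)
}

#' Ray-integral (Radon) phase sinogram of a refractive-index map
#'
#' Straight-ray model: for each projection angle the map is rotated by
#' `-phi` about the grid center (about y in 3D) and the refractive-index
#' excess \eqn{n - n_m} is integrated along the propagation axis z, giving
#' the optical phase \eqn{\Phi = k_0 \int (n - n_m)\, dz}.
#'
#' @param ri an [ri_map()].
#' @param angles projection angles in radians.
#' @param geometry an [imaging_geometry()]; defaults to the map's.
#' @return a `scattering_data` object with approximation `"radon"` holding
#'   the real phase sinogram (`N_angles x Nx`, or `N_angles x Ny x Nx`).
#' @export
radon_forward <- function(ri, angles, geometry = NULL) {
  if (!inherits(ri, "ri_map")) stop("ri must be an ri_map")
  if (is.null(geometry)) geometry <- ri$geometry
  if (length(angles) == 0) stop("empty angle list")
  k0 <- wavenumbers(geometry)[["k0"]]
  dn <- ri$n - geometry$medium_index
  d <- dim(dn)
  if (length(d) == 2) {
    out <- matrix(0, length(angles), d[2])
    for (a in seq_along(angles))
      out[a, ] <- k0 * colSums(rotate_image(dn, -angles[a]))
  } else {
    out <- array(0, c(length(angles), d[2], d[3]))
    for (a in seq_along(angles)) {
      rot <- rotate_volume_y(dn, -angles[a])
      out[a, , ] <- k0 * apply(rot, c(2, 3), sum)
    }
  }
  scattering_data(out, angles, geometry, "radon")
}

#' Born scattered field of an object function (Fourier diffraction theorem)
#'
#' For each projection angle the rotated object spectrum is sampled on the
#' Ewald arc (2D) or cap (3D) \eqn{k = (k_{Dx}[, k_{Dy}], \gamma - k_m)},
#' \eqn{\gamma = \sqrt{k_m^2 - k_{Dx}^2 [- k_{Dy}^2]}}, weighted by the
#' free-space Green's-function factor \eqn{i/(2\gamma)}, propagated to the
#' detector plane at `l_D` and inverse-transformed to detector coordinates.
#' Evanescent frequencies (\eqn{k_\perp \ge k_m}) carry no far-field
#' information and are set to zero (numerical aperture 1).
#'
#' @param obj an [object_map()] (see [object_from_ri()]).
#' @param angles projection angles in radians (non-empty).
#' @param geometry an [imaging_geometry()]; defaults to the map's.
#' @return a `scattering_data` object with approximation `"born"` holding
#'   the normalized scattered field \eqn{b = u/u_0 - 1} per angle.
#' @export
born_forward <- function(obj, angles, geometry = NULL) {
  if (!inherits(obj, "object_map")) stop("obj must be an object_map")
  if (is.null(geometry)) geometry <- obj$geometry
  if (length(angles) == 0) stop("empty angle list")
  check_nyquist(geometry)
  d <- dim(obj$f)
  if (length(d) == 2) born_forward_2d(obj$f, angles, geometry)
  else born_forward_3d(obj$f, angles, geometry)
}

born_forward_2d <- function(f, angles, geometry) {
  n <- ncol(f)
  m <- pad_length_prop(n, geometry$detector_distance)
  km <- wavenumbers(geometry)[["km"]]
  ld <- geometry$detector_distance
  k <- kgrid(m)
  mask <- k^2 < km^2
  gam <- sqrt(pmax(km^2 - k^2, 0))
  zc <- grid_coords(nrow(f))
  # E[j, z] = exp(-i (gamma_j - k_m) z_c): depth phase of the Ewald sampling
  E <- exp(-1i * outer(gam - km, zc))
  w0 <- ifelse(mask, 1i / (2 * gam) * exp(1i * (gam - km) * ld), 0i)
  out <- matrix(0i, length(angles), n)
  for (a in seq_along(angles)) {
    frot <- rotate_image(f, -angles[a])
    # pad the detector axis; columns of P index depth z
    P <- matrix(0i, m, nrow(f))
    off <- grid_center0(m) - grid_center0(n)
    P[off + seq_len(n), ] <- t(frot)
    Fx <- cfft_cols(P)
    A <- rowSums(Fx * E)
    out[a, ] <- crop_center_vec(cifft(w0 * A), n)
  }
  scattering_data(out, angles, geometry, "born")
}

born_forward_3d <- function(f, angles, geometry) {
  d <- dim(f)  # (Nz, Ny, Nx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  ld <- geometry$detector_distance
  my <- pad_length_prop(ny, ld); mx <- pad_length_prop(nx, ld)
  km <- wavenumbers(geometry)[["km"]]
  ky <- kgrid(my); kx <- kgrid(mx)
  K2 <- outer(ky^2, kx^2, `+`)
  mask <- K2 < km^2
  gam <- sqrt(pmax(km^2 - K2, 0))
  zc <- grid_coords(nz)
  w0 <- ifelse(mask, 1i / (2 * gam) * exp(1i * (gam - km) * ld), 0i)
  gkm <- gam - km
  out <- array(0i, c(length(angles), ny, nx))
  for (a in seq_along(angles)) {
    frot <- rotate_volume_y(f, -angles[a])
    A <- matrix(0i, my, mx)
    for (z in seq_len(nz)) {
      slab <- pad_center_mat(frot[z, , ], my, mx)
      A <- A + cfft2(slab) * exp(-1i * gkm * zc[z])
    }
    out[a, , ] <- crop_center_mat(cifft2(w0 * A), ny, nx)
  }
  scattering_data(out, angles, geometry, "born")
}

#' Brute-force Green's-function scattered field (oracle)
#'
#' Direct summation of the first-order scattering integral
#' \eqn{u_B(r_D) = \sum_{voxels} G(r_D - r') f(r') u_0(r') \Delta V} with the
#' free-space Green's function — 2D: \eqn{(i/4) H_0^{(1)}(k_m |r|)} (Hankel
#' function of the first kind), 3D: \eqn{e^{i k_m |r|}/(4\pi |r|)}. Cost is
#' `O(N_detector * N_voxels)`, so this is intended for small grids only; it
#' is the independent reference that pins the FFT conventions and
#' normalization of [born_forward()]. The detector plane must lie outside
#' the object support; a detector point coincident with a voxel center is
#' skipped (principal value).
#'
#' @param obj an [object_map()].
#' @param angle single projection angle, radians.
#' @param geometry an [imaging_geometry()]; `detector_distance` must place
#'   the detector beyond the object (e.g. `N/2 + 1`).
#' @return complex vector (2D object) or `Ny x Nx` matrix (3D object) of
#'   normalized scattered field \eqn{b = u_B/u_0} at the detector.
#' @export
born_forward_bruteforce <- function(obj, angle, geometry = NULL) {
  if (!inherits(obj, "object_map")) stop("obj must be an object_map")
  if (is.null(geometry)) geometry <- obj$geometry
  stopifnot(length(angle) == 1)
  km <- wavenumbers(geometry)[["km"]]
  ld <- geometry$detector_distance
  d <- dim(obj$f)
  if (length(d) == 2) {
    f <- rotate_image(obj$f, -angle)
    nz <- d[1]; nx <- d[2]
    zc <- grid_coords(nz); xc <- grid_coords(nx)
    idx <- which(f != 0, arr.ind = TRUE)
    u <- rep(0i, nx)
    if (nrow(idx) > 0) {
      fz <- zc[idx[, 1]]; fx <- xc[idx[, 2]]
      fv <- f[idx] * exp(1i * km * fz)   # f * u0 at the voxel
      for (j in seq_len(nx)) {
        rho <- sqrt((xc[j] - fx)^2 + (ld - fz)^2)
        ok <- rho > 0
        g <- (1i / 4) * (besselJ(km * rho[ok], 0) + 1i * besselY(km * rho[ok], 0))
        u[j] <- sum(g * fv[ok])
      }
    }
    u * exp(-1i * km * ld)
  } else {
    f <- rotate_volume_y(obj$f, -angle)
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    zc <- grid_coords(nz); yc <- grid_coords(ny); xc <- grid_coords(nx)
    idx <- which(f != 0, arr.ind = TRUE)
    u <- matrix(0i, ny, nx)
    if (nrow(idx) > 0) {
      fz <- zc[idx[, 1]]; fy <- yc[idx[, 2]]; fx <- xc[idx[, 3]]
      fv <- f[idx] * exp(1i * km * fz)
      for (jy in seq_len(ny)) for (jx in seq_len(nx)) {
        rho <- sqrt((xc[jx] - fx)^2 + (yc[jy] - fy)^2 + (ld - fz)^2)
        ok <- rho > 0
        g <- exp(1i * km * rho[ok]) / (4 * pi * rho[ok])
        u[jy, jx] <- sum(g * fv[ok])
      }
    }
    u * exp(-1i * km * ld)
  }
}

#' Rytov-consistent complex-field sinogram
#'
#' Exponentiates the Born field into a complex field
#' \eqn{u/u_0 = \exp(b_{Born})}, the field for which the Rytov inversion is
#' exact within scalar first-order theory. Optionally adds circular complex
#' Gaussian noise to the normalized fields, emulating coherent measurement
#' noise; the noise draws use R's RNG, so seed with [set.seed()] for
#' reproducibility.
#'
#' @inheritParams born_forward
#' @param noise_sigma standard deviation of the complex noise added to
#'   `u/u0` (total, i.e. `sd(|noise|) = noise_sigma`); default 0 (off).
#' @return a [complex_sinogram()] of background-normalized fields.
#' @export
rytov_forward <- function(obj, angles, geometry = NULL, noise_sigma = 0) {
  if (is.null(geometry) && inherits(obj, "object_map")) geometry <- obj$geometry
  b <- born_forward(obj, angles, geometry)
  u <- exp(b$data)
  if (noise_sigma > 0) {
    s <- noise_sigma / sqrt(2)
    nz <- stats::rnorm(length(u), sd = s) + 1i * stats::rnorm(length(u), sd = s)
    u <- u + array(nz, dim(u))
  }
  complex_sinogram(u, angles, geometry)
}
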