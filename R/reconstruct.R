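# Steps (b) + (c): backpropagation (Born/Rytov) in 2D and 3D, filtered
# backprojection (Radon baseline), and conversion of the recovered object
# function to refractive index.
#
# Backpropagation inverts the Fourier diffraction theorem: per angle the
# (padded) detector data are Fourier transformed, multiplied by the ramp
# filter |k_Dx|, the evanescent low-pass (k_perp^2 < k_m^2) and the
# depth-dependent free-space kernel exp(i (gamma - k_m)(z' - l_D)),
# inverse transformed per depth, rotated into the lab frame and accumulated
# with weight dphi. The discrete normalization constant
# -i * k_m * dphi / (2*pi) follows from the package's forward convention
# (Weyl expansion of the Green's function, angle/frequency Jacobian
# |k_Dx| k_m / gamma, double coverage of the full turn) and is pinned by the
# weak-scattering calibration and brute-force-oracle tests.

#' Frequency-domain plan for backpropagation
#'
#' Precomputes everything that depends only on grid shape and geometry:
#' padded detector length(s), spatial-frequency grids, \eqn{\gamma},
#' the evanescent low-pass mask, the ramp filter \eqn{|k_{Dx}|}, the angle
#' weight and the global normalization constant. Deterministic for fixed
#' inputs.
#'
#' @param detector_shape integer: `Nx` (2D) or `c(Ny, Nx)` (3D).
#' @param n_angles number of projections.
#' @param geometry an [imaging_geometry()].
#' @return list of class `backpropagation_plan`.
#' @export
backpropagation_plan <- function(detector_shape, n_angles, geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"), n_angles >= 1)
  km <- wavenumbers(geometry)[["km"]]
  dphi <- 2 * pi / n_angles
  if (length(detector_shape) == 1) {
    m <- pad_length(detector_shape)
    kx <- kgrid(m)
    mask <- kx^2 < km^2
    gam <- sqrt(pmax(km^2 - kx^2, 0))
    plan <- list(dim = 2L, nx = detector_shape, mx = m, kx = kx,
                 gamma = gam, mask = mask, filter = abs(kx))
  } else {
    my <- pad_length(detector_shape[1]); mx <- pad_length(detector_shape[2])
    ky <- kgrid(my); kx <- kgrid(mx)
    K2 <- outer(ky^2, kx^2, `+`)
    mask <- K2 < km^2
    gam <- sqrt(pmax(km^2 - K2, 0))
    # single rotation axis y: ramp filter acts along k_Dx only
    filt <- matrix(abs(kx), my, mx, byrow = TRUE)
    plan <- list(dim = 3L, ny = detector_shape[1], nx = detector_shape[2],
                 my = my, mx = mx, kx = kx, ky = ky, gamma = gam,
                 mask = mask, filter = filt)
  }
  plan$km <- km
  plan$dphi <- dphi
  plan$norm_const <- -1i * km * dphi / (2 * pi)
  class(plan) <- "backpropagation_plan"
  plan
}

check_full_view <- function(angles, tol = 1e-9) {
  n <- length(angles)
  dphi <- 2 * pi / n
  expected <- angles[1] + dphi * (seq_len(n) - 1)
  if (max(abs(angles - expected)) > tol || abs(angles[1]) > tol)
    stop("backpropagation requires equally spaced full-view angles over [0, 2*pi)")
  invisible(dphi)
}

#' Diffraction-tomography backpropagation, 2D
#'
#' Reconstructs the complex object function f from Born or Rytov scattering
#' data of a full-view, equally spaced sinogram. Per-angle contributions are
#' rotated into the lab frame in real space (bilinear interpolation) and
#' accumulated. Convert the result with [object_to_ri()].
#'
#' @param sd a `scattering_data` object with approximation `"born"` or
#'   `"rytov"` (see [to_born_data()], [to_rytov_data()]); Radon data belong
#'   to [filtered_backprojection()].
#' @param geometry an [imaging_geometry()]; defaults to the data's.
#' @return an [object_map()] of shape `Nx x Nx`.
#' @export
backpropagate_2d <- function(sd, geometry = NULL) {
  stopifnot(inherits(sd, "scattering_data"))
  if (sd$approximation == "radon")
    stop("Radon data are reconstructed with filtered_backprojection()")
  if (is.null(geometry)) geometry <- sd$geometry
  if (!is.matrix(sd$data)) stop("2D backpropagation expects N_angles x Nx data")
  check_full_view(sd$angles)
  n <- ncol(sd$data)
  plan <- backpropagation_plan(n, length(sd$angles), geometry)
  m <- plan$mx
  ld <- geometry$detector_distance
  zc <- grid_coords(n)
  # E[j, z'] = exp(i (gamma_j - km)(z'_c - l_D)), zero on evanescent rows
  E <- exp(1i * outer(plan$gamma - plan$km, zc - ld))
  E[!plan$mask, ] <- 0i
  W <- plan$filter * plan$mask
  accum <- matrix(0i, n, n)
  for (a in seq_along(sd$angles)) {
    B <- cfft(pad_center_vec(sd$data[a, ] + 0i, m))
    Q <- cifft_cols((W * B) * E)          # rows x' (padded), cols z'
    Cc <- t(Q[grid_center0(m) - grid_center0(n) + seq_len(n), , drop = FALSE])
    accum <- accum + rotate_image(Cc, sd$angles[a])
  }
  object_map(plan$norm_const * accum, geometry)
}

#' Diffraction-tomography backpropagation, 3D (rotation about y)
#'
#' As [backpropagate_2d()] with 2D detector transforms,
#' \eqn{\gamma = \sqrt{k_m^2 - k_{Dx}^2 - k_{Dy}^2}} and the ramp filter
#' \eqn{|k_{Dx}|} only (single rotation axis y). Per-angle volume
#' contributions are rotated about y and accumulated.
#'
#' @param sd `scattering_data` with array data `(N_angles, Ny, Nx)`.
#' @inheritParams backpropagate_2d
#' @return an [object_map()] of shape `N x N x N` (`Nz = Ny = Nx`).
#' @export
backpropagate_3d <- function(sd, geometry = NULL) {
  stopifnot(inherits(sd, "scattering_data"))
  if (sd$approximation == "radon")
    stop("Radon data are reconstructed with filtered_backprojection()")
  if (is.null(geometry)) geometry <- sd$geometry
  d <- dim(sd$data)
  if (length(d) != 3) stop("3D backpropagation expects (N_angles, Ny, Nx) data")
  if (d[2] != d[3]) stop("detector must be square (Ny == Nx)")
  check_full_view(sd$angles)
  ny <- d[2]; nx <- d[3]; nz <- nx
  plan <- backpropagation_plan(c(ny, nx), length(sd$angles), geometry)
  ld <- geometry$detector_distance
  zc <- grid_coords(nz)
  gkm <- plan$gamma - plan$km
  W <- ifelse(plan$mask, plan$filter, 0)
  # depth kernels shared across angles
  Elist <- lapply(zc, function(z) {
    E <- exp(1i * gkm * (z - ld))
    E[!plan$mask] <- 0i
    E
  })
  accum <- array(0i, c(nz, ny, nx))
  Cc <- array(0i, c(nz, ny, nx))
  for (a in seq_along(sd$angles)) {
    B <- cfft2(pad_center_mat(sd$data[a, , ] + 0i, plan$my, plan$mx))
    BW <- B * W
    for (z in seq_len(nz))
      Cc[z, , ] <- crop_center_mat(cifft2(BW * Elist[[z]]), ny, nx)
    accum <- accum + rotate_volume_y(Cc, sd$angles[a])
  }
  object_map(plan$norm_const * accum, geometry)
}

#' Filtered backprojection (inverse Radon transform)
#'
#' Classical projection-tomography baseline: each real unwrapped phase
#' projection is ramp-filtered (\eqn{|k_{Dx}|}) and backprojected along
#' straight rays; the accumulated line-integral density is divided by
#' \eqn{k_0} and added to the medium index. 3D input is processed
#' slice-by-slice along y.
#'
#' @param sd `scattering_data` with approximation `"radon"` (real phases;
#'   see [to_radon_data()], [radon_forward()]).
#' @inheritParams backpropagate_2d
#' @return an [ri_map()] (real).
#' @export
filtered_backprojection <- function(sd, geometry = NULL) {
  stopifnot(inherits(sd, "scattering_data"))
  if (sd$approximation != "radon")
    stop("filtered_backprojection expects Radon phase data; ",
         "use backpropagate_2d/backpropagate_3d for Born or Rytov data")
  if (is.complex(sd$data))
    stop("Radon phase sinogram must be real-valued")
  if (is.null(geometry)) geometry <- sd$geometry
  check_full_view(sd$angles)
  k0 <- wavenumbers(geometry)[["k0"]]
  d <- dim(sd$data)
  fbp_slice <- function(p_mat, angles, dphi) {
    n <- ncol(p_mat)
    m <- pad_length(n)
    ramp <- abs(kgrid(m))
    accum <- matrix(0, n, n)
    off <- grid_center0(m) - grid_center0(n)
    for (a in seq_along(angles)) {
      q <- Re(cifft(ramp * cfft(pad_center_vec(p_mat[a, ] + 0i, m))))
      B <- matrix(q[off + seq_len(n)], n, n, byrow = TRUE)  # constant along z
      accum <- accum + rotate_image(B, angles[a])
    }
    accum * dphi / (4 * pi)
  }
  if (length(d) == 2) {
    dens <- fbp_slice(sd$data, sd$angles, sd$dphi)
    ri_map(geometry$medium_index + dens / k0, geometry)
  } else {
    ny <- d[2]; nx <- d[3]
    vol <- array(0, c(nx, ny, nx))
    for (y in seq_len(ny))
      vol[, y, ] <- geometry$medium_index +
        fbp_slice(sd$data[, y, ], sd$angles, sd$dphi) / k0
    ri_map(vol, geometry)
  }
}

#' Refractive index from the recovered object function
#'
#' Inverts \eqn{f = k_m^2[(n/n_m)^2 - 1]}:
#' \eqn{n = n_m \sqrt{1 + f/k_m^2}} on the complex field. Voxels where
#' \eqn{1 + \mathrm{Re}(f)/k_m^2 < 0} are clamped to zero real argument
#' before the square root; their count is attached as attribute
#' `clamped_voxels` and reported in a warning. Metrics consume the real
#' part.
#'
#' @param obj an [object_map()].
#' @param geometry an [imaging_geometry()]; defaults to the map's.
#' @return an [ri_map()] (complex in general).
#' @export
object_to_ri <- function(obj, geometry = NULL) {
  stopifnot(inherits(obj, "object_map"))
  if (is.null(geometry)) geometry <- obj$geometry
  km <- wavenumbers(geometry)[["km"]]
  arg <- 1 + obj$f / km^2
  bad <- Re(arg) < 0
  nbad <- sum(bad)
  if (nbad > 0) {
    warning(sprintf("%d voxel(s) with negative real argument clamped to 0", nbad))
    arg[bad] <- complex(real = 0, imaginary = Im(arg[bad]))
  }
  n <- geometry$medium_index * sqrt(arg)
  out <- ri_map(n, geometry)
  attr(out, "clamped_voxels") <- nbad
  out
}

#' Inscribed reconstruction mask
#'
#' Logical mask of the inscribed circle (2D) or sphere (3D) of radius `N/2`
#' about the grid center. Points outside it do not receive contributions
#' from all projections and are excluded from the error metrics.
#'
#' @param shape integer vector `c(N, N)` or `c(N, N, N)`, or a map object.
#' @return logical array of the given shape.
#' @export
inscribed_mask <- function(shape) {
  if (inherits(shape, "ri_map")) shape <- dim(shape$n)
  if (inherits(shape, "object_map")) shape <- dim(shape$f)
  if (!(length(shape) %in% c(2, 3)) || length(unique(shape)) != 1)
    stop("inscribed_mask requires a square or cubic shape")
  n <- shape[1]
  co <- grid_coords(n)
  r2 <- (n / 2)^2
  if (length(shape) == 2) {
    outer(co^2, co^2, `+`) < r2
  } else {
    arr <- array(0, shape)
    C2 <- outer(co^2, co^2, `+`)  # (z, y)
    for (x in seq_len(n)) arr[, , x] <- C2 + co[x]^2
    arr < r2
  }
}
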