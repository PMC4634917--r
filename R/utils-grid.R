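# Grid, FFT and rotation conventions shared by the forward models and the
# reconstruction algorithms.
#
# Conventions (fixed package-wide, asserted in tests):
#   * all lengths in detector pixels, pixel pitch 1;
#   * the grid center (= rotation axis) sits at 0-based index floor(N/2),
#     i.e. R index floor(N/2) + 1, for even and odd N alike;
#   * spatial coordinates are taken relative to that center;
#   * "centered" transforms below evaluate sum_x v(x) exp(-i k (x - x_c)),
#     implemented exactly via circular shifts around plain fft() calls;
#   * incident plane wave exp(+i k_m z), propagation along +z (rows).

#' @keywords internal
grid_center0 <- function(n) floor(n / 2)  # 0-based center index

#' Coordinates of the n grid points relative to the grid center (pixels).
#' @keywords internal
grid_coords <- function(n) seq_len(n) - 1 - grid_center0(n)

#' Angular spatial frequencies in fft() output order, length m.
#' @keywords internal
kgrid <- function(m) {
  j <- seq_len(m) - 1
  j[j >= ceiling(m / 2)] <- j[j >= ceiling(m / 2)] - m
  2 * pi * j / m
}

#' Padded transform length: next power of two of twice the grid size.
#' @keywords internal
pad_length <- function(n) 2^ceiling(log2(2 * n))

# Padded length accounting for the transverse spread of a field propagated
# over a distance ld at NA = 1: the periodic replicas of the FFT model must
# stay clear of the detector window; the Hankel tails of the replicas
# decay only algebraically, so a generous margin M >= 2 n + 8 |ld| is used.
# Reduces to pad_length() for ld = 0 (refocused data).
#' @keywords internal
pad_length_prop <- function(n, ld) 2^ceiling(log2(2 * n + 8 * abs(ld)))

# Circular shift of a vector by s positions (element i -> i + s, wrapped).
#' @keywords internal
circshift <- function(v, s) {
  n <- length(v)
  if (n == 0) return(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else c(v[(n - s + 1):n], v[1:(n - s)])
}

# Centered 1D FFT pair: cfft(v)[j] = sum_x v[x] exp(-i k_j (x - x_c)).
#' @keywords internal
cfft <- function(v) stats::fft(circshift(v, -grid_center0(length(v))))

#' @keywords internal
cifft <- function(w) {
  n <- length(w)
  circshift(stats::fft(w, inverse = TRUE) / n, grid_center0(n))
}

# Column-wise centered FFT of a matrix (each column transformed).
#' @keywords internal
cfft_cols <- function(m) {
  n <- nrow(m)
  c0 <- grid_center0(n)
  idx <- circshift(seq_len(n), -c0)
  stats::mvfft(m[idx, , drop = FALSE])
}

#' @keywords internal
cifft_cols <- function(m) {
  n <- nrow(m)
  c0 <- grid_center0(n)
  out <- stats::mvfft(m, inverse = TRUE) / n
  out[circshift(seq_len(n), -c0), , drop = FALSE]
}

# Centered 2D FFT of a matrix over both dimensions.
#' @keywords internal
cfft2 <- function(m) {
  i1 <- circshift(seq_len(nrow(m)), -grid_center0(nrow(m)))
  i2 <- circshift(seq_len(ncol(m)), -grid_center0(ncol(m)))
  stats::fft(m[i1, i2, drop = FALSE])
}

#' @keywords internal
cifft2 <- function(m) {
  i1 <- circshift(seq_len(nrow(m)), -grid_center0(nrow(m)))
  i2 <- circshift(seq_len(ncol(m)), -grid_center0(ncol(m)))
  out <- stats::fft(m, inverse = TRUE) / length(m)
  out[order(i1), order(i2), drop = FALSE]
}

# Embed a vector/matrix centered on an enlarged zero grid (and its inverse).
# The center voxel of the input lands on the center voxel of the output.
#' @keywords internal
pad_center_vec <- function(v, m, fill = 0) {
  n <- length(v)
  off <- grid_center0(m) - grid_center0(n)
  out <- rep(fill + 0 * v[1], m)
  out[off + seq_len(n)] <- v
  out
}

#' @keywords internal
crop_center_vec <- function(v, n) {
  off <- grid_center0(length(v)) - grid_center0(n)
  v[off + seq_len(n)]
}

#' @keywords internal
pad_center_mat <- function(m, m1, m2, fill = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  o1 <- grid_center0(m1) - grid_center0(n1)
  o2 <- grid_center0(m2) - grid_center0(n2)
  out <- matrix(fill + 0 * m[1], m1, m2)
  out[o1 + seq_len(n1), o2 + seq_len(n2)] <- m
  out
}

#' @keywords internal
crop_center_mat <- function(m, n1, n2) {
  o1 <- grid_center0(nrow(m)) - grid_center0(n1)
  o2 <- grid_center0(ncol(m)) - grid_center0(n2)
  m[o1 + seq_len(n1), o2 + seq_len(n2), drop = FALSE]
}

# Bilinear sampling map for an in-plane rotation by `theta` about the grid
# center: returns, for every target pixel of an n1 x n2 (rows = z, cols = x)
# image, the four source corner indices and weights. Shared by image and
# volume rotation so forward models and inverters use one convention.
#' @keywords internal
rotation_map <- function(n1, n2, theta) {
  zc <- grid_coords(n1)
  xc <- grid_coords(n2)
  Z <- matrix(zc, n1, n2)
  X <- matrix(xc, n1, n2, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  # source point = R(-theta) applied to (x, z): content rotates by +theta
  xs <- ct * X + st * Z
  zs <- -st * X + ct * Z
  iz <- zs + grid_center0(n1) + 1   # fractional R row index
  ix <- xs + grid_center0(n2) + 1   # fractional R col index
  z0 <- floor(iz); x0 <- floor(ix)
  fz <- iz - z0;   fx <- ix - x0
  inside <- z0 >= 1 & z0 + 1 <= n1 & x0 >= 1 & x0 + 1 <= n2
  # clamp out-of-range corners to 1 so indices stay legal; masked later
  z0c <- pmin(pmax(z0, 1), n1 - 1)
  x0c <- pmin(pmax(x0, 1), n2 - 1)
  list(
    i00 = cbind(as.vector(z0c), as.vector(x0c)),
    w00 = as.vector((1 - fz) * (1 - fx)),
    w10 = as.vector(fz * (1 - fx)),
    w01 = as.vector((1 - fz) * fx),
    w11 = as.vector(fz * fx),
    inside = as.vector(inside),
    n1 = n1, n2 = n2
  )
}

# Apply a rotation map to a (possibly complex) matrix.
#' @keywords internal
apply_rotation_map <- function(m, map, fill = 0) {
  i00 <- map$i00
  lin00 <- (i00[, 2] - 1) * map$n1 + i00[, 1]
  v <- map$w00 * m[lin00] +
    map$w10 * m[lin00 + 1] +
    map$w01 * m[lin00 + map$n1] +
    map$w11 * m[lin00 + map$n1 + 1]
  v[!map$inside] <- fill
  matrix(v, map$n1, map$n2)
}

#' Rotate an image about the grid center (bilinear interpolation).
#'
#' Rows are the propagation axis z, columns the detector axis x; positive
#' `theta` rotates the image content counter-clockwise in the (x, z) plane.
#' Used by the ray-integral and diffraction forward models and, with the
#' opposite angle, by the reconstruction algorithms.
#'
#' @param m numeric or complex matrix.
#' @param theta rotation angle in radians.
#' @param fill value for pixels rotated in from outside the grid.
#' @return matrix of the same shape as `m`.
#' @keywords internal
rotate_image <- function(m, theta, fill = 0) {
  if (abs(theta %% (2 * pi)) < 1e-15) return(m)
  apply_rotation_map(m, rotation_map(nrow(m), ncol(m), theta), fill)
}

# Rotate a volume dim (Nz, Ny, Nx) about the y axis: every y slice (z, x)
# undergoes the same in-plane rotation. Vectorized across y.
#' @keywords internal
rotate_volume_y <- function(vol, theta, fill = 0) {
  d <- dim(vol)
  if (abs(theta %% (2 * pi)) < 1e-15) return(vol)
  map <- rotation_map(d[1], d[3], theta)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  i00 <- map$i00
  # linear index within a (z, x) slice of the (z, y, x) volume at fixed y:
  # lin(z, y, x) = z + (y-1) nz + (x-1) nz ny
  base <- i00[, 1] + (i00[, 2] - 1) * nz * ny        # y = 1 plane
  out <- array(fill + 0 * vol[1], d)
  dz <- 1; dx <- nz * ny
  for (y in seq_len(ny)) {
    lin <- base + (y - 1) * nz
    v <- map$w00 * vol[lin] + map$w10 * vol[lin + dz] +
      map$w01 * vol[lin + dx] + map$w11 * vol[lin + dz + dx]
    v[!map$inside] <- fill
    out[, y, ] <- matrix(v, nz, nx)
  }
  out
}

#' @keywords internal
relative_l2 <- function(a, b) {
  d <- sqrt(sum(Mod(a - b)^2))
  r <- sqrt(sum(Mod(b)^2))
  if (r == 0) return(if (d == 0) 0 else Inf)
  d / r
}
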