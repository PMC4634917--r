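# Shared fixtures, all generated in code.

water_geometry <- function(wavelength = 4, detector_distance = 0)
  imaging_geometry(wavelength, 1.333, detector_distance)

# homogeneous disk of refractive-index excess dn, radius in pixels
disk_phantom_2d <- function(grid, radius, dn, geometry = water_geometry(),
                            center = c(0, 0)) {
  co <- seq_len(grid) - 1 - floor(grid / 2)
  Z <- matrix(co, grid, grid)
  X <- matrix(co, grid, grid, byrow = TRUE)
  n <- matrix(geometry$medium_index, grid, grid)
  n[(X - center[1])^2 + (Z - center[2])^2 <= radius^2] <-
    geometry$medium_index + dn
  ri_map(n, geometry)
}

# y-extruded version of a 2D map
extrude_y <- function(map2d) {
  n <- dim(map2d$n)[1]
  vol <- array(0, c(n, n, n))
  for (y in seq_len(n)) vol[, y, ] <- map2d$n
  ri_map(vol, map2d$geometry)
}

# band-limited, nearly pure-phase detector field (in focus: almost flat
# amplitude). Band limitation keeps it free of evanescent components for a
# wavelength of 4 px (k_m ~ 2.09 rad/px).
phase_object_field <- function(n, amplitude = 1, cutoff = 0.8) {
  co <- seq(-1, 1, length.out = n)
  ph <- amplitude * (exp(-(co / 0.3)^2) + 0.5 * exp(-((co - 0.4) / 0.25)^2))
  f <- stats::fft(exp(1i * ph))
  k <- 2 * pi * (seq_len(n) - 1) / n
  k[k >= pi] <- k[k >= pi] - 2 * pi
  f[abs(k) >= cutoff * 2 * pi * 1.333 / 4] <- 0i
  stats::fft(f, inverse = TRUE) / n
}

wrap_to_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# remove a global multiple of 2*pi before comparing unwrapped phases
align_offset <- function(x, ref) x - 2 * pi * round(stats::median(x - ref) / (2 * pi))

grid_coords_test <- function(n) seq_len(n) - 1 - floor(n / 2)
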