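# Three-compartment cell phantoms: a cytoplasm disk/sphere containing an
# offset nucleus (ellipse/ellipsoid) which in turn contains a small nucleolus.
# Piecewise-constant refractive index, used as ground truth for the
# reconstruction-error metrics.

#' Specification of the three-compartment cell phantom
#'
#' Geometry is parameterized in units of the cytoplasm radius `a`, so the
#' whole phantom scales with its diameter. Defaults give a cell of diameter \eqn{2a = 17\lambda} with refractive
#' indices medium 1.333, cytoplasm 1.365, nucleus 1.360 and nucleolus 1.387
#' — typical values for biological cells in aqueous medium.
#'
#' @param diameter_wl cell (cytoplasm) diameter `2a`, in vacuum wavelengths.
#' @param n_medium,n_cytoplasm,n_nucleus,n_nucleolus refractive indices
#'   (all >= 1).
#' @param nucleus_semiaxes_a nucleus semi-axes along (x, z, y), as fractions
#'   of `a`.
#' @param nucleus_offset_a nucleus center offset along (x, z, y), as
#'   fractions of `a`.
#' @param nucleolus_radius_a nucleolus radius as a fraction of `a`.
#' @param nucleolus_center_a nucleolus center along (x, z, y) as fractions
#'   of `a`; the default places it 2 wavelengths from the volume center for
#'   the default 17-wavelength cell and scales with the cell.
#' @return object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' spec$n_nucleolus
#' @export
phantom_spec <- function(diameter_wl = 17,
                         n_medium = 1.333,
                         n_cytoplasm = 1.365,
                         n_nucleus = 1.360,
                         n_nucleolus = 1.387,
                         nucleus_semiaxes_a = c(0.6, 0.55, 0.55),
                         nucleus_offset_a = c(-0.1, 0.08, 0),
                         nucleolus_radius_a = 0.12,
                         nucleolus_center_a = c(4, 4, 4) / 17) {
  stopifnot(diameter_wl > 0)
  ris <- c(n_medium, n_cytoplasm, n_nucleus, n_nucleolus)
  if (any(ris < 1)) stop("all refractive indices must be >= 1")
  stopifnot(length(nucleus_semiaxes_a) == 3, all(nucleus_semiaxes_a > 0),
            length(nucleus_offset_a) == 3, nucleolus_radius_a > 0,
            length(nucleolus_center_a) == 3)
  spec <- structure(
    list(diameter_wl = diameter_wl,
         n_medium = n_medium, n_cytoplasm = n_cytoplasm,
         n_nucleus = n_nucleus, n_nucleolus = n_nucleolus,
         nucleus_semiaxes_a = nucleus_semiaxes_a,
         nucleus_offset_a = nucleus_offset_a,
         nucleolus_radius_a = nucleolus_radius_a,
         nucleolus_center_a = nucleolus_center_a),
    class = "phantom_spec")
  # nesting invariants (sufficient conservative checks)
  a <- 1  # work in units of a
  if (max(abs(spec$nucleus_offset_a) + spec$nucleus_semiaxes_a) >= a)
    stop("nucleus is not strictly inside the cytoplasm")
  # nucleolus-in-nucleus check: sample the nucleolus surface (units of a)
  cc <- nucleolus_center_a - nucleus_offset_a
  u <- seq(0, pi, length.out = 24)
  v <- seq(0, 2 * pi, length.out = 48)
  dirs <- cbind(as.vector(outer(sin(u), cos(v))),
                as.vector(outer(sin(u), sin(v))),
                as.vector(outer(cos(u), rep(1, length(v)))))
  p <- sweep(dirs * nucleolus_radius_a, 2, cc, "+")
  phi <- (p[, 1] / nucleus_semiaxes_a[1])^2 +
    (p[, 2] / nucleus_semiaxes_a[2])^2 +
    (p[, 3] / nucleus_semiaxes_a[3])^2
  if (max(phi) >= 1)
    stop("nucleolus is not strictly inside the nucleus")
  spec
}

# innermost-compartment RI lookup for points (x, z[, y]) in pixels from center
phantom_lookup <- function(spec, wavelength_px, x, z, y = NULL) {
  a <- spec$diameter_wl * wavelength_px / 2
  n <- rep(spec$n_medium, length(x))
  two_d <- is.null(y)
  if (two_d) y <- rep(0, length(x))
  # cytoplasm sphere/disk
  in_cyto <- x^2 + z^2 + y^2 <= a^2
  n[in_cyto] <- spec$n_cytoplasm
  # nucleus ellipse/ellipsoid, axes (x, z, y)
  sx <- spec$nucleus_semiaxes_a[1] * a
  sz <- spec$nucleus_semiaxes_a[2] * a
  sy <- spec$nucleus_semiaxes_a[3] * a
  ox <- spec$nucleus_offset_a[1] * a
  oz <- spec$nucleus_offset_a[2] * a
  oy <- if (two_d) 0 else spec$nucleus_offset_a[3] * a
  in_nuc <- ((x - ox) / sx)^2 + ((z - oz) / sz)^2 + ((y - oy) / sy)^2 <= 1
  n[in_nuc & in_cyto] <- spec$n_nucleus
  # nucleolus disk/sphere, position scaling with the cell radius
  cc <- spec$nucleolus_center_a * a
  rn <- spec$nucleolus_radius_a * a
  cy <- if (two_d) 0 else cc[3]
  in_nll <- (x - cc[1])^2 + (z - cc[2])^2 + (y - cy)^2 <= rn^2
  n[in_nll & in_nuc & in_cyto] <- spec$n_nucleolus
  n
}

#' Rasterize the 2D cell phantom
#'
#' Each pixel takes the refractive index of the innermost compartment
#' containing its center (no anti-aliasing), yielding the piecewise-constant
#' ground truth required by the reconstruction-error metrics. Rows of the
#' returned map are the propagation axis z, columns the detector axis x,
#' with the rotation axis at 0-based index `floor(N/2)`.
#'
#' @param grid_size side length N of the square grid, pixels.
#' @param wavelength_px vacuum wavelength in pixels.
#' @param spec a [phantom_spec()].
#' @param geometry optional [imaging_geometry()]; defaults to
#'   `imaging_geometry(wavelength_px, spec$n_medium)`.
#' @return an [ri_map()] of shape `N x N`.
#' @examples
#' ph <- make_cell_phantom_2d(64, 3)
#' sort(unique(as.vector(ph$n)))
#' @export
make_cell_phantom_2d <- function(grid_size, wavelength_px,
                                 spec = phantom_spec(), geometry = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$diameter_wl * wavelength_px >= grid_size)
    stop(sprintf("cell (%g px) exceeds the grid (%d px)",
                 spec$diameter_wl * wavelength_px, grid_size))
  if (is.null(geometry))
    geometry <- imaging_geometry(wavelength_px, spec$n_medium)
  co <- grid_coords(grid_size)
  Z <- matrix(co, grid_size, grid_size)
  X <- matrix(co, grid_size, grid_size, byrow = TRUE)
  n <- phantom_lookup(spec, wavelength_px, as.vector(X), as.vector(Z))
  ri_map(matrix(n, grid_size, grid_size), geometry)
}

#' Rasterize the 3D cell phantom
#'
#' Spherical cytoplasm, ellipsoidal nucleus and spherical nucleolus (centered
#' 2 wavelengths from the volume center along each axis by default). The
#' volume has dimensions `(Nz, Ny, Nx)`; the specimen rotates about y.
#'
#' @inheritParams make_cell_phantom_2d
#' @param extrude_y if `TRUE`, build the 2D phantom and replicate it along y
#'   (a y-invariant specimen, useful for 2D/3D consistency checks).
#' @return an [ri_map()] of shape `N x N x N`.
#' @export
make_cell_phantom_3d <- function(grid_size, wavelength_px,
                                 spec = phantom_spec(), geometry = NULL,
                                 extrude_y = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$diameter_wl * wavelength_px >= grid_size)
    stop(sprintf("cell (%g px) exceeds the grid (%d px)",
                 spec$diameter_wl * wavelength_px, grid_size))
  if (is.null(geometry))
    geometry <- imaging_geometry(wavelength_px, spec$n_medium)
  if (extrude_y) {
    m2 <- make_cell_phantom_2d(grid_size, wavelength_px, spec, geometry)$n
    vol <- array(0, c(grid_size, grid_size, grid_size))
    for (y in seq_len(grid_size)) vol[, y, ] <- m2
    return(ri_map(vol, geometry))
  }
  co <- grid_coords(grid_size)
  g <- expand.grid(z = co, y = co, x = co)  # matches dim (Nz, Ny, Nx)
  n <- phantom_lookup(spec, wavelength_px, g$x, g$z, g$y)
  ri_map(array(n, c(grid_size, grid_size, grid_size)), geometry)
}

#' Refractive-index contrast series for the phantom
#'
#' Interpolates the compartment refractive indices linearly from a uniform
#' value just above water (all compartments 1.334 at `t = 0`) to a
#' high-contrast endpoint (cytoplasm 1.455, nucleus 1.435, nucleolus 1.543 at
#' `t = 1`), with the medium fixed at 1.333 — the contrast ladder used to
#' study how reconstruction quality degrades with increasing refractive-index
#' variation.
#'
#' @param t position in the series, in `[0, 1]`.
#' @param ... further arguments passed to [phantom_spec()] (geometry knobs).
#' @return a [phantom_spec()].
#' @examples
#' ri_series(0.5)[c("n_cytoplasm", "n_nucleus", "n_nucleolus")]
#' @export
ri_series <- function(t, ...) {
  stopifnot(is.numeric(t), length(t) == 1)
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  lo <- c(1.334, 1.334, 1.334)
  hi <- c(1.455, 1.435, 1.543)
  v <- lo + t * (hi - lo)
  phantom_spec(n_medium = 1.333, n_cytoplasm = v[1], n_nucleus = v[2],
               n_nucleolus = v[3], ...)
}
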