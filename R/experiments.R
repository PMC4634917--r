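# Deterministic sweep drivers reproducing the three reconstruction-quality
# studies at desk scale: error versus projection count, versus
# refractive-index contrast, and versus object size. One forward simulation
# per condition; the Born, Rytov and Radon data are all derived from the
# same complex fields and inverted with the matching algorithm.

reconstruct_all <- function(sino, phantom, approximations, dims) {
  res <- list()
  for (ap in approximations) {
    rec <- switch(ap,
      born = object_to_ri(
        if (dims == 2) backpropagate_2d(to_born_data(sino))
        else backpropagate_3d(to_born_data(sino))),
      rytov = object_to_ri(
        if (dims == 2) backpropagate_2d(to_rytov_data(sino))
        else backpropagate_3d(to_rytov_data(sino))),
      radon = filtered_backprojection(to_radon_data(sino)))
    res[[ap]] <- error_report(phantom, rec)
  }
  res
}

sweep_rows <- function(value, reports, dims) {
  do.call(rbind, lapply(names(reports), function(ap)
    data.frame(value = value, approximation = ap, dims = dims,
               e_rms = reports[[ap]]$e_rms, e_tv = reports[[ap]]$e_tv)))
}

as_sweep_result <- function(df, sweep, meta) {
  rownames(df) <- NULL
  structure(df, class = c("sweep_result", "data.frame"),
            sweep = sweep, meta = meta)
}

#' Reconstruction error versus number of projections
#'
#' For each projection count a Rytov-consistent complex-field sinogram of
#' the phantom is simulated, the Born/Rytov/Radon data are derived from the
#' same fields, each is inverted with its matching algorithm and both error
#' metrics are computed against the phantom. Deterministic for
#' `noise_sigma = 0`; with noise, seed R's RNG for reproducibility.
#'
#' @param counts ascending vector of projection counts (each >= 4);
#'   duplicates are dropped with a warning.
#' @param phantom an [ri_map()] (2D or 3D) serving as ground truth.
#' @param geometry an [imaging_geometry()]; defaults to the phantom's.
#' @param approximations subset of `c("born", "rytov", "radon")`.
#' @param noise_sigma complex noise level passed to [rytov_forward()].
#' @return a `sweep_result` data frame with columns `value` (projection
#'   count), `approximation`, `dims`, `e_rms`, `e_tv` (percent).
#' @export
sweep_projections <- function(counts, phantom, geometry = NULL,
                              approximations = c("born", "rytov", "radon"),
                              noise_sigma = 0) {
  stopifnot(inherits(phantom, "ri_map"))
  if (is.null(geometry)) geometry <- phantom$geometry
  if (is.unsorted(counts)) stop("counts must be sorted ascending")
  if (any(counts < 4)) stop("projection counts below 4 are rejected")
  if (anyDuplicated(counts)) {
    warning("duplicate projection counts dropped")
    counts <- unique(counts)
  }
  dims <- length(dim(phantom$n))
  obj <- object_from_ri(phantom, geometry)
  rows <- lapply(counts, function(cnt) {
    sino <- rytov_forward(obj, full_turn_angles(cnt), geometry, noise_sigma)
    sweep_rows(cnt, reconstruct_all(sino, phantom, approximations, dims), dims)
  })
  as_sweep_result(do.call(rbind, rows), "projections",
                  list(grid = dim(phantom$n)[1],
                       wavelength_px = geometry$wavelength,
                       noise_sigma = noise_sigma))
}

#' Plateau onset of a projection-count sweep
#'
#' The smallest sampled projection count from which on every successive
#' change of both error metrics stays below `threshold_pp` percentage
#' points — the point beyond which adding projections no longer improves
#' the reconstruction. If the errors never settle, the largest count is
#' returned with attribute `reached = FALSE` and a warning.
#'
#' @param sweep a `sweep_result` from [sweep_projections()].
#' @param threshold_pp plateau threshold, percentage points (absolute).
#' @param approximation which approximation's rows to use.
#' @param dims which dimensionality's rows to use (default: the only one
#'   present).
#' @return the onset projection count (with attribute `reached`).
#' @export
plateau_onset <- function(sweep, threshold_pp = 1.0,
                          approximation = "rytov", dims = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep[sweep$approximation == approximation, , drop = FALSE]
  if (!is.null(dims)) df <- df[df$dims == dims, , drop = FALSE]
  df <- df[order(df$value), , drop = FALSE]
  if (nrow(df) < 3) stop("plateau detection needs at least 3 sampled counts")
  # successive changes; the first sample has no incoming change
  d_rms <- c(0, abs(diff(df$e_rms)))
  d_tv <- c(0, abs(diff(df$e_tv)))
  settled <- d_rms < threshold_pp & d_tv < threshold_pp
  # smallest index i such that all j >= i are settled
  ok <- rev(cumprod(rev(settled))) > 0
  if (!any(ok)) {
    warning("errors never settle below the threshold; returning largest count")
    return(structure(df$value[nrow(df)], reached = FALSE))
  }
  structure(df$value[which(ok)[1]], reached = TRUE)
}

#' Reconstruction error versus refractive-index contrast
#'
#' Sweeps the phantom's compartment refractive indices along the linear
#' series of [ri_series()] at a fixed number of projections.
#'
#' @param steps vector of series positions `t` in `[0, 1]`.
#' @param geometry an [imaging_geometry()] (supplies the wavelength).
#' @param dims 2 or 3.
#' @param grid_size reconstruction grid side, pixels.
#' @param n_angles number of projections (default 200).
#' @inheritParams sweep_projections
#' @return a `sweep_result` with `value = t`.
#' @export
sweep_ri <- function(steps, geometry, dims = 2,
                     grid_size = if (dims == 2) 128 else 64,
                     n_angles = 200,
                     approximations = c("born", "rytov", "radon"),
                     noise_sigma = 0) {
  stopifnot(inherits(geometry, "imaging_geometry"), dims %in% c(2, 3))
  rows <- lapply(steps, function(t) {
    spec <- ri_series(t)
    ph <- if (dims == 2)
      make_cell_phantom_2d(grid_size, geometry$wavelength, spec, geometry)
    else
      make_cell_phantom_3d(grid_size, geometry$wavelength, spec, geometry)
    sino <- rytov_forward(object_from_ri(ph, geometry),
                          full_turn_angles(n_angles), geometry, noise_sigma)
    sweep_rows(t, reconstruct_all(sino, ph, approximations, dims), dims)
  })
  as_sweep_result(do.call(rbind, rows), "ri",
                  list(grid = grid_size, wavelength_px = geometry$wavelength,
                       n_angles = n_angles, noise_sigma = noise_sigma))
}

#' Reconstruction error versus object size
#'
#' Varies the cell diameter at a fixed simulation-volume extent (fixed grid
#' and resolution), at a fixed number of projections. Larger cells fill
#' more of the fixed grid and are harder to reconstruct.
#'
#' @param diameters_wl cell diameters in wavelengths, all strictly smaller
#'   than `volume_extent_wl`.
#' @param volume_extent_wl extent of the simulation volume, wavelengths.
#' @inheritParams sweep_ri
#' @return a `sweep_result` with `value =` diameter in wavelengths.
#' @export
sweep_size <- function(diameters_wl, volume_extent_wl, geometry, dims = 2,
                       n_angles = 200,
                       approximations = c("born", "rytov", "radon"),
                       noise_sigma = 0) {
  stopifnot(inherits(geometry, "imaging_geometry"), dims %in% c(2, 3))
  if (any(diameters_wl >= volume_extent_wl))
    stop("cell diameter must be strictly smaller than the volume extent")
  grid_size <- ceiling(volume_extent_wl * geometry$wavelength)
  rows <- lapply(diameters_wl, function(dw) {
    spec <- phantom_spec(diameter_wl = dw)
    ph <- if (dims == 2)
      make_cell_phantom_2d(grid_size, geometry$wavelength, spec, geometry)
    else
      make_cell_phantom_3d(grid_size, geometry$wavelength, spec, geometry)
    sino <- rytov_forward(object_from_ri(ph, geometry),
                          full_turn_angles(n_angles), geometry, noise_sigma)
    sweep_rows(dw, reconstruct_all(sino, ph, approximations, dims), dims)
  })
  as_sweep_result(do.call(rbind, rows), "size",
                  list(grid = grid_size, wavelength_px = geometry$wavelength,
                       volume_extent_wl = volume_extent_wl,
                       n_angles = n_angles, noise_sigma = noise_sigma))
}

#' Plot a sweep result
#'
#' Line plot of both error metrics against the sweep variable, one line per
#' approximation. Requires ggplot2.
#'
#' @param sweep a `sweep_result`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep requires the ggplot2 package")
  long <- rbind(
    data.frame(value = sweep$value, approximation = sweep$approximation,
               dims = sweep$dims, metric = "E_RMS", error = sweep$e_rms),
    data.frame(value = sweep$value, approximation = sweep$approximation,
               dims = sweep$dims, metric = "E_TV", error = sweep$e_tv))
  xlab <- switch(attr(sweep, "sweep"),
                 projections = "number of projections",
                 ri = "contrast series position t",
                 size = "cell diameter (wavelengths)",
                 "sweep variable")
  ggplot2::ggplot(long, ggplot2::aes(x = value, y = error,
                                     colour = approximation)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = xlab, y = "normalized error (%)")
}
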