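# Step (a) of the reconstruction pipeline: turn measured complex fields into
# Born / Rytov / Radon scattering data. Includes angular-spectrum refocusing
# with a gradient-metric autofocus and phase unwrapping (simple cumulative
# 2*pi correction along the detector for 2D sinograms; quality-guided,
# reliability-sorted region merging for 2D images / 3D sinograms).

#' Angular-spectrum free-space propagation
#'
#' Propagates a detector field over a distance `d` by multiplying its
#' spatial-frequency spectrum with \eqn{\exp(i \gamma d)},
#' \eqn{\gamma = \sqrt{k_m^2 - k_\perp^2}}; evanescent components
#' (\eqn{k_\perp \ge k_m}) are zeroed. The transform is taken on the field's
#' own periodic grid (no padding), so propagation of band-limited fields is
#' exactly unitary and `propagate(propagate(x, d), -d) == x`.
#'
#' @param field complex vector (1D field) or matrix (2D field, rows y,
#'   cols x).
#' @param distance propagation distance in pixels (positive = along +z).
#' @param geometry an [imaging_geometry()].
#' @return refocused field, same shape as the input.
#' @export
propagate <- function(field, distance, geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field + 0i))))
    stop("field contains non-finite values")
  km <- wavenumbers(geometry)[["km"]]
  if (is.matrix(field)) {
    ky <- kgrid(nrow(field)); kx <- kgrid(ncol(field))
    K2 <- outer(ky^2, kx^2, `+`)
    gam <- sqrt(pmax(km^2 - K2, 0))
    H <- ifelse(K2 < km^2, exp(1i * gam * distance), 0i)
    cifft2(cfft2(field + 0i) * H)
  } else {
    k <- kgrid(length(field))
    gam <- sqrt(pmax(km^2 - k^2, 0))
    H <- ifelse(k^2 < km^2, exp(1i * gam * distance), 0i)
    cifft(cfft(field + 0i) * H)
  }
}

# sharpness metric: total absolute forward-difference gradient of |field|
amplitude_gradient_metric <- function(field) {
  a <- Mod(field)
  if (is.matrix(a)) sum(abs(diff(a))) + sum(abs(t(diff(t(a)))))
  else sum(abs(diff(a)))
}

#' Autofocus by minimizing the amplitude-gradient metric
#'
#' Searches the propagation distance that minimizes the total gradient of
#' the field amplitude — in focus, a phase object shows minimal amplitude
#' contrast. A coarse grid of `n_coarse` candidate distances over
#' `search_interval` is scanned, then the bracketed minimum is refined by
#' golden-section search to a tolerance of `lambda/100`.
#'
#' @param field complex vector or matrix.
#' @param geometry an [imaging_geometry()].
#' @param search_interval numeric length-2 interval of distances, pixels.
#' @param n_coarse number of coarse candidates (default 50).
#' @return list with `distance` (the argmin), `field` (the refocused field),
#'   `metric` (its metric value) and `ambiguous` (`TRUE` when the coarse
#'   metric has several local minima, in which case the global grid minimum
#'   is refined and returned with a warning).
#' @export
autofocus <- function(field, geometry, search_interval, n_coarse = 50) {
  stopifnot(length(search_interval) == 2, diff(search_interval) > 0)
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field + 0i))))
    stop("field contains non-finite values")
  ds <- seq(search_interval[1], search_interval[2], length.out = n_coarse)
  vals <- vapply(ds, function(d)
    amplitude_gradient_metric(propagate(field, d, geometry)), numeric(1))
  i <- which.min(vals)
  n_min <- sum(diff(sign(diff(vals))) > 0) +
    (vals[1] < vals[2]) + (vals[n_coarse] < vals[n_coarse - 1])
  ambiguous <- n_min > 1
  if (ambiguous)
    warning("autofocus metric is not unimodal in the interval; ",
            "returning the refined global grid minimum")
  lo <- ds[max(i - 1, 1)]; hi <- ds[min(i + 1, n_coarse)]
  opt <- stats::optimize(function(d)
    amplitude_gradient_metric(propagate(field, d, geometry)),
    lower = lo, upper = hi, tol = geometry$wavelength / 100)
  best <- opt$minimum
  list(distance = best, field = propagate(field, best, geometry),
       metric = opt$objective, ambiguous = ambiguous)
}

# wrap to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' One-dimensional phase unwrapping
#'
#' Cumulative 2*pi correction along a line: whenever the jump between
#' neighboring samples exceeds pi in magnitude, a multiple of 2*pi is added
#' to all following samples. A final global offset places the median of the
#' endpoint phases in `(-pi, pi]` (background pixels carry ~zero phase).
#'
#' @param wrapped numeric vector of wrapped phases.
#' @return numeric vector; differs from `wrapped` by integer multiples of
#'   2*pi at every sample.
#' @export
unwrap_phase_1d <- function(wrapped) {
  n <- length(wrapped)
  if (n < 2) return(wrapped)
  d <- diff(wrapped)
  corr <- cumsum(-2 * pi * round(d / (2 * pi)))
  out <- wrapped + c(0, corr)
  med <- stats::median(out[c(1, n)])
  out - 2 * pi * floor((med + pi) / (2 * pi))
}

#' Quality-guided two-dimensional phase unwrapping
#'
#' Implements reliability-sorted region-merging unwrapping: each pixel gets
#' a reliability from the inverse magnitude of its wrapped second
#' differences (horizontal, vertical and both diagonals); edges between
#' 4-neighbors are sorted by the sum of their pixels' reliabilities
#' (noncontinuous path) and processed in that order, merging pixel groups
#' with the integer 2*pi offset that reconciles them. Ties in edge
#' reliability are broken by the enumeration order (all horizontal edges in
#' column-major order, then all vertical edges); the sort is stable.
#'
#' @param wrapped numeric matrix of wrapped phases in `(-pi, pi]`.
#' @return list of class `unwrap_result`: `phase` (unwrapped, equal to the
#'   input modulo 2*pi at every pixel, global offset fixed so the median
#'   border phase lies in `(-pi, pi]`), `reliability` (per-pixel map, higher
#'   is better) and `branch_cuts` (number of group merges that required a
#'   nonzero 2*pi offset).
#' @export
unwrap_phase_2d <- function(wrapped) {
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  n1 <- nrow(wrapped); n2 <- ncol(wrapped)
  np <- n1 * n2
  if (n1 < 2 || n2 < 2) {
    ph <- unwrap_phase_1d(as.vector(wrapped))
    return(structure(list(phase = matrix(ph, n1, n2),
                          reliability = matrix(1, n1, n2), branch_cuts = 0L),
                     class = "unwrap_result"))
  }
  p <- wrapped
  # second differences with replicated borders
  pad <- p[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  ctr <- pad[2:(n1 + 1), 2:(n2 + 1)]
  sd2 <- function(a, b) wrap_phase(a - ctr) - wrap_phase(ctr - b)
  H  <- sd2(pad[2:(n1 + 1), 1:n2], pad[2:(n1 + 1), 3:(n2 + 2)])
  V  <- sd2(pad[1:n1, 2:(n2 + 1)], pad[3:(n1 + 2), 2:(n2 + 1)])
  D1 <- sd2(pad[1:n1, 1:n2], pad[3:(n1 + 2), 3:(n2 + 2)])
  D2 <- sd2(pad[3:(n1 + 2), 1:n2], pad[1:n1, 3:(n2 + 2)])
  D <- sqrt(H^2 + V^2 + D1^2 + D2^2)
  rel <- 1 / (D + .Machine$double.eps)

  # edges: horizontal (p, p + n1) then vertical (p, p + 1), column-major
  lin <- matrix(seq_len(np), n1, n2)
  eh_a <- as.vector(lin[, -n2]); eh_b <- as.vector(lin[, -1])
  ev_a <- as.vector(lin[-n1, ]); ev_b <- as.vector(lin[-1, ])
  ea <- c(eh_a, ev_a); eb <- c(eh_b, ev_b)
  erel <- rel[ea] + rel[eb]
  ord <- sort.list(erel, decreasing = TRUE, method = "radix")

  grp <- seq_len(np)          # group id of each pixel (id = a root pixel)
  off <- integer(np)          # per-pixel 2*pi multiple
  nxt <- integer(np)          # linked list of group members
  head_ <- seq_len(np); tail_ <- seq_len(np); size_ <- rep(1L, np)
  phv <- as.vector(p)
  branch_cuts <- 0L
  two_pi <- 2 * pi
  for (e in ord) {
    a <- ea[e]; b <- eb[e]
    ga <- grp[a]; gb <- grp[b]
    if (ga == gb) next
    if (size_[ga] < size_[gb]) { tmp <- a; a <- b; b <- tmp; tmp <- ga; ga <- gb; gb <- tmp }
    k <- round((phv[a] + two_pi * off[a] - phv[b] - two_pi * off[b]) / two_pi)
    if (k != 0L) branch_cuts <- branch_cuts + 1L
    m <- head_[gb]
    repeat {
      off[m] <- off[m] + k
      grp[m] <- ga
      if (m == tail_[gb]) break
      m <- nxt[m]
    }
    nxt[tail_[ga]] <- head_[gb]
    tail_[ga] <- tail_[gb]
    size_[ga] <- size_[ga] + size_[gb]
  }
  out <- p + two_pi * matrix(off, n1, n2)
  border <- c(out[1, ], out[n1, ], out[, 1], out[, n2])
  out <- out - two_pi * floor((stats::median(border) + pi) / two_pi)
  structure(list(phase = out, reliability = rel, branch_cuts = branch_cuts),
            class = "unwrap_result")
}

# per-angle unwrapped argument of a sinogram (1D rule for 2D data,
# quality-guided 2D rule for 3D data)
unwrap_sinogram_arg <- function(fields) {
  if (is.matrix(fields)) {
    t(apply(fields, 1, function(r) unwrap_phase_1d(Arg(r))))
  } else {
    out <- array(0, dim(fields))
    for (a in seq_len(dim(fields)[1]))
      out[a, , ] <- unwrap_phase_2d(Arg(fields[a, , ]))$phase
    out
  }
}

#' Born scattering data from a complex-field sinogram
#'
#' The Born linearization treats the scattered field as a small additive
#' perturbation: \eqn{b = u/u_0 - 1}. No unwrapping is required.
#'
#' @param sinogram a [complex_sinogram()].
#' @return `scattering_data` with approximation `"born"`.
#' @export
to_born_data <- function(sinogram) {
  stopifnot(inherits(sinogram, "complex_sinogram"))
  scattering_data(sinogram$fields - 1, sinogram$angles, sinogram$geometry,
                  "born")
}

#' Rytov scattering data from a complex-field sinogram
#'
#' The Rytov linearization works on the complex phase:
#' \eqn{\varphi_R = \ln|u/u_0| + i\, \mathrm{unwrap}(\arg(u/u_0))}. The
#' phase is unwrapped per projection (1D along the detector for 2D
#' sinograms, quality-guided 2D unwrapping for 3D sinograms).
#'
#' @param sinogram a [complex_sinogram()] with nonzero modulus everywhere.
#' @return `scattering_data` with approximation `"rytov"`.
#' @export
to_rytov_data <- function(sinogram) {
  stopifnot(inherits(sinogram, "complex_sinogram"))
  nzero <- sum(Mod(sinogram$fields) == 0)
  if (nzero > 0)
    stop(sprintf("cannot take the complex logarithm: %d zero-modulus pixel(s)",
                 nzero))
  phi <- log(Mod(sinogram$fields)) + 1i * unwrap_sinogram_arg(sinogram$fields)
  scattering_data(phi, sinogram$angles, sinogram$geometry, "rytov")
}

#' Radon phase data from a complex-field sinogram
#'
#' Straight-ray projection tomography operates on the measured phase only:
#' returns the unwrapped \eqn{\arg(u/u_0)} per projection, discarding the
#' amplitude.
#'
#' @inheritParams to_rytov_data
#' @return `scattering_data` with approximation `"radon"` (real data).
#' @export
to_radon_data <- function(sinogram) {
  stopifnot(inherits(sinogram, "complex_sinogram"))
  nzero <- sum(Mod(sinogram$fields) == 0)
  if (nzero > 0)
    stop(sprintf("phase undefined: %d zero-modulus pixel(s)", nzero))
  scattering_data(unwrap_sinogram_arg(sinogram$fields), sinogram$angles,
                  sinogram$geometry, "radon")
}
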