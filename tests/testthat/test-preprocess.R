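test_that("propagation is the identity at zero distance and unitary", {
  geo <- water_geometry()
  fld <- phase_object_field(64)
  expect_equal(propagate(fld, 0, geo), fld, tolerance = 1e-12)
  # forward then backward on a band-limited field
  rt <- propagate(propagate(fld, 5.5, geo), -5.5, geo)
  expect_lt(max(Mod(rt - fld)), 1e-10)
  # 2D fields: outer product of lines band-limited to 0.6 k_m keeps the
  # corner frequencies below k_m
  f2 <- outer(phase_object_field(32, cutoff = 0.6),
              phase_object_field(32, cutoff = 0.6))
  rt2 <- propagate(propagate(f2, 3, geo), -3, geo)
  expect_lt(max(Mod(rt2 - f2)), 1e-10)
  expect_error(propagate(c(1, NaN), 1, geo), "non-finite")
})

test_that("a uniform field only accrues the plane-wave phase", {
  geo <- water_geometry()
  km <- wavenumbers(geo)[["km"]]
  u <- rep(1 + 0i, 32)
  for (d in c(1, -2.5, 7))
    expect_equal(propagate(u, d, geo), exp(1i * km * d) * u,
                 tolerance = 1e-12)
})

test_that("autofocus recovers known defocus distances", {
  geo <- water_geometry(4)
  wl <- geo$wavelength
  fld <- phase_object_field(96, amplitude = 2)
  # already focused: pure phase object has flat amplitude
  af0 <- autofocus(fld, geo, c(-2 * wl, 2 * wl))
  expect_lt(abs(af0$distance), wl / 50)
  # propagated by +1 lambda: refocusing needs -1 lambda
  for (d in c(1, -2, 3)) {
    defocused <- propagate(fld, d * wl, geo)
    af <- autofocus(defocused, geo, c(-3.5 * wl, 3.5 * wl))
    expect_lt(abs(af$distance + d * wl), wl / 50)
    expect_lt(max(Mod(af$field - fld)), 0.02)
  }
})

test_that("autofocus minimum beats the interval endpoints", {
  geo <- water_geometry(4)
  fld <- propagate(phase_object_field(96), 3, geo)
  iv <- c(-8, 8)
  af <- autofocus(fld, geo, iv)
  m_end <- vapply(iv, function(d)
    difftomo:::amplitude_gradient_metric(propagate(fld, d, geo)), numeric(1))
  expect_lt(af$metric, min(m_end))
})

test_that("1D unwrapping recovers ramps and keeps the 2*pi residue", {
  x <- seq(0, 6 * pi, length.out = 100)
  w <- wrap_to_pi(x)
  u <- unwrap_phase_1d(w)
  expect_equal(diff(u), diff(x), tolerance = 1e-12)
  expect_true(all(abs(wrap_to_pi(u - w)) < 1e-12))
  expect_equal(unwrap_phase_1d(rep(0.3, 5)), rep(0.3, 5))
})

test_that("2D unwrapping recovers smooth fields exactly", {
  expect_equal(unwrap_phase_2d(matrix(0.3, 8, 8))$phase, matrix(0.3, 8, 8))
  # wrapped linear ramp 0 -> 6*pi across the image
  n <- 48
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  u <- unwrap_phase_2d(wrap_to_pi(ramp))$phase
  expect_lt(max(abs(align_offset(u, ramp) - ramp)), 1e-9)
  # smooth Gaussian bump of peak 4*pi
  co <- seq(-2, 2, length.out = n)
  bump <- 4 * pi * exp(-outer(co^2, co^2, `+`) / 0.8)
  ub <- unwrap_phase_2d(wrap_to_pi(bump))$phase
  expect_lt(max(abs(align_offset(ub, bump) - bump)), 1e-6)
})

test_that("rewrapping the unwrapped phase reproduces the input", {
  set.seed(11)
  n <- 32
  co <- seq(-1.5, 1.5, length.out = n)
  ph <- 5 * exp(-outer(co^2, co^2, `+`)) +
    matrix(0.2 * rnorm(n * n), n, n)
  w <- wrap_to_pi(ph)
  res <- unwrap_phase_2d(w)
  expect_lt(max(abs(wrap_to_pi(res$phase) - w)), 1e-9)
  expect_equal(dim(res$reliability), c(n, n))
  expect_gte(res$branch_cuts, 0)
})

test_that("approximation filters agree with their definitions", {
  geo <- water_geometry()
  ones <- matrix(1 + 0i, 4, 16)
  sg <- complex_sinogram(ones, full_turn_angles(4), geo)
  expect_true(all(to_born_data(sg)$data == 0))
  expect_true(all(to_rytov_data(sg)$data == 0))
  expect_true(all(to_radon_data(sg)$data == 0))

  eps <- 1e-4 + 0i
  sg2 <- complex_sinogram(ones + eps, full_turn_angles(4), geo)
  expect_equal(to_born_data(sg2)$data, matrix(eps, 4, 16), tolerance = 1e-12)

  # uniform u/u0 = exp(0.2 + 0.3i): no wrapping, log identity
  sg3 <- complex_sinogram(array(exp(0.2 + 0.3i), dim(ones)),
                          full_turn_angles(4), geo)
  expect_equal(to_rytov_data(sg3)$data,
               matrix(0.2 + 0.3i, 4, 16), tolerance = 1e-12)
})

test_that("rytov filter unwraps phase excursions beyond pi", {
  geo <- water_geometry()
  # smooth phase ramp to 3*pi across the detector: wrapped arg, true phase
  ph <- seq(0, 3 * pi, length.out = 64)
  fields <- matrix(exp(1i * ph), 4, 64, byrow = TRUE)
  sg <- complex_sinogram(fields, full_turn_angles(4), geo)
  ry <- to_rytov_data(sg)$data
  # matches the true ramp up to one global 2*pi multiple; a wrapped phase
  # could never span 3*pi
  expect_equal(align_offset(Im(ry[1, ]), ph), ph, tolerance = 1e-9)
  expect_gt(diff(range(Im(ry[1, ]))), 2 * pi)
  # radon filter equals the imaginary part for unit-modulus fields
  ra <- to_radon_data(sg)$data
  expect_equal(ra, Im(ry), tolerance = 1e-12)
})

test_that("zero-modulus pixels are rejected with a count", {
  geo <- water_geometry()
  f <- matrix(1 + 0i, 4, 8); f[2, 3] <- 0i; f[3, 1] <- 0i
  sg <- complex_sinogram(f, full_turn_angles(4), geo)
  expect_error(to_rytov_data(sg), "2 zero-modulus")
  expect_error(to_radon_data(sg), "2 zero-modulus")
})

test_that("born and rytov data coincide to second order for weak fields", {
  geo <- water_geometry()
  obj <- object_from_ri(disk_phantom_2d(48, 8, 2e-5, geo))
  sino <- rytov_forward(obj, full_turn_angles(8), geo)
  b <- to_born_data(sino)$data
  r <- to_rytov_data(sino)$data
  expect_lt(max(Mod(b)), 1e-3)
  expect_lt(max(Mod(b - r)), 1e-6)
})
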