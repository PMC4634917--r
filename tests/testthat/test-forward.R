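test_that("radon projections of a uniform medium are zero", {
  geo <- water_geometry()
  ph <- ri_map(matrix(1.333, 32, 32), geo)
  sd <- radon_forward(ph, full_turn_angles(8))
  expect_true(all(sd$data == 0))
  expect_identical(sd$approximation, "radon")
  expect_error(radon_forward(ph, numeric(0)), "empty")
})

test_that("central-ray radon phase equals the chord closed form", {
  # disk dn = 0.032, diameter 17 lambda: Phi = k0 * 0.032 * 17 lambda
  geo <- water_geometry(4)
  ph <- disk_phantom_2d(128, 8.5 * 4, 0.032, geo)
  sd <- radon_forward(ph, 0)
  c0 <- floor(128 / 2) + 1
  expect_equal(sd$data[1, c0], 2 * pi * 0.544, tolerance = 0.02)
})

test_that("a centered disk projects identically at every angle", {
  geo <- water_geometry(4)
  ph <- disk_phantom_2d(64, 20, 0.01, geo)
  sd <- radon_forward(ph, full_turn_angles(8))
  # oblique angles differ only by edge rasterization of the sharp disk
  for (a in 2:8)
    expect_lt(difftomo:::relative_l2(sd$data[a, ], sd$data[1, ]), 0.06)
  # quarter-turn rotations are exact on the grid
  expect_equal(sd$data[3, ], sd$data[1, ], tolerance = 1e-12)
})

test_that("born_forward is linear and vanishes for empty objects", {
  geo <- water_geometry()
  f0 <- object_map(matrix(0i, 32, 32), geo)
  expect_true(all(born_forward(f0, full_turn_angles(4))$data == 0))

  ph <- disk_phantom_2d(32, 6, 1e-3, geo)
  obj <- object_from_ri(ph)
  b1 <- born_forward(obj, c(0, pi / 3), geo)$data
  b2 <- born_forward(object_map(2 * obj$f, geo), c(0, pi / 3), geo)$data
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("born_forward matches the Green's-function oracle per angle", {
  # weak disk, detector just outside the support
  geo <- imaging_geometry(4, 1.333, detector_distance = 24)
  ph <- disk_phantom_2d(64, 20, 1e-3, geo)
  obj <- object_from_ri(ph)
  for (ang in c(0, 0.7, 2.3)) {
    b_fft <- born_forward(obj, ang, geo)$data[1, ]
    b_ref <- born_forward_bruteforce(obj, ang, geo)
    expect_lt(difftomo:::relative_l2(b_fft, b_ref), 0.01)
  }
})

test_that("brute-force field of a single voxel is the Green's function", {
  geo <- imaging_geometry(4, 1.333, detector_distance = 10)
  km <- wavenumbers(geo)[["km"]]
  f <- matrix(0i, 16, 16)
  c0 <- floor(16 / 2) + 1
  zi <- c0 - 3; xi <- c0 + 2   # voxel at z = -3, x = +2
  f[zi, xi] <- 1 + 0i
  b <- born_forward_bruteforce(object_map(f, geo), 0, geo)
  xc <- seq_len(16) - 1 - floor(16 / 2)
  rho <- sqrt((xc - 2)^2 + (10 - (-3))^2)
  g <- (1i / 4) * (besselJ(km * rho, 0) + 1i * besselY(km * rho, 0))
  expected <- g * exp(1i * km * (-3)) * exp(-1i * km * 10)
  expect_equal(b, expected, tolerance = 1e-12)
})

test_that("brute-force field obeys source-detector reciprocity", {
  geo <- imaging_geometry(4, 1.333, detector_distance = 9)
  c0 <- floor(16 / 2) + 1
  fA <- matrix(0i, 16, 16); fA[c0, c0 - 4] <- 1 + 0i  # voxel at x = -4
  fB <- matrix(0i, 16, 16); fB[c0, c0 + 4] <- 1 + 0i  # voxel at x = +4
  bA <- born_forward_bruteforce(object_map(fA, geo), 0, geo)
  bB <- born_forward_bruteforce(object_map(fB, geo), 0, geo)
  # field at +x from voxel at -x equals field at -x from voxel at +x
  xc <- seq_len(16) - 1 - floor(16 / 2)
  iplus <- which(xc == 4); iminus <- which(xc == -4)
  expect_equal(bA[iplus], bB[iminus], tolerance = 1e-12)
})

test_that("rytov fields are unity without scattering and Born-like when weak", {
  geo <- water_geometry()
  f0 <- object_map(matrix(0i, 32, 32), geo)
  sino <- rytov_forward(f0, full_turn_angles(4), geo)
  expect_true(all(sino$fields == 1))
  expect_true(all(abs(Mod(sino$fields) - 1) == 0))

  # |b| <= 1e-3 implies exp(b) - (1 + b) below 1e-6 in modulus
  ph <- disk_phantom_2d(48, 8, 2e-5, geo)
  obj <- object_from_ri(ph)
  b <- born_forward(obj, full_turn_angles(6), geo)$data
  expect_lt(max(Mod(b)), 1e-3)
  u <- rytov_forward(obj, full_turn_angles(6), geo)$fields
  expect_lt(max(Mod(u - (1 + b))), 1e-6)
})

test_that("rytov noise is seed-reproducible and off by default", {
  geo <- water_geometry()
  obj <- object_from_ri(disk_phantom_2d(32, 6, 1e-3, geo))
  u1 <- rytov_forward(obj, full_turn_angles(4), geo)$fields
  u2 <- rytov_forward(obj, full_turn_angles(4), geo)$fields
  expect_identical(u1, u2)
  set.seed(5)
  n1 <- rytov_forward(obj, full_turn_angles(4), geo, noise_sigma = 0.01)$fields
  set.seed(5)
  n2 <- rytov_forward(obj, full_turn_angles(4), geo, noise_sigma = 0.01)$fields
  expect_identical(n1, n2)
  expect_false(identical(n1, u1))
})

test_that("object_from_ri evaluates f and round-trips with object_to_ri", {
  geo <- water_geometry()
  km <- wavenumbers(geo)[["km"]]
  nm <- geo$medium_index
  n <- matrix(nm, 16, 16)
  expect_true(all(object_from_ri(ri_map(n, geo))$f == 0))
  n2 <- matrix(2 * nm, 16, 16)
  expect_equal(object_from_ri(ri_map(n2, geo))$f,
               matrix(3 * km^2 + 0i, 16, 16))
  n3 <- matrix(nm + runif(256, 0, 0.05), 16, 16)
  rt <- object_to_ri(object_from_ri(ri_map(n3, geo)))
  expect_equal(Re(rt$n), n3, tolerance = 1e-12)
})

test_that("aliased wavelengths are rejected with guidance", {
  geo <- imaging_geometry(2, 1.333)  # under two pixels per medium wavelength
  obj <- object_map(matrix(0i, 16, 16), geo)
  expect_error(born_forward(obj, 0, geo), "wavelength")
})

test_that("3D born data of an extruded object match the 2D model centrally", {
  geo <- water_geometry()
  ph2 <- disk_phantom_2d(32, 6, 1e-3, geo)
  ph3 <- extrude_y(ph2)
  ang <- full_turn_angles(4)
  sd2 <- born_forward(object_from_ri(ph2), ang, geo)
  sd3 <- born_forward(object_from_ri(ph3), ang, geo)
  yc <- floor(32 / 2) + 1
  expect_lt(difftomo:::relative_l2(sd3$data[, yc, ], sd2$data), 0.02)
})
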