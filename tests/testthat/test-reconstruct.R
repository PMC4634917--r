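test_that("backpropagation of zero data gives a zero object", {
  geo <- water_geometry()
  sd <- difftomo:::scattering_data(matrix(0i, 8, 32), full_turn_angles(8),
                                   geo, "born")
  expect_true(all(backpropagate_2d(sd)$f == 0))
  sd3 <- difftomo:::scattering_data(array(0i, c(8, 16, 16)),
                                    full_turn_angles(8), geo, "born")
  expect_true(all(backpropagate_3d(sd3)$f == 0))
})

test_that("backpropagation is linear in the data", {
  geo <- water_geometry()
  obj <- object_from_ri(disk_phantom_2d(32, 6, 1e-3, geo))
  sd <- born_forward(obj, full_turn_angles(16), geo)
  f1 <- backpropagate_2d(sd)$f
  sd2 <- difftomo:::scattering_data(3 * sd$data, sd$angles, geo, "born")
  expect_equal(backpropagate_2d(sd2)$f, 3 * f1, tolerance = 1e-12)
})

test_that("radon data are rejected by backpropagation and vice versa", {
  geo <- water_geometry()
  rd <- difftomo:::scattering_data(matrix(0, 8, 32), full_turn_angles(8),
                                   geo, "radon")
  expect_error(backpropagate_2d(rd), "filtered_backprojection")
  bd <- difftomo:::scattering_data(matrix(0i, 8, 32), full_turn_angles(8),
                                   geo, "born")
  expect_error(filtered_backprojection(bd), "Born or Rytov")
  # non-full-view angles
  nv <- difftomo:::scattering_data(matrix(0i, 8, 32),
                                   seq(0, pi, length.out = 8), geo, "born")
  expect_error(backpropagate_2d(nv), "full-view")
})

test_that("weak-scattering round trip calibrates the 2D reconstruction", {
  geo <- water_geometry(4)
  ph <- disk_phantom_2d(128, 20, 1e-3, geo)   # 2a = 10 lambda
  sd <- born_forward(object_from_ri(ph), full_turn_angles(200), geo)
  rec <- object_to_ri(backpropagate_2d(sd))
  expect_lt(rms_error(ph, rec), 5)
  co <- grid_coords_test(128)
  inside <- outer(co^2, co^2, `+`) <= 18^2
  ratio <- mean(Re(rec$n)[inside] - 1.333) / 1e-3
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
})

test_that("weak-scattering round trip calibrates the 3D reconstruction", {
  geo <- water_geometry(4)
  # 2a = 10 lambda sphere on a 48 grid
  co <- grid_coords_test(48)
  vol <- array(1.333, c(48, 48, 48))
  R2 <- outer(co^2, co^2, `+`)
  for (x in seq_len(48)) vol[, , x][R2 + co[x]^2 <= 20^2] <- 1.333 + 1e-3
  ph <- ri_map(vol, geo)
  sd <- born_forward(object_from_ri(ph), full_turn_angles(100), geo)
  rec <- object_to_ri(backpropagate_3d(sd))
  expect_lt(rms_error(ph, rec), 5)
  inside <- array(FALSE, c(48, 48, 48))
  for (x in seq_len(48)) inside[, , x] <- R2 + co[x]^2 <= 17^2
  ratio <- mean(Re(rec$n)[inside] - 1.333) / 1e-3
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
})

test_that("central slice of the 3D reconstruction matches the 2D one", {
  geo <- water_geometry()
  ph2 <- disk_phantom_2d(32, 6, 1e-3, geo)
  ph3 <- extrude_y(ph2)
  ang <- full_turn_angles(40)
  f2 <- backpropagate_2d(born_forward(object_from_ri(ph2), ang, geo))
  f3 <- backpropagate_3d(born_forward(object_from_ri(ph3), ang, geo))
  yc <- floor(32 / 2) + 1
  expect_lt(difftomo:::relative_l2(f3$f[, yc, ], f2$f), 0.03)
})

test_that("filtered backprojection recovers a homogeneous disk", {
  geo <- water_geometry(4)
  ph <- disk_phantom_2d(128, 8.5 * 4, 0.032, geo)   # n = 1.365 inside
  rec <- filtered_backprojection(radon_forward(ph, full_turn_angles(200)))
  co <- grid_coords_test(128)
  inside <- outer(co^2, co^2, `+`) <= 30^2
  expect_lt(abs(mean(rec$n[inside]) - 1.365) / 1.365, 0.01)
  # zero sinogram gives the uniform medium
  z <- difftomo:::scattering_data(matrix(0, 8, 32), full_turn_angles(8),
                                  geo, "radon")
  expect_true(all(filtered_backprojection(z)$n == geo$medium_index))
})

test_that("full-view data equal their opposite-angle average (odd grid)", {
  # Fourier-coverage symmetry: averaging each projection with the mirrored
  # opposite projection leaves the FBP reconstruction unchanged within 1 %
  geo <- water_geometry(4)
  ph <- disk_phantom_2d(65, 18, 0.01, geo, center = c(4, -3))
  sd <- radon_forward(ph, full_turn_angles(40))
  rec1 <- filtered_backprojection(sd)
  p <- sd$data
  flip <- rev(seq_len(ncol(p)))
  avg <- p
  for (a in seq_len(40)) {
    opp <- ((a - 1 + 20) %% 40) + 1
    avg[a, ] <- (p[a, ] + p[opp, flip]) / 2
  }
  rec2 <- filtered_backprojection(
    difftomo:::scattering_data(avg, sd$angles, geo, "radon"))
  expect_lt(difftomo:::relative_l2(rec2$n - 1.333, rec1$n - 1.333), 0.01)
})

test_that("rytov beats born on RMS and radon on TV for the strong phantom", {
  geo <- water_geometry(4)
  ph <- make_cell_phantom_2d(128, 4)
  sino <- rytov_forward(object_from_ri(ph), full_turn_angles(200), geo)
  rec_ry <- object_to_ri(backpropagate_2d(to_rytov_data(sino)))
  rec_bo <- object_to_ri(backpropagate_2d(to_born_data(sino)))
  rec_ra <- filtered_backprojection(to_radon_data(sino))
  expect_lt(rms_error(ph, rec_ry), rms_error(ph, rec_bo))
  expect_lt(tv_error(ph, rec_ry), tv_error(ph, rec_ra))
  # the straight-ray model smears the reconstruction: higher TV than rytov
  expect_lt(rms_error(ph, rec_ry), 5)
})

test_that("object_to_ri inverts the object function and clamps when forced", {
  geo <- water_geometry()
  km <- wavenumbers(geo)[["km"]]
  f0 <- object_map(matrix(0i, 8, 8), geo)
  expect_true(all(object_to_ri(f0)$n == geo$medium_index))
  f3 <- object_map(matrix(3 * km^2 + 0i, 8, 8), geo)
  expect_equal(Re(object_to_ri(f3)$n), matrix(2 * 1.333, 8, 8),
               tolerance = 1e-12)
  fneg <- object_map(matrix(-2 * km^2 + 0i, 4, 4), geo)
  expect_warning(r <- object_to_ri(fneg), "clamped")
  expect_equal(attr(r, "clamped_voxels"), 16)
  expect_true(all(Re(r$n) >= 0))
})

test_that("inscribed mask matches the analytic circle and sphere", {
  m <- inscribed_mask(c(101, 101))
  expect_lt(abs(sum(m) - pi * 50.5^2) / (pi * 50.5^2), 0.01)
  expect_false(any(m[1, 1], m[1, 101], m[101, 1], m[101, 101]))
  # 2 x 2: center at 0-based (1, 1); strict radius-1 rule keeps only it
  m2 <- inscribed_mask(c(2, 2))
  expect_identical(as.vector(m2), c(FALSE, FALSE, FALSE, TRUE))
  m3 <- inscribed_mask(c(21, 21, 21))
  expect_lt(abs(sum(m3) - 4 / 3 * pi * 10.5^3) / (4 / 3 * pi * 10.5^3), 0.02)
  expect_error(inscribed_mask(c(4, 8)), "square or cubic")
})

test_that("backpropagation plans are deterministic and well-formed", {
  geo <- water_geometry()
  p1 <- backpropagation_plan(32, 100, geo)
  p2 <- backpropagation_plan(32, 100, geo)
  expect_identical(p1, p2)
  expect_equal(p1$filter, abs(p1$kx))    # even ramp filter
  expect_true(all(!p1$mask[p1$kx^2 >= p1$km^2]))
  expect_equal(p1$norm_const, -1i * p1$km * 2 * pi / 100 / (2 * pi))
})
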