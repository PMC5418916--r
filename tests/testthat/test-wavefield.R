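test_that("shear modulus is quadratic in wavelength and frequency", {
  expect_equal(shear_modulus(1000, 2 * 0.29, 1), 4 * shear_modulus(1000, 0.29, 1))
  expect_equal(shear_modulus(1000, 0.29, 2), 4 * shear_modulus(1000, 0.29, 1))
  expect_identical(shear_modulus(1000, 0.58, 0), 0)
  expect_error(shear_modulus(-1, 0.29, 1), "non-negative")
})

test_that("wavelength profile and accumulated phase", {
  const <- wave_params(0.58, 4.35)
  expect_equal(lambda_at(c(0, 1, 4.35), const), rep(0.58, 3))
  expect_error(lambda_at(5, const), "within")

  inc <- wave_params("increasing", 4.35)
  expect_equal(lambda_at(0.5, inc), 0.29)  # first third
  expect_equal(lambda_at(2.0, inc), 0.58)  # second third
  expect_equal(lambda_at(3.0, inc), 1.45)  # 3.0 >= 2 * 4.35 / 3 = 2.9
  expect_equal(lambda_at(4.35, inc), 1.45)

  # phase: zero at the surface, continuous and non-decreasing across bands
  expect_identical(wave_phase(0, inc), 0)
  r <- seq(0, 4.35, length.out = 2001)
  ph <- wave_phase(r, inc)
  expect_true(all(diff(ph) > 0))
  b <- 4.35 / 3
  for (edge in c(b, 2 * b)) {
    eps <- 1e-9
    expect_lt(abs(wave_phase(edge + eps, inc) - wave_phase(edge - eps, inc)),
              1e-6)
  }
  # constant profile phase is the textbook 2 pi r / lambda
  expect_equal(wave_phase(0.29, wave_params(0.29, 4.35)), 2 * pi)
})

test_that("the twelve conditions enumerate the study grid", {
  conds <- enumerate_conditions()
  expect_identical(nrow(conds), 12L)
  expect_identical(anyDuplicated(conds$condition), 0L)
  expect_true("lambda1.45_dmax4.35" %in% conds$condition)
  expect_setequal(unique(conds$d_max), c(1.45, 2.9, 4.35))
  expect_setequal(unique(conds$lambda), c("0.29", "0.58", "1.45", "increasing"))
})

test_that("distances to an isolated plane and simple neighbours", {
  g <- halfspace_grid(n = 16, i0 = 4, pixel_um = 100)
  surf <- extract_surface(g)
  dt <- distance_transform(g, surf, d_max = 0.95)
  # face-adjacent voxel: r = one pixel; next: two pixels
  expect_equal(dt$distance[5, 8, 8], 0.1)
  expect_equal(dt$distance[6, 8, 8], 0.2)
  expect_true(is.na(dt$distance[16, 8, 8])) # 1.1 mm from the plane: beyond d_max
  expect_true(is.na(dt$distance[2, 8, 8]))  # occupied interior

  # in-plane diagonal from a single surface voxel
  occ <- array(FALSE, dim = c(9, 9, 9))
  occ[5, 5, 5] <- TRUE
  g1 <- voxel_grid(occ, 100)
  dt1 <- distance_transform(g1, extract_surface(g1), d_max = 0.5)
  expect_equal(dt1$distance[6, 6, 5], sqrt(2) * 0.1)
})

test_that("distance transform equals the all-pairs oracle on random grids", {
  set.seed(11)
  for (rep in 1:3) {
    occ <- array(runif(8000) < 0.02, dim = c(20, 20, 20))
    if (!any(occ)) next
    g <- voxel_grid(occ, 100)
    surf <- extract_surface(g)
    dt <- distance_transform(g, surf, d_max = 0.8)
    want <- brute_force_nearest(occ, surf, 0.1)
    over <- !is.na(want$distance) & want$distance > 0.8
    want$distance[over] <- NA
    want$source[over] <- 0L
    expect_equal(dt$distance, want$distance, tolerance = 1e-12)
    expect_identical(dt$source, want$source) # incl. smallest-id ties
  }
})

test_that("displacement follows xi0 cos(k r) with a hard cutoff", {
  g <- halfspace_grid(n = 24, i0 = 5, pixel_um = 100)
  surf <- uniform_surface(g, dir = c(0, 0, -1))
  # lambda = 0.8 mm so that r = 0.2 mm is a quarter wavelength
  params <- wave_params(0.8, d_max = 1.6)
  field <- compute_displacement(g, surf, params)
  mag <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  expect_true(all(mag <= params$xi0 + 1e-12))
  # r = pixel: u = xi0 cos(2 pi 0.1 / 0.8) along -z
  expect_equal(field$uz[6, 12, 12], -0.1 * cos(2 * pi * 0.1 / 0.8))
  # quarter wavelength: zero displacement, excluded from the displaced area
  expect_equal(mag[7, 12, 12], 0, tolerance = 1e-13)
  expect_false(field$displaced[7, 12, 12])
  # half wavelength: direction reversed at full amplitude
  expect_equal(field$uz[9, 12, 12], 0.1)
  # strict zero beyond d_max and inside the villi
  expect_true(all(mag[22:24, , ] == 0))
  expect_true(all(mag[1:5, , ] == 0))
})

test_that("a point source radiates spherically symmetric magnitudes", {
  occ <- array(FALSE, dim = c(41, 41, 41))
  occ[21, 21, 21] <- TRUE
  g <- voxel_grid(occ, 100)
  surf <- uniform_surface(g, dir = c(1, 0, 0))
  field <- compute_displacement(g, surf, wave_params(0.58, 1.9))
  dt <- distance_transform(g, surf, 1.9)
  mag <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  idx <- which(!is.na(dt$distance))
  by_r <- split(mag[idx], round(dt$distance[idx], 9))
  spread <- vapply(by_r, function(v) diff(range(v)), numeric(1))
  expect_true(all(spread < 1e-12))
})

test_that("field computation is hash-stable", {
  g <- halfspace_grid(n = 16, i0 = 4, pixel_um = 100)
  surf <- uniform_surface(g)
  f1 <- compute_displacement(g, surf, wave_params(0.29, 1.0))
  f2 <- compute_displacement(g, surf, wave_params(0.29, 1.0))
  expect_identical(digest::digest(f1[c("ux", "uy", "uz")]),
                   digest::digest(f2[c("ux", "uy", "uz")]))
})

test_that("slab streaming reproduces the single pass bit-exactly", {
  tree <- suppressWarnings(build_villous_tree(master_seed = 6,
                                              n_particles = 40))
  g <- rasterize_tree(tree, 464)
  surf <- assign_contraction(extract_surface(g), tree)
  d1 <- distance_transform(g, surf, 2.9)
  d2 <- distance_transform(g, surf, 2.9, slab_nz = 7)
  expect_identical(d1$distance, d2$distance)
  expect_identical(d1$source, d2$source)
  f1 <- displacement_field(d1, surf, wave_params("increasing", 2.9))
  f2 <- displacement_field(d2, surf, wave_params("increasing", 2.9))
  expect_identical(f1$ux, f2$ux)
  expect_identical(f1$uy, f2$uy)
  expect_identical(f1$uz, f2$uz)
})
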