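# wrap raw component arrays into a displacement_field-shaped object
fake_field <- function(ux, uy, uz, xi0 = 0.1, pixel = 100) {
  d <- dim(ux)
  mag <- sqrt(ux^2 + uy^2 + uz^2)
  structure(list(ux = ux, uy = uy, uz = uz,
                 displaced = mag > 1e-12 * xi0,
                 params = wave_params(1.45, 4.35, xi0 = xi0),
                 pixel_size = pixel, dims = d),
            class = "displacement_field")
}

test_that("polar decomposition of axis-aligned vectors", {
  z <- array(0, dim = c(1, 1, 3))
  ux <- z; uy <- z; uz <- z
  ux[1, 1, 2] <- 0.05          # (b, 0, 0)
  uy[1, 1, 3] <- -0.02         # (0, -b, 0)
  uz[1, 1, 1] <- 0.07          # (0, 0, a)
  p <- to_polar(fake_field(ux, uy, uz))
  expect_equal(p$magnitude[1, 1, 1], 0.07)
  expect_equal(p$phi[1, 1, 1], 0)
  expect_false(p$theta_defined[1, 1, 1])
  expect_true(is.na(p$theta[1, 1, 1]))
  expect_equal(p$phi[1, 1, 2], 90)
  expect_equal(p$theta[1, 1, 2], 0)
  expect_equal(p$phi[1, 1, 3], 90)
  expect_equal(p$theta[1, 1, 3], -90)
})

test_that("polar decomposition round-trips random vectors", {
  set.seed(3)
  n <- 500
  v <- matrix(rnorm(3 * n), ncol = 3) * 0.03
  ux <- array(v[, 1], dim = c(n, 1, 1))
  uy <- array(v[, 2], dim = c(n, 1, 1))
  uz <- array(v[, 3], dim = c(n, 1, 1))
  p <- to_polar(fake_field(ux, uy, uz))
  ok <- p$theta_defined[, 1, 1]
  phi <- p$phi[, 1, 1][ok] * pi / 180
  th <- p$theta[, 1, 1][ok] * pi / 180
  mag <- p$magnitude[, 1, 1][ok]
  back <- cbind(mag * sin(phi) * cos(th), mag * sin(phi) * sin(th),
                mag * cos(phi))
  expect_equal(back, unname(v[ok, ]), tolerance = 1e-9)
  # theta lives in [-180, 180)
  expect_true(all(p$theta[ok] >= -180 & p$theta[ok] < 180))
})

test_that("slice statistics match hand computations", {
  # slice 1: two voxels, magnitudes 1 and 3 along +x
  ux <- array(0, dim = c(2, 1, 2))
  uy <- array(0, dim = c(2, 1, 2))
  uz <- array(0, dim = c(2, 1, 2))
  ux[1, 1, 1] <- 1
  ux[2, 1, 1] <- 3
  st <- slice_stats(to_polar(fake_field(ux, uy, uz, xi0 = 3)))
  expect_identical(st$displaced_area, c(2L, 0L))
  expect_equal(st$mean_magnitude[1], 2)
  expect_equal(st$sd_magnitude[1], 1) # population SD
  expect_equal(st$normalized_sd[1], 0.5)
  expect_equal(st$mean_phi[1], 90)
  expect_equal(st$sd_phi[1], 0)
  expect_equal(st$area_fraction_phi_45_135[1], 1)
  # empty slice: area 0, stats missing
  expect_true(is.na(st$mean_magnitude[2]))
})

test_that("phi area fractions behave at the extremes and partition to one", {
  expect_equal(area_fraction_phi(rep(90, 10)), 1)
  expect_equal(area_fraction_phi(c(rep(0, 5), rep(180, 5))), 0)
  set.seed(5)
  phi <- runif(1000, 0, 180)
  expect_equal(area_fraction_phi(phi, 0, 180), 1)
  # a full partition sums to one (continuous phi never hits the band edges)
  expect_equal(area_fraction_phi(phi, 0, 60) +
                 area_fraction_phi(phi, 60, 120) +
                 area_fraction_phi(phi, 120, 180), 1,
               tolerance = 1e-9)
})

test_that("isotropic directions give the closed-form in-plane fraction", {
  set.seed(1234)
  n <- 1e5
  v <- matrix(rnorm(3 * n), ncol = 3)
  phi <- acos(v[, 3] / sqrt(rowSums(v^2))) * 180 / pi
  # solid-angle integral: (cos 45 - cos 135) / 2 = sqrt(2)/2
  expect_equal(area_fraction_phi(phi), sqrt(2) / 2, tolerance = 0.01)
})

test_that("theta histogram SD matches closed forms", {
  # perfectly uniform across the 360 one-degree bins
  theta <- rep(seq(-180, 179) + 0.5, times = 3)
  expect_equal(theta_histogram_sd(theta), 0)
  # one-hot: population SD of (1, 0, ..., 0)
  expect_equal(theta_histogram_sd(rep(10.2, 50)),
               sqrt(1 / 360 - (1 / 360)^2))
  # two equal bins: direct formula
  frac <- c(rep(0.5, 2), rep(0, 358))
  expect_equal(theta_histogram_sd(c(rep(-90.5, 7), rep(45.5, 7))),
               sqrt(mean((frac - mean(frac))^2)))
  expect_true(is.na(theta_histogram_sd(numeric(0))))
})

test_that("characteristic positions are found on synthetic profiles", {
  z <- seq(0.1, 24.5, by = 0.116)
  n <- length(z)
  base <- tibble::tibble(
    k = seq_len(n), z_mm = z, displaced_area = 1000L,
    mean_magnitude = 0.05, sd_magnitude = 0.02,
    normalized_sd = 0.4 + 0.3 * exp(-(z - 2.9)^2 / 0.5),
    mean_phi = 90, sd_phi = 20 + 40 * exp(-(z - 3)^2 / 0.8) +
      50 * exp(-(z - 10)^2 / 0.8),
    mean_theta = -2 * exp(-(z - 13.5)^2 / 2), sd_theta = 90,
    area_fraction_phi_45_135 = 0.7, sd_in = 0.01
  )
  class(base) <- c("villi_slice_stats", class(base))
  cp <- find_characteristic_positions(base)
  expect_true(cp$complete)
  expect_lt(abs(cp$z_phi1 - 3), 0.2)
  expect_lt(abs(cp$z_phi2 - 10), 0.2)
  expect_lt(abs(cp$z_d - 2.9), 0.2)
  expect_lt(abs(cp$z_theta - 13.5), 0.2)
  expect_equal(c(cp$z_t, cp$z_r, cp$z_rl), c(1.45, 8.2, 19.0))

  # flat profiles: no phi peaks, incomplete flag raised
  flat <- base
  flat$sd_phi <- 20
  cp_flat <- find_characteristic_positions(flat)
  expect_false(cp_flat$complete)
  expect_identical(nrow(cp_flat$phi_peaks), 0L)
})

test_that("find_peaks ranks by prominence and ignores endpoints", {
  y <- c(5, 1, 0, 1, 0.2, 3, 0.5, 0.4, 6)
  pk <- find_peaks(y)
  expect_false(1 %in% pk$index)
  expect_false(length(y) %in% pk$index)
  expect_identical(pk$index[1], 6L) # the interior maximum
  expect_equal(pk$prominence[1], 3 - 0.4)
  # threshold filters the small bump
  expect_identical(nrow(find_peaks(y, min_prominence = 3)), 0L)
})

test_that("the displaced area grows with the propagation cutoff", {
  g <- halfspace_grid(n = 20, i0 = 4, pixel_um = 100)
  surf <- uniform_surface(g)
  small <- compute_displacement(g, surf, wave_params(0.29, 0.5))
  large <- compute_displacement(g, surf, wave_params(0.29, 1.2))
  expect_true(all(large$displaced[small$displaced]))
  st_small <- slice_stats(to_polar(small))
  st_large <- slice_stats(to_polar(large))
  expect_true(all(st_large$displaced_area >= st_small$displaced_area))
})
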