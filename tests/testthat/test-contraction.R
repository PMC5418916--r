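test_that("surface extraction matches forced cases", {
  # single occupied voxel is all surface
  occ <- array(FALSE, dim = c(5, 5, 5))
  occ[3, 3, 3] <- TRUE
  s <- extract_surface(voxel_grid(occ, 100))
  expect_identical(nrow(s), 1L)
  expect_identical(c(s$i, s$j, s$k), c(3L, 3L, 3L))

  # 5^3 solid cube: interior 3^3 removed
  occ <- array(TRUE, dim = c(7, 7, 7))
  occ[c(1, 7), , ] <- FALSE
  occ[, c(1, 7), ] <- FALSE
  occ[, , c(1, 7)] <- FALSE
  s <- extract_surface(voxel_grid(occ, 100))
  expect_identical(nrow(s), 125L - 27L)

  expect_error(extract_surface(voxel_grid(array(FALSE, dim = c(3, 3, 3)), 100)),
               "empty")
})

test_that("surface extraction agrees with the exhaustive neighbour scan", {
  set.seed(7)
  for (rep in 1:3) {
    occ <- array(runif(4096) < 0.3, dim = c(16, 16, 16))
    if (!any(occ)) next
    s <- extract_surface(voxel_grid(occ, 100))
    want <- brute_force_surface(occ)
    got <- array(FALSE, dim = dim(occ))
    got[cbind(s$i, s$j, s$k)] <- TRUE
    expect_identical(got, want)
  }
})

test_that("truncus contraction direction follows the taper", {
  prof <- truncus_profile()
  # at z_tr the taper vanishes: direction is straight down
  d <- truncus_direction(prof$z_tr, theta_o = 0.7, prof)
  expect_equal(unname(d[1, ]), c(0, 0, -1), tolerance = 1e-12)

  # z -> 0: the direction flattens into the xy plane toward (cos, sin, 0)
  th <- 1.1
  d0 <- truncus_direction(1e-6 * prof$z_tr, th, prof)
  expect_equal(unname(d0[1, ]), c(cos(th), sin(th), 0), tolerance = 0.01)

  # z = z_tr/2, symbolic: dr/dz = -(r_max - r_min) / (sqrt(3) z_tr)
  z <- prof$z_tr / 2
  slope <- -(prof$r_max - prof$r_min) / (sqrt(3) * prof$z_tr)
  expect_equal(truncus_radius_slope(z, prof), slope, tolerance = 1e-12)
  dm <- truncus_direction(z, 0, prof)
  expect_equal(unname(attr(dm, "phi_o")), pi + atan(slope), tolerance = 1e-12)

  # phi_o stays in (pi/2, pi] and decreases toward pi/2 as z -> 0
  z <- seq(0.01, prof$z_tr, length.out = 100)
  phi <- attr(truncus_direction(z, 0, prof), "phi_o")
  expect_true(all(phi > pi / 2 & phi <= pi))
  expect_true(all(diff(phi) > 0))
})

test_that("axial directions are proximal unit tangents", {
  # straight z-aligned branch: everything pulls (0, 0, -1)
  ax <- cbind(x = rep(1, 5), y = rep(1, 5), z = seq(1, 3, length.out = 5))
  d <- axial_direction(ax, 1:5)
  expect_equal(unname(d), matrix(rep(c(0, 0, -1), each = 5), 5),
               tolerance = 1e-12)

  # 45-degree inclined branch: +/- (1,0,1)/sqrt(2) with negative z
  ax45 <- cbind(x = seq(0, 2, 0.5), y = 0, z = seq(0, 2, 0.5))
  d45 <- axial_direction(ax45, 3)
  expect_equal(unname(d45[1, ]), c(-1, 0, -1) / sqrt(2), tolerance = 1e-12)
  expect_lt(d45[1, 3], 0)

  # curved arc: tangent at mid-arclength against the finite difference of a
  # much finer polyline
  tt <- seq(0, pi / 2, length.out = 41)
  arc <- cbind(x = sin(tt), y = 0, z = 1 - cos(tt))
  d_mid <- axial_direction(arc, 21)
  t_mid <- tt[21]
  expect_equal(unname(d_mid[1, ]), -c(cos(t_mid), 0, sin(t_mid)),
               tolerance = 1e-3)
})

test_that("assignment gives unit vectors and exact directions on a cylinder", {
  cyl <- cylinder_branches(x = 1.2, y = 1.2, z0 = 0.2, z1 = 2.2,
                           diameter = 0.8)
  tree <- structure(list(branches = cyl, profile = truncus_profile(),
                         center = c(1.2, 1.2), bounds = tier_bounds()),
                    class = "villous_tree")
  g <- rasterize_tree(cyl, 100, dims = c(24L, 24L, 26L))
  surf <- assign_contraction(extract_surface(g), tree)
  nrm <- sqrt(surf$dir_x^2 + surf$dir_y^2 + surf$dir_z^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
  # a z-aligned rami/ramuli tube contracts along (0, 0, -1) exactly
  expect_true(all(surf$dir_x == 0 & surf$dir_y == 0 & surf$dir_z == -1))
})

test_that("full-tree assignment keeps unit norms and covers all tiers", {
  tree <- suppressWarnings(build_villous_tree(master_seed = 5,
                                              n_particles = 60))
  g <- rasterize_tree(tree, 232)
  surf <- assign_contraction(extract_surface(g), tree)
  nrm <- sqrt(surf$dir_x^2 + surf$dir_y^2 + surf$dir_z^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
  expect_setequal(unique(surf$tier), c("truncus", "rami", "ramuli"))
  # the taper tilt keeps truncus contraction pointing plate-ward or in-plane
  expect_true(all(surf$dir_z[surf$tier == "truncus"] <= 0))
})
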