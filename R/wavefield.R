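#' Shear modulus from density, wavelength and frequency
#'
#' For a shear (transverse) wave, mu = rho * lambda^2 * nu^2. With tissue
#' density 1000 kg/m^3 and 1 Hz contraction frequency, the studied
#' wavelengths 0.29, 0.58 and 1.45 mm correspond to shear moduli
#' 8.41e-5, 3.36e-4 and 2.10e-3 Pa.
#'
#' @param rho density (kg/m^3).
#' @param lambda_mm wavelength (mm).
#' @param nu frequency (Hz); 0 is allowed (degenerate, mu = 0).
#' @return Shear modulus in Pa.
#' @export
#' @examples
#' shear_modulus(1000, 0.29, 1)
shear_modulus <- function(rho = 1000, lambda_mm, nu = 1) {
  if (any(rho < 0) || any(lambda_mm < 0) || any(nu < 0)) {
    stop("rho, lambda and nu must be non-negative")
  }
  rho * (lambda_mm * 1e-3)^2 * nu^2
}

#' Wave parameters of one computational condition
#'
#' The contraction propagates into the surroundings as a shear wave
#' `u = xi0 * cos(k r)` at t = 0, cut off hard at `d_max` (the viscoelastic
#' attenuation is folded into the cutoff). The wavelength is either
#' constant or increases with distance from the surface: 0.29 mm in the
#' first third of `d_max`, 0.58 mm in the second, 1.45 mm in the last.
#'
#' @param lambda either a constant wavelength in mm (0.29, 0.58 or 1.45 in
#'   the study) or the string "increasing".
#' @param d_max maximum propagation distance (mm): 1.45, 2.9 or 4.35.
#' @param xi0 amplitude (um).
#' @param nu frequency (Hz).
#' @param rho density (kg/m^3).
#' @return An object of class `wave_params`.
#' @export
wave_params <- function(lambda = 1.45, d_max = 4.35, xi0 = 0.1, nu = 1,
                        rho = 1000) {
  stopifnot(xi0 > 0, nu > 0, rho > 0, d_max > 0)
  increasing <- identical(lambda, "increasing")
  if (!increasing) {
    lambda <- as.numeric(lambda)
    stopifnot(length(lambda) == 1, lambda > 0)
  }
  structure(
    list(
      lambda_profile = if (increasing) "increasing" else "constant",
      lambda_mm = if (increasing) NA_real_ else lambda,
      lambda_stages = c(0.29, 0.58, 1.45),
      d_max = d_max, xi0 = xi0, nu = nu, rho = rho, t = 0
    ),
    class = "wave_params"
  )
}

#' @export
print.wave_params <- function(x, ...) {
  cat("<wave_params> lambda = ",
      if (x$lambda_profile == "increasing") "increasing (0.29 -> 1.45 mm)"
      else paste0(x$lambda_mm, " mm"),
      ", d_max = ", x$d_max, " mm, xi0 = ", x$xi0, " um, nu = ", x$nu,
      " Hz\n", sep = "")
  invisible(x)
}

#' Condition label (for tables and file names)
#' @param params a [wave_params()].
#' @return Character scalar, e.g. `"lambda1.45_dmax4.35"`.
#' @export
condition_label <- function(params) {
  lam <- if (params$lambda_profile == "increasing") "inc" else
    format(params$lambda_mm, nsmall = 2)
  paste0("lambda", lam, "_dmax", format(params$d_max, nsmall = 2))
}

#' Enumerate the twelve computational conditions
#'
#' The cross product of the four wavelength profiles (0.29, 0.58, 1.45 mm
#' constant, and distance-increasing) with the three propagation cutoffs
#' (1.45, 2.9, 4.35 mm).
#'
#' @return A tibble with `condition` (label), `lambda` (character),
#'   `d_max` and a list-column `params` of [wave_params()] objects.
#' @export
enumerate_conditions <- function() {
  lambdas <- list(0.29, 0.58, 1.45, "increasing")
  d_maxes <- c(1.45, 2.9, 4.35)
  grid <- expand.grid(lam = seq_along(lambdas), dm = d_maxes,
                      KEEP.OUT.ATTRS = FALSE)
  params <- lapply(seq_len(nrow(grid)), function(i) {
    wave_params(lambda = lambdas[[grid$lam[i]]], d_max = grid$dm[i])
  })
  tibble::tibble(
    condition = vapply(params, condition_label, character(1)),
    lambda = vapply(seq_len(nrow(grid)), function(i)
      as.character(lambdas[[grid$lam[i]]]), character(1)),
    d_max = grid$dm,
    params = params
  )
}

#' Local wavelength at distance r from the surface
#'
#' @param r distance from the villous surface (mm); vectorized.
#' @param params a [wave_params()].
#' @return Wavelength in mm.
#' @export
lambda_at <- function(r, params) {
  if (any(r < 0 | r > params$d_max)) {
    stop("r must lie within [0, d_max] = [0, ", params$d_max, "] mm")
  }
  if (params$lambda_profile == "constant") {
    return(rep(params$lambda_mm, length(r)))
  }
  b <- params$d_max / 3
  st <- params$lambda_stages
  ifelse(r < b, st[1], ifelse(r < 2 * b, st[2], st[3]))
}

#' Accumulated wave phase at distance r
#'
#' For constant wavelength, `Phi(r) = 2 pi r / lambda`. For the increasing
#' profile the phase accumulates piecewise, `Phi(r) = integral of
#' 2 pi / lambda(s) ds`, so it is continuous and non-decreasing across the
#' third-of-d_max boundaries (no amplitude jumps).
#'
#' @inheritParams lambda_at
#' @return Phase in radians.
#' @export
wave_phase <- function(r, params) {
  if (params$lambda_profile == "constant") {
    return(2 * pi * r / params$lambda_mm)
  }
  b <- params$d_max / 3
  st <- params$lambda_stages
  2 * pi * (pmin(r, b) / st[1] +
              pmin(pmax(r - b, 0), b) / st[2] +
              pmin(pmax(r - 2 * b, 0), b) / st[3])
}

#' Band-limited Euclidean distance transform with nearest-element map
#'
#' Computes, for every unoccupied voxel within `d_max` of the villous
#' surface, the exact Euclidean distance to the nearest surface-voxel
#' center and that element's id. Ties are broken toward the smallest
#' element id (elements are numbered in ascending linear-index order).
#' With `slab_nz` the volume is processed in z-slabs with a halo of
#' ceiling(d_max / pixel) slices, keeping memory bounded; the result is
#' identical to the single-pass computation.
#'
#' @param grid a [voxel_grid].
#' @param surface an [extract_surface()] result on the same grid.
#' @param d_max propagation cutoff (mm).
#' @param slab_nz optional slab thickness (z slices) for streaming.
#' @return A `distance_field`: list with `distance` (mm, `NA` outside the
#'   band and inside the villi), `d2` (squared distance in voxel units),
#'   `source` (integer element ids, 0 outside the band), `d_max`,
#'   `pixel_size`, `dims`.
#' @export
distance_transform <- function(grid, surface, d_max, slab_nz = NULL) {
  v <- grid$pixel_size / 1000
  if (d_max < v) {
    warning("d_max (", d_max, " mm) is below the voxel size (", v,
            " mm): the propagation band is nearly empty")
  }
  d <- grid$dims
  max_r2 <- as.integer(floor((d_max / v)^2 + 1e-9))
  surf_id <- array(0L, dim = d)
  lin <- (surface$k - 1) * d[1] * d[2] + (surface$j - 1) * d[1] + surface$i
  surf_id[lin] <- seq_len(nrow(surface))
  occ <- grid$occupancy

  if (is.null(slab_nz) || slab_nz >= d[3]) {
    d2 <- array(cpp_edt3d(surf_id, d), dim = d)
    src <- array(cpp_resolve_sources(as.numeric(d2), as.integer(surf_id),
                                     as.logical(occ), d, max_r2), dim = d)
  } else {
    halo <- as.integer(ceiling(d_max / v))
    d2 <- array(Inf, dim = d)
    src <- array(0L, dim = d)
    k0 <- 1L
    while (k0 <= d[3]) {
      k1 <- min(d[3], k0 + as.integer(slab_nz) - 1L)
      a <- max(1L, k0 - halo)
      b <- min(d[3], k1 + halo)
      sub_dims <- c(d[1], d[2], b - a + 1L)
      sub_sid <- surf_id[, , a:b, drop = FALSE]
      sub_occ <- occ[, , a:b, drop = FALSE]
      sub_d2 <- cpp_edt3d(as.integer(sub_sid), as.integer(sub_dims))
      sub_src <- cpp_resolve_sources(sub_d2, as.integer(sub_sid),
                                     as.logical(sub_occ), as.integer(sub_dims),
                                     max_r2)
      keep <- (k0 - a + 1L):(k1 - a + 1L)
      d2[, , k0:k1] <- array(sub_d2, dim = sub_dims)[, , keep]
      src[, , k0:k1] <- array(sub_src, dim = sub_dims)[, , keep]
      k0 <- k1 + 1L
    }
  }
  in_band <- !occ & d2 <= max_r2
  distance <- array(NA_real_, dim = d)
  distance[in_band] <- sqrt(d2[in_band]) * v
  src[!in_band] <- 0L
  structure(
    list(distance = distance, d2 = d2, source = src, d_max = d_max,
         max_r2 = max_r2, pixel_size = grid$pixel_size, dims = d),
    class = "distance_field"
  )
}

#' Displacement field of the contracting villous tree
#'
#' Every voxel in the propagation band is displaced along the contraction
#' direction of its nearest surface element by `xi0 * cos(Phi(r))` (t = 0).
#' Voxels beyond `d_max` and voxels inside the villi have zero
#' displacement; the displaced area is where |u| exceeds 1e-12 * xi0
#' (voxels sitting exactly on cosine zeros are excluded).
#'
#' @param dist a [distance_transform()] result. Its band may be wider than
#'   `params$d_max` (it is reused across conditions); the tighter cutoff is
#'   applied here.
#' @param surface an assigned surface (see [assign_contraction()]).
#' @param params a [wave_params()].
#' @return A `displacement_field`: list with `ux`, `uy`, `uz` (um),
#'   `displaced` (logical), plus the distance/source volumes and metadata.
#' @export
displacement_field <- function(dist, surface, params) {
  if (is.null(surface$dir_x)) {
    stop("surface has no contraction directions; run assign_contraction() first")
  }
  d <- dist$dims
  v <- dist$pixel_size / 1000
  max_r2 <- as.integer(floor((params$d_max / v)^2 + 1e-9))
  if (max_r2 > dist$max_r2) {
    stop("distance field band (d_max = ", dist$d_max,
         " mm) is narrower than params$d_max = ", params$d_max, " mm")
  }
  idx <- which(dist$source > 0L & dist$d2 <= max_r2)
  r <- sqrt(dist$d2[idx]) * v
  src <- dist$source[idx]
  amp <- params$xi0 * cos(wave_phase(r, params))
  ux <- array(0, dim = d); uy <- array(0, dim = d); uz <- array(0, dim = d)
  ux[idx] <- surface$dir_x[src] * amp
  uy[idx] <- surface$dir_y[src] * amp
  uz[idx] <- surface$dir_z[src] * amp
  displaced <- array(FALSE, dim = d)
  displaced[idx] <- abs(amp) > 1e-12 * params$xi0
  structure(
    list(ux = ux, uy = uy, uz = uz, displaced = displaced,
         params = params, pixel_size = dist$pixel_size, dims = d),
    class = "displacement_field"
  )
}

#' Distance transform plus displacement field in one call
#'
#' @inheritParams distance_transform
#' @param surface an assigned surface (see [assign_contraction()]).
#' @param params a [wave_params()].
#' @return A `displacement_field`.
#' @export
compute_displacement <- function(grid, surface, params, slab_nz = NULL) {
  dist <- distance_transform(grid, surface, params$d_max, slab_nz = slab_nz)
  displacement_field(dist, surface, params)
}
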