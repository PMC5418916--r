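#' Tier boundaries of the stem-villi model
#'
#' The stem villi are divided into three tiers stacked along the z axis
#' (z = 0 at the chorionic plate, +z toward the basal plate): the truncus
#' chorii (0--2.9 mm), the rami chorii (2.9--13.5 mm) and the ramuli chorii
#' (13.5--24.5 mm).
#'
#' @return A tibble with columns `tier`, `z_min`, `z_max` (mm) and the
#'   tier's diameter range `d_min`, `d_max` (mm).
#' @export
#' @examples
#' tier_bounds()
tier_bounds <- function() {
  tibble::tibble(
    tier  = c("truncus", "rami", "ramuli"),
    z_min = c(0, 2.9, 13.5),
    z_max = c(2.9, 13.5, 24.5),
    d_min = c(1, 0.5, 0.3),
    d_max = c(3, 1, 0.5)
  )
}

#' Mid-plane z coordinates of the three tiers
#'
#' @param bounds tier table as returned by [tier_bounds()].
#' @return Named numeric vector (mm) with elements `z_t`, `z_r`, `z_rl`.
#' @export
tier_midpoints <- function(bounds = tier_bounds()) {
  mids <- (bounds$z_min + bounds$z_max) / 2
  stats::setNames(mids, c("z_t", "z_r", "z_rl"))
}

#' Truncus radius profile
#'
#' The truncus chorii tapers from `r_max` at the chorionic plate to `r_min`
#' at the truncus--rami boundary `z_tr` along a quarter-ellipse, chosen so
#' that dr/dz vanishes at `z_tr` and the truncus joins the rami smoothly.
#'
#' @param r_max,r_min maximum and minimum radius (mm).
#' @param z_tr z coordinate of the truncus--rami boundary (mm).
#' @return An object of class `truncus_profile`.
#' @export
truncus_profile <- function(r_max = 1.5, r_min = 0.5, z_tr = 2.9) {
  stopifnot(r_max > r_min, r_min > 0, z_tr > 0)
  structure(list(r_max = r_max, r_min = r_min, z_tr = z_tr),
            class = "truncus_profile")
}

#' Truncus radius at height z
#'
#' r(z) = r_max - (r_max - r_min)/z_tr * sqrt(z_tr^2 - (z - z_tr)^2).
#' At z = 0 this gives `r_max`, at z = z_tr it gives `r_min`, and the slope
#' dr/dz is zero at z_tr.
#'
#' @param z height above the chorionic plate (mm); vectorized.
#' @param profile a [truncus_profile()].
#' @return Radius in mm.
#' @export
#' @examples
#' truncus_radius(c(0, 1.45, 2.9), truncus_profile())
truncus_radius <- function(z, profile = truncus_profile()) {
  if (any(z < 0 | z > profile$z_tr)) {
    stop("z must lie within [0, z_tr] = [0, ", profile$z_tr, "] mm")
  }
  with(profile, r_max - (r_max - r_min) / z_tr * sqrt(z_tr^2 - (z - z_tr)^2))
}

#' Slope dr/dz of the truncus radius profile
#'
#' dr/dz = (r_max - r_min)/z_tr * (z - z_tr) / sqrt(z_tr^2 - (z - z_tr)^2).
#' Tends to -Inf as z -> 0 and to 0 at z = z_tr.
#'
#' @inheritParams truncus_radius
#' @return dr/dz (dimensionless, mm/mm); `-Inf` at z = 0.
#' @export
truncus_radius_slope <- function(z, profile = truncus_profile()) {
  if (any(z < 0 | z > profile$z_tr)) {
    stop("z must lie within [0, z_tr] = [0, ", profile$z_tr, "] mm")
  }
  with(profile, {
    denom <- sqrt(z_tr^2 - (z - z_tr)^2)
    out <- ifelse(denom == 0, -Inf,
                  (r_max - r_min) / z_tr * (z - z_tr) / denom)
    # at z = z_tr the numerator is 0 first: slope is exactly 0
    out[z == z_tr] <- 0
    out
  })
}

#' Voxel grid dimensions for the model volume
#'
#' The reference volume is 1200 x 1200 x 847 voxels at 29 um/pixel
#' (34.8 x 34.8 x 24.563 mm). Coarser working resolutions keep the same
#' physical extent.
#'
#' @param pixel_size_um voxel edge length in micrometres.
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
#' @examples
#' default_grid_dims(29)   # 1200 1200 847
#' default_grid_dims(116)  # 300 300 212
default_grid_dims <- function(pixel_size_um = 29) {
  stopifnot(pixel_size_um > 0)
  as.integer(ceiling(c(1200, 1200, 847) * 29 / pixel_size_um))
}

#' Physical extent of a voxel grid
#'
#' @param dims integer dims `c(nx, ny, nz)`.
#' @param pixel_size_um voxel edge (um).
#' @return Extent in mm per axis.
#' @export
grid_extent_mm <- function(dims, pixel_size_um) {
  dims * pixel_size_um / 1000
}

# ---- contextual morphometry of the placental disc -------------------------

#' Distance between chorionic and basal plates
#'
#' The placental thickness minus the chorioamniotic membrane thickness.
#' With the literature values (25 mm and 243 um) this gives 24.757 mm,
#' i.e. 24.8 mm to one decimal, which the deepest branch of the model
#' (24.5 mm) approaches.
#'
#' @param placenta_thickness_mm placental thickness (mm).
#' @param membrane_thickness_um chorioamniotic membrane thickness (um).
#' @return Plate separation in mm.
#' @export
plate_separation <- function(placenta_thickness_mm = 25,
                             membrane_thickness_um = 243) {
  placenta_thickness_mm - membrane_thickness_um / 1000
}

#' Area of the placental disc
#'
#' @param diameter_mm disc diameter (mm); 220 mm for a term placenta.
#' @return Disc area in mm^2.
#' @export
placenta_disc_area <- function(diameter_mm = 220) {
  pi * (diameter_mm / 2)^2
}

#' Cross-sectional territory of a single villous tree
#'
#' Divides the placental disc area among the villous stems and converts the
#' per-tree cross section to an equivalent circular diameter. A term
#' placenta of 220 mm diameter with 60--70 stems yields per-tree areas of
#' 5.4e2--6.3e2 mm^2 (equivalent diameters 26--28 mm).
#'
#' @param n_stems number of villous stems sharing the disc.
#' @param disc_area_mm2 disc area (mm^2).
#' @return A tibble with `n_stems`, `area_mm2` and `diameter_mm`.
#' @export
stem_territory <- function(n_stems, disc_area_mm2 = placenta_disc_area()) {
  stopifnot(all(n_stems > 0))
  area <- disc_area_mm2 / n_stems
  tibble::tibble(
    n_stems = n_stems,
    area_mm2 = area,
    diameter_mm = 2 * sqrt(area / pi)
  )
}
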