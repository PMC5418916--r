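#' Extract the villous surface from a voxel grid
#'
#' A surface voxel is an occupied voxel with at least one unoccupied
#' face-neighbour (6-connectivity) or a face on the volume boundary.
#' Elements are returned in ascending linear-index order; their row number
#' is the surface-element id used by the distance transform's tie-break.
#'
#' @param grid a [voxel_grid].
#' @return A `contraction_surface` tibble with voxel indices `i`, `j`, `k`
#'   (1-based) and center positions `x`, `y`, `z` (mm).
#' @export
extract_surface <- function(grid) {
  occ <- grid$occupancy
  if (!any(occ)) stop("empty grid: no occupied voxels")
  d <- dim(occ)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  neighbours_all <- array(FALSE, dim = d) # TRUE iff all 6 face-neighbours occupied
  if (nx > 2 && ny > 2 && nz > 2) {
    core <- 2:(nx - 1)
    corey <- 2:(ny - 1)
    corez <- 2:(nz - 1)
    neighbours_all[core, corey, corez] <-
      occ[core - 1, corey, corez] & occ[core + 1, corey, corez] &
      occ[core, corey - 1, corez] & occ[core, corey + 1, corez] &
      occ[core, corey, corez - 1] & occ[core, corey, corez + 1]
  }
  surf <- occ & !neighbours_all
  lin <- which(surf) # ascending linear index
  ijk <- arrayInd(lin, d)
  v <- grid$pixel_size / 1000
  out <- tibble::tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = (ijk[, 1] - 0.5) * v, y = (ijk[, 2] - 0.5) * v,
    z = (ijk[, 3] - 0.5) * v
  )
  attr(out, "pixel_size") <- grid$pixel_size
  attr(out, "dims") <- d
  class(out) <- c("contraction_surface", class(out))
  out
}

#' Contraction direction on the truncus surface
#'
#' The contractile cells run along the branch axis; on the truncus the
#' surface tangential direction closest to the axis direction (0, 0, -1) is
#' tilted by the radius taper: phi_o = pi + atan(dr/dz), and the unit
#' direction is (sin(phi_o) cos(theta_o), sin(phi_o) sin(theta_o),
#' cos(phi_o)). At z = z_tr the taper vanishes and the direction is
#' (0, 0, -1); toward the chorionic plate dr/dz -> -Inf and the direction
#' flattens into the xy plane.
#'
#' @param z height (mm), within `[0, z_tr]`; vectorized.
#' @param theta_o azimuth of the surface point around the truncus axis
#'   (rad); vectorized.
#' @param profile a [truncus_profile()].
#' @return Matrix with columns `dx`, `dy`, `dz` of unit vectors, plus
#'   attribute `phi_o` (rad).
#' @export
truncus_direction <- function(z, theta_o, profile = truncus_profile()) {
  slope <- truncus_radius_slope(z, profile)
  phi_o <- pi + atan(slope)
  out <- cbind(dx = sin(phi_o) * cos(theta_o),
               dy = sin(phi_o) * sin(theta_o),
               dz = cos(phi_o))
  attr(out, "phi_o") <- phi_o
  out
}

#' Axial contraction direction on rami/ramuli branches
#'
#' The contraction is parallel to the local branch axis and points toward
#' the branch's proximal junction (toward the root).
#'
#' @param axis branch axis polyline (n x 3 matrix, ordered root-to-tip).
#' @param idx index (or indices) of the axis point nearest the surface
#'   element.
#' @return Matrix of proximal unit tangents.
#' @export
axial_direction <- function(axis, idx) {
  n <- nrow(axis)
  if (n < 2) stop("axis needs at least 2 points")
  nxt <- pmin(idx + 1L, n)
  prv <- pmax(idx - 1L, 1L)
  tan <- axis[prv, , drop = FALSE] - axis[nxt, , drop = FALSE]
  nrm <- sqrt(rowSums(tan^2))
  nrm[nrm == 0] <- 1
  tan / nrm
}

#' Assign contraction directions to a surface
#'
#' Each surface element is mapped to its nearest branch-axis point. Truncus
#' elements get the taper-tilted direction of [truncus_direction()] (with
#' theta_o measured around the truncus axis); rami and ramuli elements get
#' the proximally oriented axis tangent at the nearest axis point.
#'
#' @param surface a positions-only [extract_surface()] result.
#' @param tree the `villous_tree` the grid was rasterized from.
#' @return The surface tibble with `branch_id`, `tier`, `dir_x`, `dir_y`,
#'   `dir_z` (unit vectors), `phi_o` and `theta_o` (rad) added.
#' @export
assign_contraction <- function(surface, tree) {
  samples <- axis_samples(tree)
  profile <- tree$profile
  center <- tree$center
  q <- as.matrix(surface[, c("x", "y", "z")])
  ref <- as.matrix(samples[, c("x", "y", "z")])
  nearest <- cpp_nearest_point(q, ref)

  branch_id <- samples$branch_id[nearest]
  tier <- samples$tier[nearest]
  dir <- cbind(samples$tx[nearest], samples$ty[nearest], samples$tz[nearest])

  theta_o <- atan2(surface$y - center[2], surface$x - center[1])
  is_tr <- tier == "truncus"
  if (any(is_tr)) {
    z_tr <- pmin(pmax(surface$z[is_tr], 0), profile$z_tr)
    dir[is_tr, ] <- truncus_direction(z_tr, theta_o[is_tr], profile)
  }
  phi_o <- acos(pmin(1, pmax(-1, dir[, 3])))

  surface$branch_id <- branch_id
  surface$tier <- tier
  surface$dir_x <- dir[, 1]
  surface$dir_y <- dir[, 2]
  surface$dir_z <- dir[, 3]
  surface$phi_o <- phi_o
  surface$theta_o <- theta_o
  surface
}

#' Write a contraction surface to CSV
#'
#' @param surface an assigned surface (see [assign_contraction()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  readr::write_csv(as.data.frame(surface), path)
  invisible(path)
}
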