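#' Construct a voxel grid object
#'
#' Voxel centers sit at `((i - 0.5) * pixel)` mm for 1-based index `i`;
#' z = 0 is the chorionic plate and slice `k` spans
#' `((k-1) * pixel, k * pixel)` mm.
#'
#' @param occupancy logical 3D array.
#' @param pixel_size_um voxel edge (um).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(occupancy, pixel_size_um) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3)
  structure(list(occupancy = occupancy, pixel_size = pixel_size_um,
                 dims = dim(occupancy)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  ext <- grid_extent_mm(x$dims, x$pixel_size)
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "), " voxels at ",
      x$pixel_size, " um/pixel (", paste(format(ext, digits = 4),
                                         collapse = " x "),
      " mm), ", sum(x$occupancy), " occupied\n", sep = "")
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param grid a [voxel_grid].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of center coordinates in mm.
#' @export
voxel_centers <- function(grid, axis = 3) {
  (seq_len(grid$dims[axis]) - 0.5) * grid$pixel_size / 1000
}

#' Rasterize a villous tree into a voxel occupancy grid
#'
#' A voxel is occupied iff its center lies within the local branch radius of
#' some axis segment (flat-ended tube union: the occupied volume of a
#' straight branch of radius R and length L is pi R^2 L, without end caps).
#'
#' @param tree a `villous_tree` or branch table.
#' @param pixel_size_um voxel edge (um); the reference resolution is 29.
#' @param dims grid dimensions, default [default_grid_dims()] for the
#'   requested resolution.
#' @param max_voxels memory guard; grids larger than this raise an error
#'   advising a coarser `pixel_size_um`.
#' @return A [voxel_grid].
#' @export
rasterize_tree <- function(tree, pixel_size_um = 116,
                           dims = default_grid_dims(pixel_size_um),
                           max_voxels = 6e8) {
  branches <- if (inherits(tree, "villous_tree")) tree$branches else tree
  if (prod(as.numeric(dims)) > max_voxels) {
    stop("grid of ", paste(dims, collapse = " x "),
         " voxels exceeds the memory budget; use a coarser pixel_size_um")
  }
  seg_list <- lapply(seq_len(nrow(branches)), function(i) {
    a <- branches$axis[[i]]
    r <- branches$diameter[[i]] / 2
    n <- nrow(a)
    if (n < 2) return(NULL)
    cbind(a[-n, 1], a[-n, 2], a[-n, 3], a[-1, 1], a[-1, 2], a[-1, 3],
          r[-n], r[-1])
  })
  seg_list <- seg_list[!vapply(seg_list, is.null, logical(1))]
  dims <- as.integer(dims)
  if (length(seg_list) == 0) {
    occ <- array(FALSE, dim = dims)
  } else {
    segs <- do.call(rbind, seg_list)
    occ <- array(cpp_rasterize(segs, dims, pixel_size_um / 1000), dim = dims)
  }
  voxel_grid(occ, pixel_size_um)
}
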