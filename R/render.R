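# Documented, invertible colour maps for the slice renderings.

#' Colour maps for slice renderings
#'
#' `magnitude_colors` maps linearly from 0 (black) to `xi0` (white);
#' `phi_colors` maps 0--180 degrees onto a red/blue ramp with
#' red = phi/180 and blue = 1 - phi/180 (green 0); `theta_colors` uses a
#' cyclic HSV hue with hue = (theta + 180)/360, so -180 and 180 degrees
#' share a colour. All maps are invertible from the RGB channels; `NA`
#' renders black.
#'
#' @param x values to map (um for magnitude, degrees for angles).
#' @param xi0 amplitude for the magnitude scale (um).
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
magnitude_colors <- function(x, xi0 = 0.1) {
  t <- pmin(1, pmax(0, x / xi0))
  t[is.na(t)] <- 0
  cbind(r = t, g = t, b = t)
}

#' @rdname magnitude_colors
#' @export
phi_colors <- function(x) {
  t <- pmin(1, pmax(0, x / 180))
  na <- is.na(t)
  t[na] <- 0
  out <- cbind(r = t, g = 0, b = 1 - t)
  out[na, ] <- 0
  out
}

#' @rdname magnitude_colors
#' @export
theta_colors <- function(x) {
  h <- (x + 180) / 360
  na <- is.na(h)
  h[na] <- 0
  cols <- t(grDevices::col2rgb(grDevices::hsv(pmin(h, 1 - 1e-9), 1, 1))) / 255
  cols[na, ] <- 0
  colnames(cols) <- c("r", "g", "b")
  cols
}

#' Render slice images of the displacement quantities
#'
#' Writes one PNG per (quantity, z) pair: the magnitude on a linear scale
#' from 0 to xi0, phi and theta with the colour maps of
#' [magnitude_colors()]. Requested z positions outside the volume are
#' skipped with a warning.
#'
#' @param volumes named list of 3D arrays; recognized names are
#'   `magnitude`, `phi`, `theta` (others use the magnitude map).
#' @param z_list z positions (mm) to render.
#' @param pixel_size_um voxel edge (um).
#' @param dir output directory.
#' @param xi0 amplitude (um) for the magnitude scale.
#' @return Character vector of files written, invisibly.
#' @export
render_slices <- function(volumes, z_list, pixel_size_um, dir = ".",
                          xi0 = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- pixel_size_um / 1000
  written <- character(0)
  for (qty in names(volumes)) {
    vol <- volumes[[qty]]
    nz <- dim(vol)[3]
    for (z in z_list) {
      k <- floor(z / v) + 1L
      if (is.na(z) || k < 1 || k > nz) {
        warning("z = ", z, " mm is outside the volume; skipped")
        next
      }
      slice <- vol[, , k]
      cols <- switch(qty,
                     phi = phi_colors(as.vector(slice)),
                     theta = theta_colors(as.vector(slice)),
                     magnitude_colors(as.vector(slice), xi0))
      img <- array(0, dim = c(ncol(slice), nrow(slice), 3))
      for (ch in 1:3) img[, , ch] <- t(matrix(cols[, ch], nrow(slice)))
      path <- file.path(dir, sprintf("%s_z%05.2f.png", qty, z))
      png::writePNG(img, path)
      written <- c(written, path)
    }
  }
  invisible(written)
}
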