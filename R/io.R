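#' Write a volume as NIfTI-1
#'
#' The quantitative volume format: voxel values are stored as-is and the
#' physical pixel size (mm) is recorded in the header, z as the slice axis
#' and z = 0 at the chorionic plate.
#'
#' @param vol 3D numeric array.
#' @param path output file (`.nii` / `.nii.gz`).
#' @param pixel_size_um voxel edge (um).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, pixel_size_um) {
  v <- pixel_size_um / 1000
  im <- RNifti::asNifti(vol)
  RNifti::pixdim(im) <- c(v, v, v)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume_nifti()]
#' @param path file path.
#' @return A list with `vol` (array) and `pixel_size_um`.
#' @export
read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  list(vol = array(as.numeric(im), dim = dim(im)),
       pixel_size_um = RNifti::pixdim(im)[1] * 1000)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Values are rescaled to 16-bit; the linear scale and offset, and the
#' pixel size, are recorded in a JSON sidecar (`<path>.json`) so the stack
#' remains quantitative. z is the page axis. NIfTI
#' ([write_volume_nifti()]) is the lossless format.
#'
#' @inheritParams write_volume_nifti
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, pixel_size_um) {
  rng <- range(vol, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(vol)[3]), function(k) {
    (t(vol[, , k]) - rng[1]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = pixel_size_um, offset = rng[1], scale = scale,
         slice_axis = "z", z_origin = "chorionic plate"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Default run configuration
#'
#' Groups the tunables of a full pipeline run. The defaults reproduce the
#' study parameterization at a coarse working resolution (116 um/pixel);
#' `pixel_size_um = 29` is the reference resolution (combine with a
#' `slab_nz` to keep the distance transform memory-bounded).
#'
#' @param pixel_size_um voxel edge (um).
#' @param master_seed integer; drives all DLA seeds.
#' @param n_particles DLA particles per ramuli subtree.
#' @param condition a [condition_label()] string, or "all" for the twelve
#'   conditions.
#' @param out_dir output directory.
#' @param slab_nz optional z-slab thickness for streaming.
#' @param write_volumes write displacement/occupancy volumes (TIFF+NIfTI)?
#' @param lateral_halfwidth ramuli lateral half-extent (mm).
#' @param r_max,r_min,z_tr truncus profile (mm).
#' @return A `run_config` list with sections `geometry`, `wave`,
#'   `analysis`, `seeds`, `io`.
#' @export
run_config <- function(pixel_size_um = 116, master_seed = 1,
                       n_particles = 300,
                       condition = "lambda1.45_dmax4.35",
                       out_dir = tempfile("villiwave-run-"),
                       slab_nz = NULL, write_volumes = TRUE,
                       lateral_halfwidth = 4,
                       r_max = 1.5, r_min = 0.5, z_tr = 2.9) {
  structure(list(
    geometry = list(pixel_size_um = pixel_size_um, r_max = r_max,
                    r_min = r_min, z_tr = z_tr, n_particles = n_particles,
                    lateral_halfwidth = lateral_halfwidth),
    wave = list(condition = condition),
    analysis = list(smooth_width = 5, noise_mult = 5, window_mm = 2),
    seeds = list(master_seed = master_seed),
    io = list(out_dir = out_dir,
              slab_nz = slab_nz,
              write_volumes = write_volumes)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (sec in names(cfg)) {
    for (key in names(raw[[sec]])) cfg[[sec]][[key]] <- raw[[sec]][[key]]
  }
  cfg
}
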