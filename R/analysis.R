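# population SD (divide by N): well defined for any N >= 1, which the
# per-bin fraction SDs need
sd_pop <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Polar decomposition of a displacement field
#'
#' Magnitude, polar angle phi (degrees from the +z axis, 0--180) and
#' azimuth theta (degrees in the xy plane, -180 to <180, from atan2(y, x)).
#' Where the displacement is perpendicular to the chorionic plate (purely
#' axial) theta cannot be determined; such voxels carry
#' `theta_defined = FALSE` and are excluded from theta statistics.
#'
#' @param field a [displacement_field()].
#' @return A `polar_field`: list with `magnitude` (um), `phi`, `theta`
#'   (degrees), `theta_defined`, `displaced` (logical volumes) and
#'   metadata.
#' @export
to_polar <- function(field) {
  mag <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  inplane <- sqrt(field$ux^2 + field$uy^2)
  phi <- array(NA_real_, dim = field$dims)
  theta <- array(NA_real_, dim = field$dims)
  idx <- which(field$displaced)
  phi[idx] <- acos(pmin(1, pmax(-1, field$uz[idx] / mag[idx]))) * 180 / pi
  theta_defined <- array(FALSE, dim = field$dims)
  theta_defined[idx] <- inplane[idx] > 1e-9 * mag[idx]
  tidx <- which(theta_defined)
  th <- atan2(field$uy[tidx], field$ux[tidx]) * 180 / pi
  th[th >= 180] <- -180 # theta lives in [-180, 180)
  theta[tidx] <- th
  structure(
    list(magnitude = mag, phi = phi, theta = theta,
         theta_defined = theta_defined, displaced = field$displaced,
         params = field$params, pixel_size = field$pixel_size,
         dims = field$dims),
    class = "polar_field"
  )
}

#' Area fraction with phi in a band
#'
#' Fraction of displaced voxels whose polar angle lies in `[lo, hi]`
#' (inclusive band edges). For isotropically distributed directions the
#' 45--135 degree fraction is cos(45) - cos(135) = sqrt(2)/2.
#'
#' @param phi polar angles (degrees) of the displaced voxels of a slice.
#' @param lo,hi band edges in degrees.
#' @return Fraction in `[0, 1]`; `NA` for an empty slice.
#' @export
area_fraction_phi <- function(phi, lo = 45, hi = 135) {
  phi <- phi[!is.na(phi)]
  if (length(phi) == 0) return(NA_real_)
  mean(phi >= lo & phi <= hi)
}

#' Azimuthal uniformity SD_in of a theta histogram
#'
#' The theta values are binned into 360 one-degree class intervals spanning
#' [-180, 180); the area fraction of each bin is its count over the total,
#' and SD_in is the population SD across the 360 bin fractions. A
#' perfectly uniform azimuth distribution gives SD_in = 0.
#'
#' @param theta azimuths (degrees) of the theta-defined displaced voxels of
#'   a slice.
#' @return SD_in; `NA` if no theta-defined voxels.
#' @export
theta_histogram_sd <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0) return(NA_real_)
  b <- pmin(floor(theta) + 181L, 360L)
  frac <- tabulate(b, nbins = 360L) / length(theta)
  sd_pop(frac)
}

#' Per-slice displacement statistics
#'
#' For each z slice: the displaced area (voxel count with |u| > 0), mean
#' and population SD of the magnitude, the SD normalized by the mean, mean
#' and SD of phi, mean and SD of theta (theta-defined voxels only; theta is
#' averaged arithmetically on [-180, 180)), the area fraction with phi in
#' 45--135 degrees, and the azimuthal uniformity SD_in.
#'
#' @param polar a [to_polar()] result.
#' @return A `villi_slice_stats` tibble, one row per z slice.
#' @export
slice_stats <- function(polar) {
  d <- polar$dims
  v <- polar$pixel_size / 1000
  rows <- lapply(seq_len(d[3]), function(k) {
    disp <- polar$displaced[, , k]
    n <- sum(disp)
    if (n == 0) {
      return(tibble::tibble(
        k = k, z_mm = (k - 0.5) * v, displaced_area = 0L,
        mean_magnitude = NA_real_, sd_magnitude = NA_real_,
        normalized_sd = NA_real_, mean_phi = NA_real_, sd_phi = NA_real_,
        mean_theta = NA_real_, sd_theta = NA_real_,
        area_fraction_phi_45_135 = NA_real_, sd_in = NA_real_
      ))
    }
    m <- polar$magnitude[, , k][disp]
    p <- polar$phi[, , k][disp]
    tdef <- polar$theta_defined[, , k]
    th <- polar$theta[, , k][tdef]
    mean_m <- mean(m)
    sd_m <- sd_pop(m)
    tibble::tibble(
      k = k, z_mm = (k - 0.5) * v, displaced_area = n,
      mean_magnitude = mean_m, sd_magnitude = sd_m,
      normalized_sd = if (mean_m > 0) sd_m / mean_m else NA_real_,
      mean_phi = mean(p), sd_phi = sd_pop(p),
      mean_theta = if (length(th)) mean(th) else NA_real_,
      sd_theta = if (length(th)) sd_pop(th) else NA_real_,
      area_fraction_phi_45_135 = area_fraction_phi(p),
      sd_in = theta_histogram_sd(th)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pixel_size") <- polar$pixel_size
  attr(out, "condition") <- if (!is.null(polar$params))
    condition_label(polar$params) else NA_character_
  class(out) <- c("villi_slice_stats", class(out))
  out
}

# centered moving average with partial windows at the edges
.smooth_ma <- function(y, width = 5) {
  n <- length(y)
  half <- (width - 1) %/% 2
  vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    v <- y[w]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Local maxima with a prominence criterion
#'
#' A peak's prominence is its height above the higher of the two valley
#' minima separating it from the nearest higher ground on each side (or
#' the profile end). Peaks with prominence below `min_prominence` are
#' discarded. The first and last samples are never peaks (a rising profile
#' truncated by the domain boundary is not a maximum).
#'
#' @param y numeric profile (NA allowed; NA cannot be a peak).
#' @param min_prominence minimum prominence (same units as `y`).
#' @return A tibble with `index`, `value`, `prominence`, sorted by
#'   decreasing prominence.
#' @export
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  yy <- ifelse(is.na(y), -Inf, y)
  is_peak <- logical(n)
  for (i in seq_len(n)[-c(1, n)]) {
    if (!is.finite(yy[i])) next
    is_peak[i] <- yy[i] > yy[i - 1] && yy[i] >= yy[i + 1]
  }
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(i) {
    # valley minimum on each side, walking to the nearest strictly higher
    # point; a walk that runs off the profile end contributes no base (the
    # domain is physically truncated at the plates, so an edge is an open
    # end, not a valley)
    side_min <- function(range_idx) {
      m <- Inf
      for (j in range_idx) {
        if (yy[j] > yy[i]) return(m)
        m <- min(m, yy[j])
      }
      NA_real_ # reached the boundary without higher ground
    }
    lmin <- if (i > 1) side_min((i - 1):1) else NA_real_
    rmin <- if (i < n) side_min((i + 1):n) else NA_real_
    sides <- c(lmin, rmin)
    sides <- sides[!is.na(sides) & is.finite(sides)]
    base <- if (length(sides)) max(sides) else min(yy[is.finite(yy)])
    yy[i] - base
  }, numeric(1))
  out <- tibble::tibble(index = peaks, value = y[peaks], prominence = prom)
  out <- out[out$prominence >= min_prominence, ]
  out[order(-out$prominence), ]
}

#' Characteristic z positions of the displacement profiles
#'
#' Four positions recur in every computational condition: `z_d`, the peak
#' of the normalized SD of the magnitude (localized around the
#' truncus--rami boundary); `z_phi1` and `z_phi2`, the two most prominent
#' peaks of SD(phi), reported in increasing z; and `z_theta`, the dip of
#' mean theta around the rami--ramuli boundary. The tier midpoints `z_t`,
#' `z_r`, `z_rl` are reported alongside. Profiles are smoothed with a
#' 5-slice moving average before peak detection; a peak is significant when
#' its prominence reaches `noise_mult` times the median absolute
#' slice-to-slice change of the smoothed profile (a robust noise scale
#' that keeps the genuine shallow peak near the truncus flare while
#' rejecting plateau wiggles).
#'
#' @param stats a [slice_stats()] table covering the full z range.
#' @param bounds tier table, see [tier_bounds()].
#' @param smooth_width moving-average window (slices).
#' @param noise_mult prominence threshold as a multiple of the smoothed
#'   profile's median absolute successive difference.
#' @param window_mm half-width of the search windows for `z_d` (around the
#'   truncus--rami boundary) and `z_theta` (around the rami--ramuli
#'   boundary).
#' @return A `villi_char_positions` list with the positions (mm), the
#'   SD(phi) peak candidate table, and `complete` (TRUE when all four
#'   positions were found).
#' @export
find_characteristic_positions <- function(stats, bounds = tier_bounds(),
                                          smooth_width = 5,
                                          noise_mult = 5,
                                          window_mm = 2) {
  z <- stats$z_mm
  z_tr <- bounds$z_max[bounds$tier == "truncus"]
  z_rr <- bounds$z_max[bounds$tier == "rami"]

  nsd <- .smooth_ma(stats$normalized_sd, smooth_width)
  in_win_d <- abs(z - z_tr) <= window_mm
  z_d <- if (any(in_win_d & !is.na(nsd))) {
    z[in_win_d][which.max(nsd[in_win_d])]
  } else NA_real_

  sphi <- .smooth_ma(stats$sd_phi, smooth_width)
  noise <- stats::median(abs(diff(sphi)), na.rm = TRUE)
  peaks <- find_peaks(sphi, min_prominence = noise_mult * noise)
  peaks$z_mm <- z[peaks$index]
  peaks$area_fraction_phi_45_135 <- stats$area_fraction_phi_45_135[peaks$index]
  top2 <- utils::head(peaks, 2)
  z_phi <- sort(top2$z_mm)
  z_phi1 <- if (length(z_phi) >= 1) z_phi[1] else NA_real_
  z_phi2 <- if (length(z_phi) >= 2) z_phi[2] else NA_real_

  mth <- .smooth_ma(stats$mean_theta, smooth_width)
  in_win_t <- abs(z - z_rr) <= window_mm
  z_theta <- if (any(in_win_t & !is.na(mth))) {
    z[in_win_t][which.min(mth[in_win_t])]
  } else NA_real_

  mids <- tier_midpoints(bounds)
  out <- list(
    z_d = z_d, z_phi1 = z_phi1, z_phi2 = z_phi2, z_theta = z_theta,
    z_t = unname(mids["z_t"]), z_r = unname(mids["z_r"]),
    z_rl = unname(mids["z_rl"]),
    phi_peaks = peaks,
    complete = !any(is.na(c(z_d, z_phi1, z_phi2, z_theta)))
  )
  class(out) <- "villi_char_positions"
  out
}

#' Peak in-plane slice among the SD(phi) peak candidates
#'
#' Enumerates every interior local maximum of the smoothed SD(phi) profile
#' (the peak candidates, with no significance threshold) and picks the
#' slice with the largest 45--135 degree area fraction. The deep-model
#' SD(phi) structure varies with the DLA realization, but the winning
#' candidate sits in the truncus/rami region, which is deterministic, so
#' the selection is stable across seeds.
#'
#' @param stats a [slice_stats()] table.
#' @param smooth_width moving-average window (slices).
#' @return A list with `z_mm`, `fraction`, `displaced_area` of the winning
#'   slice and the full `candidates` table.
#' @export
inplane_peak_slice <- function(stats, smooth_width = 5) {
  sphi <- .smooth_ma(stats$sd_phi, smooth_width)
  cand <- find_peaks(sphi, min_prominence = 0)
  if (nrow(cand) == 0) {
    return(list(z_mm = NA_real_, fraction = NA_real_,
                displaced_area = NA_integer_, candidates = cand))
  }
  cand$z_mm <- stats$z_mm[cand$index]
  cand$fraction <- stats$area_fraction_phi_45_135[cand$index]
  best <- cand[which.max(cand$fraction), ]
  list(z_mm = best$z_mm, fraction = best$fraction,
       displaced_area = stats$displaced_area[best$index],
       candidates = cand)
}

#' @export
print.villi_char_positions <- function(x, ...) {
  cat("Characteristic positions (mm): z_d =", format(x$z_d, digits = 3),
      ", z_phi1 =", format(x$z_phi1, digits = 3),
      ", z_phi2 =", format(x$z_phi2, digits = 3),
      ", z_theta =", format(x$z_theta, digits = 3), "\n")
  cat("Tier midpoints: z_t =", x$z_t, ", z_r =", x$z_r, ", z_rl =", x$z_rl,
      if (!x$complete) "  [incomplete]" else "", "\n")
  invisible(x)
}

#' Plot per-slice displacement statistics
#'
#' One panel per statistic against z, with the tier boundaries marked.
#'
#' @param object a [slice_stats()] table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.villi_slice_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "z_mm", "displaced_area",
                  "mean_magnitude", "normalized_sd", "mean_phi", "sd_phi",
                  "mean_theta", "sd_theta", "area_fraction_phi_45_135",
                  "sd_in"),
    -"z_mm", names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z_mm, y = .data$value)) +
    ggplot2::geom_vline(xintercept = c(2.9, 13.5), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "z (mm, chorionic plate at 0)", y = NULL) +
    ggplot2::theme_minimal()
}
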