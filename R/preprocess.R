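#' Thickness from segmented layer boundaries
#'
#' Converts a pair of segmented boundary surfaces (axial pixel row of the
#' upper and lower layer boundary at each A-scan position) into a thickness
#' map. A-scans where either boundary is flagged erroneous are excluded from
#' further analyses (invalid pixels).
#'
#' @param upper,lower numeric matrices of boundary rows (axial pixels), same
#'   shape; `lower >= upper` wherever both are valid.
#' @param axial_scale_um axial scale in micrometres per pixel. Default 1.953
#'   (2.0 mm imaging depth over 1024 axial pixels).
#' @param erroneous logical matrix flagging A-scans with visible segmentation
#'   error; these become invalid pixels.
#' @param ... passed to [thickness_map()] (laterality, tilt, layer, fovea).
#' @return A [thickness_map] at the raw scan geometry.
#' @export
thickness_from_boundaries <- function(upper, lower, axial_scale_um = 2000 / 1024,
                                      erroneous = NULL, ...) {
  stopifnot(is.matrix(upper), is.matrix(lower), all(dim(upper) == dim(lower)))
  if (is.null(erroneous)) erroneous <- matrix(FALSE, nrow(upper), ncol(upper))
  stopifnot(all(dim(erroneous) == dim(upper)))
  valid <- !erroneous & !is.na(upper) & !is.na(lower)
  bad <- valid & (lower < upper)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("lower boundary above upper boundary at pixel (row %d, col %d)",
                 i[1], i[2]))
  }
  thick <- (lower - upper) * axial_scale_um
  thick[!valid] <- NA_real_
  thickness_map(thick, valid = valid, provenance = "thickness_from_boundaries", ...)
}

# Interpolation weight matrix for cubic-convolution resampling of a uniformly
# sampled axis from n_in to n_out samples (pixel-centre alignment, border
# replication). Returns an n_out x n_in dense matrix.
resample_matrix <- function(n_in, n_out) {
  s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(s)
  f <- s - i0
  W <- matrix(0, n_out, n_in)
  S <- matrix(FALSE, n_out, n_in)  # support (any nonzero tap, pre-clamp)
  for (m in -1:2) {
    w <- keys_kernel(f - m)
    src <- pmin(pmax(i0 + m, 0), n_in - 1) + 1
    use <- abs(w) > 1e-12
    idx <- cbind(seq_len(n_out)[use], src[use])
    W[idx] <- W[idx] + w[use]
    S[idx] <- TRUE
  }
  list(W = W, support = S)
}

#' Resize a raw macular cube map to 512 x 512
#'
#' Upsamples the slow (B-scan) axis from 128 to 512 rows by bicubic
#' interpolation, compensating for the anisotropic sampling of the raw
#' macular cube. The validity mask is resampled conservatively: an output
#' pixel is invalid if any source pixel in its interpolation support is
#' invalid, so no invalid measurement leaks into the resized map.
#'
#' @param map a [thickness_map] with 128 rows x 512 columns.
#' @return A 512 x 512 [thickness_map].
#' @export
resize_map <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (map$height_px != 128 || map$width_px != 512)
    stop("resize_map expects a raw 512 (wide) x 128 (high) map, got ",
         map$width_px, "x", map$height_px)
  rs <- resample_matrix(128, 512)
  v <- map$values
  v[!map$valid] <- 0
  out <- rs$W %*% v
  invalid_hit <- (rs$support %*% (!map$valid)) > 0
  valid <- !invalid_hit
  out[!valid] <- NA_real_
  fovea <- c(map$fovea_xy[1], (map$fovea_xy[2] + 0.5) * 512 / 128 - 0.5)
  thickness_map(out, valid = valid, fovea_xy = fovea,
                laterality = map$laterality, tilt_deg = map$tilt_deg,
                layer = map$layer,
                provenance = c(map$provenance, "resize_512x512"))
}

#' Convert a map to right-eye format
#'
#' Left-eye (OS) maps are mirrored about the vertical axis so that column 0
#' is temporal retina for every eye; the fovea coordinate and the tilt sign
#' are updated accordingly. Right-eye (OD) maps pass through unchanged.
#'
#' @param map a [thickness_map].
#' @return A [thickness_map] in right-eye format.
#' @export
orient_right_eye <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (map$laterality == "OD") {
    map$provenance <- c(map$provenance, "orient_right_eye(OD:identity)")
    return(map)
  }
  nc <- map$width_px
  vals <- map$values[, nc:1, drop = FALSE]
  valid <- map$valid[, nc:1, drop = FALSE]
  thickness_map(vals, valid = valid,
                fovea_xy = c((nc - 1) - map$fovea_xy[1], map$fovea_xy[2]),
                laterality = "OD", tilt_deg = -map$tilt_deg, layer = map$layer,
                provenance = c(map$provenance, "orient_right_eye(OS:mirrored)"))
}

#' Rotate a map about the fovea to zero disc-to-fovea tilt
#'
#' Rotates the image content by minus the recorded tilt around the foveal
#' centre with bicubic resampling, so that the disc-to-fovea axis is
#' horizontal in every standardised map. A pixel whose polar angle about the
#' fovea is `theta` before rotation appears at `theta - tilt` afterwards.
#' Pixels resampled from outside the field, or fed by any invalid pixel,
#' become invalid.
#'
#' @param map a [thickness_map]; `tilt_deg` must be known.
#' @return A [thickness_map] with `tilt_deg = 0`.
#' @export
rotate_to_zero_tilt <- function(map) {
  stopifnot(inherits(map, "thickness_map"), is.finite(map$tilt_deg))
  if (map$tilt_deg == 0) {
    map$provenance <- c(map$provenance, "rotate_to_zero_tilt(identity)")
    return(map)
  }
  t <- map$tilt_deg * pi / 180
  nr <- map$height_px; nc <- map$width_px
  fx <- map$fovea_xy[1]; fy <- map$fovea_xy[2]
  col <- rep(seq_len(nc) - 1, each = nr)
  row <- rep(seq_len(nr) - 1, times = nc)
  # fovea-centred frame with y up = superior (towards row 0)
  x <- col - fx
  y <- fy - row
  # output angle phi samples source content at phi + tilt
  sx <- cos(t) * x - sin(t) * y
  sy <- sin(t) * x + cos(t) * y
  smp <- bicubic_sample(map$values, map$valid, x = fx + sx, y = fy - sy)
  vals <- matrix(smp$values, nr, nc)
  valid <- matrix(smp$valid, nr, nc)
  thickness_map(vals, valid = valid, fovea_xy = map$fovea_xy,
                laterality = map$laterality, tilt_deg = 0, layer = map$layer,
                provenance = c(map$provenance,
                               sprintf("rotate_to_zero_tilt(%.3f deg)", map$tilt_deg)))
}

#' Radial displacement profile
#'
#' Eccentricity-dependent lateral displacement between outer-retinal
#' (photoreceptor) locations and their displaced inner-retinal partners,
#' used to re-align ORC content with the connecting INL/GCIPL components.
#' Displacement is linearly interpolated between samples, anchored at
#' (0, 0) if the first sample is not at zero eccentricity, and is zero
#' beyond the last sample.
#'
#' @param eccentricity_deg strictly ascending, non-negative eccentricities.
#' @param displacement_deg radial displacement (degrees) at each sample.
#' @return An object of class `displacement_profile`.
#' @export
displacement_profile <- function(eccentricity_deg, displacement_deg) {
  stopifnot(length(eccentricity_deg) == length(displacement_deg),
            length(eccentricity_deg) >= 1,
            all(eccentricity_deg >= 0),
            all(diff(eccentricity_deg) > 0))
  if (eccentricity_deg[1] > 0) {
    eccentricity_deg <- c(0, eccentricity_deg)
    displacement_deg <- c(0, displacement_deg)
  }
  structure(list(eccentricity_deg = eccentricity_deg,
                 displacement_deg = displacement_deg),
            class = "displacement_profile")
}

#' Read a displacement profile from a two-column CSV
#'
#' @param path CSV with columns `eccentricity_deg`, `displacement_deg`.
#' @return A [displacement_profile].
#' @export
read_displacement_profile <- function(path) {
  d <- utils::read.csv(path)
  displacement_profile(d$eccentricity_deg, d$displacement_deg)
}

eval_displacement <- function(profile, ecc_deg) {
  stats::approx(profile$eccentricity_deg, profile$displacement_deg,
                xout = ecc_deg, rule = 1, yleft = 0, yright = 0)$y |>
    (\(v) ifelse(is.na(v), 0, v))()
}

#' Apply eccentricity-dependent displacement correction
#'
#' Re-aligns outer-retina content with its inner-retina partners by
#' resampling each pixel from a radially displaced source location: a pixel
#' at eccentricity `e` (degrees) takes the source value at eccentricity
#' `e + d(e)` along the same meridian (outward/centrifugal remap). The
#' degree-to-mm conversion at the retina is configurable.
#'
#' @param map a standardised (right-eye, zero-tilt) [thickness_map].
#' @param profile a [displacement_profile].
#' @param mm_per_deg retinal mm per degree of visual angle (default 0.288).
#' @return A displacement-corrected [thickness_map].
#' @export
apply_displacement_correction <- function(map, profile, mm_per_deg = 0.288) {
  stopifnot(inherits(map, "thickness_map"))
  if (!inherits(profile, "displacement_profile") ||
      length(profile$eccentricity_deg) == 0)
    stop("a non-empty displacement_profile is required")
  off <- fovea_offsets_mm(map)
  ecc_mm <- sqrt(off$dx^2 + off$dy^2)
  ecc_deg <- ecc_mm / mm_per_deg
  d <- matrix(eval_displacement(profile, as.vector(ecc_deg)),
              map$height_px, map$width_px)
  scale <- (ecc_deg + d) / ecc_deg
  scale[ecc_deg == 0] <- 1
  px <- pixel_size_mm(map)
  sx <- map$fovea_xy[1] + (off$dx * scale) / px[1]
  sy <- map$fovea_xy[2] - (off$dy * scale) / px[2]
  smp <- bicubic_sample(map$values, map$valid,
                        x = as.vector(sx), y = as.vector(sy))
  vals <- matrix(smp$values, map$height_px, map$width_px)
  valid <- matrix(smp$valid, map$height_px, map$width_px)
  thickness_map(vals, valid = valid, fovea_xy = map$fovea_xy,
                laterality = map$laterality, tilt_deg = map$tilt_deg,
                layer = map$layer,
                provenance = c(map$provenance, "displacement_correction"))
}

#' Standardise a raw thickness map
#'
#' Fixed preprocessing order: resize to 512 x 512, convert to right-eye
#' format, rotate to zero tilt, and (ORC only, when a profile is supplied)
#' apply displacement correction. Each step is recorded in the map's
#' provenance.
#'
#' @param map a raw 512 x 128 [thickness_map].
#' @param profile optional [displacement_profile]; applied only to ORC maps.
#' @param mm_per_deg retinal mm per degree (see
#'   [apply_displacement_correction()]).
#' @return A standardised 512 x 512 [thickness_map].
#' @export
standardise_map <- function(map, profile = NULL, mm_per_deg = 0.288) {
  out <- rotate_to_zero_tilt(orient_right_eye(resize_map(map)))
  if (!is.null(profile) && map$layer == "ORC")
    out <- apply_displacement_correction(out, profile, mm_per_deg)
  out
}
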