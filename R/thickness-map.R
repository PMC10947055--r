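#' En-face layer thickness map
#'
#' Container for a single eye's en-face thickness map of one retinal layer.
#' Values are in micrometres on a regular pixel grid covering a fixed
#' 6.00 x 6.00 mm macular area. Pixels flagged invalid (e.g. segmentation
#' failures, or fed by out-of-field samples during resampling) carry `NA`
#' in `values` and `FALSE` in `valid` and are excluded from all statistics.
#'
#' Coordinate convention (right-eye format): row 0 (top) is superior retina,
#' column 0 (left) is temporal retina; `fovea_xy` is a continuous 0-based
#' (column, row) coordinate.
#'
#' @param values numeric matrix of thickness (um), rows = vertical axis.
#' @param valid logical matrix, same shape; defaults to all pixels valid.
#' @param fovea_xy length-2 numeric, 0-based (column, row) of the foveal
#'   centre; defaults to the grid centre.
#' @param laterality `"OD"` or `"OS"`.
#' @param tilt_deg disc-to-fovea tilt in degrees (positive = fovea-to-disc
#'   axis rotated counter-clockwise about the fovea in right-eye format).
#' @param layer one of `"GCIPL"`, `"INL"`, `"ORC"`.
#' @param extent_mm physical (width, height) of the scan, fixed at 6 x 6 mm.
#' @param provenance character vector of processing steps applied so far.
#'
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, valid = NULL,
                          fovea_xy = NULL,
                          laterality = c("OD", "OS"),
                          tilt_deg = 0,
                          layer = c("GCIPL", "INL", "ORC"),
                          extent_mm = c(6, 6),
                          provenance = character()) {
  stopifnot(is.matrix(values), is.numeric(values))
  laterality <- match.arg(laterality)
  layer <- match.arg(layer)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(is.logical(valid), all(dim(valid) == dim(values)))
  if (is.null(fovea_xy)) fovea_xy <- c((ncol(values) - 1) / 2, (nrow(values) - 1) / 2)
  stopifnot(length(fovea_xy) == 2,
            fovea_xy[1] >= 0, fovea_xy[1] <= ncol(values) - 1,
            fovea_xy[2] >= 0, fovea_xy[2] <= nrow(values) - 1)
  if (!isTRUE(all(extent_mm == c(6, 6))))
    stop("scan extent is fixed at 6.00 x 6.00 mm")
  mn <- suppressWarnings(min(values, na.rm = TRUE))
  if (is.finite(mn) && mn < -0.5) stop("negative thickness in valid pixels")
  # sub-resolution undershoot from cubic resampling at sharp gradients is
  # clamped; anything beyond 0.5 um below zero is treated as corrupt data
  if (is.finite(mn) && mn < 0) values <- pmax(values, 0)
  if (!all(valid)) values[!valid] <- NA_real_
  structure(
    list(values = values, valid = valid,
         width_px = ncol(values), height_px = nrow(values),
         extent_mm = extent_mm, fovea_xy = as.numeric(fovea_xy),
         laterality = laterality, tilt_deg = as.numeric(tilt_deg),
         layer = layer, provenance = provenance),
    class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s %s  %dx%d px, %.2fx%.2f mm, tilt %.2f deg\n",
              x$layer, x$laterality, x$height_px, x$width_px,
              x$extent_mm[1], x$extent_mm[2], x$tilt_deg))
  cat(sprintf("  fovea (col,row) = (%.2f, %.2f); %d/%d pixels valid\n",
              x$fovea_xy[1], x$fovea_xy[2], sum(x$valid), length(x$valid)))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Pixel size of a thickness map
#'
#' @param map a [thickness_map].
#' @return `c(dx, dy)` in mm per pixel.
#' @keywords internal
pixel_size_mm <- function(map) {
  c(map$extent_mm[1] / map$width_px, map$extent_mm[2] / map$height_px)
}

#' Pixel-centre offsets from the fovea, in mm
#'
#' Returns matrices `dx` (positive towards nasal retina, i.e. increasing
#' column) and `dy` (positive towards superior retina, i.e. decreasing row),
#' both fovea-centred.
#'
#' @param map a [thickness_map].
#' @keywords internal
fovea_offsets_mm <- function(map) {
  px <- pixel_size_mm(map)
  cols <- (seq_len(map$width_px) - 1 - map$fovea_xy[1]) * px[1]
  rows <- (map$fovea_xy[2] - (seq_len(map$height_px) - 1)) * px[2]
  list(dx = matrix(cols, map$height_px, map$width_px, byrow = TRUE),
       dy = matrix(rows, map$height_px, map$width_px))
}

#' Mean layer thickness over valid pixels
#'
#' Arithmetic mean thickness across the entire scan area, excluding invalid
#' pixels; the per-participant summary used when modelling demographic
#' effects on layer thickness in the healthy cohort.
#'
#' @param map a [thickness_map].
#' @return Mean thickness in micrometres.
#' @export
mean_layer_thickness <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (!any(map$valid)) stop("no valid pixels in map")
  mean(map$values[map$valid])
}
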