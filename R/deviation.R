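#' Matching specification for normative subgroups
#'
#' @param age_window plus/minus years (default 7.5).
#' @param se_window plus/minus dioptres (default 2.00).
#' @param match_sex logical; also require identical sex (layer-dependent,
#'   from the normative regression outcome).
#' @param min_subgroup minimum acceptable subgroup size (default 3).
#' @return An object of class `match_spec`.
#' @export
match_spec <- function(age_window = 7.5, se_window = 2.00, match_sex = FALSE,
                       min_subgroup = 3) {
  stopifnot(age_window > 0, se_window > 0, min_subgroup >= 1)
  structure(list(age_window = age_window, se_window = se_window,
                 match_sex = match_sex, min_subgroup = min_subgroup),
            class = "match_spec")
}

#' Select the demographics-matched healthy subgroup
#'
#' Healthy participants within the age and refractive-error windows of a
#' glaucoma participant (and of the same sex when `match_sex`). The
#' participant's own record, if present in the healthy pool, is excluded.
#'
#' @param g a participant record (list with `id`, `age`, `se`, `sex`).
#' @param healthy list of healthy participant records.
#' @param spec a [match_spec].
#' @return Integer indices into `healthy`; attribute `flagged` is `TRUE`
#'   (with a warning) when fewer than `min_subgroup` members match.
#' @export
select_matched_subgroup <- function(g, healthy, spec = match_spec()) {
  stopifnot(length(healthy) >= 1)
  idx <- which(vapply(healthy, function(h) {
    !identical(h$id, g$id) &&
      abs(h$age - g$age) <= spec$age_window &&
      abs(h$se - g$se) <= spec$se_window &&
      (!spec$match_sex || h$sex == g$sex)
  }, logical(1)))
  flagged <- length(idx) < spec$min_subgroup
  if (flagged)
    warning(sprintf("participant %s: matched subgroup has %d member(s) (< %d)",
                    g$id, length(idx), spec$min_subgroup))
  attr(idx, "flagged") <- flagged
  idx
}

#' Per-pixel mean of a set of standardised maps
#'
#' The normative comparison map: for each pixel, the mean over the maps in
#' which that pixel is valid, with the number of contributing maps recorded
#' per pixel. A pixel with no contributing map is invalid.
#'
#' @param maps list of standardised [thickness_map]s (same shape).
#' @param min_count minimum number of contributing maps for a pixel to be
#'   valid (default 1); pixels supported by fewer maps carry unstable
#'   normative values and can be excluded by raising this.
#' @return List with `values`, `valid` and `counts` matrices.
#' @export
normative_mean_map <- function(maps, min_count = 1) {
  stopifnot(length(maps) >= 1, min_count >= 1)
  dims <- dim(maps[[1]]$values)
  s <- matrix(0, dims[1], dims[2])
  counts <- matrix(0L, dims[1], dims[2])
  for (m in maps) {
    stopifnot(all(dim(m$values) == dims))
    v <- m$values
    v[!m$valid] <- 0
    s <- s + v
    counts <- counts + m$valid
  }
  valid <- counts >= min_count
  values <- s / pmax(counts, 1L)
  values[!valid] <- NA_real_
  list(values = values, valid = valid, counts = counts)
}

#' Raw deviation map: glaucoma minus normative mean
#'
#' Pixel-wise difference in micrometres (negative = thinner than the
#' matched normative mean); raw units, never normalised to percent of
#' normal. Invalid where either side is invalid.
#'
#' @param g_map the participant's standardised [thickness_map].
#' @param norm output of [normative_mean_map()].
#' @return List with `values` and `valid` matrices (512 x 512).
#' @export
compute_deviation_map <- function(g_map, norm) {
  if (!all(dim(g_map$values) == dim(norm$values)))
    stop("map shapes differ")
  valid <- g_map$valid & norm$valid
  values <- g_map$values - norm$values
  values[!valid] <- NA_real_
  list(values = values, valid = valid)
}

#' Average a deviation map over the 64 x 64 analysis grid
#'
#' Averages the 512 x 512 pixel deviations over 8 x 8 pixel blocks
#' (93.75 x 93.75 um each) anchored at pixel (0, 0), for a 64 x 64 grid. A
#' cell is valid when at least half of its 64 pixels are valid.
#'
#' @param dev output of [compute_deviation_map()] (or a list with `values`
#'   and `valid` 512 x 512 matrices).
#' @param layer,participant_id,subgroup_size metadata carried on the grid.
#' @return An object of class `deviation_grid`: `values`, `valid` (64 x 64),
#'   `layer`, `participant_id`, `subgroup_size`, `cell_um`.
#' @export
grid_average <- function(dev, layer = NA_character_,
                         participant_id = NA_character_,
                         subgroup_size = NA_integer_) {
  v <- dev$values
  ok <- dev$valid
  if (!all(dim(v) == c(512, 512))) stop("grid_average expects a 512 x 512 map")
  cell_um <- 6000 / 64
  stopifnot(identical(cell_um, 93.75))  # 6.00 mm / 64 cells, exactly
  g <- rep(seq_len(64), each = 8)
  v0 <- v
  v0[!ok] <- 0
  sums <- t(rowsum(t(rowsum(v0, g)), g))
  counts <- t(rowsum(t(rowsum(ok + 0, g)), g))
  valid <- counts >= 32
  values <- sums / pmax(counts, 1)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, layer = layer,
                 participant_id = participant_id,
                 subgroup_size = subgroup_size, cell_um = cell_um),
            class = "deviation_grid")
}

#' @export
print.deviation_grid <- function(x, ...) {
  cat(sprintf("<deviation_grid> %s %s: 64 x 64 cells of %.2f um, %d valid\n",
              x$layer, x$participant_id, x$cell_um, sum(x$valid)))
  invisible(x)
}

#' Deviation grids for a glaucoma cohort against a healthy pool
#'
#' For each glaucoma participant and layer: select the matched healthy
#' subgroup (per-layer matching covariates), average the subgroup's
#' standardised maps into a normative mean, subtract, and grid-average.
#' Normative means are cached per distinct subgroup membership.
#'
#' @param glaucoma,healthy lists of participant records with standardised
#'   maps under `$maps_std` (named by layer).
#' @param layers character vector of layers to process.
#' @param match_specs named list of [match_spec] per layer.
#' @return Nested list: `result[[participant_id]][[layer]]` is a
#'   [grid_average()] output; participants whose subgroup is under-sized
#'   are flagged via the grid's `subgroup_size`.
#' @export
cohort_deviation_grids <- function(glaucoma, healthy, layers = c("GCIPL", "INL", "ORC"),
                                   match_specs = NULL) {
  if (is.null(match_specs))
    match_specs <- stats::setNames(replicate(length(layers), match_spec(),
                                             simplify = FALSE), layers)
  cache <- new.env(parent = emptyenv())
  out <- lapply(glaucoma, function(g) {
    per_layer <- lapply(layers, function(ly) {
      idx <- suppressWarnings(select_matched_subgroup(g, healthy, match_specs[[ly]]))
      if (!length(idx)) return(NULL)
      key <- paste(ly, paste(idx, collapse = ","))
      norm <- if (!is.null(cache[[key]])) cache[[key]] else {
        nm <- normative_mean_map(lapply(healthy[idx], function(h) h$maps_std[[ly]]),
                                 min_count = min(match_specs[[ly]]$min_subgroup,
                                                 length(idx)))
        cache[[key]] <- nm
        nm
      }
      dev <- compute_deviation_map(g$maps_std[[ly]], norm)
      grid_average(dev, layer = ly, participant_id = g$id,
                   subgroup_size = length(idx))
    })
    stats::setNames(per_layer, layers)
  })
  stats::setNames(out, vapply(glaucoma, `[[`, "", "id"))
}
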