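#' The 10-2 visual field test lattice
#'
#' The 68 test locations of the 10-2 pattern: points with odd-degree
#' coordinates `x, y` in `{-9, -7, ..., 9}` lying within 10 degrees of
#' fixation (x^2 + y^2 <= 82). In this package's right-eye convention
#' `x > 0` is the nasal visual field and `y > 0` the superior visual field.
#'
#' @return A data.frame with columns `x`, `y` (degrees), 68 rows.
#' @export
vf_lattice_10_2 <- function() {
  g <- expand.grid(x = seq(-9, 9, 2), y = seq(-9, 9, 2))
  g <- g[g$x^2 + g$y^2 <= 82, ]
  g <- g[order(-g$y, g$x), ]
  rownames(g) <- NULL
  g
}

#' Probability-flag levels, least to most severe
#' @keywords internal
vf_flag_levels <- function() c("none", "p5", "p2", "p1", "p05")

#' 10-2 visual field result
#'
#' @param points data.frame with columns `x`, `y`, `td` (total deviation,
#'   dB), `pd` (pattern deviation, dB) and `prob` (probability flag, one of
#'   `"none"`, `"p5"`, `"p2"`, `"p1"`, `"p05"`); must be the 68 locations of
#'   [vf_lattice_10_2()].
#' @param md mean deviation (dB); defaults to the mean of `td`.
#' @param psd pattern standard deviation (dB); defaults to the standard
#'   deviation of `pd` (simplified, unweighted index).
#' @return An object of class `vf_result`.
#' @export
vf_result <- function(points, md = NULL, psd = NULL) {
  lat <- vf_lattice_10_2()
  stopifnot(is.data.frame(points), nrow(points) == 68,
            all(c("x", "y", "td", "pd", "prob") %in% names(points)))
  o <- order(-points$y, points$x)
  points <- points[o, ]
  rownames(points) <- NULL
  if (!isTRUE(all(points$x == lat$x & points$y == lat$y)))
    stop("points must lie on the 10-2 lattice")
  points$prob <- factor(as.character(points$prob), levels = vf_flag_levels(),
                        ordered = TRUE)
  if (anyNA(points$prob)) stop("unknown probability flag")
  if (is.null(md)) md <- mean(points$td)
  if (is.null(psd)) psd <- stats::sd(points$pd)
  structure(list(points = points, md = md, psd = psd), class = "vf_result")
}

#' @export
print.vf_result <- function(x, ...) {
  nf <- sum(x$points$prob != "none")
  cat(sprintf("<vf_result> 10-2: MD %.2f dB, PSD %.2f dB, %d flagged point(s)\n",
              x$md, x$psd, nf))
  invisible(x)
}

#' Find visual field defect clusters
#'
#' Connected components of probability-flagged points (flag at p < 5% or
#' worse) under 8-connectivity on the 2-degree lattice. A component
#' qualifies as a defect cluster when it contains at least three points and
#' at least one point flagged at the p < 1% level or worse
#' (Hodapp-Parrish-Anderson criterion).
#'
#' @param vf a [vf_result].
#' @return List of integer vectors (row indices into `vf$points`), one per
#'   qualifying cluster; empty list if none qualify.
#' @export
find_vf_defect_clusters <- function(vf) {
  stopifnot(inherits(vf, "vf_result"))
  p <- vf$points
  flagged <- which(p$prob >= "p5")
  if (!length(flagged)) return(list())
  # union-find over flagged points; adjacency = both |dx|,|dy| <= 2 deg
  parent <- seq_along(flagged)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in seq_along(flagged)) for (b in seq_len(a - 1L)) {
    if (abs(p$x[flagged[a]] - p$x[flagged[b]]) <= 2 &&
        abs(p$y[flagged[a]] - p$y[flagged[b]]) <= 2) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(flagged), find, integer(1))
  comps <- split(flagged, roots)
  keep <- vapply(comps, function(idx)
    length(idx) >= 3 && any(p$prob[idx] >= "p1"), logical(1))
  out <- unname(comps[keep])
  out[order(vapply(out, min, integer(1)))]
}

# arcuate test: cluster shows greater loss nasally than temporally
is_arcuate <- function(points, idx) {
  nasal <- idx[points$x[idx] > 0]
  temporal <- idx[points$x[idx] < 0]
  if (!length(nasal)) return(FALSE)
  if (!length(temporal)) return(TRUE)
  mean(points$pd[nasal]) <= mean(points$pd[temporal])
}

#' Classify visual field defect type
#'
#' Classifies a field as clear (C), inferior (I), superior (S) or ring (R):
#' C when no cluster qualifies (regardless of MD); I/S when all defect
#' points lie in one hemifield with at most one point encroaching on the
#' opposite hemifield; R when each hemifield contains a qualifying cluster
#' with an arcuate character (greater loss nasally than temporally);
#' otherwise two-hemifield non-arcuate cases take the hemifield of the
#' larger cluster by point count (tie: the cluster with the more negative
#' mean pattern deviation).
#'
#' @param clusters output of [find_vf_defect_clusters()].
#' @param vf the corresponding [vf_result].
#' @return One of `"C"`, `"I"`, `"S"`, `"R"`.
#' @export
classify_defect_type <- function(clusters, vf) {
  stopifnot(inherits(vf, "vf_result"))
  if (!length(clusters)) return("C")
  p <- vf$points
  pts <- unlist(clusters)
  n_sup <- sum(p$y[pts] > 0)
  n_inf <- sum(p$y[pts] < 0)
  if (n_inf <= 1 && n_sup > n_inf) return("S")
  if (n_sup <= 1 && n_inf > n_sup) return("I")
  sup_cl <- clusters[vapply(clusters, function(i) any(p$y[i] > 0), logical(1))]
  inf_cl <- clusters[vapply(clusters, function(i) any(p$y[i] < 0), logical(1))]
  sup_arc <- any(vapply(sup_cl, function(i) is_arcuate(p, i[p$y[i] > 0]), logical(1)))
  inf_arc <- any(vapply(inf_cl, function(i) is_arcuate(p, i[p$y[i] < 0]), logical(1)))
  if (sup_arc && inf_arc) return("R")
  sizes <- vapply(clusters, length, integer(1))
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    depth <- vapply(clusters[best], function(i) mean(p$pd[i]), numeric(1))
    best <- best[which.min(depth)]
  } else best <- best[1]
  hemis <- vapply(clusters, function(i) sum(p$y[i] > 0) - sum(p$y[i] < 0), numeric(1))
  if (hemis[best] >= 0) "S" else "I"
}

#' Assign mean-deviation severity bin
#'
#' Three-decibel MD strata with boundaries closed on the worse side:
#' bin1 MD > -3.00; bin2 -6.00 < MD <= -3.00; bin3 -9.00 < MD <= -6.00;
#' bin4 MD <= -9.00.
#'
#' @param md mean deviation (dB).
#' @return `"bin1"`, `"bin2"`, `"bin3"` or `"bin4"`.
#' @export
assign_md_bin <- function(md) {
  if (!is.finite(md)) stop("MD must be finite")
  if (md > -3) "bin1" else if (md > -6) "bin2" else if (md > -9) "bin3" else "bin4"
}

#' Classify a 10-2 result into defect type and MD bin
#'
#' @param vf a [vf_result].
#' @return List with `defect_type`, `md_bin`, `clusters` (point-index sets)
#'   and `stratum` (the combined label, e.g. `"S.bin2"`).
#' @export
classify_vf <- function(vf) {
  cl <- find_vf_defect_clusters(vf)
  ty <- classify_defect_type(cl, vf)
  bin <- assign_md_bin(vf$md)
  list(defect_type = ty, md_bin = bin, clusters = cl,
       stratum = paste(ty, bin, sep = "."))
}
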