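#' Classify clusters as defective
#'
#' A cluster is defective when its mean deviation is negative (a reduction
#' from the matched normative data) AND falls below the macula-wide average
#' deviation of the subcohort grid; both conditions are required.
#'
#' @param solution a `cluster_solution` (see [cluster_deviation_grids()]).
#' @param grid_mean mean deviation over all valid cells of the subcohort
#'   grid (um); defaults to the value stored on the solution.
#' @return Logical vector, one flag per cluster (in `solution$clusters`
#'   order).
#' @export
classify_defective_clusters <- function(solution, grid_mean = solution$grid_mean) {
  stopifnot(inherits(solution, "cluster_solution"), is.finite(grid_mean))
  solution$clusters$mean < 0 & solution$clusters$mean < grid_mean
}

#' Binary defective-cell map from a cluster solution
#'
#' @param solution a `cluster_solution` with a `label_map`.
#' @param grid_mean see [classify_defective_clusters()].
#' @return List with `defective` (64 x 64 logical) and `valid` (64 x 64
#'   logical, cells that entered clustering).
#' @export
defective_cell_map <- function(solution, grid_mean = solution$grid_mean) {
  flags <- classify_defective_clusters(solution, grid_mean)
  lm <- solution$label_map
  defective <- matrix(FALSE, nrow(lm), ncol(lm))
  valid <- lm > 0
  defective[valid] <- flags[lm[valid]]
  list(defective = defective, valid = valid)
}

#' Percentage agreement and Cohen's kappa between two binary maps
#'
#' Builds the 2 x 2 contingency table of defective/not-defective status over
#' the cells valid in both maps; reports percentage agreement, Cohen's
#' kappa with chance agreement from the marginals, and a p-value from the
#' large-sample normal approximation. Kappa is undefined (`NA`) when either
#' map is single-category over the common cells.
#'
#' @param mapA,mapB logical matrices (defective status), same shape.
#' @param validA,validB logical validity masks (default: all cells).
#' @return An object of class `agreement_result`: `contingency` (2 x 2,
#'   rows = A, `TRUE` first), `n`, `percent_agreement`, `kappa`, `p_value`.
#' @export
agreement_stats <- function(mapA, mapB, validA = NULL, validB = NULL) {
  stopifnot(all(dim(mapA) == dim(mapB)))
  if (is.null(validA)) validA <- matrix(TRUE, nrow(mapA), ncol(mapA))
  if (is.null(validB)) validB <- matrix(TRUE, nrow(mapB), ncol(mapB))
  common <- validA & validB
  n <- sum(common)
  if (n == 0) stop("no commonly valid cells")
  a <- sum(mapA[common] & mapB[common])
  b <- sum(mapA[common] & !mapB[common])
  cc <- sum(!mapA[common] & mapB[common])
  d <- sum(!mapA[common] & !mapB[common])
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(A = c("defective", "not"),
                                B = c("defective", "not")))
  po <- (a + d) / n
  pA <- c(a + b, cc + d) / n  # A marginals (TRUE, FALSE)
  pB <- c(a + cc, b + d) / n
  pe <- sum(pA * pB)
  single <- any(pA == 1) || any(pB == 1)
  if (single || pe == 1) {
    kappa <- NA_real_
    p_value <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    # asymptotic SE under the null of chance agreement
    se0 <- sqrt(pe + pe^2 - sum(pA * pB * (pA + pB))) / ((1 - pe) * sqrt(n))
    z <- kappa / se0
    p_value <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(contingency = tab, n = n,
                 percent_agreement = 100 * po,
                 kappa = kappa, p_value = p_value),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d, agreement %.1f%%, kappa %s\n",
              x$n, x$percent_agreement,
              if (is.na(x$kappa)) "N/A"
              else sprintf("%.3f (p = %.3g)", x$kappa, x$p_value)))
  invisible(x)
}

#' Layer-pair agreement table for a set of cluster solutions
#'
#' Computes percentage agreement and Cohen's kappa for the GCIPL-INL,
#' GCIPL-ORC and INL-ORC defective-map comparisons of one subcohort.
#'
#' @param solutions named list of `cluster_solution`s (names = layers).
#' @return data.frame with columns `layer_pair`, `percent_agreement`,
#'   `kappa`, `p_value`, `n`.
#' @export
layer_agreement_table <- function(solutions) {
  layers <- names(solutions)
  pairs <- utils::combn(layers, 2, simplify = FALSE)
  maps <- lapply(solutions, defective_cell_map)
  do.call(rbind, lapply(pairs, function(p) {
    ag <- agreement_stats(maps[[p[1]]]$defective, maps[[p[2]]]$defective,
                          maps[[p[1]]]$valid, maps[[p[2]]]$valid)
    data.frame(layer_pair = paste(p, collapse = "-"),
               percent_agreement = ag$percent_agreement,
               kappa = ag$kappa, p_value = ag$p_value, n = ag$n)
  }))
}
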