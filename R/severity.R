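#' Mean deviation difference within versus outside defective GCIPL cells
#'
#' For one participant's deviation grid (any layer) and the defective-GCIPL
#' cell mask of the participant's stratum: mean of grid values inside the
#' mask minus mean outside, over the grid's valid cells. Negative values
#' indicate greater loss inside the defective region. Undefined (`NA`) when
#' either class is empty among the valid cells.
#'
#' @param grid a [grid_average()] output.
#' @param defective_mask 64 x 64 logical.
#' @return Difference in um, or `NA`.
#' @export
within_outside_difference <- function(grid, defective_mask) {
  stopifnot(inherits(grid, "deviation_grid"),
            all(dim(defective_mask) == c(64, 64)))
  inside <- grid$valid & defective_mask
  outside <- grid$valid & !defective_mask
  if (!any(inside) || !any(outside)) return(NA_real_)
  mean(grid$values[inside]) - mean(grid$values[outside])
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation with mid-ranks for ties; the p-value uses
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors (`n >= 5` after removing incomplete
#'   pairs).
#' @return List with `r`, `p_value`, `n`; `r` is `NA` when either variable
#'   is constant.
#' @export
spearman_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("at least 5 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  r <- stats::cor(x, y, method = "spearman")
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Cross-layer spatial correlation for one participant
#'
#' Spearman correlation between two layers' deviation values across the
#' commonly valid cells of the 64 x 64 grid (not pooled over clusters).
#'
#' @param grid1,grid2 [grid_average()] outputs for two layers of the same
#'   participant.
#' @return List with `r`, `p_value`, `n` (cells used).
#' @export
cross_layer_r <- function(grid1, grid2) {
  stopifnot(inherits(grid1, "deviation_grid"), inherits(grid2, "deviation_grid"))
  common <- grid1$valid & grid2$valid
  spearman_r(grid1$values[common], grid2$values[common])
}

#' Per-participant severity quantities
#'
#' For each participant: the within/outside-defective-GCIPL difference for
#' each layer, and the three cross-layer spatial correlations, alongside
#' the participant's 10-2 MD and PSD. The defective-GCIPL mask is the one
#' from the participant's (defect type x MD bin) stratum solution;
#' participants whose stratum has no defective GCIPL cluster (or no
#' solution) contribute `NA` differences.
#'
#' @param grids nested list `grids[[id]][[layer]]` of [grid_average()]
#'   outputs.
#' @param strata named character vector: stratum label per participant id.
#' @param stratum_solutions named list (by stratum) of named lists (by
#'   layer) of `cluster_solution`s; only the GCIPL solution is used for the
#'   mask.
#' @param vf named list of [vf_result]s per participant id.
#' @return data.frame with one row per participant: `id`, `stratum`,
#'   `GCIPL_diff`, `INL_diff`, `ORC_diff`, `r_GCIPL_INL`, `r_GCIPL_ORC`,
#'   `r_INL_ORC`, `MD`, `PSD`.
#' @export
participant_severity_table <- function(grids, strata, stratum_solutions, vf) {
  ids <- names(grids)
  rows <- lapply(ids, function(id) {
    st <- strata[[id]]
    sols <- stratum_solutions[[st]]
    mask <- NULL
    if (!is.null(sols) && !is.null(sols$GCIPL)) {
      dm <- defective_cell_map(sols$GCIPL)
      if (any(dm$defective)) mask <- dm$defective
    }
    g <- grids[[id]]
    diffs <- vapply(c("GCIPL", "INL", "ORC"), function(ly) {
      if (is.null(mask) || is.null(g[[ly]])) NA_real_
      else within_outside_difference(g[[ly]], mask)
    }, numeric(1))
    pair_r <- function(a, b) {
      if (is.null(g[[a]]) || is.null(g[[b]])) return(NA_real_)
      cross_layer_r(g[[a]], g[[b]])$r
    }
    rr <- c(r_GCIPL_INL = pair_r("GCIPL", "INL"),
            r_GCIPL_ORC = pair_r("GCIPL", "ORC"),
            r_INL_ORC = pair_r("INL", "ORC"))
    data.frame(id = id, stratum = st,
               GCIPL_diff = diffs[["GCIPL"]], INL_diff = diffs[["INL"]],
               ORC_diff = diffs[["ORC"]],
               r_GCIPL_INL = rr[["r_GCIPL_INL"]],
               r_GCIPL_ORC = rr[["r_GCIPL_ORC"]],
               r_INL_ORC = rr[["r_INL_ORC"]],
               MD = vf[[id]]$md, PSD = vf[[id]]$psd)
  })
  do.call(rbind, rows)
}

#' Global Spearman correlations of severity quantities with MD and PSD
#'
#' For each of the six per-participant quantities (three within/outside
#' differences and three cross-layer correlations), the global Spearman
#' correlation across participants against 10-2 MD and against PSD.
#'
#' @param tab a [participant_severity_table()] output.
#' @return data.frame with columns `quantity`, `versus`, `r_g`, `p_value`,
#'   `n`.
#' @export
global_severity_correlations <- function(tab) {
  quantities <- c("GCIPL_diff", "INL_diff", "ORC_diff",
                  "r_GCIPL_INL", "r_GCIPL_ORC", "r_INL_ORC")
  out <- expand.grid(quantity = quantities, versus = c("MD", "PSD"),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    x <- tab[[out$quantity[i]]]; y <- tab[[out$versus[i]]]
    n_ok <- sum(is.finite(x) & is.finite(y))
    if (n_ok < 5)
      return(data.frame(r_g = NA_real_, p_value = NA_real_, n = n_ok))
    sp <- spearman_r(x, y)
    data.frame(r_g = sp$r, p_value = sp$p_value, n = sp$n)
  })
  cbind(out, do.call(rbind, res))
}
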