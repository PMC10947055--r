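# Agglomerative clustering with "within-groups" average linkage on squared
# Euclidean distance: the next merge minimises the mean pairwise squared
# distance over all pairs inside the merged cluster. For a candidate union S
# with m members, sufficient statistics give
#   sum_{a<b in S} ||x_a - x_b||^2 = m * Q - ||S1||^2,
# with S1 the member sum and Q the sum of squared norms, so each candidate
# cost is O(d). Nearest-neighbour costs are cached exactly (a pair's cost
# depends only on the two clusters' statistics, so cached entries stay valid
# until one endpoint is consumed by a merge).

#' Within-groups hierarchical merge tree
#'
#' Full agglomerative merge sequence from singletons to one cluster, where
#' each step merges the pair minimising the average squared Euclidean
#' distance over all pairs within the merged cluster. Deterministic, with
#' ties broken in cluster-index order.
#'
#' @param features numeric vector (scalar feature per item) or matrix with
#'   one row per item.
#' @return An object of class `merge_tree`: `merge` ((n-1) x 2 matrix,
#'   hclust coding: negative = singleton), `height` (merge cost per step),
#'   `n`.
#' @export
hierarchical_merge_tree <- function(features) {
  x <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  n <- nrow(x)
  if (n < 2) stop("at least 2 items are required")
  d <- ncol(x)
  scalar <- d == 1L
  nmax <- 2L * n - 1L
  size <- numeric(nmax); size[1:n] <- 1
  s1v <- if (scalar) { v <- numeric(nmax); v[1:n] <- x[, 1L]; v } else NULL
  s1 <- if (scalar) NULL else rbind(x, matrix(0, n - 1L, d))
  q <- numeric(nmax); q[1:n] <- rowSums(x^2)
  n2 <- numeric(nmax); n2[1:n] <- q[1:n]          # ||S1||^2 per cluster
  act <- 1:n                                      # active cluster ids, ascending
  nn_cost <- rep(Inf, nmax); nn_id <- integer(nmax)

  cost_to <- function(i, js) {
    m <- size[i] + size[js]
    Q <- q[i] + q[js]
    cross <- if (scalar) s1v[js] * s1v[i]
             else as.vector(s1[js, , drop = FALSE] %*% s1[i, ])
    (m * Q - (n2[i] + 2 * cross + n2[js])) * 2 / (m * (m - 1))
  }
  rescan <- function(i) {
    js <- act[act != i]
    cc <- cost_to(i, js)
    b <- which.min(cc)
    nn_cost[i] <<- cc[b]; nn_id[i] <<- js[b]
  }
  for (i in 1:n) rescan(i)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  code <- function(id) if (id <= n) -id else id - n
  for (s in seq_len(n - 1L)) {
    i <- act[which.min(nn_cost[act])]
    j <- nn_id[i]
    a <- min(i, j); b <- max(i, j)
    merge[s, ] <- c(code(a), code(b))
    height[s] <- nn_cost[i]
    cid <- n + s
    size[cid] <- size[a] + size[b]
    if (scalar) s1v[cid] <- s1v[a] + s1v[b] else s1[cid, ] <- s1[a, ] + s1[b, ]
    q[cid] <- q[a] + q[b]
    n2[cid] <- if (scalar) s1v[cid]^2 else sum(s1[cid, ]^2)
    act <- c(act[act != a & act != b], cid)
    if (s == n - 1L) break
    js <- act[-length(act)]
    cc <- cost_to(cid, js)
    bb <- which.min(cc)
    nn_cost[cid] <- cc[bb]; nn_id[cid] <- js[bb]
    # neighbours may have found a better partner in the new cluster
    upd <- cc < nn_cost[js]
    nn_cost[js[upd]] <- cc[upd]
    nn_id[js[upd]] <- cid
    # neighbours whose cached partner was consumed must rescan
    stale <- js[!upd & (nn_id[js] == a | nn_id[js] == b)]
    for (k in stale) rescan(k)
  }
  structure(list(merge = merge, height = height, n = n), class = "merge_tree")
}

#' Cut a merge tree into k clusters
#'
#' Replays the first `n - k` merges and labels items 1..k in order of first
#' appearance.
#'
#' @param tree a [hierarchical_merge_tree()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels, one per item.
#' @export
cut_merge_tree <- function(tree, k) {
  n <- tree$n
  stopifnot(k >= 1, k <= n)
  # node ids: 1..n singletons, n+s for merge step s
  members <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) members[[i]] <- i
  for (s in seq_len(n - k)) {
    ch <- tree$merge[s, ]
    ids <- ifelse(ch < 0L, -ch, ch + n)
    members[[n + s]] <- c(members[[ids[1]]], members[[ids[2]]])
    members[[ids[1]]] <- integer(0)
    members[[ids[2]]] <- integer(0)
  }
  labels <- integer(n)
  nxt <- 1L
  for (i in seq_len(2L * n - 1L)) {
    if (length(members[[i]])) {
      labels[members[[i]]] <- nxt
      nxt <- nxt + 1L
    }
  }
  labels
}

#' Choose the starting cluster count by BIC
#'
#' For each `k` up to `k_max`, cuts the tree into `k` clusters and scores
#' the classification log-likelihood of a Gaussian model with
#' cluster-specific means, a pooled variance and multinomial mixing
#' proportions:
#' `logL = sum_k n_k log(n_k/n) - n/2 (log(2 pi sigma^2) + 1)`,
#' `BIC(k) = -2 logL + 2k log(n)` (k means, k - 1 proportions, 1 variance).
#' Returns the `k` minimising BIC. Degenerate data (zero total variance)
#' give `k = 1`. The mixing-proportion term is what keeps the criterion
#' from over-splitting one-dimensional tree cuts, so the d-prime
#' refinement starts from a coarse, defensible count.
#'
#' @param features numeric vector of item values.
#' @param tree the corresponding [hierarchical_merge_tree()].
#' @param k_max largest cluster count considered (default 10).
#' @return Integer `k0`.
#' @export
select_initial_k_bic <- function(features, tree, k_max = 10) {
  x <- as.numeric(features)
  n <- length(x)
  stopifnot(k_max >= 1, n == tree$n)
  if (stats::var(x) < 1e-24 || k_max == 1) return(1L)
  k_hi <- min(k_max, n)
  # one incremental walk over the merge sequence: cluster sizes and sums
  # give the within-SS update for each merge, so BIC(k) for all k <= k_max
  # comes out of a single pass
  nmax <- 2L * n - 1L
  sz <- numeric(nmax); sz[1:n] <- 1
  sm <- numeric(nmax); sm[1:n] <- x
  alive <- logical(nmax); alive[1:n] <- TRUE
  sse <- 0
  bic <- rep(NA_real_, k_hi)
  score <- function(k) {
    sigma2 <- sse / n
    if (sigma2 < 1e-24) return(-Inf)
    nk <- sz[alive]
    logl <- sum(nk * log(nk / n)) - n / 2 * (log(2 * pi * sigma2) + 1)
    -2 * logl + 2 * k * log(n)
  }
  if (n <= k_hi) bic[n] <- score(n)
  for (s in seq_len(n - 1L)) {
    ch <- tree$merge[s, ]
    ids <- ifelse(ch < 0L, -ch, ch + n)
    a <- ids[1]; b <- ids[2]; cid <- n + s
    sse <- sse + (sz[a] * sz[b] / (sz[a] + sz[b])) *
      (sm[a] / sz[a] - sm[b] / sz[b])^2
    sz[cid] <- sz[a] + sz[b]; sm[cid] <- sm[a] + sm[b]
    alive[a] <- alive[b] <- FALSE; alive[cid] <- TRUE
    k <- n - s
    if (k >= 1 && k <= k_hi) bic[k] <- score(k)
  }
  which.min(bic)
}

#' d-prime separability between two clusters
#'
#' `d' = |x1 - x2| / sqrt(0.5 (s1^2 + s2^2))` from the cluster means and
#' standard deviations. When both SDs are zero: 0 for equal means, `Inf`
#' otherwise.
#'
#' @param a,b lists with elements `mean` and `sd` (cluster statistics).
#' @return Non-negative numeric (possibly `Inf`).
#' @export
dprime <- function(a, b) {
  denom <- sqrt(0.5 * (a$sd^2 + b$sd^2))
  num <- abs(a$mean - b$mean)
  if (denom == 0) return(if (num == 0) 0 else Inf)
  num / denom
}

cluster_stats <- function(x, labels) {
  ks <- sort(unique(labels))
  data.frame(label = ks,
             mean = vapply(ks, function(k) mean(x[labels == k]), numeric(1)),
             sd = vapply(ks, function(k) {
               v <- x[labels == k]
               if (length(v) < 2) 0 else stats::sd(v)
             }, numeric(1)),
             n = vapply(ks, function(k) sum(labels == k), integer(1)))
}

dprime_matrix <- function(stats_df) {
  k <- nrow(stats_df)
  D <- matrix(NA_real_, k, k)
  if (k < 2) return(D)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- dprime(list(mean = stats_df$mean[i], sd = stats_df$sd[i]),
                                 list(mean = stats_df$mean[j], sd = stats_df$sd[j]))
  }
  D
}

#' Refine a cluster cut by the d-prime criterion
#'
#' Starting from the `k0`-cluster cut, repeatedly merges the cluster pair
#' with the smallest d-prime while that value is below the criterion,
#' recomputing cluster statistics and the d-prime matrix after every merge.
#' The final solution has every pairwise d-prime at or above the criterion
#' (or a single cluster). Labels are ordinal: cluster 1 has the most
#' positive mean deviation.
#'
#' @param features numeric vector of item values (cell mean deviations, um).
#' @param tree the [hierarchical_merge_tree()] of `features`.
#' @param k0 starting cluster count (see [select_initial_k_bic()]).
#' @param criterion minimum acceptable pairwise d-prime (default 1).
#' @return An object of class `cluster_solution`: `labels` (per item,
#'   ordinal by descending cluster mean), `clusters` (data.frame label /
#'   mean / sd / n), `dprime_matrix`, `k`.
#' @export
refine_by_dprime <- function(features, tree, k0, criterion = 1) {
  x <- as.numeric(features)
  labels <- cut_merge_tree(tree, k0)
  repeat {
    st <- cluster_stats(x, labels)
    if (nrow(st) <= 1) break
    D <- dprime_matrix(st)
    dmin <- min(D, na.rm = TRUE)
    if (dmin >= criterion) break
    ij <- which(D == dmin, arr.ind = TRUE)[1, ]
    keep <- st$label[min(ij)]
    drop <- st$label[max(ij)]
    labels[labels == drop] <- keep
  }
  st <- cluster_stats(x, labels)
  ord <- order(-st$mean)
  relab <- match(labels, st$label[ord])
  st <- st[ord, ]
  st$label <- seq_len(nrow(st))
  rownames(st) <- NULL
  structure(list(labels = relab, clusters = st,
                 dprime_matrix = dprime_matrix(st), k = nrow(st)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d; min pairwise d' = %.3f\n", x$k,
              if (x$k > 1) min(x$dprime_matrix, na.rm = TRUE) else NA))
  print(x$clusters, digits = 4)
  invisible(x)
}

#' Cluster a subcohort's deviation grids for one layer
#'
#' Builds the per-cell feature (default: the subcohort mean deviation at
#' each cell, over the participants whose cell is valid), runs the
#' within-groups merge tree, selects the starting count by BIC and refines
#' by the d-prime criterion. Cells valid in fewer than `min_valid_frac` of
#' participants are excluded (label 0).
#'
#' @param grids list of [grid_average()] outputs (same layer, one
#'   subcohort).
#' @param k_max BIC search bound (default 10).
#' @param criterion d-prime criterion (default 1).
#' @param feature `"mean"` (scalar per cell, default) or `"vector"`
#'   (per-participant deviation vectors; complete cells only).
#' @param min_valid_frac minimum fraction of participants with a valid cell.
#' @return A `cluster_solution` with extra fields: `label_map` (64 x 64,
#'   0 = excluded), `mean_grid` (subcohort mean deviation per cell),
#'   `grid_mean` (macula-wide mean of the valid cells), `cells` (indices).
#' @export
cluster_deviation_grids <- function(grids, k_max = 10, criterion = 1,
                                    feature = c("mean", "vector"),
                                    min_valid_frac = 0.5) {
  feature <- match.arg(feature)
  stopifnot(length(grids) >= 1)
  P <- length(grids)
  vals <- vapply(grids, function(g) g$values, matrix(0, 64, 64))
  ok <- vapply(grids, function(g) g$valid, matrix(TRUE, 64, 64))
  dim(vals) <- c(64 * 64, P); dim(ok) <- c(64 * 64, P)
  nvalid <- rowSums(ok)
  v0 <- vals; v0[!ok] <- 0
  mean_cell <- rowSums(v0) / pmax(nvalid, 1)
  mean_cell[nvalid == 0] <- NA_real_
  cells <- if (feature == "vector") which(nvalid == P)
           else which(nvalid >= min_valid_frac * P & nvalid > 0)
  if (length(cells) < 2) stop("fewer than 2 usable grid cells")
  feats <- if (feature == "vector") vals[cells, , drop = FALSE] else mean_cell[cells]
  tree <- hierarchical_merge_tree(feats)
  scalar <- mean_cell[cells]
  k0 <- select_initial_k_bic(scalar, tree, k_max = k_max)
  sol <- refine_by_dprime(scalar, tree, k0, criterion = criterion)
  label_map <- matrix(0L, 64, 64)
  label_map[cells] <- sol$labels
  mean_grid <- matrix(mean_cell, 64, 64)
  sol$label_map <- label_map
  sol$mean_grid <- mean_grid
  sol$grid_mean <- mean(scalar)
  sol$cells <- cells
  sol$k0 <- k0
  sol
}
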