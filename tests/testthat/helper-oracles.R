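# Brute-force oracles, independent of the package's implementation paths.

# Within-groups linkage by explicit search over the full pairwise distance
# matrix: the average pairwise squared distance inside a candidate union S
# is sum(D[S, S]) / (m (m - 1)).
oracle_merge_tree <- function(x) {
  n <- length(x)
  D <- outer(x, x, function(a, b) (a - b)^2)
  clusters <- as.list(seq_len(n))
  ids <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  code <- function(id) if (id <= n) -id else id - n
  for (s in seq_len(n - 1L)) {
    k <- length(clusters)
    bc <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      S <- c(clusters[[i]], clusters[[j]])
      m <- length(S)
      cost <- sum(D[S, S]) / (m * (m - 1))
      if (cost < bc - 1e-15) { bc <- cost; bi <- i; bj <- j }
    }
    a <- ids[bi]; b <- ids[bj]
    merge[s, ] <- c(code(min(a, b)), code(max(a, b)))
    height[s] <- bc
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[bi] <- n + s
    clusters[[bj]] <- NULL
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# Cohen's kappa from explicit observed/chance agreement.
oracle_kappa <- function(a, b, cc, d) {
  n <- a + b + cc + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + cc) / n) + ((cc + d) / n) * ((b + d) / n)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Spearman rho via explicit mid-rank transform + Pearson on the ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Hand-built merge tree whose cut at k returns prescribed groups (groups
# listed in label order); used to exercise the d-prime refinement
# independently of the linkage stage.
manual_tree <- function(group_sizes) {
  n <- sum(group_sizes)
  idx <- split(seq_len(n), rep(seq_along(group_sizes), group_sizes))
  merge <- matrix(0L, n - 1L, 2L)
  s <- 0L
  heads <- integer(length(idx))
  for (g in seq_along(idx)) {
    members <- idx[[g]]
    node <- -members[1]
    for (m in members[-1]) {
      s <- s + 1L
      merge[s, ] <- c(node, -m)
      node <- s
    }
    heads[g] <- node
  }
  node <- heads[1]
  for (g in seq_along(idx)[-1]) {
    s <- s + 1L
    merge[s, ] <- c(node, heads[g])
    node <- s
  }
  structure(list(merge = merge, height = rep(0, n - 1L), n = n),
            class = "merge_tree")
}

# Deterministic sample with exact mean m and exact SD s (n >= 2).
exact_sample <- function(n, m, s) {
  v <- seq_len(n) - mean(seq_len(n))
  m + s * v / stats::sd(v)
}

# A flat participant record for map synthesis.
flat_record <- function(age = 50, sex = "F", se = 0, eye = "OD", tilt = 0) {
  list(id = "T", age = age, sex = sex, se = se, eye = eye, tilt = tilt)
}

# Deterministic layer model (no noise, no subject effects).
quiet_model <- function(layer = "GCIPL", ...) {
  layer_effect_model(layer, noise_sd = 0, between_subject_sd = 0,
                     profile_scale_sd = 0, ...)
}

# Build a vf_result from sparse (x, y, pd, prob) assignments; all other
# lattice points are 0 / "none".
vf_from_points <- function(df) {
  lat <- vf_lattice_10_2()
  pts <- data.frame(x = lat$x, y = lat$y, td = 0, pd = 0, prob = "none",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    j <- which(pts$x == df$x[i] & pts$y == df$y[i])
    stopifnot(length(j) == 1)
    pts$pd[j] <- df$pd[i]
    pts$td[j] <- df$pd[i]
    pts$prob[j] <- df$prob[i]
  }
  vf_result(pts)
}

# Wrap a plain matrix as a deviation_grid.
as_grid <- function(values, valid = NULL, layer = "GCIPL", id = "X") {
  if (is.null(valid)) valid <- !is.na(values)
  structure(list(values = values, valid = valid, layer = layer,
                 participant_id = id, subgroup_size = 1L, cell_um = 93.75),
            class = "deviation_grid")
}
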