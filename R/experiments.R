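# Self-contained simulation experiments exercising the pipeline end-to-end
# on cohorts with known ground truth. These back the package's validation
# suite and the reproduction script.

#' Planted defect mask on the 64 x 64 analysis grid
#'
#' Evaluates the arcuate defect in the standardised 512 x 512 geometry and
#' marks a grid cell as inside the defect when at least half of its 64
#' pixels fall inside the arc.
#'
#' @param defect a [defect_spec].
#' @param mm_per_deg retinal mm per degree (default 0.288).
#' @return 64 x 64 logical matrix.
#' @export
defect_grid_mask <- function(defect, mm_per_deg = 0.288) {
  n <- 512L
  f <- (n - 1) / 2
  px <- 6 / n
  dx <- matrix((seq_len(n) - 1 - f) * px, n, n, byrow = TRUE)
  dy <- matrix((f - (seq_len(n) - 1)) * px, n, n)
  ecc_deg <- sqrt(dx^2 + dy^2) / mm_per_deg
  theta <- atan2(dy, dx) * 180 / pi
  inside <- matrix(arc_mask_std(defect, as.vector(ecc_deg), as.vector(theta)),
                   n, n)
  g <- rep(seq_len(64), each = 8)
  frac <- t(rowsum(t(rowsum(inside + 0, g)), g)) / 64
  frac >= 0.5
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; `NA` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

#' Regression and elimination recovery on simulated healthy cohorts
#'
#' Simulates replicate healthy cohorts (default n = 548) at the mean-
#' thickness level from the default layer effect models, fits the
#' three-layer demographic regressions, and runs the backward elimination.
#' Reports (i) the fraction of fitted coefficients within `2 SE` of the
#' generating truth and (ii) the rate at which the elimination reproduces
#' the expected retain/drop pattern: final covariates {age, se} for GCIPL
#' and INL, {age, se, sex} for ORC.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n cohort size.
#' @param seed master seed.
#' @param models named list of [layer_effect_model]s.
#' @return List with `coverage` (pooled fraction), `coverage_by_layer`,
#'   `pattern_rate` (fraction of replicates reproducing the pattern in all
#'   three layers), `pattern_rate_by_layer`, and `estimates` (long
#'   data.frame of all fitted coefficients).
#' @export
run_normative_recovery_experiment <- function(n_replicates = 50, n = 548,
                                              seed = 1,
                                              models = default_layer_models()) {
  layers <- names(models)
  expected <- list(GCIPL = c("age", "se"), INL = c("age", "se"),
                   ORC = c("age", "se", "sex"))
  rows <- list()
  pattern <- matrix(NA, n_replicates, length(layers),
                    dimnames = list(NULL, layers))
  for (r in seq_len(n_replicates)) {
    spec <- healthy_demographics_spec(n, seed = derive_seed(seed, r, 0L))
    demo <- sample_demographics(spec)
    withr::local_seed(derive_seed(seed, r, 1L))
    for (ly in layers) {
      m <- models[[ly]]
      base <- layer_baseline_mean(m)
      mu <- base + m$age_slope * (demo$age - m$ref_age) + m$se_slope * demo$se +
        m$sex_offset * (demo$sex == "M")
      y <- mu + base * stats::rnorm(n, 0, m$profile_scale_sd) +
        stats::rnorm(n, 0, m$between_subject_sd)
      fit <- fit_normative_model(y, demo, layer = ly)
      rep_ <- backward_stepwise_elimination(fit)
      truth <- c(age = m$age_slope, se = m$se_slope, sex = m$sex_offset)
      tm <- fit$terms
      tm$truth <- truth[tm$covariate]
      tm$covered <- abs(tm$estimate - tm$truth) <= 2 * tm$se
      tm$layer <- ly
      tm$replicate <- r
      rows[[length(rows) + 1L]] <- tm
      pattern[r, ly] <- setequal(required_matching_covariates(rep_),
                                 expected[[ly]])
    }
  }
  est <- do.call(rbind, rows)
  list(coverage = mean(est$covered),
       coverage_by_layer = tapply(est$covered, est$layer, mean),
       pattern_rate = mean(rowSums(pattern) == length(layers)),
       pattern_rate_by_layer = colMeans(pattern),
       estimates = est)
}

# Tight demographic window so every healthy participant matches every
# glaucoma participant (age within +-7.5 y, SE within +-2 D by design) and
# the per-layer normative mean is shared; tilt 0 keeps the experiment
# focused on the deviation/clustering stages.
recovery_demo_spec <- function(n, seed) {
  demographics_spec(n = n, age_range = c(60, 65), sex_ratio = 0.5,
                    se_range = c(-1, 1), se_mean = 0, se_age_slope = 0,
                    se_sex_offset = 0, se_sd = 0.5,
                    tilt_mean = 0, tilt_sd = 0, seed = seed)
}

#' One planted-defect recovery replicate
#'
#' Simulates a glaucoma subcohort with a common superior-VF (inferior
#' retina) arcuate defect plus a matched healthy pool, runs the full
#' deviation/clustering/agreement pipeline for all three layers, and
#' summarises recovery: visual-field typing, Dice overlap of the
#' most-negative GCIPL cluster with the planted mask, and the GCIPL-INL /
#' GCIPL-ORC kappa values.
#'
#' @param n_glaucoma,n_healthy subcohort sizes.
#' @param defect the planted [defect_spec].
#' @param noise_sd map noise SD (um).
#' @param seed integer seed.
#' @param k_max,criterion clustering settings.
#' @return One-row data.frame: `all_S`, `dice`, `kappa_gcipl_inl`,
#'   `kappa_gcipl_orc`, `kappa_inl_orc`, `k_gcipl`.
#' @export
run_defect_recovery_replicate <- function(n_glaucoma = 20, n_healthy = 15,
                                          defect = defect_spec(
                                            hemifields = "inferior_retina",
                                            gcipl_depth = 10, inl_ratio = 0.3,
                                            orc_delta = 0, vf_depth = 8),
                                          noise_sd = 2, seed = 1,
                                          k_max = 10, criterion = 1) {
  models <- default_layer_models(noise_sd = noise_sd)
  healthy <- simulate_cohort(recovery_demo_spec(n_healthy, derive_seed(seed, 1L, 100L)),
                             models = models)
  glaucoma <- simulate_cohort(recovery_demo_spec(n_glaucoma, derive_seed(seed, 2L, 200L)),
                              models = models, defect_fn = defect,
                              vf = TRUE, vf_noise_sd = 0)
  glaucoma <- lapply(glaucoma, function(g) { g$id <- paste0("G", g$id); g })
  std <- function(p) { p$maps_std <- lapply(p$maps, standardise_map); p }
  healthy <- lapply(healthy, std)
  glaucoma <- lapply(glaucoma, std)
  types <- vapply(glaucoma, function(g) classify_vf(g$vf)$defect_type, "")
  grids <- cohort_deviation_grids(glaucoma, healthy)
  layers <- c("GCIPL", "INL", "ORC")
  sols <- stats::setNames(lapply(layers, function(ly)
    cluster_deviation_grids(lapply(grids, `[[`, ly), k_max = k_max,
                            criterion = criterion)), layers)
  planted <- defect_grid_mask(defect)
  g_sol <- sols$GCIPL
  worst <- g_sol$clusters$label[which.min(g_sol$clusters$mean)]
  dice <- dice_coefficient(g_sol$label_map == worst, planted)
  ag <- layer_agreement_table(sols)
  kap <- stats::setNames(ag$kappa, ag$layer_pair)
  any_def <- vapply(sols, function(s) any(classify_defective_clusters(s)),
                    logical(1))
  data.frame(all_S = all(types == "S"), dice = dice,
             kappa_gcipl_inl = kap[["GCIPL-INL"]],
             kappa_gcipl_orc = kap[["GCIPL-ORC"]],
             kappa_inl_orc = kap[["INL-ORC"]],
             k_gcipl = g_sol$k,
             gcipl_defective = any_def[["GCIPL"]],
             inl_defective = any_def[["INL"]],
             orc_defective = any_def[["ORC"]])
}

#' Replicated planted-defect recovery experiment
#'
#' @param n_replicates number of independent replicates.
#' @param seed master seed.
#' @param ... passed to [run_defect_recovery_replicate()].
#' @return data.frame with one row per replicate.
#' @export
run_defect_recovery_experiment <- function(n_replicates = 50, seed = 1, ...) {
  do.call(rbind, lapply(seq_len(n_replicates), function(r)
    run_defect_recovery_replicate(seed = derive_seed(seed, r, 0L), ...)))
}

#' Severity-gradient experiment
#'
#' Simulates a glaucoma cohort whose planted defect depth grows linearly
#' across participants, with visual-field defect depth increasing linearly
#' in structural depth (`vf_depth = vf_depth_base + vf_depth_per_um *
#' depth`), runs the deviation pipeline, clusters each stratum's GCIPL map,
#' and returns the per-participant severity table and the global Spearman
#' correlations against MD and PSD. The default VF mapping keeps the whole
#' cohort inside a single defect-type/MD stratum so that every participant
#' shares one defective-GCIPL mask: with a common mask, a layer that does
#' not change with severity (the ORC) has a within/outside difference that
#' is pure noise with respect to MD, which is the property the experiment
#' probes.
#'
#' @param n_glaucoma,n_healthy cohort sizes.
#' @param depth_range GCIPL defect depth range (um) across the cohort.
#' @param inl_ratio INL attenuation fraction.
#' @param vf_depth_base baseline VF defect depth (dB); deep enough that the
#'   mildest eye still meets the cluster-defect criterion.
#' @param vf_depth_per_um additional dB of VF defect depth per um of GCIPL
#'   depth.
#' @param noise_sd map noise SD (um).
#' @param vf_noise_sd VF noise SD (dB).
#' @param seed master seed.
#' @return List with `table` ([participant_severity_table()] output) and
#'   `correlations` ([global_severity_correlations()] output).
#' @export
run_severity_experiment <- function(n_glaucoma = 60, n_healthy = 30,
                                    depth_range = c(2, 16), inl_ratio = 0.3,
                                    vf_depth_base = 6.6, vf_depth_per_um = 0.15,
                                    noise_sd = 2,
                                    vf_noise_sd = 0.3, seed = 1) {
  models <- default_layer_models(noise_sd = noise_sd)
  healthy <- simulate_cohort(recovery_demo_spec(n_healthy, derive_seed(seed, 1L, 100L)),
                             models = models)
  defect_fn <- function(rec, i) {
    depth <- depth_range[1] + (i - 1) / max(1, n_glaucoma - 1) *
      diff(depth_range)
    defect_spec(hemifields = "inferior_retina", gcipl_depth = depth,
                inl_ratio = inl_ratio, orc_delta = 0,
                vf_depth = vf_depth_base + vf_depth_per_um * depth)
  }
  glaucoma <- simulate_cohort(recovery_demo_spec(n_glaucoma, derive_seed(seed, 2L, 200L)),
                              models = models, defect_fn = defect_fn,
                              vf = TRUE, vf_noise_sd = vf_noise_sd)
  glaucoma <- lapply(glaucoma, function(g) { g$id <- paste0("G", g$id); g })
  std <- function(p) { p$maps_std <- lapply(p$maps, standardise_map); p }
  healthy <- lapply(healthy, std)
  glaucoma <- lapply(glaucoma, std)
  strata_tab <- do.call(rbind, lapply(glaucoma, function(g) {
    cl <- classify_vf(g$vf)
    data.frame(id = g$id, stratum = cl$stratum)
  }))
  grids <- cohort_deviation_grids(glaucoma, healthy)
  strata <- stats::setNames(strata_tab$stratum, strata_tab$id)
  solutions <- lapply(split(strata_tab$id, strata_tab$stratum), function(ids) {
    gg <- Filter(Negate(is.null), lapply(ids, function(id) grids[[id]]$GCIPL))
    if (length(gg) < 2) return(NULL)
    list(GCIPL = cluster_deviation_grids(gg))
  })
  vfs <- stats::setNames(lapply(glaucoma, `[[`, "vf"),
                         vapply(glaucoma, `[[`, "", "id"))
  tab <- participant_severity_table(grids, strata, solutions, vfs)
  list(table = tab, correlations = global_severity_correlations(tab))
}
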