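#' Demographics specification for a synthetic cohort
#'
#' Describes the marginal and joint distribution of age, sex, spherical
#' equivalent (SE), eye and disc-to-fovea tilt for a simulated cohort. Ages
#' are drawn from a normal distribution truncated to `age_range` when
#' `age_mean`/`age_sd` are supplied, otherwise uniformly on `age_range`.
#' SE is generated with a linear age trend (age-related hyperopic shift) and
#' a male offset, then truncated to `se_range`; this demographic covariance
#' is what makes backward-elimination behaviour realistic.
#'
#' @param n cohort size (>= 1).
#' @param age_range years, `c(min, max)`.
#' @param sex_ratio fraction male, in [0, 1].
#' @param se_range dioptres, `c(min, max)`.
#' @param tilt_sd SD of disc-to-fovea tilt (degrees).
#' @param seed integer seed.
#' @param age_mean,age_sd optional truncated-normal age parameters.
#' @param se_mean mean SE (D) at the cohort mean age.
#' @param se_age_slope D per year of age.
#' @param se_sex_offset D, male minus female.
#' @param se_sd residual SD of SE (D).
#' @param tilt_mean mean tilt (degrees).
#' @return An object of class `demographics_spec`.
#' @export
demographics_spec <- function(n, age_range = c(20, 86), sex_ratio = 0.453,
                              se_range = c(-6, 6), tilt_sd = 3.36, seed = 1,
                              age_mean = NULL, age_sd = NULL,
                              se_mean = -0.55, se_age_slope = 0.0458,
                              se_sex_offset = -0.55, se_sd = 1.77,
                              tilt_mean = 6.87) {
  stopifnot(n >= 1, length(age_range) == 2, diff(age_range) >= 0,
            length(se_range) == 2, diff(se_range) >= 0,
            sex_ratio >= 0, sex_ratio <= 1, tilt_sd >= 0, se_sd >= 0)
  structure(list(n = as.integer(n), age_range = age_range,
                 sex_ratio = sex_ratio, se_range = se_range,
                 tilt_sd = tilt_sd, seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, se_mean = se_mean,
                 se_age_slope = se_age_slope, se_sex_offset = se_sex_offset,
                 se_sd = se_sd, tilt_mean = tilt_mean),
            class = "demographics_spec")
}

#' Demographics matching the healthy reference cohort
#'
#' Age 50.36 +/- 16.90 y truncated to 20-86 y, 45.3% male,
#' SE -0.55 +/- 1.94 D, tilt 6.87 +/- 3.36 degrees.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param ... overrides passed to [demographics_spec()].
#' @export
healthy_demographics_spec <- function(n = 548, seed = 1, ...) {
  demographics_spec(n = n, seed = seed, age_mean = 50.36, age_sd = 16.90,
                    age_range = c(20, 86), sex_ratio = 0.453, ...)
}

#' Demographics matching the glaucoma cohort
#'
#' Age 64.44 +/- 11.46 y truncated to 27-88 y, 59.8% male,
#' SE -0.73 +/- 2.10 D, tilt 6.90 +/- 3.60 degrees.
#'
#' @inheritParams healthy_demographics_spec
#' @export
glaucoma_demographics_spec <- function(n = 271, seed = 1, ...) {
  demographics_spec(n = n, seed = seed, age_mean = 64.44, age_sd = 11.46,
                    age_range = c(27, 88), sex_ratio = 0.598,
                    se_mean = -0.73, tilt_mean = 6.90, tilt_sd = 3.60, ...)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0 || lo == hi) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample cohort demographics
#'
#' Deterministic for a fixed spec (including its seed). Maps are left empty;
#' see [synth_thickness_map()] and [synth_vf()].
#'
#' @param spec a [demographics_spec].
#' @return A data.frame with columns `id`, `age`, `sex` ("M"/"F"), `se`,
#'   `eye` ("OD"/"OS"), `tilt`.
#' @export
sample_demographics <- function(spec) {
  stopifnot(inherits(spec, "demographics_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n
  age <- if (!is.null(spec$age_mean) && !is.null(spec$age_sd)) {
    rnorm_trunc(n, spec$age_mean, spec$age_sd, spec$age_range[1], spec$age_range[2])
  } else {
    stats::runif(n, spec$age_range[1], spec$age_range[2])
  }
  male <- stats::runif(n) < spec$sex_ratio
  mean_age <- if (!is.null(spec$age_mean)) spec$age_mean else mean(spec$age_range)
  se <- spec$se_mean + spec$se_age_slope * (age - mean_age) +
    spec$se_sex_offset * (male - spec$sex_ratio) +
    stats::rnorm(n, 0, spec$se_sd)
  se <- pmin(pmax(se, spec$se_range[1]), spec$se_range[2])
  eye <- ifelse(stats::runif(n) < 0.5, "OD", "OS")
  tilt <- stats::rnorm(n, spec$tilt_mean, spec$tilt_sd)
  data.frame(id = sprintf("P%04d", seq_len(n)), age = age,
             sex = ifelse(male, "M", "F"), se = se, eye = eye, tilt = tilt,
             stringsAsFactors = FALSE)
}

#' Layer effect model for synthetic thickness maps
#'
#' Radial baseline profile plus linear demographic effects. The expected
#' thickness at a pixel with eccentricity `e` (mm from the fovea) is
#' `baseline(e) + age_slope*(age - ref_age) + se_slope*SE +
#' sex_offset*[male]`, to which a per-subject random intercept
#' (`between_subject_sd`), spatially correlated noise (`noise_sd`,
#' `spatial_correlation_length`) and any planted defect are added.
#'
#' @param layer `"GCIPL"`, `"INL"` or `"ORC"`.
#' @param baseline_profile data.frame with columns `ecc_mm` (ascending) and
#'   `thickness_um` (>= 0); linearly interpolated, constant beyond the last
#'   sample.
#' @param age_slope um per year.
#' @param se_slope um per dioptre.
#' @param sex_offset um, male minus female.
#' @param noise_sd SD of the spatially correlated map noise (um).
#' @param spatial_correlation_length Gaussian correlation length of the map
#'   noise (mm).
#' @param between_subject_sd SD of the per-subject thickness intercept (um).
#' @param profile_scale_sd SD of the per-subject multiplicative scaling of
#'   the radial baseline profile (dimensionless); models interindividual
#'   differences in profile shape, which give healthy deviation fields a
#'   smooth eccentricity-dependent structure.
#' @param ref_age reference age for the age effect (years).
#' @return An object of class `layer_effect_model`.
#' @export
layer_effect_model <- function(layer = c("GCIPL", "INL", "ORC"),
                               baseline_profile = NULL,
                               age_slope = 0, se_slope = 0, sex_offset = 0,
                               noise_sd = 0, spatial_correlation_length = 0.25,
                               between_subject_sd = 0, profile_scale_sd = 0,
                               ref_age = 50) {
  layer <- match.arg(layer)
  if (is.null(baseline_profile)) baseline_profile <- baseline_profiles()[[layer]]
  stopifnot(is.data.frame(baseline_profile),
            all(c("ecc_mm", "thickness_um") %in% names(baseline_profile)),
            all(diff(baseline_profile$ecc_mm) > 0),
            all(baseline_profile$thickness_um >= 0),
            noise_sd >= 0, between_subject_sd >= 0, profile_scale_sd >= 0,
            spatial_correlation_length > 0)
  structure(list(layer = layer, baseline_profile = baseline_profile,
                 age_slope = age_slope, se_slope = se_slope,
                 sex_offset = sex_offset, noise_sd = noise_sd,
                 spatial_correlation_length = spatial_correlation_length,
                 between_subject_sd = between_subject_sd,
                 profile_scale_sd = profile_scale_sd, ref_age = ref_age),
            class = "layer_effect_model")
}

#' Piecewise-linear radial thickness templates
#'
#' Editable baseline profiles per layer (foveal pit, perifoveal peak,
#' peripheral decline), in um versus eccentricity in mm.
#'
#' @return Named list of data.frames (`GCIPL`, `INL`, `ORC`).
#' @export
baseline_profiles <- function() {
  list(
    GCIPL = data.frame(ecc_mm = c(0, 0.4, 0.9, 1.5, 2.5, 3.5, 4.5),
                       thickness_um = c(20, 55, 95, 85, 60, 45, 38)),
    INL = data.frame(ecc_mm = c(0, 0.5, 1.2, 2.0, 3.0, 4.5),
                     thickness_um = c(10, 25, 41, 37, 33, 30)),
    ORC = data.frame(ecc_mm = c(0, 0.8, 1.5, 2.5, 3.5, 4.5),
                     thickness_um = c(225, 200, 185, 172, 165, 160))
  )
}

#' Default layer effect models
#'
#' Demographic effect truth per layer: GCIPL age -0.112 um/y, SE 0.513 um/D,
#' sex 0; INL age -0.039, SE 0.258, sex 0; ORC age -0.078, SE 0.437, sex
#' -1.953 um. Between-subject variability is split into a profile-shape
#' scaling (3% of the radial baseline) and a flat intercept, with the
#' intercept SDs (3.83, 0.94, 2.57 um) chosen so the total SD of
#' scan-mean thickness (4.3, 1.4, 5.9 um) reproduces the reported
#' coefficient standard errors in an n = 548 cohort.
#'
#' @param noise_sd map noise SD in um (applied to all layers).
#' @param spatial_correlation_length noise correlation length (mm).
#' @param between_subject multiplier on the default between-subject SDs
#'   (set 0 for deterministic subject means).
#' @return Named list of [layer_effect_model]s.
#' @export
default_layer_models <- function(noise_sd = 2, spatial_correlation_length = 0.25,
                                 between_subject = 1) {
  list(
    GCIPL = layer_effect_model("GCIPL", age_slope = -0.112, se_slope = 0.513,
                               sex_offset = 0, noise_sd = noise_sd,
                               spatial_correlation_length = spatial_correlation_length,
                               between_subject_sd = 3.83 * between_subject,
                               profile_scale_sd = 0.03 * between_subject),
    INL = layer_effect_model("INL", age_slope = -0.039, se_slope = 0.258,
                             sex_offset = 0, noise_sd = noise_sd,
                             spatial_correlation_length = spatial_correlation_length,
                             between_subject_sd = 0.94 * between_subject,
                             profile_scale_sd = 0.03 * between_subject),
    ORC = layer_effect_model("ORC", age_slope = -0.078, se_slope = 0.437,
                             sex_offset = -1.953, noise_sd = noise_sd,
                             spatial_correlation_length = spatial_correlation_length,
                             between_subject_sd = 2.57 * between_subject,
                             profile_scale_sd = 0.03 * between_subject)
  )
}

#' Arcuate defect specification
#'
#' A hemifield-specific arcuate thinning of the GCIPL with an attenuated
#' colocalised INL deficit and an unchanged or slightly thickened ORC, plus
#' the corresponding visual-field defect depth. Hemifields are named in
#' retinal coordinates; a superior-retina defect projects to the inferior
#' visual field and vice versa.
#'
#' @param hemifields subset of `c("superior_retina", "inferior_retina")`.
#' @param inner_ecc_deg,outer_ecc_deg radial extent of the arc (degrees).
#' @param angular_extent_deg angular width of the arc, centred on the
#'   vertical meridian of each hemifield (degrees).
#' @param gcipl_depth GCIPL thinning inside the arc (um, >= 0).
#' @param inl_ratio fraction of `gcipl_depth` applied to the INL, in [0, 1].
#' @param orc_delta ORC thickening inside the arc (um, 0 or small positive).
#' @param vf_depth pattern-deviation depth of the projected VF defect (dB).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(hemifields = "superior_retina",
                        inner_ecc_deg = 1.5, outer_ecc_deg = 8,
                        angular_extent_deg = 160,
                        gcipl_depth = 10, inl_ratio = 0.3, orc_delta = 0,
                        vf_depth = 8) {
  stopifnot(all(hemifields %in% c("superior_retina", "inferior_retina")),
            length(hemifields) >= 1,
            gcipl_depth >= 0, inl_ratio >= 0, inl_ratio <= 1, orc_delta >= 0,
            inner_ecc_deg >= 0, outer_ecc_deg > inner_ecc_deg,
            angular_extent_deg > 0, vf_depth >= 0)
  structure(list(hemifields = hemifields, inner_ecc_deg = inner_ecc_deg,
                 outer_ecc_deg = outer_ecc_deg,
                 angular_extent_deg = angular_extent_deg,
                 gcipl_depth = gcipl_depth, inl_ratio = inl_ratio,
                 orc_delta = orc_delta, vf_depth = vf_depth),
            class = "defect_spec")
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Is a standard-frame retinal location (ecc in deg, angle in deg with 90 =
# superior retina) inside the arcuate mask?
arc_mask_std <- function(defect, ecc_deg, angle_deg) {
  inside <- ecc_deg >= defect$inner_ecc_deg & ecc_deg <= defect$outer_ecc_deg
  hit <- rep(FALSE, length(ecc_deg))
  for (h in defect$hemifields) {
    centre <- if (h == "superior_retina") 90 else -90
    hit <- hit | abs(ang_diff(angle_deg, centre)) <= defect$angular_extent_deg / 2
  }
  inside & hit
}

# Spatially correlated unit-variance Gaussian field via FFT-smoothed white
# noise (periodic boundary); sigma given per axis in pixels.
correlated_noise <- function(nr, nc, sigma_row, sigma_col) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_row <= 0 && sigma_col <= 0) return(w)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = max(sigma_row, 1e-6))
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = max(sigma_col, 1e-6))
  K <- outer(kr, kc)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / length(w)
  sm / sqrt(sum(K^2))
}

#' Synthesise a raw thickness map for one participant
#'
#' Generates a 512 (wide) x 128 (high) raw macular cube map in the eye's
#' native orientation: the radial baseline plus linear demographic effects,
#' a per-subject intercept, any planted arcuate defect (pre-rotated by the
#' recorded tilt and mirrored for left eyes, so that preprocessing restores
#' it to the standard position), and spatially correlated noise.
#'
#' @param record one row of [sample_demographics()] output (or a list with
#'   `age`, `sex`, `se`, `eye`, `tilt`).
#' @param model a [layer_effect_model].
#' @param defect a [defect_spec] or `NULL`.
#' @param seed integer seed (per participant x layer).
#' @param mm_per_deg retinal mm per degree (default 0.288).
#' @param dropout_prob probability that an A-scan column is flagged as a
#'   segmentation failure (invalid); default 0, all pixels valid.
#' @return A raw [thickness_map].
#' @export
synth_thickness_map <- function(record, model, defect = NULL, seed = 1,
                                mm_per_deg = 0.288, dropout_prob = 0) {
  stopifnot(inherits(model, "layer_effect_model"))
  withr::local_seed(seed)
  nr <- 128L; nc <- 512L
  fovea <- c((nc - 1) / 2, (nr - 1) / 2)
  px <- c(6 / nc, 6 / nr)
  dx <- matrix((seq_len(nc) - 1 - fovea[1]) * px[1], nr, nc, byrow = TRUE)
  dy <- matrix((fovea[2] - (seq_len(nr) - 1)) * px[2], nr, nc)
  ecc_mm <- sqrt(dx^2 + dy^2)
  base <- stats::approx(model$baseline_profile$ecc_mm,
                        model$baseline_profile$thickness_um,
                        xout = as.vector(ecc_mm), rule = 2)$y
  male <- record$sex == "M"
  gam <- if (model$profile_scale_sd > 0)
    stats::rnorm(1, 0, model$profile_scale_sd) else 0
  subj <- if (model$between_subject_sd > 0)
    stats::rnorm(1, 0, model$between_subject_sd) else 0
  vals <- matrix(base, nr, nc) * (1 + gam) +
    model$age_slope * (record$age - model$ref_age) +
    model$se_slope * record$se +
    model$sex_offset * as.numeric(male) + subj

  if (!is.null(defect)) {
    stopifnot(inherits(defect, "defect_spec"))
    # native-frame angle -> standard-frame angle (mirror for OS, then
    # subtract the post-mirror tilt), so preprocessing restores the arc
    theta_native <- atan2(dy, if (record$eye == "OS") -dx else dx) * 180 / pi
    tilt_after_mirror <- if (record$eye == "OS") -record$tilt else record$tilt
    theta_std <- theta_native - tilt_after_mirror
    mask <- arc_mask_std(defect, as.vector(ecc_mm) / mm_per_deg,
                         as.vector(theta_std))
    depth <- switch(model$layer,
                    GCIPL = defect$gcipl_depth,
                    INL = defect$gcipl_depth * defect$inl_ratio,
                    ORC = -defect$orc_delta)
    vals <- vals - depth * matrix(mask, nr, nc)
  }

  if (model$noise_sd > 0) {
    sig <- model$spatial_correlation_length
    vals <- vals + model$noise_sd *
      correlated_noise(nr, nc, sig / px[2], sig / px[1])
  }
  vals <- pmax(vals, 0)
  valid <- matrix(TRUE, nr, nc)
  if (dropout_prob > 0) {
    bad <- stats::runif(nc) < dropout_prob
    valid[, bad] <- FALSE
    vals[, bad] <- NA_real_
  }
  thickness_map(vals, valid = valid, fovea_xy = fovea,
                laterality = record$eye, tilt_deg = record$tilt,
                layer = model$layer, provenance = "synthetic")
}

#' Expected mean layer thickness for a participant
#'
#' The scan-area mean implied by a [layer_effect_model] (baseline mean plus
#' linear effects), with the per-subject intercept drawn from
#' `between_subject_sd`. Used for cohort-level simulations where full maps
#' are not needed (e.g. regression recovery experiments).
#'
#' @inheritParams synth_thickness_map
#' @return Mean thickness in um.
#' @export
synth_mean_thickness <- function(record, model, seed = 1) {
  stopifnot(inherits(model, "layer_effect_model"))
  withr::local_seed(seed)
  nr <- 128L; nc <- 512L
  fovea <- c((nc - 1) / 2, (nr - 1) / 2)
  px <- c(6 / nc, 6 / nr)
  dx <- matrix((seq_len(nc) - 1 - fovea[1]) * px[1], nr, nc, byrow = TRUE)
  dy <- matrix((fovea[2] - (seq_len(nr) - 1)) * px[2], nr, nc)
  base_mean <- mean(stats::approx(model$baseline_profile$ecc_mm,
                                  model$baseline_profile$thickness_um,
                                  xout = sqrt(dx^2 + dy^2), rule = 2)$y)
  gam <- if (model$profile_scale_sd > 0)
    stats::rnorm(1, 0, model$profile_scale_sd) else 0
  subj <- if (model$between_subject_sd > 0)
    stats::rnorm(1, 0, model$between_subject_sd) else 0
  base_mean * (1 + gam) + model$age_slope * (record$age - model$ref_age) +
    model$se_slope * record$se +
    model$sex_offset * as.numeric(record$sex == "M") + subj
}

#' Scan-area mean of a model's baseline profile
#'
#' @param model a [layer_effect_model].
#' @return Mean baseline thickness over the raw scan grid (um).
#' @export
layer_baseline_mean <- function(model) {
  nr <- 128L; nc <- 512L
  f <- c((nc - 1) / 2, (nr - 1) / 2)
  px <- c(6 / nc, 6 / nr)
  dx <- matrix((seq_len(nc) - 1 - f[1]) * px[1], nr, nc, byrow = TRUE)
  dy <- matrix((f[2] - (seq_len(nr) - 1)) * px[2], nr, nc)
  mean(stats::approx(model$baseline_profile$ecc_mm,
                     model$baseline_profile$thickness_um,
                     xout = sqrt(dx^2 + dy^2), rule = 2)$y)
}

#' Synthesise a 10-2 visual field result
#'
#' Pattern deviation is `-vf_depth` inside the visual-field projection of
#' the planted defect plus optional Gaussian noise; total deviation equals
#' pattern deviation (no generalised depression is modelled). MD is the mean
#' of the total deviations and PSD the standard deviation of the pattern
#' deviations (simplified, unweighted analogues of the perimeter's indices).
#' Probability flags are assigned by fixed dB thresholds.
#'
#' @param defect a [defect_spec] or `NULL`.
#' @param noise_sd measurement noise SD (dB).
#' @param seed integer seed.
#' @param thresholds named vector of dB cutoffs for flags `p5`, `p2`, `p1`,
#'   `p05` (a point gets the most severe flag whose cutoff its pattern
#'   deviation does not exceed).
#' @return A [vf_result].
#' @export
synth_vf <- function(defect = NULL, noise_sd = 0, seed = 1,
                     thresholds = c(p5 = -3, p2 = -5, p1 = -6.5, p05 = -8)) {
  stopifnot(noise_sd >= 0)
  withr::local_seed(seed)
  lat <- vf_lattice_10_2()
  pd <- rep(0, nrow(lat))
  if (!is.null(defect)) {
    stopifnot(inherits(defect, "defect_spec"))
    # VF (x, y) projects to the retinal location (x, -y): vertical flip
    ecc <- sqrt(lat$x^2 + lat$y^2)
    theta_ret <- atan2(-lat$y, lat$x) * 180 / pi
    inside <- arc_mask_std(defect, ecc, theta_ret)
    pd[inside] <- -defect$vf_depth
  }
  if (noise_sd > 0) pd <- pd + stats::rnorm(length(pd), 0, noise_sd)
  prob <- rep("none", length(pd))
  for (fl in c("p5", "p2", "p1", "p05")) prob[pd <= thresholds[[fl]]] <- fl
  vf_result(data.frame(x = lat$x, y = lat$y, td = pd, pd = pd, prob = prob,
                       stringsAsFactors = FALSE))
}

#' Simulate a full cohort of participants
#'
#' Draws demographics, synthesises raw thickness maps for all three layers
#' and (optionally) a 10-2 visual field per participant. Per-participant
#' seeds are derived deterministically from the spec seed.
#'
#' @param spec a [demographics_spec].
#' @param models named list of [layer_effect_model]s (see
#'   [default_layer_models()]).
#' @param defect_fn `NULL` (healthy), a single [defect_spec] applied to all
#'   participants, or `function(record, i)` returning a [defect_spec] or
#'   `NULL` per participant.
#' @param vf logical; synthesise visual fields?
#' @param vf_noise_sd VF measurement noise SD (dB).
#' @param dropout_prob per-column segmentation failure probability.
#' @return List of participant records, each a list with `id`, demographic
#'   fields, `defect`, `maps` (named list of raw [thickness_map]s) and `vf`.
#' @export
simulate_cohort <- function(spec, models = default_layer_models(),
                            defect_fn = NULL, vf = FALSE, vf_noise_sd = 0,
                            dropout_prob = 0) {
  demo <- sample_demographics(spec)
  lapply(seq_len(nrow(demo)), function(i) {
    rec <- as.list(demo[i, ])
    defect <- if (is.null(defect_fn)) NULL
      else if (inherits(defect_fn, "defect_spec")) defect_fn
      else defect_fn(rec, i)
    rec$defect <- defect
    rec$maps <- lapply(models, function(m)
      synth_thickness_map(rec, m, defect = defect,
                          seed = derive_seed(spec$seed, i,
                                             match(m$layer, c("GCIPL", "INL", "ORC"))),
                          dropout_prob = dropout_prob))
    names(rec$maps) <- vapply(models, `[[`, "", "layer")
    if (vf) rec$vf <- synth_vf(defect, noise_sd = vf_noise_sd,
                               seed = derive_seed(spec$seed, i, 5L))
    rec
  })
}

# deterministic per-participant seed stream, kept inside 32-bit range
derive_seed <- function(base, i, k) {
  as.integer((as.numeric(base) * 1009 + i * 7 + k) %% 2147483629)
}
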