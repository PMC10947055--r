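#' Write / read a thickness map as delimited text
#'
#' Values are tab-delimited with `NA` at invalid pixels; metadata travels in
#' a JSON sidecar (`<path>.json`).
#'
#' @param map a [thickness_map].
#' @param path output file (values matrix).
#' @export
write_thickness_map <- function(map, path) {
  utils::write.table(map$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- map[c("fovea_xy", "laterality", "tilt_deg", "layer", "extent_mm",
                "provenance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  thickness_map(v, valid = !is.na(v), fovea_xy = meta$fovea_xy,
                laterality = meta$laterality, tilt_deg = meta$tilt_deg,
                layer = meta$layer, provenance = meta$provenance)
}

#' Read scan metadata from a minimal Cirrus-style XML stub
#'
#' Expects elements `<fovea_x>`, `<fovea_y>` (0-based pixel coordinates),
#' `<laterality>` (OD/OS) and `<tilt_deg>` under the document root.
#'
#' @param path XML file.
#' @return List with `fovea_xy`, `laterality`, `tilt_deg`.
#' @export
read_scan_metadata <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(doc, paste0(".//", tag))))
  list(fovea_xy = c(num("fovea_x"), num("fovea_y")),
       laterality = xml2::xml_text(xml2::xml_find_first(doc, ".//laterality")),
       tilt_deg = num("tilt_deg"))
}

#' Default pipeline configuration
#'
#' A small, self-contained demonstration cohort: healthy pool plus a
#' glaucoma cohort with severity-graded arcuate defects.
#'
#' @param seed master seed for every stage.
#' @return Configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_healthy = 24,
    n_glaucoma = 16,
    map_noise_sd = 2,
    vf_noise_sd = 0.5,
    defect = list(depth_range = c(8, 16), inl_ratio = 0.3, orc_delta = 0,
                  vf_depth_base = 6.6, vf_depth_per_um = 0.12),
    match = list(age_window = 7.5, se_window = 2.0, min_subgroup = 3),
    clustering = list(k_max = 10, criterion = 1, feature = "mean"),
    displacement_profile = system.file("extdata",
                                       "displacement_profile_synthetic.csv",
                                       package = "maculadev")
  )
}

severity_graded_defect_fn <- function(cfg) {
  dr <- cfg$defect$depth_range
  function(rec, i) {
    u <- (i - 1) / max(1, cfg$n_glaucoma - 1)
    depth <- dr[1] + u * (dr[2] - dr[1])
    hemi <- if (i %% 2 == 0) "superior_retina" else "inferior_retina"
    defect_spec(hemifields = hemi, gcipl_depth = depth,
                inl_ratio = cfg$defect$inl_ratio,
                orc_delta = cfg$defect$orc_delta,
                vf_depth = cfg$defect$vf_depth_base +
                  cfg$defect$vf_depth_per_um * depth)
  }
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order: simulate, preprocess (standardise maps),
#' classify visual fields, fit the normative demographic models and derive
#' the per-layer matching covariates, build deviation grids, cluster each
#' (defect type x MD bin) stratum per layer, compute the between-layer
#' agreement table and the severity correlations. All tabular outputs and a
#' JSON provenance record are written under `out_dir`. Rerunning with the
#' same configuration reproduces all numeric outputs exactly.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file with the same fields.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(cfg$displacement_profile) && nzchar(cfg$displacement_profile) &&
      !file.exists(cfg$displacement_profile))
    stop("displacement profile not found: ", cfg$displacement_profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tables", "grids", "logs")) dir.create(file.path(out_dir, d),
                                                     showWarnings = FALSE)
  log_path <- file.path(out_dir, "logs", "pipeline.log")
  stamp <- list()
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste0(..., collapse = ""))
    cat(msg, "\n", file = log_path, append = TRUE)
    stamp[[stage]] <<- format(Sys.time())
  }

  profile <- if (!is.null(cfg$displacement_profile) && nzchar(cfg$displacement_profile))
    read_displacement_profile(cfg$displacement_profile) else NULL

  say("simulate", sprintf("healthy n=%d glaucoma n=%d", cfg$n_healthy, cfg$n_glaucoma))
  models <- default_layer_models(noise_sd = cfg$map_noise_sd)
  healthy <- simulate_cohort(healthy_demographics_spec(cfg$n_healthy, seed = cfg$seed),
                             models = models)
  glc_spec <- glaucoma_demographics_spec(cfg$n_glaucoma, seed = cfg$seed + 1)
  glaucoma <- simulate_cohort(glc_spec, models = models,
                              defect_fn = severity_graded_defect_fn(cfg),
                              vf = TRUE, vf_noise_sd = cfg$vf_noise_sd)
  glaucoma <- lapply(glaucoma, function(g) { g$id <- paste0("G", g$id); g })
  cohort_df <- function(x) do.call(rbind, lapply(x, function(p)
    data.frame(id = p$id, age = p$age, sex = p$sex, se = p$se, eye = p$eye,
               tilt = p$tilt)))
  utils::write.csv(cohort_df(healthy), file.path(out_dir, "tables", "healthy.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_df(glaucoma), file.path(out_dir, "tables", "glaucoma.csv"),
                   row.names = FALSE)

  say("preprocess")
  std <- function(p) { p$maps_std <- lapply(p$maps, standardise_map, profile = profile); p }
  healthy <- lapply(healthy, std)
  glaucoma <- lapply(glaucoma, std)

  say("classify-vf")
  strata_tab <- do.call(rbind, lapply(glaucoma, function(g) {
    cl <- classify_vf(g$vf)
    data.frame(id = g$id, defect_type = cl$defect_type, md_bin = cl$md_bin,
               stratum = cl$stratum, MD = g$vf$md, PSD = g$vf$psd,
               n_clusters = length(cl$clusters))
  }))
  utils::write.csv(strata_tab, file.path(out_dir, "tables", "strata.csv"),
                   row.names = FALSE)

  say("fit-normative")
  layers <- c("GCIPL", "INL", "ORC")
  hl_cov <- cohort_df(healthy)
  norm_fits <- lapply(layers, function(ly) {
    means <- vapply(healthy, function(h) mean_layer_thickness(h$maps_std[[ly]]),
                    numeric(1))
    fit <- fit_normative_model(means, hl_cov, layer = ly)
    rep <- backward_stepwise_elimination(fit)
    list(fit = fit, report = rep,
         matching = required_matching_covariates(rep))
  })
  names(norm_fits) <- layers
  match_specs <- lapply(norm_fits, function(nf)
    match_spec(age_window = cfg$match$age_window, se_window = cfg$match$se_window,
               match_sex = "sex" %in% nf$matching,
               min_subgroup = cfg$match$min_subgroup))
  norm_tab <- do.call(rbind, lapply(layers, function(ly) {
    tm <- norm_fits[[ly]]$fit$terms
    tm$layer <- ly
    tm
  }))
  utils::write.csv(norm_tab, file.path(out_dir, "tables", "normative_models.csv"),
                   row.names = FALSE)

  say("deviations")
  grids <- cohort_deviation_grids(glaucoma, healthy, layers = layers,
                                  match_specs = match_specs)

  say("cluster")
  strata <- stats::setNames(strata_tab$stratum, strata_tab$id)
  solutions <- lapply(split(strata_tab$id, strata_tab$stratum), function(ids) {
    stats::setNames(lapply(layers, function(ly) {
      gg <- Filter(Negate(is.null), lapply(ids, function(id) grids[[id]][[ly]]))
      if (length(gg) == 0) return(NULL)
      cluster_deviation_grids(gg, k_max = cfg$clustering$k_max,
                              criterion = cfg$clustering$criterion,
                              feature = cfg$clustering$feature)
    }), layers)
  })
  cl_tab <- do.call(rbind, lapply(names(solutions), function(st)
    do.call(rbind, lapply(layers, function(ly) {
      s <- solutions[[st]][[ly]]
      if (is.null(s)) return(NULL)
      cbind(stratum = st, layer = ly, s$clusters)
    }))))
  utils::write.csv(cl_tab, file.path(out_dir, "tables", "clusters.csv"),
                   row.names = FALSE)
  for (st in names(solutions)) for (ly in layers) {
    s <- solutions[[st]][[ly]]
    if (!is.null(s))
      utils::write.table(s$label_map,
                         file.path(out_dir, "grids",
                                   sprintf("labels_%s_%s.tsv", st, ly)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
  }

  say("agreement")
  agree_tab <- do.call(rbind, lapply(names(solutions), function(st) {
    sols <- Filter(Negate(is.null), solutions[[st]])
    if (length(sols) < 2) return(NULL)
    cbind(stratum = st, layer_agreement_table(sols))
  }))
  utils::write.csv(agree_tab, file.path(out_dir, "tables", "agreement.csv"),
                   row.names = FALSE)

  say("severity")
  vfs <- stats::setNames(lapply(glaucoma, `[[`, "vf"),
                         vapply(glaucoma, `[[`, "", "id"))
  sev_tab <- participant_severity_table(grids, strata, solutions, vfs)
  utils::write.csv(sev_tab, file.path(out_dir, "tables", "severity.csv"),
                   row.names = FALSE)
  sev_cor <- global_severity_correlations(sev_tab)
  utils::write.csv(sev_cor, file.path(out_dir, "tables", "severity_correlations.csv"),
                   row.names = FALSE)

  say("provenance")
  jsonlite::write_json(
    list(config = cfg, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("maculadev")),
         r_version = R.version.string, stages = stamp,
         outputs = list.files(out_dir, recursive = TRUE)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  invisible(list(config = cfg, healthy = healthy, glaucoma = glaucoma,
                 strata = strata_tab, normative = norm_fits, grids = grids,
                 solutions = solutions, agreement = agree_tab,
                 severity = sev_tab, severity_correlations = sev_cor,
                 out_dir = out_dir))
}
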