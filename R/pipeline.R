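#' Default end-to-end run configuration
#'
#' A complete synthetic run on a small isotropic template: three crossing
#' fiber bundles, a set of jittered controls, a two-visit multicenter
#' cohort with the default planted effects, disconnectome maps thresholded
#' at >50%, the longitudinal mixed models, and a voxel-wise TFCE
#' permutation analysis.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed (mandatory; every stage derives its own
#'   stream from it).
#' @param n_subjects,n_controls,n_perm,grid_size Problem-size knobs.
#' @return A nested `run_config` list, serialisable to YAML/JSON.
#' @export
default_run_config <- function(out_dir, seed, n_subjects = 30L,
                               n_controls = 10L, n_perm = 500L,
                               grid_size = 32L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    grid = list(shape = rep(as.integer(grid_size), 3L), voxel_size = 1),
    controls = list(n_controls = as.integer(n_controls), jitter = 0.75,
                    bundles = "default"),
    cohort = list(n_subjects = as.integer(n_subjects), n_centers = 4L,
                  timepoints = 2L, beta_nfl_gd = 0.03, beta_time = -0.04,
                  beta_interaction = -0.01,
                  center_shifts = c(0, -0.29, -0.41, 0.44),
                  subject_sd = 0.92, center_sd = 0, noise_sd = 0.05,
                  outlier_rate = 0),
    disconnectome = list(cutoff = 0.5),
    models = list(center = "fixed", robust = TRUE),
    voxelwise = list(n_perm = as.integer(n_perm),
                     tfce = list(H = 2, E = 0.5, dh = 0.1,
                                 connectivity = 26L),
                     alpha = 0.05))
}

#' Read and validate a run configuration
#'
#' @param config A list, or a path to a YAML/JSON file mapping 1:1 to the
#'   [default_run_config()] structure. `seed` and `out_dir` are mandatory
#'   and checked before any computation.
#' @return Validated `run_config` list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    stop("config schema violation: integer `seed` is mandatory")
  if (is.null(config$out_dir))
    stop("config schema violation: `out_dir` is mandatory")
  defaults <- default_run_config(config$out_dir, config$seed)
  modifyList(defaults, config)
}

default_bundles <- function(grid) {
  b <- grid_world_bounds(grid)
  mid <- colMeans(b)
  lo <- b[1, ] + 0.12 * (b[2, ] - b[1, ])
  hi <- b[1, ] + 0.88 * (b[2, ] - b[1, ])
  list(
    bundle_spec(rbind(c(lo[1], mid[2], mid[3]), c(hi[1], mid[2], mid[3])),
                n_streamlines = 20L, radial_spread = 1.2, step = 0.5),
    bundle_spec(rbind(c(mid[1], lo[2], mid[3]), c(mid[1], hi[2], mid[3])),
                n_streamlines = 20L, radial_spread = 1.2, step = 0.5),
    bundle_spec(rbind(c(lo[1], lo[2], lo[3]), c(hi[1], hi[2], hi[3])),
                n_streamlines = 20L, radial_spread = 1.2, step = 0.5))
}

stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: phantom simulation (grid, controls, lesions,
#' cohort), per-subject disconnectome maps, GD/T2LV extraction, baseline
#' cohort statistics, longitudinal mixed models, and the voxel-wise TFCE
#' permutation analysis. Every stage writes its outputs under `out_dir`
#' and the run ends with a JSON manifest (config, seeds, stage timings,
#' output MD5 hashes, package/R versions). Re-running with an identical
#' config reproduces identical numerical outputs.
#'
#' @param config A validated config, or anything [read_run_config()]
#'   accepts.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  manifest <- list(config = cfg, stages = list(),
                   versions = list(R = R.version.string,
                                   disconnectome =
                                     as.character(utils::packageVersion(
                                       "disconnectome"))))
  t_stage <- function(name, expr) {
    stage_log(log_path, name, "start")
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    manifest$stages[[name]] <<- list(status = "complete",
                                     seconds = round(el, 2))
    stage_log(log_path, name, sprintf("complete (%.1fs)", el))
    val
  }

  # -- stage 1: simulate --------------------------------------------------
  sim <- t_stage("simulate", {
    grid <- template_grid(cfg$grid$shape, cfg$grid$voxel_size)
    bundles <- if (identical(cfg$controls$bundles, "default"))
      default_bundles(grid) else cfg$controls$bundles
    controls <- generate_controls(grid, bundles,
                                  n_controls = cfg$controls$n_controls,
                                  jitter = cfg$controls$jitter,
                                  seed = cfg$seed + 1L)
    ccfg <- do.call(cohort_sim_config,
                    c(cfg$cohort, list(seed = cfg$seed + 2L)))
    sim <- generate_cohort(ccfg, grid = grid, controls = controls)
    write_cohort(sim$cohort, file.path(out, "cohort.tsv"))
    lesion_dir <- file.path(out, "lesions")
    dir.create(lesion_dir, showWarnings = FALSE)
    for (key in names(sim$lesions))
      write_volume(sim$lesions[[key]], grid,
                   file.path(lesion_dir, paste0(key, ".nii.gz")),
                   datatype = "uint8")
    ctl_dir <- file.path(out, "controls")
    dir.create(ctl_dir, showWarnings = FALSE)
    for (i in seq_along(controls))
      write_tractogram(controls[[i]],
                       file.path(ctl_dir, sprintf("control%02d.tck", i)),
                       dialect = "tck")
    list(grid = grid, controls = controls, cohort = sim$cohort,
         lesions = sim$lesions)
  })

  # -- stage 2: disconnectome maps ---------------------------------------
  maps <- t_stage("disconnectome", {
    cv <- voxelize_controls(sim$controls, sim$grid)
    map_dir <- file.path(out, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    maps <- list()
    for (key in names(sim$lesions)) {
      m <- disconnectome_map(sim$lesions[[key]], sim$controls, sim$grid,
                             control_voxels = cv)
      m <- threshold_map(m, cutoff = cfg$disconnectome$cutoff)
      maps[[key]] <- m
      write_volume(m$prob, sim$grid,
                   file.path(map_dir, paste0(key, "_disco.nii.gz")))
    }
    maps
  })

  # -- stage 3: GD and lesion volumes ------------------------------------
  gd_tab <- t_stage("gd", {
    wm <- build_wm_mask(maps)
    write_volume(wm, sim$grid, file.path(out, "wm_mask.nii.gz"),
                 datatype = "uint8")
    keys <- paste0(sim$cohort$subject_id, "_", sim$cohort$timepoint)
    tab <- data.frame(
      subject_id = sim$cohort$subject_id,
      timepoint = sim$cohort$timepoint,
      gd = vapply(keys, function(k)
        global_disconnectome(maps[[k]], wm), numeric(1)),
      t2lv = vapply(keys, function(k)
        lesion_volume_ml(sim$lesions[[k]], sim$grid), numeric(1)),
      row.names = NULL)
    utils::write.table(tab, file.path(out, "gd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  # measured imaging phenotypes replace the generator's latent ones for
  # all downstream statistics
  records <- sim$cohort
  records$gd <- gd_tab$gd
  records$t2lv <- gd_tab$t2lv

  # -- stage 4: cohort statistics ----------------------------------------
  cohort_res <- t_stage("cohort_stats", {
    base <- records[records$timepoint == "baseline", ]
    outl <- remove_nfl_outliers(base$snfl)
    base_kept <- if (length(outl$removed)) base[-outl$removed, ] else base
    assoc <- gd_t2lv_association(base)
    cs_gd <- fit_cross_sectional(base_kept, "gd")
    cs_t2 <- fit_cross_sectional(base_kept, "t2lv")
    utils::write.table(cs_gd$table, file.path(out, "cross_sectional_gd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cs_t2$table,
                       file.path(out, "cross_sectional_t2lv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    wide <- stats::reshape(
      records[, c("subject_id", "timepoint", "edss")],
      idvar = "subject_id", timevar = "timepoint", direction = "wide")
    if (all(c("edss.baseline", "edss.followup") %in% names(wide))) {
      edss_tab <- data.frame(
        subject_id = wide$subject_id,
        change = classify_edss_change(wide$edss.baseline,
                                      wide$edss.followup))
      utils::write.table(edss_tab, file.path(out, "edss_change.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(assoc_r = assoc$r, outliers_removed = length(outl$removed))
  })

  # -- stage 5: longitudinal mixed models --------------------------------
  lmm_res <- t_stage("lmm", {
    fits <- list(gd = fit_lmm_interaction(records, "gd",
                                          center = cfg$models$center),
                 t2lv = fit_lmm_interaction(records, "t2lv",
                                            center = cfg$models$center))
    if (isTRUE(cfg$models$robust)) {
      fits$gd_robust <- fit_robust_lmm(records, "gd", interaction = TRUE,
                                       center = cfg$models$center)
      fits$t2lv_robust <- fit_robust_lmm(records, "t2lv",
                                         interaction = TRUE,
                                         center = cfg$models$center)
    }
    for (nm in names(fits))
      utils::write.table(fits[[nm]]$table,
                         file.path(out, paste0("lmm_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    fits
  })

  # -- stage 6: voxel-wise permutation analysis --------------------------
  t_stage("voxelwise", {
    base <- records[records$timepoint == "baseline", ]
    outl <- remove_nfl_outliers(base$snfl)
    if (length(outl$removed)) base <- base[-outl$removed, ]
    wm <- read_volume(file.path(out, "wm_mask.nii.gz"))$data
    keys <- paste0(base$subject_id, "_baseline")
    Y <- t(vapply(keys, function(k) maps[[k]]$prob[wm != 0],
                  numeric(sum(wm != 0))))
    des <- build_design(base)
    tc <- do.call(tfce_config, cfg$voxelwise$tfce)
    res <- permutation_fwer(Y, des$X, des$contrast, wm,
                            n_perm = cfg$voxelwise$n_perm, cfg = tc,
                            seed = cfg$seed + 3L,
                            alpha = cfg$voxelwise$alpha)
    grid <- sim$grid
    write_volume(unmask(res$t_map, wm), grid,
                 file.path(out, "voxelwise_t.nii.gz"))
    for (side in c("positive", "negative")) {
      write_volume(unmask(res$tfce_obs[[side]], wm), grid,
                   file.path(out, sprintf("voxelwise_tfce_%s.nii.gz", side)))
      write_volume(unmask(1 - res$fwer_p[[side]], wm), grid,
                   file.path(out, sprintf("voxelwise_1mp_%s.nii.gz", side)))
    }
    res
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, c("run.log", "manifest.json")))
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- substring(names(manifest$outputs),
                                       nchar(out) + 2L)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  stage_log(log_path, "pipeline", "complete")
  invisible(manifest)
}
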