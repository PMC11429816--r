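#' Configure an end-to-end motility analysis run
#'
#' Bundles every stage's parameters into one serializable document:
#' simulate (scene + one motion model per group), detect, track, describe,
#' compare. Defaults are desk-scale — a 256 x 256 px scene, 120 frames and
#' 30 cells per group — so a full run stays interactive; pass
#' `full_scale = TRUE` for the acquisition-scale geometry (72 h at 1
#' frame/min, i.e. 4320 frames).
#'
#' @param scene A [scene_config()].
#' @param model_ctrl,model_treated [motion_model()]s for the two groups.
#' @param n_cells Cells per group.
#' @param r_min_um,r_max_um Detection radius range (um).
#' @param detect A [detect_params()].
#' @param max_disp Linking gate in um; default `4 * r_max_um`.
#' @param min_duration Track filter threshold in min.
#' @param smoothing,sigma_loc,angle_convention,fit_lags Kinematics settings
#'   (see [smooth_track()], [turning_angle_signal()], [msd_profile()]).
#' @param seed Master seed.
#' @param start_from `"simulate"` (default), `"stacks"` or `"tracks"`: where
#'   the run begins; later stages then expect `stacks`/`tracks` inputs in
#'   [run_pipeline()].
#' @param full_scale Use the acquisition-scale scene.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL,
                            model_ctrl = motion_model("brownian",
                                                      diffusion_coefficient = 1),
                            model_treated = motion_model("brownian",
                                                         diffusion_coefficient = 1),
                            n_cells = 30L,
                            r_min_um = 5, r_max_um = 8,
                            detect = detect_params(),
                            max_disp = 4 * r_max_um,
                            min_duration = 50,
                            smoothing = "gcv", sigma_loc = 0.2,
                            angle_convention = "printed",
                            fit_lags = NULL,
                            seed = 1L,
                            start_from = c("simulate", "stacks", "tracks"),
                            full_scale = FALSE) {
  if (is.null(scene))
    scene <- if (full_scale) scene_config(n_frames = 4320L)
             else scene_config(n_frames = 120L)
  structure(list(scene = scene, model_ctrl = model_ctrl,
                 model_treated = model_treated, n_cells = as.integer(n_cells),
                 r_min_um = r_min_um, r_max_um = r_max_um, detect = detect,
                 max_disp = max_disp, min_duration = min_duration,
                 smoothing = smoothing, sigma_loc = sigma_loc,
                 angle_convention = angle_convention, fit_lags = fit_lags,
                 seed = as.integer(seed),
                 start_from = match.arg(start_from)),
            class = "pipeline_config")
}

#' Run the full motility platform
#'
#' Executes simulate -> render -> detect -> track -> filter -> describe ->
#' compare for the two configured groups, writing every intermediate
#' artifact under `output_dir` (TIFF stacks with JSON sidecars, detections /
#' tracks / descriptors CSVs, `report.json`, optional plots) plus a
#' `manifest.json` recording the configuration, seed and per-stage counts.
#' With `config$start_from = "stacks"` the caller supplies `stacks` (a list
#' with elements `ctrl` and `treated`); with `"tracks"`, `tracks` (same
#' shape); earlier stages are skipped.
#'
#' Any stage failure is rethrown with the stage name; artifacts of completed
#' stages remain on disk.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @param stacks,tracks Optional stage inputs (see above).
#' @param seed Optional master-seed override.
#' @param write_tiff Write the rendered stacks to TIFF (on by default when
#'   simulating).
#' @param plots Also write ROC / histogram panels as PNG.
#' @param verbose Log stage progress via `message()`.
#' @return The manifest, invisibly (list with `counts`, `auc`, file paths).
#' @export
run_pipeline <- function(config, output_dir, stacks = NULL, tracks = NULL,
                         seed = NULL, write_tiff = TRUE, plots = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; completed artifacts are under ", output_dir, call. = FALSE))
  }
  manifest <- list(config = .config_to_list(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("motilitylab")),
                   counts = list(), files = list())
  groups <- c("ctrl", "treated")
  truth <- list()

  if (config$start_from == "simulate") {
    say("stage simulate")
    ds <- stage("simulate", make_two_group_dataset(
      config$model_ctrl, config$model_treated, config$n_cells, config$scene,
      seed = config$seed, render = TRUE))
    truth <- list(ctrl = ds$truth_a, treated = ds$truth_b)
    stacks <- list(ctrl = ds$stack_a, treated = ds$stack_b)
    for (g in groups) {
      tp <- file.path(output_dir, paste0("truth_", g, ".csv"))
      write_ground_truth(truth[[g]], tp)
      manifest$files[[paste0("truth_", g)]] <- tp
      if (write_tiff) {
        sp <- file.path(output_dir, paste0("stack_", g, ".tif"))
        write_image_stack(stacks[[g]], sp, bit_depth = config$scene$bit_depth,
                          seed = config$seed)
        manifest$files[[paste0("stack_", g)]] <- sp
      }
    }
  }

  if (config$start_from %in% c("simulate", "stacks")) {
    if (is.null(stacks) || !all(groups %in% names(stacks)))
      stop("run_pipeline: start_from = 'stacks' needs stacks$ctrl and ",
           "stacks$treated", call. = FALSE)
    tracks <- list()
    for (g in groups) {
      say("stage detect (", g, ")")
      dets <- stage("detect", detect_stack(stacks[[g]], config$r_min_um,
                                           config$r_max_um, config$detect))
      dp <- file.path(output_dir, paste0("detections_", g, ".csv"))
      write_detections(dets, dp)
      manifest$files[[paste0("detections_", g)]] <- dp
      manifest$counts[[paste0("detections_", g)]] <- nrow(dets)
      say("stage track (", g, ")")
      tr <- stage("track", build_tracks(dets, max_disp = config$max_disp,
                                        r_max_um = config$r_max_um))
      manifest$counts[[paste0("tracks_built_", g)]] <-
        length(unique(tr$track_id))
      tracks[[g]] <- tr
    }
  }

  if (is.null(tracks) || !all(groups %in% names(tracks)))
    stop("run_pipeline: start_from = 'tracks' needs tracks$ctrl and ",
         "tracks$treated", call. = FALSE)
  descriptors <- list()
  for (g in groups) {
    say("stage filter + describe (", g, ")")
    kept <- stage("filter", filter_tracks(tracks[[g]], config$min_duration))
    manifest$counts[[paste0("tracks_kept_", g)]] <-
      length(unique(kept$track_id))
    tp <- file.path(output_dir, paste0("tracks_", g, ".csv"))
    write_tracks(kept, tp)
    manifest$files[[paste0("tracks_", g)]] <- tp
    desc <- stage("describe", summarize_tracks(
      kept, group = g, smoothing = config$smoothing,
      sigma_loc = config$sigma_loc,
      angle_convention = config$angle_convention, fit_lags = config$fit_lags))
    dp <- file.path(output_dir, paste0("descriptors_", g, ".csv"))
    write_descriptors(desc, dp)
    manifest$files[[paste0("descriptors_", g)]] <- dp
    descriptors[[g]] <- desc
  }

  say("stage compare")
  report <- stage("compare", compare_groups(descriptors$ctrl,
                                            descriptors$treated))
  rp <- file.path(output_dir, "report.json")
  write_separability_report(report, rp)
  manifest$files$report <- rp
  manifest$auc <- lapply(report$descriptors, function(d) d$roc$auc)
  if (plots) {
    for (nm in c("roc_panel", "histogram_panel")) {
      p <- if (nm == "roc_panel") plot_roc_curves(report) else plot_histograms(report)
      pp <- file.path(output_dir, paste0(nm, ".png"))
      ggplot2::ggsave(pp, p, width = 7, height = 6, dpi = 120)
      manifest$files[[nm]] <- pp
    }
  }
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$report <- report
  invisible(manifest)
}

# Serializable view of a pipeline_config (drops closures, keeps scalars).
.config_to_list <- function(config) {
  strip <- function(x) {
    if (inherits(x, c("scene_config", "detect_params", "motion_model",
                      "pipeline_config")))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  strip(config)
}

#' Read and write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(.config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_model <- function(m) do.call(motion_model, m)
  sc <- do.call(scene_config, raw$scene[!vapply(raw$scene, is.null, TRUE)])
  pipeline_config(scene = sc,
                  model_ctrl = mk_model(raw$model_ctrl),
                  model_treated = mk_model(raw$model_treated),
                  n_cells = raw$n_cells,
                  r_min_um = raw$r_min_um, r_max_um = raw$r_max_um,
                  detect = do.call(detect_params,
                                   raw$detect[!vapply(raw$detect, is.null, TRUE)]),
                  max_disp = raw$max_disp, min_duration = raw$min_duration,
                  smoothing = raw$smoothing, sigma_loc = raw$sigma_loc,
                  angle_convention = raw$angle_convention,
                  fit_lags = raw$fit_lags,
                  seed = raw$seed, start_from = raw$start_from)
}
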