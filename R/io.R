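# Formats and orchestration: multi-page TIFF stacks with JSON sidecars,
# long-format CSV profiles, reference-library round-trips, end-to-end runs
# and the classical-vs-model measurement comparison.

#' Write a video (and optionally its masks) as multi-page TIFF
#'
#' One TIFF page per frame, 8-bit grayscale, plus a JSON sidecar recording
#' pixel scale, frame interval, seed and (unless blinded) the material
#' truth. Masks are written as 0/1 8-bit stacks.
#'
#' @param video A `synthetic_video`.
#' @param path Output TIFF path.
#' @param masks_path Optional path for the truth-mask stack.
#' @param sidecar Write the JSON sidecar next to `path` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path, masks_path = NULL,
                             sidecar = TRUE) {
  tiff::writeTIFF(video$frames, path, bits.per.sample = 8L)
  if (!is.null(masks_path))
    tiff::writeTIFF(lapply(video$truth_masks, function(m) m * 1),
                    masks_path, bits.per.sample = 8L)
  if (sidecar) {
    meta <- list(pixel_scale_um_per_px = video$scene$pixel_scale,
                 frame_interval_s = video$scene$frame_interval,
                 n_frames = length(video$frames),
                 hfw_um = video$scene$hfw,
                 material = video$material,
                 seed = video$seed)
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                      ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack (with optional JSON sidecar)
#'
#' @param path TIFF path; a sidecar `<path>.json` is read when present.
#' @return List with `frames` (list of matrices) and `meta` (list or NULL).
#' @export
read_video_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    f
  })
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  list(frames = frames, meta = meta)
}

#' Write / read long-format profile tables
#'
#' Columns `particle_id`, `material`, `time_s`, `percent_remaining`.
#'
#' @param profiles Profile data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference-library round-trip
#'
#' The library is stored as a long-format CSV of profiles plus a JSON
#' metadata file (time grid, thresholds, alpha, beam current, seed).
#'
#' @param library A `reference_library`.
#' @param dir Directory to write into (created if missing).
#' @return `dir` (write) or a `reference_library` (read).
#' @export
write_reference_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles_csv(library$profiles, file.path(dir, "profiles.csv"))
  jsonlite::write_json(
    list(times = library$times,
         thresholds = as.list(library$thresholds),
         alpha = library$alpha, beam_current = library$beam_current,
         n_per_material = library$n_per_material, seed = library$seed),
    file.path(dir, "library.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "library.json"),
                              simplifyVector = TRUE)
  structure(list(profiles = read_profiles_csv(file.path(dir,
                                                        "profiles.csv")),
                 times = meta$times,
                 thresholds = unlist(meta$thresholds),
                 alpha = meta$alpha, beam_current = meta$beam_current,
                 n_per_material = meta$n_per_material, seed = meta$seed),
            class = "reference_library")
}

#' Write a classification report as JSON plus a text table
#'
#' @param report A `classification_report`.
#' @param path JSON path; a `.txt` sibling holds the printed table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(sample_id = report$sample_id, alpha = report$alpha,
         min_group = report$min_group, results = report$results,
         suspects = report$suspects,
         caveat = paste("presence calls rest on failure to reject",
                        "similarity; absence of evidence is not",
                        "equivalence")),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- paste0(tools::file_path_sans_ext(path), ".txt")
  con <- file(txt, open = "wt")
  sink(con); print(report); sink()
  close(con)
  invisible(path)
}

#' Run configuration
#'
#' Assembles (or reads from YAML) the configuration of an end-to-end run.
#'
#' @param mode One of `simulate`, `end_to_end`, `compare_modes`.
#' @param out_dir Output directory.
#' @param composition Named per-material particle counts for the blinded
#'   sample (default the first preset mixture).
#' @param scene A [scene_config()] or list of overrides.
#' @param segmentation `"classical"` or `"model"`.
#' @param seg_params A [segmentation_params()].
#' @param alpha,min_group,timepoints Statistical options.
#' @param n_reference Reference profiles per material.
#' @param seed Integer seed for every stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("end_to_end", "simulate", "compare_modes"),
                       out_dir = tempfile("semdeform_run_"),
                       composition = table1_compositions()$sample1,
                       scene = scene_config(),
                       segmentation = c("classical", "model"),
                       seg_params = segmentation_params(),
                       alpha = 0.05, min_group = 2L,
                       timepoints = c(0, 2, 4, 10, 20, 40),
                       n_reference = 5L, seed = 1L) {
  mode <- match.arg(mode)
  segmentation <- match.arg(segmentation)
  if (!inherits(scene, "scene_config")) scene <- do.call(scene_config, scene)
  structure(list(mode = mode, out_dir = out_dir,
                 composition = composition, scene = scene,
                 segmentation = segmentation, seg_params = seg_params,
                 alpha = alpha, min_group = as.integer(min_group),
                 timepoints = timepoints,
                 n_reference = as.integer(n_reference),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("mode", "out_dir", "segmentation", "alpha", "min_group",
               "timepoints", "n_reference", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$composition)) args$composition <- unlist(y$composition)
  if (!is.null(y$scene)) args$scene <- y$scene
  do.call(run_config, args)
}

stage <- function(name, particle_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s'%s failed: %s", name,
                 if (is.null(particle_id)) ""
                 else sprintf(" (particle %s)", particle_id),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the pipeline end to end
#'
#' Simulate a blinded sample of videos, segment every frame, track each
#' particle, normalize and restrict profiles to the screening timepoints,
#' classify against a simulated reference library, and write all artifacts
#' (TIFF stacks, profile/summary CSVs, report JSON, manifest) under
#' `config$out_dir`. Every stage derives its seed from `config$seed`, so a
#' repeated run is byte-identical.
#'
#' @param config A [run_config()].
#' @param model Optional trained segmenter for `segmentation = "model"`.
#' @return The `classification_report` (invisibly for `mode = "simulate"`,
#'   which writes frames and truth only).
#' @export
run_end_to_end <- function(config = run_config(), model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lib_times <- pmin(config$timepoints,
                    (config$scene$n_frames - 1L) *
                      config$scene$frame_interval)
  blind <- stage("simulate", NULL, generate_blinded_sample(
    config$composition, config$scene, seed = config$seed,
    sample_id = "run"))
  frames_dir <- file.path(config$out_dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  for (v in blind$videos)
    write_video_tiff(v, file.path(frames_dir,
                                  paste0(v$particle_id, ".tif")))
  utils::write.csv(blind$truth, file.path(config$out_dir, "truth.csv"),
                   row.names = FALSE)
  if (config$mode == "simulate") {
    write_manifest(config, NULL)
    return(invisible(NULL))
  }
  if (config$segmentation == "model" && is.null(model))
    stop("segmentation = 'model' requires a trained model")
  profs <- list()
  for (v in blind$videos) {
    p <- stage("segment/track", v$particle_id, video_profile(
      v, config$seg_params, method = config$segmentation, model = model))
    profs[[length(profs) + 1L]] <-
      suppressWarnings(sample_timepoints(p, config$timepoints))
  }
  profiles <- do.call(rbind, c(profs, list(make.row.names = FALSE)))
  write_profiles_csv(profiles, file.path(config$out_dir, "profiles.csv"))
  library <- stage("reference", NULL, build_reference_library(
    n_per_material = config$n_reference, times = lib_times,
    seed = config$seed + 5000L, alpha = config$alpha))
  write_reference_library(library, file.path(config$out_dir, "library"))
  report <- stage("classify", NULL, classify_sample(
    profiles, library, alpha = config$alpha,
    min_group = config$min_group,
    final_time = max(lib_times), sample_id = "run"))
  utils::write.csv(report$summaries,
                   file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)
  write_report(report, file.path(config$out_dir, "report.json"))
  write_manifest(config, report)
  report
}

write_manifest <- function(config, report) {
  cfg <- unclass(config)
  cfg$scene <- unclass(cfg$scene)
  cfg$seg_params <- unclass(cfg$seg_params)
  cfg$composition <- as.list(cfg$composition)  # keep names in JSON
  jsonlite::write_json(
    list(package = "semdeform",
         version = as.character(utils::packageVersion("semdeform")),
         seed = config$seed,
         config = cfg,
         config_hash = digest_config(cfg),
         called = if (is.null(report)) character(0)
                  else report$results$material[report$results$present]),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
}

digest_config <- function(cfg) {
  # stable content hash without external digest packages
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Compare classical- and model-derived measurements
#'
#' Runs both segmentation modes on identical videos and, per material,
#' reports the mean absolute difference in percent-remaining and the
#' between-mode p-value of a mixed-design repeated-measures ANOVA with
#' measurement mode as the grouping factor — the computational-vs-manual
#' style comparison, whose expected outcome at defaults is no significant
#' mode difference.
#'
#' @param videos List of `synthetic_video`s with material labels.
#' @param model Trained segmenter; when `NULL` the comparison degenerates to
#'   classical-vs-classical and is flagged.
#' @param params [segmentation_params()] for the classical mode.
#' @param timepoints Screening timepoints for the comparison.
#' @return Data frame `material`, `mean_abs_delta`, `p_value`, `flag`.
#' @export
compare_modes <- function(videos, model = NULL,
                          params = segmentation_params(),
                          timepoints = c(0, 2, 4, 10, 20, 40)) {
  flag <- ""
  if (is.null(model)) flag <- "model unavailable: classical-only comparison"
  else if (!isTRUE(model$trained)) flag <- "degenerate: untrained model"
  mats <- vapply(videos, function(v) v$material, character(1))
  rows <- list()
  for (m in unique(mats)) {
    vs <- videos[mats == m]
    pc <- list(); pm <- list()
    for (i in seq_along(vs)) {
      pid <- sprintf("%s_%02d", m, i)
      a <- suppressWarnings(sample_timepoints(
        video_profile(vs[[i]], params, "classical",
                      particle_id = pid, material = m), timepoints))
      b <- if (is.null(model) || !isTRUE(model$trained)) a else
        suppressWarnings(sample_timepoints(
          video_profile(vs[[i]], params, "model", model = model,
                        particle_id = pid, material = m), timepoints))
      pc[[i]] <- a; pm[[i]] <- b
    }
    dc <- do.call(rbind, pc); dm <- do.call(rbind, pm)
    delta <- mean(abs(dc$percent_remaining - dm$percent_remaining))
    d <- rbind(transform(dc, mode = "classical",
                         particle_id = paste0("c_", particle_id)),
               transform(dm, mode = "model",
                         particle_id = paste0("m_", particle_id)))
    p <- if (delta == 0) 1 else {
      at <- rm_anova_mixed(d, group = "mode")
      pv <- at$p[at$effect == "group"]
      if (is.na(pv)) 1 else pv
    }
    rows[[m]] <- data.frame(material = m, mean_abs_delta = delta,
                            p_value = p, flag = flag,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
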