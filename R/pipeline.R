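# Config-driven pipeline runner.
#
# A run is described by a YAML or JSON file:
#
#   output_dir: out
#   seed: 7                      # required if any synthetic stage is listed
#   stages:
#     - stage: synthetic_phantom
#       params: {edge_blur_um: 8}
#     - stage: ct_quant
#       volume: "@synthetic_phantom"   # reference to an earlier stage
#     - stage: edge_volume
#       volume: "@synthetic_phantom"
#
# Inputs are either file paths or "@stage" references to the outputs of an
# earlier stage. The whole configuration is validated before any stage
# executes, every randomized stage draws a sub-seed deterministically from
# the top-level seed, and all outputs (CSV tables, a JSON summary, a run
# log) are written without timestamps so that two runs with the same
# config are byte-identical.

PIPELINE_STAGES <- c("synthetic_phantom", "synthetic_sled", "synthetic_eye",
                     "synthetic_layer", "synthetic_cohort", "ct_quant",
                     "edge_volume", "layer_angle", "lvor_index", "stats")
RANDOM_STAGES <- c("synthetic_phantom", "synthetic_eye", "synthetic_layer",
                   "synthetic_cohort")

read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) stop_input("config needs `output_dir`")
  if (is.null(cfg$stages) || length(cfg$stages) == 0L)
    stop_input("config lists no stages")
  cfg
}

# resolve an input: "@stage" reference -> list(ref=stage) ; path -> path
resolve_input <- function(x, field, stage_name, seen_stages) {
  if (is.null(x))
    stop_input(sprintf("stage `%s` is missing required input `%s`",
                       stage_name, field))
  if (is.character(x) && length(x) == 1L && startsWith(x, "@")) {
    ref <- substring(x, 2)
    if (!ref %in% seen_stages)
      stop_input(sprintf(
        "stage `%s`: input `%s` references \"@%s\", which is not an earlier stage",
        stage_name, field, ref))
    return(structure(ref, class = "stage_ref"))
  }
  if (!file.exists(x))
    stop_input(sprintf("stage `%s`: input `%s` file not found: %s",
                       stage_name, field, x))
  x
}

stage_inputs <- list(
  synthetic_eye = "sled", ct_quant = "volume", edge_volume = "volume",
  layer_angle = "points", lvor_index = c("sled", "eye"), stats = "cohort")

validate_config <- function(cfg) {
  names_seen <- character(0)
  for (st in cfg$stages) {
    if (is.null(st$stage) || !st$stage %in% PIPELINE_STAGES)
      stop_input("unknown stage: ", if (is.null(st$stage)) "<missing>"
                 else st$stage)
    for (f in stage_inputs[[st$stage]])
      resolve_input(st[[f]], f, st$stage, names_seen)
    names_seen <- c(names_seen, st$stage)
  }
  if (any(vapply(cfg$stages, function(s) s$stage %in% RANDOM_STAGES,
                 logical(1))) && is.null(cfg$seed))
    stop_input("config lists randomized stages but no `seed`")
  invisible(TRUE)
}

#' Run the pipeline described by a configuration file
#'
#' Executes the requested stages in order, writing per-stage CSV outputs,
#' a `summary.json`, and a `log.txt` into the configured output directory.
#' See the package source header of this file for the config schema. The
#' configuration is validated in full (stage names, input files, stage
#' references, seed presence) before any computation starts.
#'
#' @param config path to a YAML or JSON configuration file.
#' @return invisibly, the per-stage summary list.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  summary <- list()
  log <- c("otomorph pipeline run",
           paste0("package version: ",
                  as.character(utils::packageVersion("otomorph"))),
           paste0("seed: ", if (is.null(cfg$seed)) "none" else cfg$seed))
  produced <- list()  # stage name -> named list of artifact paths

  get_in <- function(st, field) {
    x <- st[[field]]
    if (is.character(x) && startsWith(x, "@")) {
      ref <- produced[[substring(x, 2)]]
      return(ref)
    }
    x
  }

  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    nm <- st$stage
    sub_seed <- if (is.null(cfg$seed)) NULL else (cfg$seed + i) %% .Machine$integer.max
    log <- c(log, sprintf("stage %d: %s", i, nm))

    if (nm == "synthetic_phantom") {
      pars <- c(st$params, list(seed = sub_seed))
      pars <- pars[!duplicated(names(pars))]
      ph <- gen_ct_phantom(do.call(phantom_params, pars))
      write_volume(ph$volume, out("volume.nii.gz"))
      write_volume(ph$rois$otolith_roi, out("otolith_roi.nii.gz"),
                   meta = ph$volume$meta)
      write_volume(ph$rois$tissue_roi, out("tissue_roi.nii.gz"),
                   meta = ph$volume$meta)
      jsonlite::write_json(
        list(n_voxels = ph$truth$n_voxels,
             volume_um3 = ph$truth$volume_um3,
             supra_volume_um3 = ph$truth$supra_volume_um3,
             analytic_volume_um3 = ph$truth$analytic_volume_um3,
             mu_otolith = ph$truth$mu_otolith,
             mu_background = ph$truth$mu_background),
        out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      produced[[nm]] <- list(volume = out("volume.nii.gz"),
                             otolith_roi = out("otolith_roi.nii.gz"),
                             tissue_roi = out("tissue_roi.nii.gz"))
      summary[[nm]] <- list(true_volume_um3 = ph$truth$volume_um3)
    } else if (nm == "synthetic_sled") {
      tr <- gen_sled_trace(do.call(sled_params, as.list(st$params)))
      write_trace(tr, out("sled.csv"))
      produced[[nm]] <- list(sled = out("sled.csv"))
      summary[[nm]] <- list(
        n_samples = nrow(tr),
        peak_accel_G = max(abs(tr$acceleration_mm_s2)) / 1000 / G_MS2)
    } else if (nm == "synthetic_eye") {
      sled_in <- get_in(st, "sled")
      sled <- read_trace(if (is.list(sled_in)) sled_in$sled else sled_in)
      pars <- c(st$params, list(seed = sub_seed))
      pars <- pars[!duplicated(names(pars))]
      eye <- gen_eye_trace(sled, do.call(eye_model_params, pars))
      write_trace(eye, out("eye.csv"))
      produced[[nm]] <- list(eye = out("eye.csv"))
      summary[[nm]] <- list(n_samples = nrow(eye))
    } else if (nm == "synthetic_layer") {
      pars <- c(st$params, list(seed = sub_seed))
      pars <- pars[!duplicated(names(pars))]
      lt <- do.call(gen_layer_points, pars)
      write_layer_points(lt, out("layer_points.csv"))
      produced[[nm]] <- list(points = out("layer_points.csv"))
      summary[[nm]] <- list(true_angle_deg = lt$angle_deg)
    } else if (nm == "synthetic_cohort") {
      pars <- c(st$params, list(seed = sub_seed))
      pars <- pars[!duplicated(names(pars))]
      co <- gen_cohort(do.call(cohort_effects, pars))
      utils::write.csv(co, out("cohort.csv"), row.names = FALSE)
      produced[[nm]] <- list(cohort = out("cohort.csv"))
      summary[[nm]] <- list(n_records = nrow(co))
    } else if (nm %in% c("ct_quant", "edge_volume")) {
      vin <- get_in(st, "volume")
      if (is.list(vin)) {
        vol <- read_volume(vin$volume)$volume
        rois <- roi_pair(read_volume(vin$otolith_roi)$volume$voxels != 0,
                         read_volume(vin$tissue_roi)$volume$voxels != 0)
      } else {
        vol <- read_volume(vin)$volume
        rois <- roi_pair(read_volume(st$otolith_roi)$volume$voxels != 0,
                         read_volume(st$tissue_roi)$volume$voxels != 0)
      }
      keep <- isTRUE(st$keep_largest)
      thr <- compute_threshold(vol, rois,
                               summary = st$summary %||% "mean")
      if (nm == "ct_quant") {
        seg <- segment_otolith(vol, rois$otolith_roi, thr$threshold, keep)
        q <- quantify(vol, seg)
        utils::write.csv(
          data.frame(alpha = thr$alpha, beta = thr$beta,
                     threshold = thr$threshold, edge_lower = thr$edge_lower),
          out("thresholds.csv"), row.names = FALSE)
        utils::write.csv(
          data.frame(volume_voxels = q$volume_voxels,
                     volume_um3 = q$volume_um3, mean_ct = q$mean_ct),
          out("morphometry.csv"), row.names = FALSE)
        utils::write.csv(slice_areas(seg, vol$meta),
                         out("slice_areas.csv"), row.names = FALSE)
        write_volume(seg, out("segmented_mask.nii.gz"), meta = vol$meta)
        summary[[nm]] <- list(threshold = thr$threshold,
                              volume_um3 = q$volume_um3, mean_ct = q$mean_ct)
      } else {
        ev <- striola_edge_volume(vol, rois$otolith_roi, thr, keep)
        utils::write.csv(
          data.frame(edge_voxels = ev$edge_voxels,
                     edge_volume_um3 = ev$edge_volume_um3),
          out("edge_volume.csv"), row.names = FALSE)
        write_volume(ev$edge_mask, out("edge_mask.nii.gz"), meta = vol$meta)
        summary[[nm]] <- list(edge_volume_um3 = ev$edge_volume_um3)
      }
    } else if (nm == "layer_angle") {
      pin <- get_in(st, "points")
      lt <- read_layer_points(if (is.list(pin)) pin$points else pin)
      ar <- layer_angle(lt)
      utils::write.csv(data.frame(angle_deg = ar$angle_deg,
                                  rms_les_um = ar$fit_rms_um["les"],
                                  rms_base_um = ar$fit_rms_um["base"]),
                       out("layer_angle.csv"), row.names = FALSE)
      summary[[nm]] <- list(angle_deg = ar$angle_deg)
    } else if (nm == "lvor_index") {
      sin_ <- get_in(st, "sled")
      ein <- get_in(st, "eye")
      sled <- read_trace(if (is.list(sin_)) sin_$sled else sin_)
      eye <- read_trace(if (is.list(ein)) ein$eye else ein)
      if (is.null(sled$velocity_mm_s))
        sled <- derive_kinematics(sled$position_mm, attr(sled, "rate_hz"))
      cyc <- segment_cycles(sled)
      idx <- otolith_function_index(eye, cyc)
      lbl <- orient_run(st$orientation %||% "lateral",
                        st$accel %||% "1.3G")
      utils::write.csv(data.frame(cycle = seq_along(idx$per_cycle),
                                  index_deg = idx$per_cycle),
                       out("lvor_cycles.csv"), row.names = FALSE)
      utils::write.csv(cbind(lbl, index_deg = idx$index,
                             baseline_deg = idx$baseline_deg),
                       out("lvor_index.csv"), row.names = FALSE)
      summary[[nm]] <- list(index_deg = idx$index, tag = lbl$tag)
    } else if (nm == "stats") {
      cin <- get_in(st, "cohort")
      co <- read_cohort(if (is.list(cin)) cin$cohort else cin)
      meas <- st$measurement %||% unique(co$measurement)
      rows <- list()
      ph_rows <- list()
      norm_rows <- list()
      posthoc_mode <- st$posthoc %||% "auto"
      for (m in meas) {
        ns <- normality_screen(co$value[co$measurement == m], warn = FALSE)
        norm_rows[[m]] <- data.frame(measurement = m,
                                     shapiro_p = ns$shapiro_p,
                                     ks_p = ns$ks_p, pass = ns$pass)
        av <- two_way_anova(co, m)
        rows[[m]] <- cbind(measurement = m, av$effects, n = av$n)
        inter_p <- av$effects$p[av$effects$effect == "interaction"]
        if (posthoc_mode == "always" ||
            (posthoc_mode == "auto" && inter_p < 0.05)) {
          ph <- bonferroni_posthoc(co, m)
          ph_rows[[m]] <- cbind(measurement = m, as.data.frame(ph))
        }
      }
      utils::write.csv(do.call(rbind, norm_rows), out("normality.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, rows), out("anova.csv"),
                       row.names = FALSE)
      if (length(ph_rows))
        utils::write.csv(do.call(rbind, ph_rows), out("posthoc.csv"),
                         row.names = FALSE)
      summary[[nm]] <- list(measurements = meas,
                            posthoc_run = names(ph_rows))
    }
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log, out("log.txt"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
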