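#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list, checks every key against the
#' documented schema, range-checks the values, and materialises defaults.
#' All problems are reported together in a single error.
#'
#' Recognised keys: `seed`, `out_dir`, `traces_csv` (analyse an existing
#' table instead of simulating), `write_traces`, analysis parameters
#' (`frame_rate`, `stim_onset`, `baseline_window`, `response_window_s`,
#' `threshold_k`, `sigma_mode`), a `simulation` block (any argument of
#' [synthetic_config()] except `seed`), and a `dosimetry` block
#' (`fiber_core_um`, `numerical_aperture`, `wavelength_nm`,
#' `incidence_angle_deg`, `tip_distance_um`).
#'
#' @param config YAML file path, or a (possibly empty) named list.
#' @return Object of class `run_config` with all defaults filled in.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  top_keys <- c("seed", "out_dir", "traces_csv", "write_traces",
                "frame_rate", "stim_onset", "baseline_window",
                "response_window_s", "threshold_k", "sigma_mode",
                "simulation", "dosimetry")
  unknown <- setdiff(names(config), top_keys)
  if (length(unknown) > 0)
    note(paste("unknown config keys:", paste(unknown, collapse = ", ")))

  dflt <- list(seed = 1L, out_dir = NULL, traces_csv = NULL,
               write_traces = FALSE, frame_rate = 30.9375, stim_onset = 5,
               baseline_window = c(3, 4.5), response_window_s = 2,
               threshold_k = 3, sigma_mode = "trials",
               simulation = list(), dosimetry = list())
  cfg <- utils::modifyList(dflt, config[names(config) %in% top_keys])

  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    note("seed must be an integer")
  if (!is.numeric(cfg$threshold_k) || cfg$threshold_k <= 0)
    note("threshold_k must be > 0")
  if (!is.numeric(cfg$response_window_s) || cfg$response_window_s <= 0)
    note("response_window_s must be > 0")
  if (!is.numeric(cfg$frame_rate) || cfg$frame_rate <= 0)
    note("frame_rate must be > 0")
  if (length(cfg$baseline_window) != 2 ||
      cfg$baseline_window[1] >= cfg$baseline_window[2])
    note("baseline_window must be c(start, end) with start < end")
  else if (is.numeric(cfg$stim_onset) &&
           cfg$baseline_window[2] > cfg$stim_onset)
    note("baseline window must end at or before the stimulus onset")
  if (!cfg$sigma_mode %in% c("trials", "average"))
    note("sigma_mode must be 'trials' or 'average'")
  if (!is.null(cfg$traces_csv) && !file.exists(cfg$traces_csv))
    note(paste("traces_csv not found:", cfg$traces_csv))

  sim_ok <- setdiff(names(formals(synthetic_config)), "seed")
  bad <- setdiff(names(cfg$simulation), sim_ok)
  if (length(bad) > 0)
    note(paste("unknown simulation keys:", paste(bad, collapse = ", ")))

  dos_ok <- c("fiber_core_um", "numerical_aperture", "wavelength_nm",
              "incidence_angle_deg", "tip_distance_um")
  bad <- setdiff(names(cfg$dosimetry), dos_ok)
  if (length(bad) > 0)
    note(paste("unknown dosimetry keys:", paste(bad, collapse = ", ")))

  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  sim_args <- cfg$simulation
  sim_args$seed <- as.integer(cfg$seed)
  for (nm in c("frame_rate", "stim_onset"))
    if (is.null(sim_args[[nm]])) sim_args[[nm]] <- cfg[[nm]]
  cfg$synthetic <- do.call(synthetic_config, sim_args)

  d <- cfg$dosimetry
  cfg$fiber <- fiber_spec(
    core_diameter_um = d$fiber_core_um %||% 105,
    numerical_aperture = d$numerical_aperture %||% 0.15,
    wavelength_nm = d$wavelength_nm %||% 1470)
  cfg$path <- optical_path(
    incidence_angle_deg = d$incidence_angle_deg %||% 35,
    tip_distance_um = d$tip_distance_um %||% 150)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in order -- dosimetry report, simulation (or trace
#' loading), responder classification, dose-response aggregation with
#' statistics, spatial-extent analysis -- writing every stage's output
#' under `out_dir` and a manifest/report at the end. Identical
#' configuration and seed produce identical outputs.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @param quiet Suppress progress messages.
#' @return The run report (list of class `run_report`), invisibly;
#'   also written as `report.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[inscal] ", ...)
  wjson <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- character(0)
  emit <- function(f) manifest <<- c(manifest, f)

  say("stage 1/5: dosimetry")
  protocol <- stimulus_protocol(
    energy_densities_J_cm2 = config$synthetic$energy_densities_J_cm2)
  dos <- dosimetry_report(config$fiber, config$path, protocol)
  wjson(list(major_axis_um = dos$major_axis_um,
             minor_axis_um = dos$minor_axis_um,
             area_cm2 = dos$area_cm2, n_pulses = dos$n_pulses,
             pulse_energies_uJ = as.list(dos$pulse_energies_uJ),
             alpha_cm = dos$alpha_cm,
             penetration_depth_um = dos$penetration_depth_um),
        "dosimetry.json"); emit("dosimetry.json")

  if (is.null(config$traces_csv)) {
    say("stage 2/5: simulate (", config$synthetic$n_cells, " cells)")
    expmt <- simulate_experiment(config$synthetic)
    traces <- expmt$traces
    cells <- expmt$cells
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE); emit("cells.csv")
    utils::write.csv(expmt$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE); emit("ground_truth.csv")
    if (isTRUE(config$write_traces)) {
      write_traces_csv(traces, file.path(out_dir, "traces.csv"))
      emit("traces.csv")
    }
  } else {
    say("stage 2/5: load traces from ", config$traces_csv)
    traces <- read_traces_csv(config$traces_csv)
    cells <- NULL
  }

  say("stage 3/5: classify responses")
  calls <- analyze_traces(traces, frame_rate = config$frame_rate,
                          stim_onset = config$stim_onset,
                          baseline_window = config$baseline_window,
                          response_window_s = config$response_window_s,
                          threshold_k = config$threshold_k,
                          sigma_mode = config$sigma_mode)
  utils::write.csv(calls, file.path(out_dir, "calls.csv"),
                   row.names = FALSE); emit("calls.csv")

  say("stage 4/5: dose-response")
  fr <- responder_fractions(calls)
  utils::write.csv(fr$summary, file.path(out_dir, "responder_fractions.csv"),
                   row.names = FALSE); emit("responder_fractions.csv")
  mt <- multiplicity_categories(calls)
  utils::write.csv(mt$per_energy, file.path(out_dir, "multiplicity.csv"),
                   row.names = FALSE); emit("multiplicity.csv")
  dr <- tryCatch(normalized_dose_response(calls),
                 error = function(e) NULL)
  stats_out <- list()
  if (!is.null(dr)) {
    utils::write.csv(as.data.frame(dr),
                     file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE); emit("dose_response.csv")
    m <- amplitude_matrix(calls, require_energies = c(0.47, 0.58, 0.70))
    if (!is.null(m) && nrow(m) >= 2) {
      rma <- rm_anova_bonferroni(m)
      stats_out$rm_anova <- list(method = rma$anova$method,
                                 F = rma$anova$statistic,
                                 df = rma$anova$df,
                                 p_value = rma$anova$p_value)
      stats_out$pairwise <- rma$pairwise
    }
  }
  wjson(stats_out, "stats.json"); emit("stats.json")

  say("stage 5/5: spatial mapping")
  spatial_out <- list()
  if (!is.null(cells)) {
    cmap <- build_cell_map(cells, calls)
    ov <- tryCatch(align_fovs(cmap), error = function(e) NULL)
  }
  if (!is.null(cells) && !is.null(ov)) {
    utils::write.csv(ov$cells, file.path(out_dir, "overlay.csv"),
                     row.names = FALSE); emit("overlay.csv")
    wjson(ov$fits, "spatial_fits.json"); emit("spatial_fits.json")
    lf <- location_fractions(ov$cells, central_ellipse())
    spatial_out <- list(central_responsive_pct = lf$central_responsive_pct,
                        peripheral_responsive_pct = lf$peripheral_responsive_pct,
                        per_class = lf$per_class)
    wjson(spatial_out, "location_fractions.json")
    emit("location_fractions.json")
  }

  report <- list(
    package = "inscal",
    version = as.character(utils::packageVersion("inscal")),
    seed = config$seed,
    parameters = list(frame_rate = config$frame_rate,
                      stim_onset = config$stim_onset,
                      baseline_window = config$baseline_window,
                      response_window_s = config$response_window_s,
                      threshold_k = config$threshold_k,
                      sigma_mode = config$sigma_mode),
    manifest = manifest,
    summary = list(
      dosimetry = list(area_cm2 = dos$area_cm2,
                       penetration_depth_um = dos$penetration_depth_um),
      responder_fractions = fr$summary,
      normalized_dose_response = if (!is.null(dr)) as.data.frame(dr),
      spatial = spatial_out))
  wjson(report, "report.json")
  say("done: ", out_dir)
  invisible(structure(report, class = "run_report"))
}

#' Per-cell peak-amplitude matrix over an energy ladder
#'
#' Cells (rows) x energies (columns) matrix of peak dF/F0, restricted to
#' cells responding at every energy in `require_energies` -- the layout
#' needed by [rm_anova_bonferroni()].
#'
#' @param calls Response-call data frame.
#' @param require_energies Energies a cell must respond to for inclusion.
#' @return Numeric matrix (or `NULL` when no cell qualifies), columns
#'   named by energy.
#' @export
amplitude_matrix <- function(calls, require_energies = c(0.47, 0.58, 0.70)) {
  calls <- .ensure_experiment(calls)
  energies <- sort(unique(calls$energy_density))
  cell <- paste(calls$experiment_id, calls$roi_id, sep = "\r")
  ok <- tapply(seq_len(nrow(calls)), cell, function(i) {
    sub <- calls[i, ]
    length(unique(sub$energy_density)) == length(energies) &&
      all(vapply(require_energies, function(e)
        any(sub$energy_density == e & sub$is_responder), TRUE))
  })
  keep <- names(ok)[ok]
  if (length(keep) == 0) return(NULL)
  sub <- calls[cell %in% keep, ]
  sub <- sub[order(paste(sub$experiment_id, sub$roi_id, sep = "\r"),
                   sub$energy_density), ]
  m <- matrix(sub$peak_dff, ncol = length(energies), byrow = TRUE)
  colnames(m) <- format(energies)
  m
}
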