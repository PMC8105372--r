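#' Configuration of a synthetic INS experiment
#'
#' Defines the study conditions emulated by the generator: a field of view
#' with uniformly placed cells, an elliptical Gaussian fluence footprint
#' with Beer-Lambert attenuation in depth, per-cell log-normal activation
#' thresholds, a saturating amplitude model, GCaMP6f-like double-exponential
#' transients, additive Gaussian noise and optional per-recording
#' exponential bleaching.
#'
#' Defaults encode the emulated protocol: four energy densities
#' (0.35-0.70 J cm^-2), 5 trials each, 30 s recordings at 30.9375 Hz with
#' the stimulus at 5 s, a 246 x 168 um footprint and Layer 2/3 depths
#' (96-255 um). The threshold distribution and field-of-view size are a
#' calibration: they were fit once, by least squares against the recruited
#' fractions the protocol is expected to produce, and are a modelling
#' convention of the generator rather than independent evidence (see the
#' methods vignette). Amplitude defaults put the top-energy peak dF/F0
#' near 0.07, the scale typical of few-action-potential GCaMP6f signals.
#'
#' @param seed Integer seed; fixed seed implies identical output.
#' @param n_cells Number of cells in the field of view.
#' @param fov_um Field-of-view size (x, y), micrometres.
#' @param footprint_center_um Footprint centre; defaults to the FoV centre.
#' @param footprint_major_um,footprint_minor_um,footprint_orientation_deg
#'   Footprint ellipse (1/e^2 full axes) and orientation.
#' @param energy_densities_J_cm2 Radiant exposures, J cm^-2.
#' @param threshold_meanlog,threshold_sdlog Log-normal parameters of the
#'   per-cell activation threshold, in fluence units (J cm^-2).
#' @param a_max Saturating amplitude ceiling of the transient (dF/F0 of the
#'   kernel's unit-amplitude envelope; the observable peak is
#'   `a_max * transient_peak_factor(...)`).
#' @param amp_scale Fluence scale of amplitude saturation, J cm^-2.
#' @param tau_rise,tau_decay Transient kinetics, seconds.
#' @param noise_sd Additive Gaussian noise SD per trial, dF/F0 units.
#' @param bleach_rate Per-recording exponential decay rate of F0 (0 = off).
#' @param trials_per_energy Number of repeated trials per energy.
#' @param frame_rate Acquisition rate, Hz.
#' @param duration Recording length, seconds.
#' @param stim_onset Stimulus onset, seconds.
#' @param depth_range_um Uniform sampling range of cell depths, micrometres.
#' @param f0_mean,f0_sd Baseline fluorescence distribution (arbitrary units).
#' @param alpha_cm Tissue absorption coefficient; default interpolated from
#'   the packaged water table at 1470 nm.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_cells = 250,
                             fov_um = c(240, 240),
                             footprint_center_um = fov_um / 2,
                             footprint_major_um = 246,
                             footprint_minor_um = 168,
                             footprint_orientation_deg = 0,
                             energy_densities_J_cm2 = c(0.35, 0.47, 0.58, 0.70),
                             threshold_meanlog = -1.5,
                             threshold_sdlog = 0.65,
                             a_max = 0.125, amp_scale = 0.08,
                             tau_rise = 0.08, tau_decay = 0.4,
                             noise_sd = 0.005, bleach_rate = 0,
                             trials_per_energy = 5,
                             frame_rate = 30.9375, duration = 30,
                             stim_onset = 5,
                             depth_range_um = c(96, 255),
                             f0_mean = 600, f0_sd = 60,
                             alpha_cm = NULL) {
  if (is.null(alpha_cm))
    alpha_cm <- interpolate_absorption(water_absorption_table(), 1470)
  cfg <- list(seed = as.integer(seed), n_cells = n_cells, fov_um = fov_um,
              footprint_center_um = footprint_center_um,
              footprint_major_um = footprint_major_um,
              footprint_minor_um = footprint_minor_um,
              footprint_orientation_deg = footprint_orientation_deg,
              energy_densities_J_cm2 = energy_densities_J_cm2,
              threshold_meanlog = threshold_meanlog,
              threshold_sdlog = threshold_sdlog,
              a_max = a_max, amp_scale = amp_scale,
              tau_rise = tau_rise, tau_decay = tau_decay,
              noise_sd = noise_sd, bleach_rate = bleach_rate,
              trials_per_energy = trials_per_energy,
              frame_rate = frame_rate, duration = duration,
              stim_onset = stim_onset, depth_range_um = depth_range_um,
              f0_mean = f0_mean, f0_sd = f0_sd, alpha_cm = alpha_cm)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_cells > 0, all(fov_um > 0),
              footprint_minor_um > 0,
              footprint_major_um >= footprint_minor_um,
              all(energy_densities_J_cm2 > 0),
              threshold_sdlog >= 0, a_max > 0, amp_scale > 0,
              tau_rise > 0, tau_decay > 0, noise_sd >= 0,
              bleach_rate >= 0, trials_per_energy >= 1,
              frame_rate > 0, duration > 0,
              stim_onset > 0, stim_onset < duration,
              depth_range_um[1] >= 0,
              depth_range_um[2] >= depth_range_um[1],
              f0_mean > 0, f0_sd >= 0, alpha_cm > 0)
  })
  invisible(cfg)
}

#' Sample a synthetic cell map
#'
#' Uniform positions in the field of view, uniform depths, log-normal
#' activation thresholds and normal baseline fluorescence (truncated away
#' from zero). Deterministic under the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return Data frame: `roi_id`, `x_um`, `y_um`, `depth_um`, `threshold`,
#'   `f0_true`.
#' @export
sample_cells <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cells
  data.frame(
    roi_id = sprintf("cell_%04d", seq_len(n)),
    x_um = stats::runif(n, 0, config$fov_um[1]),
    y_um = stats::runif(n, 0, config$fov_um[2]),
    depth_um = stats::runif(n, config$depth_range_um[1],
                            config$depth_range_um[2]),
    threshold = stats::rlnorm(n, config$threshold_meanlog,
                              config$threshold_sdlog),
    f0_true = pmax(stats::rnorm(n, config$f0_mean, config$f0_sd),
                   0.1 * config$f0_mean))
}

#' Fluence fields of the synthetic exposure, one per energy density
#'
#' @param config A [synthetic_config()].
#' @return Named list of `fluence_field` objects (names = energies).
#' @export
synthetic_fluence_fields <- function(config) {
  fp <- beam_footprint(center = config$footprint_center_um,
                       major_axis_um = config$footprint_major_um,
                       minor_axis_um = config$footprint_minor_um,
                       orientation_deg = config$footprint_orientation_deg)
  fields <- lapply(config$energy_densities_J_cm2, function(ed)
    build_fluence_field(fp, pulse_energy(ed, fp$area_cm2), config$alpha_cm))
  stats::setNames(fields, format(config$energy_densities_J_cm2))
}

#' Ground-truth recruitment under the threshold model
#'
#' A cell responds at an energy density when the local fluence at its
#' (x, y, depth) position reaches its activation threshold; response
#' amplitude saturates as `a_max * (1 - exp(-(fluence - threshold) /
#' amp_scale))`. Because fluence is monotone in energy density, responder
#' sets are nested across energies. `true_peak` is the peak dF/F0 the
#' noiseless transient attains (`amplitude * transient_peak_factor`).
#'
#' @param cells Cell map from [sample_cells()].
#' @param config A [synthetic_config()].
#' @return Data frame, one row per cell x energy: `roi_id`,
#'   `energy_density`, `fluence_J_cm2`, `is_responder`, `amplitude`,
#'   `true_peak`.
#' @export
recruit <- function(cells, config) {
  fields <- synthetic_fluence_fields(config)
  pk <- transient_peak_factor(config$tau_rise, config$tau_decay)
  out <- lapply(seq_along(fields), function(i) {
    phi <- fluence(fields[[i]], cells$x_um, cells$y_um, cells$depth_um)
    resp <- phi >= cells$threshold
    amp <- ifelse(resp,
                  config$a_max *
                    (1 - exp(-(phi - cells$threshold) / config$amp_scale)),
                  0)
    data.frame(roi_id = cells$roi_id,
               energy_density = config$energy_densities_J_cm2[i],
               fluence_J_cm2 = phi, is_responder = resp,
               amplitude = amp, true_peak = amp * pk)
  })
  do.call(rbind, out)
}

#' Peak of the unit double-exponential transient kernel
#'
#' The transient envelope `g(t) = (1 - exp(-t / tau_rise)) *
#' exp(-t / tau_decay)` attains its maximum
#' `(td / (tr + td)) * (tr / (tr + td))^(tr / td)` at
#' `t = tau_rise * log(1 + tau_decay / tau_rise)`.
#'
#' @param tau_rise,tau_decay Kinetic time constants, seconds.
#' @return The kernel maximum (dimensionless, in (0, 1)).
#' @export
transient_peak_factor <- function(tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0)
  r <- tau_rise / (tau_rise + tau_decay)
  (1 - r) * r^(tau_rise / tau_decay)
}

#' Synthesise raw fluorescence traces from ground truth
#'
#' For every cell, energy and trial:
#' `F(t) = F0 (1 + A g(t - t0)) b(rec) + N(0, noise_sd * F0)`, where `g` is
#' the double-exponential kernel, `A` the ground-truth amplitude (trials
#' share `A`, noise is independent) and `b(rec) = exp(-bleach_rate *
#' (rec - 1))` the per-recording bleaching factor; recordings are ordered
#' energies-outer, trials-inner, as in an acquisition loop.
#'
#' @param cells Cell map from [sample_cells()].
#' @param truth Ground truth from [recruit()].
#' @param config A [synthetic_config()].
#' @return Long-format data frame `roi_id`, `trial`,
#'   `energy_density_J_cm2`, `frame`, `F` (the input schema of
#'   [analyze_traces()]).
#' @export
synthesize_traces <- function(cells, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  nf <- round(config$duration * config$frame_rate)
  tt <- (seq_len(nf) - 1) / config$frame_rate
  rel <- tt - config$stim_onset
  kern <- ifelse(rel > 0,
                 (1 - exp(-rel / config$tau_rise)) *
                   exp(-rel / config$tau_decay), 0)

  ne <- length(config$energy_densities_J_cm2)
  nt <- config$trials_per_energy
  nc <- nrow(cells)

  # amplitudes in (energy, cell) order -> column order cell-major below
  amp <- matrix(truth$amplitude, nrow = nc)      # cells x energies
  a_col <- as.vector(t(amp))                     # by cell: energies in order
  a_col <- rep(a_col, each = nt)                 # expand trials
  f0_col <- rep(cells$f0_true, each = ne * nt)
  rec <- rep(seq_len(ne * nt), times = nc)       # acquisition-loop index
  bleach <- exp(-config$bleach_rate * (rec - 1))

  ncol_tot <- nc * ne * nt
  m <- kern %o% a_col                            # frames x traces, dF/F part
  m <- 1 + m
  m <- sweep(m, 2, f0_col * bleach, "*")
  m <- m + matrix(stats::rnorm(nf * ncol_tot, 0,
                               config$noise_sd) * rep(f0_col, each = nf),
                  nrow = nf)

  data.frame(
    roi_id = rep(cells$roi_id, each = ne * nt * nf),
    trial = rep(rep(seq_len(nt), each = nf), times = nc * ne),
    energy_density_J_cm2 = rep(rep(config$energy_densities_J_cm2,
                                   each = nt * nf), times = nc),
    frame = rep(seq_len(nf), times = ncol_tot),
    F = as.vector(m))
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper: sample cells, compute ground-truth recruitment and
#' (optionally) synthesise the raw traces.
#'
#' @param config A [synthetic_config()].
#' @param with_traces Also synthesise raw traces (the expensive part).
#' @return List of class `synthetic_experiment`: `config`, `cells`,
#'   `truth`, and `traces` when requested.
#' @export
simulate_experiment <- function(config = synthetic_config(),
                                with_traces = TRUE) {
  cells <- sample_cells(config)
  truth <- recruit(cells, config)
  traces <- if (with_traces) synthesize_traces(cells, truth, config) else NULL
  structure(list(config = config, cells = cells, truth = truth,
                 traces = traces),
            class = "synthetic_experiment")
}

#' Simulate a multi-experiment study with planted field-of-view offsets
#'
#' Repeats [simulate_experiment()] with per-experiment seeds and a planted
#' footprint offset per experiment (emulating variation in fiber placement
#' across sessions); the offsets are the ground truth that field-of-view
#' alignment should recover.
#'
#' @param config Base [synthetic_config()].
#' @param n_experiments Number of experiments.
#' @param offsets_um Matrix `n_experiments x 2` of footprint offsets from
#'   the FoV centre; default small planted displacements.
#' @param n_cells Optional per-experiment cell counts (vector recycled).
#' @param with_traces Synthesise traces for each experiment.
#' @return List of class `synthetic_study`: `experiments` (named list),
#'   `offsets_um`, `config`.
#' @export
simulate_study <- function(config = synthetic_config(), n_experiments = 5,
                           offsets_um = NULL, n_cells = NULL,
                           with_traces = FALSE) {
  if (is.null(offsets_um)) {
    set.seed(config$seed + 97L)
    offsets_um <- matrix(stats::runif(2 * n_experiments, -25, 25),
                         ncol = 2)
  }
  stopifnot(nrow(offsets_um) == n_experiments)
  if (is.null(n_cells)) n_cells <- config$n_cells
  n_cells <- rep_len(n_cells, n_experiments)
  experiments <- lapply(seq_len(n_experiments), function(i) {
    cfg <- unclass(config)
    cfg$seed <- config$seed + i * 101L
    cfg$n_cells <- n_cells[i]
    cfg$footprint_center_um <- cfg$fov_um / 2 + offsets_um[i, ]
    cfg <- structure(cfg, class = "synthetic_config")
    simulate_experiment(cfg, with_traces = with_traces)
  })
  names(experiments) <- sprintf("exp%02d", seq_len(n_experiments))
  structure(list(experiments = experiments, offsets_um = offsets_um,
                 config = config),
            class = "synthetic_study")
}

#' Ground-truth response calls of a synthetic experiment or study
#'
#' Formats the generator's truth as a response-call table (the same schema
#' as [analyze_traces()] output, with `peak_dff` = the noiseless peak), for
#' feeding downstream aggregation directly.
#'
#' @param x A `synthetic_experiment` or `synthetic_study`.
#' @return Response-call data frame with `experiment_id`.
#' @export
ground_truth_calls <- function(x) {
  if (inherits(x, "synthetic_study")) {
    out <- lapply(names(x$experiments), function(nm) {
      cc <- ground_truth_calls(x$experiments[[nm]])
      cc$experiment_id <- nm
      cc
    })
    return(do.call(rbind, out))
  }
  stopifnot(inherits(x, "synthetic_experiment"))
  data.frame(experiment_id = "exp1",
             roi_id = x$truth$roi_id,
             energy_density = x$truth$energy_density,
             peak_dff = x$truth$true_peak,
             is_responder = x$truth$is_responder)
}

#' Cell map of a synthetic experiment or study with ground-truth classes
#'
#' @param x A `synthetic_experiment` or `synthetic_study`.
#' @return Data frame suitable for [align_fovs()].
#' @export
ground_truth_cell_map <- function(x) {
  build_cell_map(
    if (inherits(x, "synthetic_study"))
      do.call(rbind, lapply(names(x$experiments), function(nm) {
        cc <- x$experiments[[nm]]$cells
        cc$experiment_id <- nm
        cc
      }))
    else x$cells,
    ground_truth_calls(x))
}
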