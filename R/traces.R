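#' Frame indices covered by a time window
#'
#' Frames are indexed from 1; frame `i` carries the timestamp
#' `(i - 1) / frame_rate`. A half-open window `[start, end)` selects the
#' 0-based frames `floor(start * rate) .. floor(end * rate) - 1`, i.e. the
#' 1-based indices `floor(start * rate) + 1 .. floor(end * rate)`. At
#' 30.9375 Hz the default baseline window `[3, 4.5)` s selects 47 frames.
#'
#' @param window_s Numeric length-2, `c(start, end)` in seconds.
#' @param frame_rate Acquisition rate, Hz.
#' @param n_frames Optional trace length used to bound the indices.
#' @return Integer vector of 1-based frame indices.
#' @export
frame_indices <- function(window_s, frame_rate, n_frames = NULL) {
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1], frame_rate > 0)
  lo <- floor(window_s[1] * frame_rate) + 1
  hi <- floor(window_s[2] * frame_rate)
  if (!is.null(n_frames)) hi <- min(hi, n_frames)
  if (hi < lo) stop("window contains no frames")
  as.integer(lo):as.integer(hi)
}

#' Baseline fluorescence F0
#'
#' Arithmetic mean of the raw fluorescence over the pre-stimulus baseline
#' window (default 3.0-4.5 s).
#'
#' @param f Numeric vector of raw fluorescence values, one per frame.
#' @param frame_rate Acquisition rate, Hz.
#' @param window Baseline window in seconds, half-open on the right.
#' @return The baseline mean (same units as `f`).
#' @export
compute_f0 <- function(f, frame_rate, window = c(3, 4.5)) {
  idx <- frame_indices(window, frame_rate, length(f))
  if (length(idx) < 2) stop("baseline window contains fewer than 2 frames")
  f0 <- mean(f[idx])
  if (!is.finite(f0) || f0 <= 0) stop("degenerate baseline: F0 <= 0")
  f0
}

#' Normalise a fluorescence trace to dF/F0
#'
#' `dff = (F - F0) / F0`; the baseline noise scale `sigma_baseline` is the
#' sample standard deviation of dF/F0 over the baseline window. When `f0`
#' equals the baseline mean of `f` (the default), the baseline dF/F0 has
#' zero mean by construction.
#'
#' @param f Raw fluorescence vector.
#' @param frame_rate Acquisition rate, Hz.
#' @param f0 Baseline mean; computed from `f` with [compute_f0()] if `NULL`.
#' @param baseline_window Window used for F0 and sigma, seconds.
#' @return A list of class `dff_trace`: `dff`, `f0`, `sigma_baseline`,
#'   `frame_rate`, `baseline_window`, `n_trials_averaged`.
#' @export
compute_dff <- function(f, frame_rate, f0 = NULL, baseline_window = c(3, 4.5)) {
  if (is.null(f0)) f0 <- compute_f0(f, frame_rate, baseline_window)
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be > 0")
  dff <- (f - f0) / f0
  idx <- frame_indices(baseline_window, frame_rate, length(f))
  structure(list(dff = dff, f0 = f0,
                 sigma_baseline = stats::sd(dff[idx]),
                 frame_rate = frame_rate,
                 baseline_window = baseline_window,
                 n_trials_averaged = 1L),
            class = "dff_trace")
}

#' Average dF/F0 traces across trials
#'
#' Pointwise mean and sample standard deviation across repeated trials of
#' the same stimulus. Traces of unequal length are truncated to the
#' shortest with a warning. With a single trace the standard deviation is
#' reported as all zeros and flagged degenerate.
#'
#' @param traces List of numeric vectors or `dff_trace` objects.
#' @return List with `mean`, `sd`, `n_trials`, `degenerate_sd`.
#' @export
trial_average <- function(traces) {
  if (length(traces) == 0) stop("no traces to average")
  vecs <- lapply(traces, function(tr) if (inherits(tr, "dff_trace")) tr$dff else tr)
  lens <- lengths(vecs)
  if (length(unique(lens)) > 1) {
    warning("traces have unequal lengths; truncating to the shortest")
    vecs <- lapply(vecs, `[`, seq_len(min(lens)))
  }
  m <- do.call(cbind, vecs)
  n <- ncol(m)
  avg <- rowMeans(m)
  sdv <- if (n == 1) rep(0, nrow(m)) else
    sqrt(rowSums((m - avg)^2) / (n - 1))
  list(mean = avg, sd = sdv, n_trials = n, degenerate_sd = n == 1)
}

#' Classify a cell as responder by the 3-sigma peak criterion
#'
#' The peak dF/F0 is the maximum of the (typically trial-averaged) trace
#' inside the response window; `snr = peak / sigma_baseline`, and the cell
#' is a responder when `snr` strictly exceeds `threshold_k`. A zero
#' baseline sigma yields an undefined SNR: the call is flagged degenerate
#' and is never a responder.
#'
#' @param dff Numeric dF/F0 vector (or a `dff_trace`).
#' @param sigma_baseline Baseline noise scale used in the SNR denominator.
#' @param frame_rate Acquisition rate, Hz.
#' @param stim_onset Stimulus onset, seconds.
#' @param response_window_s Length of the response window after onset,
#'   seconds (half-open).
#' @param threshold_k SNR threshold (default 3).
#' @return A list of class `response_call`: `peak_dff`, `snr`,
#'   `is_responder`, `threshold_k`, `response_window`, `degenerate`.
#' @export
classify_response <- function(dff, sigma_baseline, frame_rate,
                              stim_onset = 5, response_window_s = 2,
                              threshold_k = 3) {
  if (inherits(dff, "dff_trace")) {
    if (missing(sigma_baseline)) sigma_baseline <- dff$sigma_baseline
    frame_rate <- dff$frame_rate
    dff <- dff$dff
  }
  stopifnot(threshold_k > 0, sigma_baseline >= 0)
  win <- c(stim_onset, stim_onset + response_window_s)
  idx <- frame_indices(win, frame_rate, length(dff))
  peak <- max(dff[idx])
  degenerate <- sigma_baseline == 0
  snr <- if (degenerate) NA_real_ else peak / sigma_baseline
  if (degenerate)
    warning("sigma_baseline is zero: SNR undefined, cell not classified as responder")
  structure(list(peak_dff = peak, snr = snr,
                 is_responder = !degenerate && snr > threshold_k,
                 threshold_k = threshold_k, response_window = win,
                 degenerate = degenerate),
            class = "response_call")
}

#' Analyse a table of raw fluorescence traces
#'
#' End-to-end responder classification for a long-format table of ROI
#' traces: per-trial F0 and dF/F0, trial averaging, baseline noise
#' estimation, peak extraction and the 3-sigma responder call, for every
#' ROI x energy-density combination.
#'
#' `sigma_mode` selects the SNR denominator: `"trials"` (default) pools the
#' per-trial baseline standard deviations (so the threshold is referenced
#' to single-recording noise, as when a response must exceed three baseline
#' standard deviations of the recordings themselves), `"average"` uses the
#' standard deviation of the trial-averaged trace's baseline (a sqrt(n)
#' lower noise floor, at the cost of a materially higher family-wise
#' false-positive rate of the peak-over-window criterion).
#'
#' @param traces Data frame with columns `roi_id`, `trial`,
#'   `energy_density_J_cm2`, `frame`, `F` (long format; all traces must
#'   have the same number of frames and trials per condition).
#' @param frame_rate Acquisition rate, Hz.
#' @param stim_onset Stimulus onset, seconds.
#' @param baseline_window Baseline window, seconds.
#' @param response_window_s Response window length after onset, seconds.
#' @param threshold_k SNR threshold.
#' @param sigma_mode `"trials"` or `"average"` (see Details).
#' @return Data frame with one row per ROI x energy: `roi_id`,
#'   `energy_density`, `n_trials`, `f0`, `sigma_baseline`, `peak_dff`,
#'   `snr`, `is_responder`.
#' @export
analyze_traces <- function(traces, frame_rate = 30.9375, stim_onset = 5,
                           baseline_window = c(3, 4.5),
                           response_window_s = 2, threshold_k = 3,
                           sigma_mode = c("trials", "average")) {
  sigma_mode <- match.arg(sigma_mode)
  need <- c("roi_id", "trial", "energy_density_J_cm2", "frame", "F")
  if (!all(need %in% names(traces)))
    stop("traces must have columns ", paste(need, collapse = ", "))
  if (baseline_window[2] > stim_onset)
    stop("baseline window must end at or before the stimulus onset")

  ord <- order(traces$roi_id, traces$energy_density_J_cm2, traces$trial,
               traces$frame)
  tr <- traces[ord, , drop = FALSE]
  key <- paste(tr$roi_id, tr$energy_density_J_cm2, tr$trial, sep = "\r")
  nf <- unique(table(key))
  if (length(nf) > 1) stop("all traces must have the same number of frames")
  nf <- as.integer(nf)

  m <- matrix(tr$F, nrow = nf)           # frames x (roi,energy,trial)
  meta <- tr[seq(1, nrow(tr), by = nf),
             c("roi_id", "energy_density_J_cm2", "trial")]
  gkey <- paste(meta$roi_id, meta$energy_density_J_cm2, sep = "\r")
  nt <- unique(table(gkey))
  if (length(nt) > 1) stop("unequal trial counts across ROI x energy groups")
  nt <- as.integer(nt)
  ng <- ncol(m) / nt

  bidx <- frame_indices(baseline_window, frame_rate, nf)
  if (length(bidx) < 2) stop("baseline window contains fewer than 2 frames")
  f0 <- colMeans(m[bidx, , drop = FALSE])
  if (any(f0 <= 0)) stop("degenerate baseline: F0 <= 0 for at least one trace")
  dffm <- sweep(sweep(m, 2, f0, "-"), 2, f0, "/")

  # per-trial baseline sd (baseline dff has zero mean by construction)
  bl <- dffm[bidx, , drop = FALSE]
  s2_trial <- colSums(sweep(bl, 2, colMeans(bl), "-")^2) / (length(bidx) - 1)

  arr <- array(dffm, dim = c(nf, nt, ng))
  meanm <- colSums(aperm(arr, c(2, 1, 3))) / nt   # frames x groups

  sigma <- if (sigma_mode == "trials")
    sqrt(colMeans(matrix(s2_trial, nrow = nt)))
  else
    apply(meanm[bidx, , drop = FALSE], 2, stats::sd)

  ridx <- frame_indices(c(stim_onset, stim_onset + response_window_s),
                        frame_rate, nf)
  peak <- apply(meanm[ridx, , drop = FALSE], 2, max)

  grp <- meta[seq(1, nrow(meta), by = nt), c("roi_id", "energy_density_J_cm2")]
  degenerate <- sigma == 0
  if (any(degenerate))
    warning(sum(degenerate), " group(s) with zero baseline sigma: SNR undefined")
  snr <- ifelse(degenerate, NA_real_, peak / sigma)
  data.frame(roi_id = grp$roi_id,
             energy_density = grp$energy_density_J_cm2,
             n_trials = nt,
             f0 = colMeans(matrix(f0, nrow = nt)),
             sigma_baseline = sigma,
             peak_dff = peak,
             snr = snr,
             is_responder = !degenerate & !is.na(snr) & snr > threshold_k,
             row.names = NULL)
}

#' Baseline stability across consecutive recordings
#'
#' Tracks photobleaching / tissue-state drift: each ROI's baseline F0 is
#' normalised to its value in the first recording, then averaged across
#' ROIs per recording with its standard error. The first entry is exactly 1.
#'
#' @param f0 Numeric matrix of baseline values, recordings (rows, in
#'   chronological order) x ROIs (columns); a vector is treated as a single
#'   ROI.
#' @return Data frame `recording_index`, `f0_normalized`, `sem`.
#' @export
baseline_stability <- function(f0) {
  if (is.vector(f0)) f0 <- matrix(f0, ncol = 1)
  stopifnot(is.matrix(f0), nrow(f0) >= 1)
  if (any(!is.finite(f0[1, ])) || any(f0[1, ] <= 0))
    stop("first-recording baseline must be positive")
  norm <- sweep(f0, 2, f0[1, ], "/")
  sem <- if (ncol(norm) == 1) rep(0, nrow(norm)) else
    apply(norm, 1, stats::sd) / sqrt(ncol(norm))
  data.frame(recording_index = seq_len(nrow(norm)),
             f0_normalized = rowMeans(norm),
             sem = sem)
}

#' Tukey boxplot outlier detection
#'
#' Flags values outside `[Q1 - k IQR, Q3 + k IQR]`, with quartiles taken as
#' the Tukey hinges (the convention behind the classic boxplot: medians of
#' the lower and upper halves, the overall median included in both halves
#' for odd n). Fewer than 4 values is a no-op with a warning.
#'
#' @param x Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return List with `values` (the kept values), `outlier` (logical flags,
#'   same length as `x`) and `fences`.
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))$outlier
#' @export
tukey_outliers <- function(x, k = 1.5) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 4) {
    warning("fewer than 4 values: outlier detection skipped")
    return(list(values = x, outlier = rep(FALSE, length(x)),
                fences = c(-Inf, Inf)))
  }
  fn <- stats::fivenum(x)
  iqr <- fn[4] - fn[2]
  fences <- c(fn[2] - k * iqr, fn[4] + k * iqr)
  out <- x < fences[1] | x > fences[2]
  list(values = x[!out], outlier = out, fences = fences)
}

#' Per-recording baseline matrix from a long trace table
#'
#' Baseline F0 of every ROI in every recording (one recording = one energy
#' x trial combination, in acquisition-loop order: energies outer, trials
#' inner) -- the input of [baseline_stability()].
#'
#' @param traces Long-format trace table (see [analyze_traces()]).
#' @param frame_rate Acquisition rate, Hz.
#' @param window Baseline window, seconds.
#' @return Numeric matrix recordings x ROIs, rows in chronological order.
#' @export
baseline_f0_matrix <- function(traces, frame_rate = 30.9375,
                               window = c(3, 4.5)) {
  nf <- max(traces$frame)
  bidx <- frame_indices(window, frame_rate, nf)
  sub <- traces[traces$frame %in% bidx, , drop = FALSE]
  eds <- sort(unique(sub$energy_density_J_cm2))
  rec <- paste(sprintf("%03d", match(sub$energy_density_J_cm2, eds)),
               sprintf("%03d", sub$trial))
  m <- tapply(sub$F, list(rec, sub$roi_id), mean)
  m[order(rownames(m)), , drop = FALSE]
}
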