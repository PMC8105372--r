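# Small in-code fixtures shared across test files.

# A long-format trace table for hand-built dF/F traces: one ROI, one energy,
# `trials` copies of the same underlying noiseless trace plus optional noise.
make_trace_table <- function(f, trials = 1, energy = 0.5, roi = "roiA",
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  nf <- length(f)
  do.call(rbind, lapply(seq_len(trials), function(tr)
    data.frame(roi_id = roi, trial = tr, energy_density_J_cm2 = energy,
               frame = seq_len(nf),
               F = f + stats::rnorm(nf, 0, noise_sd))))
}

# Response-call table built directly from a logical responder matrix
# (cells x energies), for aggregation tests that do not need traces.
make_calls <- function(resp, energies = c(0.35, 0.47, 0.58, 0.70),
                       peaks = NULL, experiment = "exp1") {
  n <- nrow(resp)
  if (is.null(peaks)) peaks <- matrix(0.05, n, length(energies))
  do.call(rbind, lapply(seq_along(energies), function(j)
    data.frame(experiment_id = experiment,
               roi_id = sprintf("c%03d", seq_len(n)),
               energy_density = energies[j],
               peak_dff = peaks[, j],
               is_responder = resp[, j])))
}

# Default-sized synthetic experiment shared by the heavier tests (cached so
# the expensive trace synthesis + analysis runs once per test session).
default_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ex <- simulate_experiment(synthetic_config(seed = 7, n_cells = 250))
      calls <- analyze_traces(ex$traces)
      cache <<- list(experiment = ex, calls = calls)
    }
    cache
  }
})
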