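test_that("cell sampling is deterministic under the seed and validates input", {
  cfg <- synthetic_config(seed = 17, n_cells = 294)
  a <- sample_cells(cfg)
  b <- sample_cells(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 294)
  expect_true(all(a$x_um >= 0 & a$x_um <= cfg$fov_um[1]))
  expect_true(all(a$threshold > 0))
  expect_error(synthetic_config(n_cells = 0))
  expect_error(synthetic_config(fov_um = c(0, 0)))
})

test_that("full simulation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 23, n_cells = 20)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$cells, ex2$cells)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(ex1$traces, ex2$traces)
})

test_that("recruitment is a nested threshold rule on the fluence field", {
  cfg <- synthetic_config(seed = 3, n_cells = 150)
  cells <- sample_cells(cfg)
  truth <- recruit(cells, cfg)
  fields <- synthetic_fluence_fields(cfg)
  # brute-force re-derivation of the flags from first principles
  for (i in seq_along(cfg$energy_densities_J_cm2)) {
    e <- cfg$energy_densities_J_cm2[i]
    phi <- fluence(fields[[i]], cells$x_um, cells$y_um, cells$depth_um)
    expect_identical(truth$is_responder[truth$energy_density == e],
                     phi >= cells$threshold)
  }
  # nestedness across energies for every cell, plus amplitude support
  resp <- matrix(truth$is_responder, nrow = nrow(cells))
  expect_true(all(resp[, 1] <= resp[, 2]))
  expect_true(all(resp[, 2] <= resp[, 3]))
  expect_true(all(resp[, 3] <= resp[, 4]))
  expect_true(all(truth$amplitude[!truth$is_responder] == 0))
  expect_true(all(truth$amplitude[truth$is_responder] > 0))
  # threshold sweep at a fixed position: nested for every theta
  f_at <- sapply(fields, function(ff) fluence(ff, 140, 130, 150))
  for (th in seq(0.01, 1.2, by = 0.01))
    expect_true(all(diff(f_at >= th) >= 0))
})

test_that("a central low-threshold cell responds to all energies, a remote one to none", {
  cfg <- synthetic_config(seed = 1, n_cells = 2, fov_um = c(1000, 1000))
  cells <- sample_cells(cfg)
  cells$x_um <- c(500, 0); cells$y_um <- c(500, 0)   # centre and far corner
  cells$depth_um <- c(100, 100)
  cells$threshold <- c(0.05, 0.05)
  truth <- recruit(cells, cfg)
  m <- matrix(truth$is_responder, nrow = 2)
  expect_true(all(m[1, ]))
  expect_false(any(m[2, ]))
})

test_that("transient kernel peak matches the closed form", {
  # numeric oracle: dense-grid maximum of (1 - e^(-t/tr)) e^(-t/td)
  for (p in list(c(0.08, 0.4), c(0.05, 1.0), c(0.3, 0.31))) {
    tr <- p[1]; td <- p[2]
    tt <- seq(0, 10 * td, by = 1e-4)
    g <- (1 - exp(-tt / tr)) * exp(-tt / td)
    expect_equal(transient_peak_factor(tr, td), max(g), tolerance = 1e-6)
  }
})

test_that("noiseless traces reproduce the analytic transient exactly", {
  cfg <- synthetic_config(seed = 2, n_cells = 12, noise_sd = 0)
  ex <- simulate_experiment(cfg)
  tr <- ex$traces
  # non-responders: F identically F0 (no bleaching by default)
  nonresp <- ex$truth$roi_id[ex$truth$energy_density == 0.70 &
                               !ex$truth$is_responder]
  if (length(nonresp) > 0) {
    id <- nonresp[1]
    f <- tr$F[tr$roi_id == id & tr$energy_density_J_cm2 == 0.70 & tr$trial == 1]
    expect_equal(f, rep(ex$cells$f0_true[ex$cells$roi_id == id], length(f)))
  }
  # responders: sampled peak equals amplitude x kernel evaluated on the grid
  rr <- ex$truth[ex$truth$energy_density == 0.70 & ex$truth$is_responder, ]
  id <- rr$roi_id[which.max(rr$amplitude)]
  f <- tr$F[tr$roi_id == id & tr$energy_density_J_cm2 == 0.70 & tr$trial == 1]
  f0 <- ex$cells$f0_true[ex$cells$roi_id == id]
  times <- (seq_along(f) - 1) / cfg$frame_rate - cfg$stim_onset
  kern <- ifelse(times > 0,
                 (1 - exp(-times / cfg$tau_rise)) * exp(-times / cfg$tau_decay), 0)
  A <- rr$amplitude[rr$roi_id == id]
  expect_equal(f, f0 * (1 + A * kern), tolerance = 1e-12)
  # the analytic true_peak bounds the sampled peak from above, tightly
  peak_sampled <- (max(f) - f0) / f0
  expect_lte(peak_sampled, rr$true_peak[rr$roi_id == id] + 1e-12)
  expect_equal(peak_sampled, rr$true_peak[rr$roi_id == id], tolerance = 0.01)
})

test_that("the pipeline recovers ground truth exactly at vanishing noise", {
  cfg <- synthetic_config(seed = 29, n_cells = 80, noise_sd = 1e-8)
  ex <- simulate_experiment(cfg)
  calls <- analyze_traces(ex$traces)
  tc <- ground_truth_calls(ex)
  m <- merge(calls, tc, by = c("roi_id", "energy_density"))
  expect_identical(m$is_responder.x, m$is_responder.y)
})

test_that("recovered responder fractions sit inside binomial CIs of the truth", {
  dx <- default_experiment()
  tc <- ground_truth_calls(dx$experiment)
  m <- merge(dx$calls, tc, by = c("roi_id", "energy_density"))
  for (e in unique(m$energy_density)) {
    sub <- m[m$energy_density == e, ]
    p <- mean(sub$is_responder.y)
    half <- 1.96 * sqrt(p * (1 - p) / nrow(sub))
    expect_gte(mean(sub$is_responder.x), p - half)
    expect_lte(mean(sub$is_responder.x), p + half)
  }
})

test_that("recovered peak amplitudes regress on truth with unit slope at low noise", {
  cfg <- synthetic_config(seed = 41, n_cells = 200, noise_sd = 5e-4)
  ex <- simulate_experiment(cfg)
  calls <- analyze_traces(ex$traces)
  tc <- ground_truth_calls(ex)
  m <- merge(calls, tc, by = c("roi_id", "energy_density"))
  m <- m[m$is_responder.y, ]
  fit <- lm(peak_dff.x ~ peak_dff.y, data = m)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("the recruitment curve is non-decreasing and saturating", {
  dx <- default_experiment()
  tc <- ground_truth_calls(dx$experiment)
  fr <- responder_fractions(tc)$summary
  fr <- fr[order(fr$energy_density), ]
  inc <- diff(fr$mean_pct)
  expect_true(all(inc >= 0))
  expect_lt(inc[3], inc[1])  # shrinking top increment: saturation
})

test_that("rendered movies round-trip through mask extraction", {
  cfg <- synthetic_config(seed = 6, n_cells = 4, fov_um = c(120, 120),
                          duration = 2, stim_onset = 1,
                          trials_per_energy = 1,
                          energy_densities_J_cm2 = 0.7)
  cells <- sample_cells(cfg)
  cells$x_um <- c(30, 90, 30, 90); cells$y_um <- c(30, 30, 90, 90)
  truth <- recruit(cells, cfg)
  traces <- synthesize_traces(cells, truth, cfg)
  movie <- file.path(tempdir(), "movie.tif")
  mask <- file.path(tempdir(), "mask.tif")
  meta <- render_movie(cells, traces, movie, mask, fov_um = cfg$fov_um)
  got <- extract_traces_tiff(movie, mask, meta$full_scale)
  nf <- max(traces$frame)
  for (i in seq_len(4)) {
    want <- traces$F[traces$roi_id == cells$roi_id[i]]
    have <- got$F[got$roi == i]
    expect_equal(have, want, tolerance = 5 * meta$full_scale / 65535 /
                   mean(want))
  }
  # empty cell list: background-only movie
  e <- render_movie(cells[0, ], traces[0, ], movie, mask,
                    fov_um = cfg$fov_um)
  img <- tiff::readTIFF(movie)
  expect_true(all(abs(img * e$full_scale - e$background) <
                    e$full_scale / 65535))
  # saturating frame clamps with a warning
  hot <- traces
  hot$F <- hot$F * 1000
  expect_warning(render_movie(cells, hot, movie, mask, fov_um = cfg$fov_um,
                              full_scale = meta$full_scale), "clamp")
})
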