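# inscal

Analysis of infrared neural stimulation (INS) evoked calcium responses in
two-photon GCaMP imaging.

INS excites cortical tissue by pulsed infrared light (here 1470 nm,
250 µs pulses at 200 Hz for 500 ms) absorbed by tissue water — a
photothermal mechanism that needs no exogenous chromophore. Whether and
where neurons respond is read out with a genetically encoded calcium
indicator (GCaMP6f) under a two-photon microscope. `inscal` is for
experimenters who have such recordings (or want a fully specified
synthetic stand-in) and need the standard population analysis:

* **Beam dosimetry** — the exposure ellipse of an obliquely incident
  multimode fiber (cone + Snell refraction), exposed area
  (A = πab/4), radiant exposure ↔ pulse energy (E = H·A), water
  absorption α = 4πk/λ with log-linear interpolation of k(λ), penetration
  depth 1/α, and a 3-D elliptical-Gaussian × Beer–Lambert fluence field.
* **Responder classification** — ΔF/F₀ = (F − F₀)/F₀ with a [3.0, 4.5) s
  baseline, trial averaging, and the 3σ criterion:
  SNR = (ΔF/F₀)ₚₑₐₖ / σ_F, responder ⇔ SNR > 3 (strict).
* **Dose–response** — per-experiment responder fractions with
  cross-experiment mean ± SEM, responder multiplicity (1×/2×/3×+4×),
  amplitude curves normalised to the top energy, pooled two-sample t
  tests, repeated-measures ANOVA + Bonferroni post-hocs, Tukey boxplot
  outlier removal.
* **Spatial extent** — field-of-view alignment on the multiple-responder
  distribution maxima, per-axis normal fits with
  FWHM = 2√(2 ln 2)·σ, and central-vs-peripheral membership in the
  exposure ellipse.
* **Synthetic generator** — deterministic experiments with known ground
  truth (fluence-threshold recruitment, saturating amplitudes,
  GCaMP6f-like transients, noise, bleaching), so the whole chain is
  testable without any data download; optional TIFF movie + ROI-mask
  rendering with exact round-trip extraction.

## Worked example

```r
library(inscal)

# Dosimetry of the default exposure (105 µm / NA 0.15 fiber at 35°)
dosimetry_report()
#> Footprint 244.5 x 167.9 um (0.0003223 cm2), 100 pulses
#> alpha = 24.815 cm-1, penetration depth 403 um
#> Pulse energies (uJ):
#>   0.35   0.47   0.58   0.70
#> 112.80 151.48 186.93 225.61

# Synthetic experiment -> responder calls -> dose-response
ex    <- simulate_experiment(synthetic_config(seed = 42, n_cells = 120))
calls <- analyze_traces(ex$traces)
responder_fractions(calls)$summary
#>   energy_density mean_pct sem_pct n_experiments
#> 1           0.35 21.66667       0             1
#> 2           0.47 26.66667       0             1
#> 3           0.58 30.83333       0             1
#> 4           0.70 37.50000       0             1
normalized_dose_response(calls)
#>   energy_density n_cells mean_peak sem_peak normalized_pct
#> 1           0.35      32    0.0410 0.004197           57.5
#> 2           0.47      32    0.0570 0.002992           79.9
#> 3           0.58      30    0.0676 0.001405           94.7
#> 4           0.70      29    0.0714 0.000614          100.0
```

Reading this: the projected footprint is within a few micrometres of the
246 × 168 µm exposure ellipse; 1470 nm light penetrates ~400 µm (the 1/e
depth), comfortably reaching Layer 2/3; recruitment grows with radiant
exposure and saturates at the top of the ladder; and among cells
responding to every energy above the weakest stimulus, peak amplitude
rises toward the 0.70 J cm⁻² reference (100%).

The end-to-end driver is `run_pipeline()` (YAML config, per-stage CSV/JSON
outputs, byte-reproducible under a fixed seed); a thin command-line
wrapper with `run` / `simulate` / `analyze` / `dosimetry` subcommands is
in `inst/cli/inscal.R`.

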