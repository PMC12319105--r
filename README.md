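# smflim

Wide-field **single-molecule fluorescence-lifetime imaging (smFLIM)** with an
alternating two-gate single-photon (SPAD) camera: a photon-level simulator,
the rapid-lifetime-determination estimator, the shot-noise photon-efficiency
theory, and the full single-molecule trace pipeline, as an R package.

## The problem and who this is for

Fluorescence lifetimes (τ, typically 0.3–5 ns for organic dyes) identify
fluorophores and sense their nanoscale environment, e.g. through FRET.
Conventional lifetime imaging (confocal TCSPC) measures one molecule at a
time. A time-gated SPAD camera instead images a whole field of view
(512 × 512 px, ~51 × 51 µm² at 100 nm pixels) and alternates **two gates**:
gate 0 opens at the start of the fluorescence decay and captures
`N₀ = S + B₀` photons per frame, gate 1 opens a delay `T` later and captures
`N₁ = S·e^(−T/τ) + B₁`. For mono-exponential single-molecule decays the
lifetime follows from one ratio:

    τ = T / ln( (N₀ − B₀) / (N₁ − B₁) )

Thousands of immobilised molecules are read out in parallel — 3000 molecules
in a 10 s movie replace 3000 s of sequential scanning, a 300× gain.

The package is for microscopists and method developers who want to (i)
analyse gated-camera single-molecule movies (detection → traces → step
segmentation → static/dynamic lifetimes → FRET), (ii) design acquisitions
(optimal gate delay vs signal-to-background ratio), or (iii) test analysis
code against a fully specified synthetic world.

### Core quantities

* **Pile-up correction** — a q-bit SPAD image is the sum of `2^q − 1` binary
  exposures, so counts saturate; the incident rate is recovered by
  `N = −ln(1 − N_meas/(2^q − 1))·(2^q − 1)`.
* **F-value** — photon efficiency `F = √N · Δτ/τ` (N = 2·N₀ photons per
  estimate; F = 1 is the TCSPC shot-noise limit). For the two-gate scheme,
  with normalized delay `u = T/τ` and background ratio `b = 1/SBR`:
  `F(u,b) = √(2(1+b)(1+b+e^u+b·e^{2u}))/u`. Minimising over `u` gives the
  design rule: `u* ≈ 2.22` at high SBR, falling towards `u* ≈ 1.11` when
  background dominates, with `F_min ≈ 2.04` at best.
* **FRET** — from an acceptor-photobleaching trace of one molecule:
  `E = 1 − τ_DA/τ_D` (lifetime) and `E = 1 − N_DA/N_D` (intensity).

## Worked example

Simulate a small FRET field (12 molecules, half donor-only at τ_D = 3.4 ns,
half donor–acceptor at τ_DA = 2.1 ns that de-quench when the acceptor
bleaches), then run the full pipeline:

```r
library(smflim)
cfg  <- acq_config(sensor_shape = c(96L, 96L), n_frame_pairs = 300L,
                   gate_delays_ns = c(0, 5.0))
plan <- fret_scene(12, tau_DA = 2.1, tau_D = 3.4, seed = 7, cfg = cfg,
                   background = background_model(30), fraction_da = 0.5,
                   bleach_time_scale = 100)
stack <- simulate_stack(plan)
res   <- analyze_stack(stack, simulate_dark_stack(plan, 100))
print(res)
#> smFLIM analysis: 12 molecule(s) detected
#>   classes: acceptor_donor = 2, rejected = 8, single_step = 2
#>   picked single-step lifetimes: Lifetime histogram: n = 2, mean = 3.266 ns, sd = 0.183 ns, mode = 3.15 ns, censored 0.0%

subset(res$results, class != "rejected",
       select = c(id, class, tau_ns, n_photons, f_empirical, E_lifetime, E_intensity))
#>    id          class   tau_ns n_photons f_empirical E_lifetime E_intensity
#> 3   3    single_step 3.395237  10165.45    2.507771         NA          NA
#> 5   5    single_step 3.136932  11277.51    3.536628         NA          NA
#> 7   7 acceptor_donor       NA        NA    6.048745  0.3739550   0.3635042
#> 11 11 acceptor_donor       NA        NA    5.893026  0.3604607   0.3962863
```

Reading this: two donor-only molecules pass the strict single-step
photobleaching selection and get static lifetimes near the planted 3.4 ns
from ~10⁴ photons each, with per-molecule F-values in the experimentally
observed 2–6 range; two molecules show the acceptor-then-donor bleaching
signature, and both FRET readouts agree near the planted
E = 1 − 2.1/3.4 = 0.382. The high rejection rate is the method working as
intended: the 15-photon step criterion rejects traces with spurious steps.

A command-line interface wraps the same chain:

```sh
Rscript -e 'quit(status = smflim::cli_main())' -- simulate --out /tmp/run --seed 5 --n-molecules 8
Rscript -e 'quit(status = smflim::cli_main())' -- analyze  --stack /tmp/run --out /tmp/run-results
Rscript -e 'quit(status = smflim::cli_main())' -- theory   --b 0,0.1,1
```

## Layout

* `R/` — model (`acq_config`, `emitter_truth`, `expected_gate_fraction`),
  estimators (`pileup_correct`, `two_gate_lifetime`, `empirical_f_value`,
  `fret_efficiencies`, `gate_scan_lifetime`), F-value theory
  (`f_value_theory`, `optimal_gate_delay`, `design_table`), simulator
  (`scene_plan`, `fret_scene`, `simulate_stack`), pipeline
  (`build_warm_pixel_mask`, `detect_molecules`, `extract_traces`,
  `detect_steps`, `classify_trace`, `static_lifetime`, `dynamic_lifetime`,
  `fret_from_segmentation`, `analyze_stack`), IO and CLI.
* `vignettes/smflim-methods.Rmd` — the model, parameter choices, numerical
  decisions and known limitations.
* `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code.
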