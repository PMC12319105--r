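---
title: "smflim: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smflim: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smflim)
```

This vignette is the package's own account of the science it implements:
the physical and statistical model, what every tunable parameter means and
why its default is what it is, what the synthetic-data generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The two-gate measurement model

A pulsed laser (26 MHz repetition, 38.46 ns period) excites immobilised
single molecules whose emission decays mono-exponentially with lifetime
$\tau$. A time-gated SPAD camera alternates two square detection gates of
equal width $W$ (6–12 ns): gate 0 opens at the start of the decay, gate 1
a delay $T$ later. The probability that an emitted photon falls inside a
gate at delay $d$ is

$$p(d) = e^{-d/\tau} - e^{-(d+W)/\tau},$$

implemented by `expected_gate_fraction()`. Two properties carry the whole
method:

* **Width independence.** For equal-width gates, $p(T)/p(0) = e^{-T/\tau}$
  for *every* $W$ — the ratio estimator needs no knowledge of the gate
  width. This holds to machine precision and is asserted as a property
  test.
* **Negligible wrap-around.** Decay spilling into the next laser period is
  bounded by $e^{-\text{period}/\tau} < 10^{-3}$ for $\tau \le 5$ ns, so it
  is ignored.

With $S$ signal photons per first-gate frame and backgrounds $B_0, B_1$,
the gates collect $N_0 = S + B_0$ and $N_1 = S e^{-T/\tau} + B_1$ photons,
and the rapid-lifetime-determination estimator (`two_gate_lifetime()`)
inverts the ratio:

$$\hat\tau = \frac{T}{\ln\left[(N_0 - B_0)/(N_1 - B_1)\right]}.$$

**Censoring, not clamping.** Shot noise can make a log argument
non-positive or the apparent rate negative. Such samples are returned as
censored values with a machine-readable reason
(`nonpositive_early`, `nonpositive_late`, `negative_rate`) and excluded
from downstream statistics, with the censored fraction reported. Clamping
would bias the spread of $\hat\tau$ and hence every F-value estimate.

**Assumptions.** Ideal square gates (the real ~200 ps rise time is not
modelled: the ratio estimator is exact for equal-width square gates, and
an edge model would add a parameter the data cannot constrain);
mono-exponential decays (true for well-behaved single molecules, not for
ensembles); no instrument-response deconvolution. The first gate delay is
taken as exactly 0 — the hardware description says only "at the very
beginning of the decay", and any common offset of both gates cancels in
the ratio.

## 2. The camera: binary frames, pile-up, warm pixels

A $q$-bit image is the sum of $2^q - 1$ one-bit exposures; each binary
exposure registers at most one photon per pixel. For a Poisson photon rate
$\lambda$ per frame the count is therefore

$$N_\text{meas} \sim \mathrm{Binomial}\!\left(2^q-1,\; 1 - e^{-\lambda/(2^q-1)}\right),$$

which saturates at $2^q - 1$. `pileup_correct()` inverts the mean of this
map,

$$N = -\ln\!\left(1 - \frac{N_\text{meas}}{2^q-1}\right)(2^q-1),$$

applied **per pixel per frame before box summation**. The operating
guidance is to stay below ~10% of saturation (25 counts at 8 bit), where
the correction is small and nearly unbiased; the simulator warns when the
expected rate exceeds half of saturation. At saturation the correction
diverges and no lifetime can be assigned: the scalar API raises an error,
while the pipeline treats a saturated pixel like a masked one (below).

**Warm pixels.** SPAD arrays have a small population of pixels with
anomalously high dark-count rates. `build_warm_pixel_mask()` estimates
per-pixel dark rates from a closed-shutter stack (≥ 10 frames) and masks
pixels above $10 \times \max(\text{median rate},\, 1/n_\text{frames})$.
The $1/n_\text{frames}$ floor is our design choice (the reference
calibration details are not public): with a finite dark stack the median
rate is typically exactly zero, and without the floor a single stray dark
count would mask a healthy pixel. A percentile-based threshold is exposed
as an alternative. Masked (and saturated) pixels are excluded from box
sums and the sum is rescaled by $25/(25 - n_\text{masked})$, preserving
the expected intensity at a small variance cost; affected traces carry a
`compensated` flag.

## 3. Photon-efficiency theory and gate-delay design

The figure of merit is $F = \sqrt{N}\,\Delta\tau/\tau$ with $N = 2 N_0$
photons available per estimate ($F = 1$: ideal TCSPC). Propagating Poisson
noise through the log-ratio estimator with known background
($b = B/S = 1/\mathrm{SBR}$, $u = T/\tau$) gives the closed form
implemented in `f_value_theory()`:

$$F(u, b) = \frac{\sqrt{2(1+b)\left(1+b+e^{u}+b\,e^{2u}\right)}}{u}.$$

$F$ diverges at $u \to 0$ (indistinguishable gates) and $u \to \infty$ (no
late photons) with a single minimum between. `optimal_gate_delay()`
minimises it on $u \in (0, 10]$ by bracketed scalar minimisation (relative
tolerance $10^{-6}$; delays beyond 10 lifetimes reject essentially all
photons). Two independent fixed-point oracles pin the endpoints in the
tests: at $b = 0$ stationarity reads $u = 2 + 2e^{-u}$ ($u^\star = 2.2177$,
$F_\min = 2.035$), and as $b \to \infty$ it reads $u = 1 + e^{-2u}$
($u^\star \to 1.1089$) — the optimum falls from "slightly above two
lifetimes" to "slightly above one lifetime" as background grows.

**Validity domain.** $F(u,b)$ is the *leading-order* (delta-method)
variance. Brute-force Monte-Carlo at realistic budgets ($S = 500$ photons
per first-gate frame) agrees within a few percent wherever the late gate
retains a clear signal, but departs at corners such as $u = 3, b = 2$,
where the late-gate signal ($S e^{-u} \approx 25$ photons) drowns in
background noise: a fifth of the samples censor, the surviving
distribution is truncated and skewed, and the measured $F$ falls tens of
percent below the formula. The acceptance suite asserts the nominal 5%
agreement across the full $\{1,2,3\}\times\{0,0.5,2\}$ grid and is
deliberately left red at those corners; the property suite asserts the
agreement where the linearisation holds and asserts the measured deviation
at the corners, so the regime boundary is itself under test.

## 4. The synthetic world

`scene_plan()` / `fret_scene()` / `simulate_stack()` generate gated frame
stacks with exactly the statistical structure the analysis assumes:

* **Emitters**: fixed sub-pixel positions, pixel-integrated Gaussian PSF
  (default $\sigma = 1$ px $\approx$ diffraction-limited at 100 nm pixels,
  truncated at $4\sigma$), brightness defined as signal photons per
  first-gate frame.
* **Counting**: per-pixel rates are converted to counts through the
  binomial binary-frame law above — so the pile-up correction is exercised
  non-trivially, not assumed away.
* **Photobleaching**: single-step, geometrically distributed waiting times
  (the discrete exponential; default scale 50 frame pairs ≈ 1 s at 50 Hz
  framing, the observed median-bleaching scale). A donor–acceptor molecule
  first loses its acceptor: the donor lifetime steps from $\tau_{DA}$ to
  $\tau_D$ and its brightness rises by $\tau_D/\tau_{DA}$ (pure dynamic
  quenching — the radiative rate is unchanged), which is what makes
  intensity- and lifetime-based FRET readouts agree; then the donor itself
  bleaches to background.
* **Background and defects**: spatially uniform background per gate
  (equal in both gates unless a fluorescent component is configured), warm
  pixels (default fraction 0.2%, rate 2 counts/frame — placeholders, since
  the reference statistics are unpublished), base dark rate $10^{-3}$.
* **Determinism**: every plan carries a mandatory seed; a stack is
  bit-identical under the same seed.

The FRET-scene donor brightness defaults to 150 photons per first-gate
frame while quenched — neither stated by the method description nor the
experiment, chosen once as a realistic level for a single immobilised
Cy3B donor at moderate excitation, with the useful property that true
bleach steps (+93/−243 photons) stand well clear of the 15-photon step
threshold.

**What the generator does not emulate** — hence what a green test does not
establish: blinking/triplet dynamics, spectral crosstalk, emitter motion
or drift, excitation-profile inhomogeneity, gate-edge shape, and
multi-exponential ensemble decays. Tests passing on this world validate
the estimator chain under its stated assumptions, not robustness to those
effects.

## 5. The trace pipeline and its parameters

`analyze_stack()` chains the reference analysis recipe; every threshold
below is exposed via `analysis_params()` and defaults to the operating
value.

| Parameter | Default | Units | Why |
|---|---|---|---|
| detection frames | 10 | gate-0 frames | average image for spot finding |
| LoG $\sigma$ range | 1–5 (10 scales) | px | diffraction-limited spots at 100 nm pixels |
| LoG threshold | 1 | corrected photons | response scale of the corrected average image |
| overlap | 0.9 | fraction | prune only near-coincident detections |
| box size | 5 × 5 | px | 0.25 µm²: contains the spot, avoids neighbours |
| step kernel | 10 | frames/side | difference-of-means changepoint response |
| min step | 15 | corrected photons | sensitivity/noise compromise |
| brightness cutoff | 50 per 20 ms | corrected photons | removes dim emitters; rescaled linearly in exposure |
| stability factor | 2 | shot-noise units | ON-state sd ≤ 2·√(mean) |
| guard | 2 | frames | step-time uncertainty margin (our choice) |
| bin factors | 2, 10 | pairs | 50 Hz → 25 Hz and 5 Hz series |

Numerical decisions worth knowing:

* **Detection** is multiscale Laplacian-of-Gaussian on the
  pile-up-corrected average of the first 10 gate-0 frames:
  scale-normalised responses, $3^3$-neighbourhood maxima over
  $(x, y, \sigma)$, quadratic sub-pixel interpolation, disk-overlap
  pruning. The reference "threshold of 1" comes without a stated
  normalisation; we define it on the corrected photon-count response
  scale and expose it. Convolutions are separable band-matrix products
  (BLAS), zero-padded at the borders.
* **Step detection** convolves $N_0(t)$ only (the high-signal gate) with
  the antisymmetric difference-of-means kernel; peaks need amplitude
  ≥ 15 photons and separation ≥ 10 frames; equal-height ties resolve to
  the earlier frame. Segment boundaries are shared with $N_1(t)$. Note a
  consequence of the fixed 15-photon threshold: above roughly 300
  corrected photons/frame it sits *inside* shot noise of the 10-frame
  means, so bright, long traces frequently show spurious steps and are
  rejected — the same strict selection that dominates rejection rates in
  real acquisitions. This is faithful behaviour, not a bug.
* **Classification**: `single_step` requires exactly one descending and
  no ascending step plus brightness and stability; `acceptor_donor`
  requires one ascending step followed by one descending one with both
  segments passing the same checks; anything else is `rejected` with the
  first failed criterion recorded. The per-gate background is the lowest
  segment mean after the last descending step (trailing-frame mean if the
  trace ends inside the last step's guard).
* **Segment means** strip a 2-frame guard on each side of every detected
  step (step times carry ±1–2 frames of kernel uncertainty); segments too
  short to guard use all frames and are flagged (`low_n`, `unreliable`).
* **Binned lifetime series** apply the estimator to *time-averaged*
  $N_0, N_1$ within each bin, never by averaging $\hat\tau$ samples — the
  log is nonlinear and averaging estimates would bias the result. The
  same applies to segment-averaged and static lifetimes.
* **Geometry conventions**: 0-based frame and pixel indices, origin
  top-left, $x$ = column; gate 0 acquired first in each pair; box centres
  rounded to integer pixels, box = centre ± 2 px; traces whose box lies
  within 5 px of another centre are flagged overlapping and excluded from
  "picked" statistics but kept in raw outputs.

## 6. Files and interfaces

Frames are written one lossless image per frame
(`frame000123_g0.png`), 8-bit PNG for $q \le 8$ (the camera's native
export format) or plain-text PGM; a concatenated PGM (P2) stream serves as
the single-file multi-page container, since no TIFF writer is available
in the supported environment. A flat YAML sidecar carries the acquisition
config (times in ns, exposure in ms) and is consumed identically by
simulator and analyser; unknown keys are rejected. Results are tab-
separated text with the config echo, its MD5 and the seed in header
comments. `cli_main()` exposes `simulate`, `analyze`, `theory` and
`calibrate-dcr` subcommands.

## 7. Known limitations

* The estimator chain assumes mono-exponential decays and ideal square
  gates; no IRF deconvolution, no bi-exponential unmixing within a spot.
* The F-value formula is asymptotic (Section 3); per-molecule empirical
  F-values from short segments scatter around it with
  $\mathrm{sd}(F)/F \approx 1/\sqrt{2 n_\text{samples}}$.
* Warm-pixel statistics are placeholders; real sensors should be
  calibrated with `calibrate-dcr` on a genuine dark stack.
* The LoG detector and step detector implement the reference recipe
  faithfully rather than improving on it: fixed thresholds mean the
  usable brightness window is bounded on both sides (dim molecules fail
  the 50-photon cutoff, very bright ones accumulate spurious steps).
* Multi-gate lifetime fitting (`gate_scan_lifetime()`) is a deliberately
  simple weighted log-linear fit for reference/calibration use, not a
  general decay fitter.
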