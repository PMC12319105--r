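#' Ground truth for one simulated emitter
#'
#' A mono-exponential emitter at a fixed sub-pixel position. Brightness `S`
#' is defined as the expected number of signal photons collected in the
#' first gate per frame (the natural observable of the two-gate scheme).
#' For donor-acceptor FRET emitters, `lifetime_post_step_ns` holds the
#' donor-only lifetime after acceptor photobleaching and
#' `t_acceptor_bleach` the frame-pair index of that step; `t_off` is the
#' final (donor) photobleaching pair index. After acceptor bleaching the
#' donor de-quenches: its brightness rises by the factor
#' `lifetime_post_step_ns / lifetime_ns` (pure dynamic quenching, radiative
#' rate unchanged), so the intensity trace shows the ascending step that
#' identifies these molecules.
#'
#' Frame-pair indices are 0-based; an emitter with `t_off = k` is dark from
#' pair `k` onwards.
#'
#' @param x,y Sub-pixel position (pixels, 0-based, x = column).
#' @param lifetime_ns Fluorescence lifetime tau (ns); for FRET emitters the
#'   quenched donor lifetime tau_DA.
#' @param brightness Expected signal photons per first-gate frame, S.
#' @param t_off Donor photobleaching frame-pair index (`Inf` = never).
#' @param lifetime_post_step_ns Optional donor-only lifetime tau_D (ns).
#' @param t_acceptor_bleach Optional acceptor photobleaching pair index.
#' @param psf_sigma_px Gaussian PSF standard deviation (pixels).
#' @return An object of class `emitter_truth`.
#' @export
emitter_truth <- function(x, y, lifetime_ns, brightness, t_off = Inf,
                          lifetime_post_step_ns = NULL,
                          t_acceptor_bleach = NULL,
                          psf_sigma_px = 1.0) {
  if (lifetime_ns <= 0) stopf("lifetime must be > 0")
  if (brightness < 0) stopf("brightness S must be >= 0")
  if (psf_sigma_px <= 0) stopf("psf_sigma_px must be > 0")
  if (!is.null(lifetime_post_step_ns) && lifetime_post_step_ns <= 0)
    stopf("post-step lifetime must be > 0")
  if (!is.null(t_acceptor_bleach) && !is.null(lifetime_post_step_ns)) {
    if (is.finite(t_off) && t_acceptor_bleach >= t_off)
      stopf("acceptor must bleach before the donor (t_acceptor_bleach < t_off)")
  }
  structure(list(
    x = as.numeric(x), y = as.numeric(y),
    lifetime_ns = as.numeric(lifetime_ns),
    brightness = as.numeric(brightness),
    t_off = as.numeric(t_off),
    lifetime_post_step_ns = lifetime_post_step_ns,
    t_acceptor_bleach = t_acceptor_bleach,
    psf_sigma_px = as.numeric(psf_sigma_px)
  ), class = "emitter_truth")
}

#' Background model per trace box
#'
#' Expected background photons per frame inside one 5x5 trace box for each
#' gate, plus the per-pixel spatial density used by the simulator. For a
#' time-constant (non-fluorescent) background and equal gate widths the two
#' gates see the same background, `B_o = B_1`; a fluorescent background
#' component makes them differ.
#'
#' @param B_o,B_1 Expected background photons per frame per trace box in
#'   gate 0 / gate 1.
#' @param spatial_density Background photons per pixel per frame (gate 0);
#'   defaults to `B_o / 25` (a 5x5 box).
#' @return An object of class `background_model`.
#' @export
background_model <- function(B_o = 0, B_1 = B_o,
                             spatial_density = B_o / 25) {
  if (B_o < 0 || B_1 < 0 || spatial_density < 0)
    stopf("background rates must be >= 0")
  structure(list(B_o = as.numeric(B_o), B_1 = as.numeric(B_1),
                 spatial_density = as.numeric(spatial_density)),
            class = "background_model")
}

#' Fraction of emitted photons captured by a square time gate
#'
#' For a mono-exponential decay with lifetime `tau`, the probability that a
#' photon emitted after one excitation pulse falls inside a square gate of
#' width `W` opened at `gate_delay` is
#' `exp(-gate_delay/tau) - exp(-(gate_delay + W)/tau)`.
#'
#' For equal-width gates at delays 0 and T the capture ratio is exactly
#' `exp(-T/tau)` for every W — the property that makes the two-gate ratio
#' estimator independent of the gate width.
#'
#' @param tau Lifetime (ns), > 0. Vectorised.
#' @param gate_delay Gate opening delay (ns), >= 0.
#' @param W Gate width (ns), > 0; `Inf` collects the whole tail.
#' @return Capture probability in \[0, 1\].
#' @examples
#' expected_gate_fraction(2.1, 2.5, 10)
#' expected_gate_fraction(2.1, 0, Inf)  # 1: the total decay integral
#' @export
expected_gate_fraction <- function(tau, gate_delay, W) {
  if (any(tau <= 0)) stopf("tau must be > 0")
  if (any(W <= 0)) stopf("gate width W must be > 0")
  if (any(gate_delay < 0)) stopf("gate delay must be >= 0")
  exp(-gate_delay / tau) - exp(-(gate_delay + W) / tau)
}

# Active (lifetime, brightness) of an emitter at frame-pair index t,
# applying the acceptor-bleach dequenching step and the final bleach.
emitter_state <- function(emitter, frame_index) {
  if (frame_index < 0) stopf("frame index must be >= 0")
  if (frame_index >= emitter$t_off)
    return(list(tau = emitter$lifetime_ns, S = 0))
  if (!is.null(emitter$t_acceptor_bleach) &&
      !is.null(emitter$lifetime_post_step_ns) &&
      frame_index >= emitter$t_acceptor_bleach) {
    boost <- emitter$lifetime_post_step_ns / emitter$lifetime_ns
    return(list(tau = emitter$lifetime_post_step_ns,
                S = emitter$brightness * boost))
  }
  list(tau = emitter$lifetime_ns, S = emitter$brightness)
}

#' Expected photons per frame in one gate for one emitter
#'
#' Expected box-level photon count for an emitter plus background, before
#' shot noise and camera saturation: `S_t * r_g(tau_t) + B_g`, where
#' `r_g` is the gate-g capture fraction normalised to gate 0 (so that `S`
#' keeps its meaning of signal photons per first-gate frame) and
#' `(tau_t, S_t)` is the emitter state at the requested frame pair
#' (acceptor-bleach dequenching and photobleaching applied).
#'
#' @param emitter An [emitter_truth()].
#' @param cfg An [acq_config()].
#' @param bg A [background_model()].
#' @param frame_index 0-based frame-pair index.
#' @param gate_index 0 or 1.
#' @return Expected photons per frame for the trace box.
#' @export
expected_counts <- function(emitter, cfg, bg, frame_index, gate_index) {
  stopifnot(inherits(emitter, "emitter_truth"), inherits(cfg, "acq_config"),
            inherits(bg, "background_model"))
  if (!(gate_index %in% c(0, 1))) stopf("gate_index must be 0 or 1")
  st <- emitter_state(emitter, frame_index)
  B <- if (gate_index == 0) bg$B_o else bg$B_1
  if (st$S == 0) return(B)
  W <- cfg$gate_width_ns
  d0 <- cfg$gate_delays_ns[1]
  dg <- cfg$gate_delays_ns[gate_index + 1L]
  ratio <- expected_gate_fraction(st$tau, dg, W) /
    expected_gate_fraction(st$tau, d0, W)
  st$S * ratio + B
}
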