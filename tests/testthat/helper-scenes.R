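# Shared fixture builders: everything is generated in code at test time.

# Small acquisition config for fast simulations; per-molecule physics
# (S, tau, T, exposure) stays at operating values, only the sensor shrinks.
tiny_cfg <- function(side = 48L, n_pairs = 100L, T_ns = 2.5, q = 8L,
                     exposure_ms = 20) {
  acq_config(sensor_shape = c(side, side), n_frame_pairs = n_pairs,
             gate_delays_ns = c(0, T_ns), bit_depth = q,
             exposure_ms = exposure_ms)
}

# One-emitter plan with no sensor defects (cleanest possible scene).
one_emitter_plan <- function(tau = 2.5, S = 500, B_box = 0, t_off = Inf,
                             seed = 1, side = 32L, n_pairs = 100L,
                             T_ns = 2.5, psf_sigma = 1.0, ...) {
  cfg <- tiny_cfg(side, n_pairs, T_ns)
  em <- emitter_truth(side / 2 - 0.5, side / 2 - 0.5, tau, S, t_off = t_off,
                      psf_sigma_px = psf_sigma)
  scene_plan(list(em), background_model(B_o = B_box), cfg, rng_seed = seed,
             warm_pixel_fraction = 0, base_dark_rate = 0, ...)
}

# Build a gate_trace directly from per-pair counts (box-level fixtures that
# skip the imaging layer).
make_trace <- function(N_o, N_1, id = 1L) {
  structure(list(id = id, x = 10, y = 10, N_o = N_o, N_1 = N_1,
                 box_size = 5L, overlapping = FALSE, compensated = FALSE,
                 n_masked = 0L),
            class = "gate_trace")
}

# Box-level Poisson trace of a bleaching emitter: signal S photons/frame
# until t_off (0-based pairs), background B per gate throughout.
poisson_trace <- function(S, tau, T_ns, B, n_pairs, t_off,
                          t_acc = NULL, tau_post = NULL) {
  sig <- rep(S, n_pairs)
  taus <- rep(tau, n_pairs)
  t <- seq_len(n_pairs) - 1
  if (!is.null(t_acc)) {
    sig[t >= t_acc] <- S * tau_post / tau
    taus[t >= t_acc] <- tau_post
  }
  sig[t >= t_off] <- 0
  make_trace(rpois(n_pairs, sig + B),
             rpois(n_pairs, sig * exp(-T_ns / taus) + B))
}

# Monte-Carlo empirical F from Poisson gate pairs: fixed signal S per
# first-gate frame with background B = b * S added on top (the experiment
# modulates background at fixed laser signal), background known and
# subtracted. N available per sample = 2 * N_o = 2 * S * (1 + b).
mc_f_poisson <- function(u, b, S = 500, reps = 1e4) {
  B <- b * S
  N0 <- rpois(reps, S + B)
  N1 <- rpois(reps, S * exp(-u) + B)
  est <- two_gate_lifetime(N0, N1, T_ns = u, B_o = B, B_1 = B)  # true tau = 1
  empirical_f_value(est$tau_ns, 2 * S * (1 + b))
}
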