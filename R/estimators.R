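#' Pile-up correction for q-bit single-photon counting
#'
#' A q-bit SPAD image is the sum of `2^q - 1` one-bit exposures, so a pixel
#' undercounts at high rates: each binary exposure registers at most one
#' photon. The measured count `N_measured` is mapped back to the expected
#' incident photon number by inverting the saturation law:
#' `N = -ln(1 - N_measured / (2^q - 1)) * (2^q - 1)`.
#'
#' The correction is strictly increasing and `>= N_measured`; it diverges at
#' saturation (`N_measured = 2^q - 1`), where no lifetime can be assigned.
#'
#' @param N_measured Measured counts (vectorised); `0 <= N_measured < 2^q - 1`.
#' @param q Bit depth.
#' @param on_saturate `"error"` (default) or `"censor"`, which returns `NA`
#'   for saturated entries instead of failing — used by the pipeline, where
#'   a saturated pixel is dropped like a masked one.
#' @return Corrected (real-valued) counts.
#' @examples
#' pileup_correct(25, 8)   # 26.31: the paper-regime operating ceiling
#' @export
pileup_correct <- function(N_measured, q, on_saturate = c("error", "censor")) {
  on_saturate <- match.arg(on_saturate)
  if (any(N_measured < 0, na.rm = TRUE)) stopf("measured counts must be >= 0")
  nmax <- 2^as.integer(q) - 1
  sat <- !is.na(N_measured) & N_measured >= nmax
  if (any(sat)) {
    if (on_saturate == "error")
      stopf("saturated pixel (N_measured >= 2^q - 1 = %d): lifetime cannot be assigned", nmax)
    N_measured[sat] <- NA_real_
  }
  -log(1 - N_measured / nmax) * nmax
}

censor_reasons <- c("nonpositive_early", "nonpositive_late", "negative_rate")

#' Two-gate rapid lifetime determination
#'
#' The core estimator of the two-gate scheme: with `N_o` photons in the
#' early gate and `N_1` in the gate delayed by `T`, after subtracting the
#' per-gate backgrounds,
#' `tau = T / ln((N_o - B_o) / (N_1 - B_1))`.
#'
#' Invalid logarithm arguments are censored, never clamped: the estimate is
#' `NA` with a machine-readable reason (`"nonpositive_early"`,
#' `"nonpositive_late"`, or `"negative_rate"` when the late gate outshines
#' the early one). Clamping would bias downstream F-value statistics.
#'
#' All count arguments are vectorised and recycled.
#'
#' @param N_o,N_1 Photons in gate 0 / gate 1 (pile-up corrected).
#' @param T_ns Gate-delay difference T (ns), > 0.
#' @param B_o,B_1 Background photons per frame in each gate.
#' @param f_value Optional F-value used to predict the relative error via
#'   `F / sqrt(N)` with `N = 2 * N_o`.
#' @return A `lifetime_estimate`: data.frame with columns `tau_ns`,
#'   `n_photons` (`= 2 * N_o`, the photons available to the scheme),
#'   `censored`, `censor_reason`, `rel_error`.
#' @examples
#' two_gate_lifetime(1000, 1000 * exp(-1), T_ns = 2.5)  # tau = T = 2.5 ns
#' @export
two_gate_lifetime <- function(N_o, N_1, T_ns, B_o = 0, B_1 = 0,
                              f_value = NULL) {
  if (T_ns <= 0) stopf("gate delay T must be > 0")
  n <- max(length(N_o), length(N_1), length(B_o), length(B_1))
  N_o <- rep_len(N_o, n); N_1 <- rep_len(N_1, n)
  B_o <- rep_len(B_o, n); B_1 <- rep_len(B_1, n)
  early <- N_o - B_o
  late <- N_1 - B_1
  reason <- rep(NA_character_, n)
  reason[late <= 0] <- "nonpositive_late"
  reason[early <= 0] <- "nonpositive_early"
  ok <- is.na(reason)
  reason[ok & early <= late] <- "negative_rate"
  bad <- !is.na(reason) | is.na(early) | is.na(late)
  tau <- rep(NA_real_, n)
  tau[!bad] <- T_ns / log(early[!bad] / late[!bad])
  nphot <- 2 * N_o
  rel <- if (is.null(f_value)) rep(NA_real_, n) else f_value / sqrt(nphot)
  structure(data.frame(
    tau_ns = tau, n_photons = nphot, censored = bad,
    censor_reason = reason, rel_error = rel,
    stringsAsFactors = FALSE
  ), class = c("lifetime_estimate", "data.frame"))
}

#' Empirical photon-efficiency F-value
#'
#' The shot-noise figure of merit `F = sqrt(N) * sd(tau) / mean(tau)`,
#' where `N` is the number of photons available per lifetime estimate
#' (`N = 2 * N_o` in the two-gate scheme: both gates together see at most
#' twice the early-gate signal). `F = 1` is the shot-noise limit reached by
#' ideal TCSPC; gated schemes are above it because they reject photons.
#'
#' The sample standard deviation (n - 1 denominator) is used — trace-level
#' sample sizes are small. Censored samples are excluded and counted.
#'
#' @param tau_samples Lifetime samples (ns); `NA` = censored.
#' @param N_per_sample Photons available per sample, > 0.
#' @return List with `F`, `n_used`, `n_censored`, `mean_tau`, `sd_tau`.
#' @export
empirical_f_value <- function(tau_samples, N_per_sample) {
  if (N_per_sample <= 0) stopf("N_per_sample must be > 0")
  tau <- tau_samples[!is.na(tau_samples)]
  n_cens <- length(tau_samples) - length(tau)
  if (length(tau) < 2)
    stopf("need >= 2 non-censored lifetime samples (%d available)", length(tau))
  list(F = sqrt(N_per_sample) * sd(tau) / mean(tau),
       n_used = length(tau), n_censored = n_cens,
       mean_tau = mean(tau), sd_tau = sd(tau))
}

#' Predicted relative lifetime error from an F-value
#'
#' `delta_tau / tau = F / sqrt(N)`: with 1000 photons available, each unit
#' of F costs about 3\% relative error.
#'
#' @param F F-value, > 0.
#' @param N Photons available, > 0.
#' @return Predicted relative error (fraction).
#' @export
predicted_rel_error <- function(F, N) {
  if (any(F <= 0) || any(N <= 0)) stopf("F and N must be > 0")
  F / sqrt(N)
}

#' Lifetime- and intensity-based FRET efficiencies
#'
#' From the quenched (donor + acceptor) and unquenched (donor-only)
#' observables of the same molecule: `E = 1 - tau_DA / tau_D` and
#' `E = 1 - N_DA / N_D` (first-gate photons). Noisy values may fall
#' slightly below 0 and are reported as-is, never clipped.
#'
#' @param tau_DA,tau_D Donor lifetimes with / without acceptor (ns).
#' @param N_DA,N_D First-gate photons per frame with / without acceptor.
#' @return A `fret_estimate` list: `E_lifetime`, `E_intensity`, and inputs.
#' @examples
#' fret_efficiencies(2.1, 3.4, 600, 1000)
#' @export
fret_efficiencies <- function(tau_DA, tau_D, N_DA = NA_real_, N_D = NA_real_) {
  if (tau_D <= 0) stopf("tau_D must be > 0")
  if (tau_DA <= 0) stopf("tau_DA must be > 0")
  E_int <- NA_real_
  if (!is.na(N_D)) {
    if (N_D <= 0) stopf("N_D must be > 0")
    E_int <- 1 - N_DA / N_D
  }
  structure(list(E_lifetime = 1 - tau_DA / tau_D, E_intensity = E_int,
                 tau_DA = tau_DA, tau_D = tau_D, N_DA = N_DA, N_D = N_D),
            class = "fret_estimate")
}

#' @export
print.fret_estimate <- function(x, ...) {
  cat(sprintf("FRET efficiency: E_lifetime = %.3f (tau %.2f -> %.2f ns)",
              x$E_lifetime, x$tau_DA, x$tau_D))
  if (!is.na(x$E_intensity))
    cat(sprintf("; E_intensity = %.3f", x$E_intensity))
  cat("\n")
  invisible(x)
}

#' Reference lifetime from a multi-delay gate scan
#'
#' Ground-truth lifetimes (e.g. of calibration beads) are measured by
#' stepping one gate across the decay and fitting the log-counts against
#' delay: for equal-width square gates the gate-width truncation factor is
#' delay-independent and cancels in the slope, so
#' `ln C(d) = const - d / tau`. A weighted least-squares fit with weights
#' proportional to the counts (the delta-method variance of `ln` of a
#' Poisson count is `1/C`) gives `tau = -1 / slope`.
#'
#' @param delays Gate delays (ns), at least 3 usable points spanning more
#'   than one lifetime.
#' @param counts Background-subtracted counts per delay; non-positive
#'   entries are dropped.
#' @return List with `tau_ns`, `slope`, `n_used`.
#' @export
gate_scan_lifetime <- function(delays, counts) {
  if (length(delays) != length(counts)) stopf("delays and counts differ in length")
  keep <- is.finite(counts) & counts > 0
  if (sum(keep) < 3) stopf("need >= 3 usable (positive-count) gate positions, have %d", sum(keep))
  d <- delays[keep]; C <- counts[keep]
  fit <- stats::lm.wfit(cbind(1, d), log(C), w = C)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    stopf("gate scan does not decay with delay; cannot fit a lifetime")
  tau <- -1 / slope
  if (diff(range(d)) <= tau)
    warnf("delay span (%.3g ns) does not exceed the fitted lifetime (%.3g ns); fit is poorly conditioned", diff(range(d)), tau)
  list(tau_ns = unname(tau), slope = unname(slope), n_used = sum(keep))
}
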