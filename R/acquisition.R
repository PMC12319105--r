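#' Acquisition configuration for a two-gate SPAD camera
#'
#' Bundles the instrument clock and geometry in one object: laser repetition
#' period, gate width, the two gate delays, bit depth of the reconstructed
#' images, exposure per gated frame, and the sensor geometry. All times are
#' in nanoseconds except the exposure, which is in milliseconds (the two
#' natural units of the experiment: the decay lives on ns, a frame on ms).
#'
#' The default repetition period corresponds to a 26 MHz pulsed laser
#' (1/26 MHz = 38.46 ns). The camera reconstructs a q-bit image from
#' `2^q - 1` binary exposures, so pixel values saturate at `2^q - 1`.
#'
#' @param repetition_period_ns Laser repetition period (ns). Default 1/26 MHz.
#' @param gate_width_ns Gate width W (ns); the hardware supports roughly
#'   6-12 ns, other positive values are accepted for simulation studies.
#' @param gate_delays_ns Length-2 numeric, delays of gate 0 and gate 1 (ns).
#'   The lifetime estimator only depends on the difference `T = delay1 -
#'   delay0`. Gate 0 sits at the very beginning of the decay by default.
#' @param bit_depth Integer q in 1..16; the camera modes of interest are 6
#'   and 8.
#' @param exposure_ms Exposure per gated frame (ms).
#' @param n_frame_pairs Number of gate-0/gate-1 frame pairs in an acquisition.
#' @param pixel_size_nm Pixel pitch at the sample (nm).
#' @param sensor_shape Length-2 integer, sensor rows x columns.
#'
#' @return An object of class `acq_config` (a validated list).
#' @examples
#' cfg <- acq_config(gate_delays_ns = c(0, 2.5), n_frame_pairs = 100)
#' gate_delay_T(cfg)
#' @export
acq_config <- function(repetition_period_ns = 1e3 / 26,
                       gate_width_ns = 10,
                       gate_delays_ns = c(0, 2.5),
                       bit_depth = 8L,
                       exposure_ms = 20,
                       n_frame_pairs = 500L,
                       pixel_size_nm = 100,
                       sensor_shape = c(512L, 512L)) {
  cfg <- structure(list(
    repetition_period_ns = as.numeric(repetition_period_ns),
    gate_width_ns = as.numeric(gate_width_ns),
    gate_delays_ns = as.numeric(gate_delays_ns),
    bit_depth = as.integer(bit_depth),
    exposure_ms = as.numeric(exposure_ms),
    n_frame_pairs = as.integer(n_frame_pairs),
    pixel_size_nm = as.numeric(pixel_size_nm),
    sensor_shape = as.integer(sensor_shape)
  ), class = "acq_config")
  validate_acq_config(cfg)
}

validate_acq_config <- function(cfg) {
  stopifnot(inherits(cfg, "acq_config"))
  if (length(cfg$gate_delays_ns) != 2L)
    stopf("gate_delays_ns must have exactly two entries (gate 0, gate 1)")
  if (cfg$gate_width_ns <= 0) stopf("gate width W must be > 0")
  if (any(cfg$gate_delays_ns < 0)) stopf("gate delays must be >= 0")
  if (diff(cfg$gate_delays_ns) <= 0)
    stopf("delay difference T = delay1 - delay0 must be > 0")
  if (cfg$gate_delays_ns[2] + cfg$gate_width_ns > cfg$repetition_period_ns + 1e-9)
    stopf("gate 1 (delay %.3g + W %.3g ns) extends past the repetition period (%.3g ns)",
          cfg$gate_delays_ns[2], cfg$gate_width_ns, cfg$repetition_period_ns)
  if (!(cfg$bit_depth %in% 1:16)) stopf("bit_depth q must be in 1..16")
  if (cfg$exposure_ms <= 0) stopf("exposure must be > 0")
  if (cfg$n_frame_pairs < 0) stopf("n_frame_pairs must be >= 0")
  if (length(cfg$sensor_shape) != 2L || any(cfg$sensor_shape < 1))
    stopf("sensor_shape must be two positive pixel counts")
  cfg
}

#' @rdname acq_config
#' @param cfg An `acq_config`.
#' @return `gate_delay_T()`: the gate-delay difference T (ns).
#' @export
gate_delay_T <- function(cfg) {
  stopifnot(inherits(cfg, "acq_config"))
  diff(cfg$gate_delays_ns)
}

#' @rdname acq_config
#' @return `max_count()`: the pixel saturation value `2^q - 1`.
#' @export
max_count <- function(cfg) {
  q <- if (inherits(cfg, "acq_config")) cfg$bit_depth else as.integer(cfg)
  2L^q - 1L
}

#' @rdname acq_config
#' @return `field_of_view_um()`: field-of-view side lengths (micrometres).
#' @export
field_of_view_um <- function(cfg) {
  stopifnot(inherits(cfg, "acq_config"))
  cfg$sensor_shape * cfg$pixel_size_nm / 1e3
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Two-gate acquisition config\n")
  cat(sprintf("  repetition period: %.3f ns (%.1f MHz)\n",
              x$repetition_period_ns, 1e3 / x$repetition_period_ns))
  cat(sprintf("  gate width W: %.2f ns; delays: %.2f / %.2f ns (T = %.2f ns)\n",
              x$gate_width_ns, x$gate_delays_ns[1], x$gate_delays_ns[2],
              gate_delay_T(x)))
  cat(sprintf("  bit depth: %d (saturation %d); exposure %.1f ms; %d pairs\n",
              x$bit_depth, max_count(x), x$exposure_ms, x$n_frame_pairs))
  fov <- field_of_view_um(x)
  cat(sprintf("  sensor: %d x %d px, %.0f nm pixels (%.1f x %.1f um)\n",
              x$sensor_shape[1], x$sensor_shape[2], x$pixel_size_nm,
              fov[1], fov[2]))
  invisible(x)
}

#' Read and write acquisition configs as flat key-value files
#'
#' The sidecar format is a flat YAML mapping (times in ns, exposure in ms),
#' shared between simulator and analyzer so both sides agree on the clock.
#' Unknown keys are rejected.
#'
#' @param cfg An `acq_config`.
#' @param path File path.
#' @return `read_acq_config()` returns an `acq_config`; `write_acq_config()`
#'   returns `path` invisibly.
#' @export
write_acq_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "acq_config"))
  flat <- list(
    repetition_period_ns = cfg$repetition_period_ns,
    gate_width_ns = cfg$gate_width_ns,
    gate_delay0_ns = cfg$gate_delays_ns[1],
    gate_delay1_ns = cfg$gate_delays_ns[2],
    bit_depth = cfg$bit_depth,
    exposure_ms = cfg$exposure_ms,
    n_frame_pairs = cfg$n_frame_pairs,
    pixel_size_nm = cfg$pixel_size_nm,
    sensor_rows = cfg$sensor_shape[1],
    sensor_cols = cfg$sensor_shape[2]
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_acq_config
#' @export
read_acq_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  flat <- yaml::read_yaml(path)
  known <- c("repetition_period_ns", "gate_width_ns", "gate_delay0_ns",
             "gate_delay1_ns", "bit_depth", "exposure_ms", "n_frame_pairs",
             "pixel_size_nm", "sensor_rows", "sensor_cols")
  extra <- setdiff(names(flat), known)
  if (length(extra)) stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(flat))
  if (length(missing)) stopf("missing config keys: %s", paste(missing, collapse = ", "))
  acq_config(
    repetition_period_ns = flat$repetition_period_ns,
    gate_width_ns = flat$gate_width_ns,
    gate_delays_ns = c(flat$gate_delay0_ns, flat$gate_delay1_ns),
    bit_depth = flat$bit_depth,
    exposure_ms = flat$exposure_ms,
    n_frame_pairs = flat$n_frame_pairs,
    pixel_size_nm = flat$pixel_size_nm,
    sensor_shape = c(flat$sensor_rows, flat$sensor_cols)
  )
}
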