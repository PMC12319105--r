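#' Build a warm-pixel mask from a dark-calibration stack
#'
#' SPAD arrays carry a population of "warm" pixels with anomalously high
#' dark count rates; they must be excluded before trace extraction. The
#' per-pixel mean dark rate is computed from a closed-shutter stack and
#' thresholded.
#'
#' Default rule: mask pixels whose rate exceeds
#' `rate_factor * max(median(rate), 1 / n_frames)`. The `1 / n_frames`
#' floor keeps the rule meaningful when the median dark rate is exactly
#' zero at finite stack length (otherwise a single stray dark count would
#' mask a healthy pixel). Alternatively pass `threshold_percentile` to mask
#' every pixel at or above that rate percentile.
#'
#' @param dark_stack A `gated_stack` from a dark acquisition, >= 10 frames.
#' @param threshold_percentile Optional percentile in \[0, 1\]; pixels with
#'   rate `>=` that quantile are masked.
#' @param rate_factor Multiplier for the default median-based rule.
#' @return A `pixel_mask`: list with `mask` (logical matrix, `TRUE` =
#'   excluded), `rates` (dark counts per frame), `threshold`.
#' @export
build_warm_pixel_mask <- function(dark_stack, threshold_percentile = NULL,
                                  rate_factor = 10) {
  stopifnot(inherits(dark_stack, "gated_stack"))
  n_frames <- dim(dark_stack$frames)[3]
  if (n_frames < 10) stopf("dark stack must have >= 10 frames, has %d", n_frames)
  rates <- apply(dark_stack$frames, c(1, 2), mean)
  if (!is.null(threshold_percentile)) {
    if (threshold_percentile < 0 || threshold_percentile > 1)
      stopf("threshold_percentile must be in [0, 1]")
    thr <- quantile(rates, threshold_percentile, names = FALSE)
    mask <- rates >= thr
  } else {
    thr <- rate_factor * max(median(rates), 1 / n_frames)
    mask <- rates > thr
  }
  if (all(mask)) stopf("warm-pixel threshold masks every pixel; calibration is unusable")
  structure(list(mask = mask, rates = rates, threshold = thr),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("Pixel mask: %d / %d pixels excluded (threshold %.4g counts/frame)\n",
              sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}
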