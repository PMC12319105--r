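#' Extract per-molecule two-gate box traces
#'
#' For each detected centre, sums pile-up-corrected photon counts inside a
#' `box_size` x `box_size` pixel box (centre rounded to the nearest integer
#' pixel) separately for gate-0 and gate-1 frames, giving the per-pair time
#' series `N_o(t)` and `N_1(t)`.
#'
#' Warm (masked) and saturated pixels are excluded from the sum and the box
#' total is rescaled by `box_area / n_valid` so the expected intensity is
#' preserved (at a slight variance cost); such traces carry a
#' `compensated` flag. Traces whose box would cross the sensor border are
#' dropped with a reason. Traces with another centre within 5 px are
#' flagged `overlapping` (kept, but excluded from "picked" statistics).
#'
#' @param stack A `gated_stack`.
#' @param centers data.frame with 0-based `x`, `y` columns (e.g. from
#'   [detect_molecules()]).
#' @param mask Optional [build_warm_pixel_mask()] result.
#' @param box_size Odd box side in pixels (default 5: 0.25 um^2 at 100 nm
#'   pixels).
#' @return List of `gate_trace` objects; dropped centres are reported in
#'   the `dropped` attribute.
#' @export
extract_traces <- function(stack, centers, mask = NULL, box_size = 5) {
  stopifnot(inherits(stack, "gated_stack"))
  if (box_size %% 2 != 1) stopf("box_size must be odd")
  if (!is.null(mask)) stopifnot(inherits(mask, "pixel_mask"))
  nr <- dim(stack$frames)[1]; nc <- dim(stack$frames)[2]
  q <- stack$cfg$bit_depth
  half <- (box_size - 1L) %/% 2L
  g0 <- which(stack$gate_index == 0L)
  g1 <- which(stack$gate_index == 1L)
  if (length(g0) != length(g1)) stopf("stack gate frames are not paired")

  n <- nrow(centers)
  traces <- list()
  dropped <- data.frame(id = integer(), reason = character())
  for (i in seq_len(n)) {
    r0 <- round(centers$y[i]) + 1L  # 1-based matrix row
    c0 <- round(centers$x[i]) + 1L
    if (r0 - half < 1 || r0 + half > nr || c0 - half < 1 || c0 + half > nc) {
      dropped <- rbind(dropped, data.frame(id = i, reason = "border"))
      next
    }
    rows <- (r0 - half):(r0 + half)
    cols <- (c0 - half):(c0 + half)
    boxmask <- if (is.null(mask)) matrix(FALSE, box_size, box_size)
               else mask$mask[rows, cols]
    overlap <- FALSE
    if (n > 1) {
      d <- sqrt((centers$x[-i] - centers$x[i])^2 +
                (centers$y[-i] - centers$y[i])^2)
      overlap <- any(d <= 5)
    }
    sum_gate <- function(frame_ids) {
      vapply(frame_ids, function(f) {
        px <- pileup_correct(stack$frames[rows, cols, f], q,
                             on_saturate = "censor")
        px[boxmask] <- NA_real_
        nv <- sum(!is.na(px))
        if (nv == 0) return(NA_real_)
        sum(px, na.rm = TRUE) * length(px) / nv
      }, numeric(1))
    }
    N_o <- sum_gate(g0)
    N_1 <- sum_gate(g1)
    traces[[length(traces) + 1L]] <- structure(list(
      id = i, x = centers$x[i], y = centers$y[i],
      N_o = N_o, N_1 = N_1, box_size = box_size,
      overlapping = overlap,
      compensated = any(boxmask),
      n_masked = sum(boxmask)
    ), class = "gate_trace")
  }
  attr(traces, "dropped") <- dropped
  traces
}

#' Detect intensity steps by step-kernel convolution
#'
#' Convolves the trace with an antisymmetric difference-of-means kernel —
#' the response at changepoint `t` is the mean of the next
#' `kernel_halfwidth` frames minus the mean of the previous
#' `kernel_halfwidth` frames — and returns signed local extrema with
#' amplitude at least `min_step`, separated by at least `min_separation`
#' frames. Ties between equal-height peaks are broken toward the earlier
#' frame.
#'
#' @param trace Numeric intensity series (corrected photons per frame).
#' @param kernel_halfwidth Frames averaged on each side (default 10: the
#'   10-frame kernel).
#' @param min_step Minimum absolute step amplitude in corrected photons
#'   (default 15).
#' @param min_separation Minimum frames between accepted steps (default:
#'   the kernel halfwidth).
#' @return data.frame with `time` (0-based index of the first frame of the
#'   new level), `sign` (+1 ascending, -1 descending) and `amplitude`
#'   (signed response height); zero rows when no step is found.
#' @export
detect_steps <- function(trace, kernel_halfwidth = 10, min_step = 15,
                         min_separation = kernel_halfwidth) {
  kh <- as.integer(kernel_halfwidth)
  n <- length(trace)
  if (n < 2 * kh) stopf("trace too short for step detection (%d < %d frames)", n, 2 * kh)
  if (any(is.na(trace))) trace[is.na(trace)] <- median(trace, na.rm = TRUE)
  cs <- c(0, cumsum(trace))
  # response at changepoint k (new level starts at 0-based frame k)
  ks <- kh:(n - kh)
  resp <- (cs[ks + kh + 1] - cs[ks + 1]) / kh - (cs[ks + 1] - cs[ks - kh + 1]) / kh
  a <- abs(resp)
  m <- length(a)
  is_peak <- vapply(seq_len(m), function(i) {
    lo <- max(1, i - 1); hi <- min(m, i + 1)
    a[i] >= max(a[lo:hi]) && a[i] >= min_step
  }, logical(1))
  cand <- which(is_peak)
  if (!length(cand))
    return(data.frame(time = integer(), sign = integer(), amplitude = numeric()))
  # strongest first; earlier frame wins ties; enforce separation
  cand <- cand[order(-a[cand], cand)]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(accepted - i) >= min_separation))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  data.frame(time = ks[accepted],
             sign = as.integer(sign(resp[accepted])),
             amplitude = resp[accepted])
}

# Mean of a segment [start, end) of a series with a guard margin stripped
# from each end (detected step times carry ~1-2 frames of uncertainty).
# Falls back to the full segment when it is too short to guard.
guarded_mean <- function(x, start, end, guard = 2L) {
  if (end - start > 2L * guard) {
    start <- start + guard; end <- end - guard
  }
  if (end <= start) return(NA_real_)
  mean(x[(start + 1L):end], na.rm = TRUE)  # 0-based [start, end)
}

segment_table <- function(trace, steps, guard = 2L) {
  n <- length(trace$N_o)
  bounds <- c(0L, sort(steps$time), n)
  data.frame(
    start = head(bounds, -1), end = tail(bounds, -1),
    mean_No = vapply(seq_len(length(bounds) - 1), function(i)
      guarded_mean(trace$N_o, bounds[i], bounds[i + 1], guard), numeric(1)),
    mean_N1 = vapply(seq_len(length(bounds) - 1), function(i)
      guarded_mean(trace$N_1, bounds[i], bounds[i + 1], guard), numeric(1))
  )
}

#' Classify a two-gate trace from its detected steps
#'
#' Applies the single-molecule selection criteria to a segmented trace:
#'
#' * `single_step` — exactly one descending and no ascending step, with the
#'   ON segment passing a brightness cutoff (default 50 corrected signal
#'   photons per 20 ms frame, rescaled linearly for other exposures) and an
#'   intensity stability criterion (sample sd of `N_o` over the ON segment
#'   at most `stability_factor` times the shot-noise limit
#'   `sqrt(segment mean)`).
#' * `acceptor_donor` — exactly one ascending step followed by one
#'   descending step, both segments passing brightness and stability: the
#'   acceptor-photobleaching signature.
#' * `rejected` — anything else; the first failed criterion is recorded.
#'
#' The per-gate background is the lowest segment mean after the last
#' descending step (or the trailing-frame mean when the trace ends inside
#' the last step's guard).
#'
#' @param trace A `gate_trace`.
#' @param steps Result of [detect_steps()] on `trace$N_o`.
#' @param exposure_ms Exposure per frame, used to rescale the brightness
#'   cutoff.
#' @param brightness_cutoff Minimum ON-state signal (corrected photons per
#'   20 ms frame).
#' @param stability_factor Allowed ON fluctuations in shot-noise units.
#' @param guard Frames stripped around each step for segment means.
#' @return A `trace_segmentation`: list with `class`, `reason`, `t_up`,
#'   `t_down`, `t_off`, `segments`, `B_o`, `B_1`.
#' @export
classify_trace <- function(trace, steps, exposure_ms = 20,
                           brightness_cutoff = 50, stability_factor = 2,
                           guard = 2L) {
  stopifnot(inherits(trace, "gate_trace"))
  n <- length(trace$N_o)
  segs <- segment_table(trace, steps, guard)
  ups <- steps$time[steps$sign > 0]
  downs <- steps$time[steps$sign < 0]
  t_off <- if (length(downs)) max(downs) else NA_integer_
  cutoff <- brightness_cutoff * exposure_ms / 20

  # background: lowest segment mean after the last descending step
  if (length(downs)) {
    after <- segs[segs$start >= max(downs), , drop = FALSE]
    if (nrow(after) && any(!is.na(after$mean_No))) {
      k <- which.min(after$mean_No)
      B_o <- after$mean_No[k]; B_1 <- after$mean_N1[k]
    } else {  # trace ends inside the guard: trailing-frame mean
      tailn <- min(5L, n)
      B_o <- mean(tail(trace$N_o, tailn), na.rm = TRUE)
      B_1 <- mean(tail(trace$N_1, tailn), na.rm = TRUE)
    }
  } else {
    tailn <- min(5L, n)
    B_o <- mean(tail(trace$N_o, tailn), na.rm = TRUE)
    B_1 <- mean(tail(trace$N_1, tailn), na.rm = TRUE)
  }

  check_segment <- function(start, end) {
    x <- trace$N_o[(start + 1L):end]
    x <- x[!is.na(x)]
    if (!length(x)) return("dim")
    m <- mean(x)
    if (m - B_o < cutoff) return("dim")
    if (length(x) >= 2 && sd(x) > stability_factor * sqrt(m)) return("unstable")
    NA_character_
  }

  label <- "rejected"; reason <- NA_character_
  if (length(downs) == 0) {
    reason <- "no_down_step"
  } else if (length(downs) == 1 && length(ups) == 0) {
    reason <- check_segment(0L, t_off)
    if (is.na(reason)) label <- "single_step"
  } else if (length(downs) == 1 && length(ups) == 1 && ups[1] < downs[1]) {
    reason <- check_segment(0L, ups[1])
    if (is.na(reason)) reason <- check_segment(ups[1], downs[1])
    if (is.na(reason)) label <- "acceptor_donor"
  } else if (length(downs) > 1) {
    reason <- "multiple_down_steps"
  } else {
    reason <- "wrong_step_pattern"
  }

  structure(list(
    class = label, reason = reason,
    t_up = ups, t_down = downs, t_off = t_off,
    segments = segs, B_o = B_o, B_1 = B_1,
    n_frames = n, guard = guard
  ), class = "trace_segmentation")
}

#' @export
print.trace_segmentation <- function(x, ...) {
  cat(sprintf("Trace segmentation: class %s", x$class))
  if (!is.na(x$reason)) cat(sprintf(" (%s)", x$reason))
  cat(sprintf("; %d up / %d down step(s); B_o = %.2f, B_1 = %.2f\n",
              length(x$t_up), length(x$t_down), x$B_o, x$B_1))
  invisible(x)
}
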