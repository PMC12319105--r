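#' Analysis parameter set with the canonical defaults
#'
#' One place for every tunable of the trace pipeline; each default is the
#' operating value of the method (LoG sigma 1-5 px, response threshold 1,
#' overlap 0.9, 5x5 box, 10-frame step kernel, 15-photon step amplitude,
#' 50 photons per 20 ms brightness cutoff, 2x shot-noise stability). Pass
#' overrides as named arguments.
#'
#' @param ... Named overrides of the defaults; unknown names are rejected.
#' @return A named list of parameters (class `analysis_params`).
#' @export
analysis_params <- function(...) {
  p <- list(
    n_mean_frames = 10L,      # gate-0 frames averaged for detection
    sigma_min = 1, sigma_max = 5, n_sigma = 10L,
    log_threshold = 1, overlap = 0.9,
    box_size = 5L,
    kernel_halfwidth = 10L, min_step = 15,
    brightness_cutoff = 50,   # corrected photons per 20 ms frame
    stability_factor = 2,
    guard = 2L,
    bin_factors = c(2L, 10L),
    hist_binwidth = 0.1, hist_range = c(0, 10),
    mask_rate_factor = 10
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stopf("unknown analysis parameter(s): %s", paste(bad, collapse = ", "))
  structure(modifyList(p, ov), class = "analysis_params")
}

# Corrected detection image: average of the first n gate-0 frames, pile-up
# corrected; masked/saturated pixels are filled with the image median so
# they neither seed nor suppress blobs.
detection_image <- function(stack, mask = NULL, n_mean_frames = 10L) {
  g0 <- which(stack$gate_index == 0L)
  use <- head(g0, n_mean_frames)
  m <- apply(stack$frames[, , use, drop = FALSE], c(1, 2), mean)
  sat <- m >= max_count(stack$cfg)
  m[sat] <- NA
  m[!sat] <- pileup_correct(m[!sat], stack$cfg$bit_depth, on_saturate = "censor")
  if (!is.null(mask)) m[mask$mask] <- NA
  m[is.na(m)] <- median(m, na.rm = TRUE)
  m
}

#' Run the full single-molecule FLIM pipeline on a gated stack
#'
#' The complete analysis chain: optional warm-pixel masking from a dark
#' stack, Laplacian-of-Gaussian detection on the corrected average of the
#' first gate-0 frames, 5x5-box trace extraction with pile-up correction,
#' step segmentation and classification of every trace, static lifetimes
#' for `single_step` molecules, dynamic lifetime traces and per-molecule
#' F-values for all, and FRET efficiencies for `acceptor_donor` molecules.
#'
#' "Picked" molecules (class `single_step`, no box overlap) feed the
#' summary lifetime histogram.
#'
#' @param stack A `gated_stack` (real or simulated).
#' @param dark_stack Optional dark-calibration `gated_stack`.
#' @param params An [analysis_params()] set.
#' @return An `smflim_results` object: list with `results` (one row per
#'   molecule), `traces`, `segmentations`, `lifetime_traces`,
#'   `fret` (per-molecule `fret_estimate` or `NULL`), `centers`, `mask`,
#'   `histogram` (picked static lifetimes; `NULL` if none), `params`.
#' @export
analyze_stack <- function(stack, dark_stack = NULL, params = analysis_params()) {
  stopifnot(inherits(stack, "gated_stack"), inherits(params, "analysis_params"))
  mask <- if (!is.null(dark_stack))
    build_warm_pixel_mask(dark_stack, rate_factor = params$mask_rate_factor)
  T_ns <- gate_delay_T(stack$cfg)
  img <- detection_image(stack, mask, params$n_mean_frames)
  centers <- detect_molecules(img, sigma_min = params$sigma_min,
                              sigma_max = params$sigma_max,
                              n_sigma = params$n_sigma,
                              threshold = params$log_threshold,
                              overlap = params$overlap)
  traces <- extract_traces(stack, centers, mask, box_size = params$box_size)

  n <- length(traces)
  segmentations <- vector("list", n)
  lifetime_traces <- vector("list", n)
  fret <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    steps <- detect_steps(tr$N_o, kernel_halfwidth = params$kernel_halfwidth,
                          min_step = params$min_step)
    seg <- classify_trace(tr, steps, exposure_ms = stack$cfg$exposure_ms,
                          brightness_cutoff = params$brightness_cutoff,
                          stability_factor = params$stability_factor,
                          guard = params$guard)
    lt <- dynamic_lifetime(tr, seg, T_ns, bin_factors = params$bin_factors)
    segmentations[[i]] <- seg
    lifetime_traces[[i]] <- lt

    tau <- NA_real_; nphot <- NA_real_; creason <- NA_character_
    if (seg$class == "single_step") {
      st <- static_lifetime(tr, seg, T_ns)
      tau <- st$tau_ns; nphot <- st$n_photons; creason <- st$censor_reason
    }
    E_lt <- NA_real_; E_int <- NA_real_
    if (seg$class == "acceptor_donor") {
      fe <- tryCatch(fret_from_segmentation(lt, seg), error = function(e) NULL)
      fret[[i]] <- fe
      if (!is.null(fe)) { E_lt <- fe$E_lifetime; E_int <- fe$E_intensity }
    }
    rows[[i]] <- data.frame(
      id = tr$id, x = tr$x, y = tr$y,
      class = seg$class, reason = seg$reason %||% NA_character_,
      overlapping = tr$overlapping, compensated = tr$compensated,
      tau_ns = tau, n_photons = nphot, censor_reason = creason,
      f_empirical = if (!is.null(lt$f_empirical)) lt$f_empirical$F else NA_real_,
      E_lifetime = E_lt, E_intensity = E_int,
      stringsAsFactors = FALSE)
  }
  results <- if (n) do.call(rbind, rows) else data.frame()
  picked <- if (n) results$class == "single_step" & !results$overlapping else logical(0)
  hist <- NULL
  if (any(picked) && any(!is.na(results$tau_ns[picked])))
    hist <- lifetime_histogram(results$tau_ns[picked],
                               binwidth = params$hist_binwidth,
                               range = params$hist_range)
  structure(list(
    results = results, traces = traces, segmentations = segmentations,
    lifetime_traces = lifetime_traces, fret = fret,
    centers = centers, mask = mask, histogram = hist, params = params,
    T_ns = T_ns
  ), class = "smflim_results")
}

#' @export
print.smflim_results <- function(x, ...) {
  n <- nrow(x$results)
  cat(sprintf("smFLIM analysis: %d molecule(s) detected\n", n))
  if (n) {
    tab <- table(x$results$class)
    cat("  classes:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$histogram)) {
    cat("  picked single-step lifetimes: ")
    print(x$histogram)
  }
  invisible(x)
}

#' Write per-molecule results as diff-able tabular text
#'
#' One row per molecule, preceded by comment lines echoing the acquisition
#' config (auditable parameter provenance), its MD5 hash and the
#' simulation seed when the stack carries one.
#'
#' @param res An [analyze_stack()] result.
#' @param stack The analysed `gated_stack` (for the config echo).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, stack, path) {
  stopifnot(inherits(res, "smflim_results"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_acq_config(stack$cfg, tmp)
  cfg_lines <- readLines(tmp)
  hdr <- c(paste0("# ", cfg_lines),
           sprintf("# config_md5: %s", unname(tools::md5sum(tmp))),
           if (!is.null(stack$plan)) sprintf("# seed: %d", stack$plan$rng_seed),
           paste0("# analysis: ",
                  paste(sprintf("%s=%s", names(res$params),
                                vapply(res$params, function(v)
                                  paste(format(v), collapse = "/"), "")),
                        collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  write.table(res$results, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
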