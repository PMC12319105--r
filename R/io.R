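# --- plain-text PGM (P2) primitives -----------------------------------------
# P2 is the ASCII portable graymap: "P2", width height, maxval, pixels.
# Several P2 images concatenated in one file form a valid multi-image
# stream, which serves as the single-file stack container (no TIFF writer
# is assumed to be installed).

pgm_format_one <- function(M, maxval) {
  c("P2", paste(ncol(M), nrow(M)), as.character(maxval),
    apply(M, 1, paste, collapse = " "))
}

pgm_tokens <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(lines, "[ \t]+"))
  toks[nzchar(toks)]
}

pgm_parse_stream <- function(path) {
  toks <- pgm_tokens(path)
  frames <- list()
  i <- 1L
  while (i <= length(toks)) {
    if (toks[i] != "P2") stopf("%s: expected P2 magic, found '%s'", path, toks[i])
    nc <- as.integer(toks[i + 1]); nr <- as.integer(toks[i + 2])
    maxval <- as.integer(toks[i + 3])
    npx <- nr * nc
    if (i + 3 + npx > length(toks)) stopf("%s: truncated PGM data", path)
    vals <- as.integer(toks[(i + 4):(i + 3 + npx)])
    frames[[length(frames) + 1L]] <- list(
      img = matrix(vals, nrow = nr, ncol = nc, byrow = TRUE), maxval = maxval)
    i <- i + 4L + npx
  }
  frames
}

frame_file_pattern <- "^frame(\\d{6})_g([01])\\.(png|pgm)$"
frame_file_name <- function(index, gate, ext)
  sprintf("frame%06d_g%d.%s", index, gate, ext)

# --- public API --------------------------------------------------------------

#' Write a gated frame stack to disk
#'
#' Lossless integer image export with a flat YAML sidecar
#' (`acquisition.yml`) holding the acquisition config. Three containers:
#'
#' * `"png"` — one 8-bit grayscale PNG per frame (the camera's native
#'   export format); requires `q <= 8`.
#' * `"pgm"` — one plain-text PGM (P2) per frame; supports `q <= 16`.
#' * `"pgm-stack"` — all frames concatenated into a single P2 stream file
#'   `stack.pgm` (the multi-page container variant).
#'
#' Per-frame filenames encode the 0-based frame index and the gate:
#' `frame000000_g0.png`, `frame000001_g1.png`, ... Output is
#' byte-deterministic.
#'
#' @param stack A `gated_stack`.
#' @param path Output directory (created if needed).
#' @param format `"png"`, `"pgm"` or `"pgm-stack"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("png", "pgm", "pgm-stack")) {
  stopifnot(inherits(stack, "gated_stack"))
  format <- match.arg(format)
  n_frames <- dim(stack$frames)[3]
  if (n_frames == 0) stopf("refusing to write an empty stack")
  q <- stack$cfg$bit_depth
  if (format == "png" && q > 8)
    stopf("q = %d exceeds the 8-bit PNG container; use format = 'pgm'", q)
  if (q > 16) stopf("q = %d exceeds the 16-bit PGM container", q)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_acq_config(stack$cfg, file.path(path, "acquisition.yml"))
  if (format == "pgm-stack") {
    lines <- unlist(lapply(seq_len(n_frames), function(f)
      pgm_format_one(stack$frames[, , f], max_count(stack$cfg))))
    writeLines(lines, file.path(path, "stack.pgm"))
  } else {
    for (f in seq_len(n_frames)) {
      gate <- stack$gate_index[f]
      fn <- file.path(path, frame_file_name(f - 1L, gate, format))
      if (format == "png") {
        png::writePNG(stack$frames[, , f] / 255, fn)
      } else {
        writeLines(pgm_format_one(stack$frames[, , f], max_count(stack$cfg)), fn)
      }
    }
  }
  invisible(path)
}

#' Read a gated frame stack from disk
#'
#' Reads what [write_stack()] writes: a directory of per-frame PNG/PGM
#' files (frame index and gate parsed from the filename) or a single-file
#' P2 stream, plus the `acquisition.yml` sidecar. Frames are validated:
#' contiguous 0-based indices, strict gate alternation starting at gate 0,
#' one shape throughout, pixel values within `[0, 2^q - 1]`. Frames
#' containing the saturation value are accepted but counted in the
#' `n_saturated_frames` attribute.
#'
#' @param path Directory written by [write_stack()].
#' @param cfg Optional [acq_config()] overriding the sidecar.
#' @return A `gated_stack`.
#' @export
read_stack <- function(path, cfg = NULL) {
  if (is.null(cfg)) {
    sidecar <- file.path(path, "acquisition.yml")
    if (!file.exists(sidecar))
      stopf("no acquisition.yml sidecar in %s and no cfg supplied", path)
    cfg <- read_acq_config(sidecar)
  }
  nmax <- max_count(cfg)
  stream <- file.path(path, "stack.pgm")
  if (file.exists(stream)) {
    parsed <- pgm_parse_stream(stream)
    if (!length(parsed)) stopf("empty stack stream %s", stream)
    imgs <- lapply(parsed, `[[`, "img")
    gates <- rep_len(c(0L, 1L), length(imgs))
  } else {
    files <- list.files(path, pattern = frame_file_pattern)
    if (!length(files)) stopf("no frame files found in %s", path)
    m <- regmatches(files, regexec(frame_file_pattern, files))
    idx <- vapply(m, function(x) as.integer(x[2]), integer(1))
    gates_all <- vapply(m, function(x) as.integer(x[3]), integer(1))
    ord <- order(idx)
    files <- files[ord]; idx <- idx[ord]; gates <- gates_all[ord]
    expect <- seq_len(length(files)) - 1L
    if (!identical(idx, expect)) {
      missing <- setdiff(seq(0L, max(idx)), idx)
      stopf("missing frame index(es): %s", paste(head(missing, 5), collapse = ", "))
    }
    imgs <- lapply(file.path(path, files), function(fn) {
      if (grepl("\\.png$", fn)) {
        im <- png::readPNG(fn)
        if (length(dim(im)) == 3) im <- im[, , 1]
        matrix(as.integer(round(im * 255)), nrow(im), ncol(im))
      } else {
        pgm_parse_stream(fn)[[1]]$img
      }
    })
  }
  shapes <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(shapes)) > 1)
    stopf("mixed frame shapes: %s", paste(unique(shapes), collapse = ", "))
  if (!identical(as.integer(gates), rep_len(c(0L, 1L), length(gates))))
    stopf("frames do not alternate gate 0 / gate 1 starting at gate 0")
  vals <- range(vapply(imgs, range, numeric(2)))
  if (vals[1] < 0 || vals[2] > nmax)
    stopf("pixel values [%g, %g] outside the %d-bit range [0, %d]",
          vals[1], vals[2], cfg$bit_depth, nmax)
  frames <- array(0L, dim = c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  for (f in seq_along(imgs)) frames[, , f] <- imgs[[f]]
  n_sat <- sum(vapply(imgs, function(x) any(x == nmax), logical(1)))
  if (n_sat > 0)
    warnf("%d frame(s) contain saturated pixels (value %d)", n_sat, nmax)
  structure(list(frames = frames,
                 gate_index = rep_len(c(0L, 1L), length(imgs)),
                 cfg = cfg, plan = NULL, n_saturated_frames = n_sat),
            class = "gated_stack")
}

#' Write / read a pixel mask as plain text
#'
#' The mask is stored as a P1-like 0/1 text matrix with the threshold in a
#' comment line, so a calibration run can be reused across analyses.
#'
#' @param mask A `pixel_mask`.
#' @param path File path.
#' @return `path` (write) or a `pixel_mask` without rates (read).
#' @export
write_pixel_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pixel_mask"))
  lines <- c(sprintf("# warm-pixel mask, threshold %.8g counts/frame", mask$threshold),
             paste(nrow(mask$mask), ncol(mask$mask)),
             apply(mask$mask * 1L, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pixel_mask
#' @export
read_pixel_mask <- function(path) {
  lines <- readLines(path)
  thr <- as.numeric(sub("^.*threshold ([0-9.eE+-]+) .*$", "\\1", lines[1]))
  lines <- lines[!grepl("^#", lines)]
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- as.integer(unlist(strsplit(lines[-1], " ")))
  structure(list(mask = matrix(vals == 1L, dims[1], dims[2], byrow = TRUE),
                 rates = NULL, threshold = thr),
            class = "pixel_mask")
}
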