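# Separable 2D convolution with zero padding, computed as band-matrix
# products (BLAS does the heavy lifting): out = Ky %*% M %*% t(Kx), where
# Ky applies kernel ky along rows (y) and Kx applies kx along columns (x).
conv_band_matrix <- function(n, k) {
  h <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - h - 1L  # column offset
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- k[j]
  }
  K
}

conv_sep <- function(M, ky, kx) {
  Ky <- conv_band_matrix(nrow(M), ky)
  Kx <- conv_band_matrix(ncol(M), kx)
  Ky %*% M %*% t(Kx)
}

# Scale-normalized negated Laplacian-of-Gaussian response: bright blobs of
# radius ~ sigma * sqrt(2) give positive peaks of height ~ their amplitude
# scale. LoG(x, y) = g''(x) g(y) + g(x) g''(y), so two separable passes.
log_response <- function(M, sigma) {
  h <- ceiling(4 * sigma)
  t <- (-h):h
  g <- dnorm(t, sd = sigma)
  g <- g / sum(g)
  gpp <- (t^2 - sigma^2) / sigma^4 * g
  -sigma^2 * (conv_sep(M, gpp, g) + conv_sep(M, g, gpp))
}

# Quadratic sub-sample interpolation of a peak position from the responses
# at (left, center, right); returns an offset in (-0.5, 0.5).
quad_offset <- function(fm, f0, fp) {
  denom <- fm - 2 * f0 + fp
  if (denom >= 0) return(0)  # not a proper maximum
  off <- 0.5 * (fm - fp) / denom
  max(-0.5, min(0.5, off))
}

# Fraction of the smaller of two disks (radii r1, r2, centre distance d)
# covered by their intersection.
disk_overlap <- function(d, r1, r2) {
  r <- min(r1, r2); R <- max(r1, r2)
  if (d >= r + R) return(0)
  if (d <= R - r) return(1)
  a1 <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r))
  a2 <- R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R))
  a3 <- 0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
  (a1 + a2 - a3) / (pi * r^2)
}

#' Detect single-molecule spots by multiscale Laplacian of Gaussian
#'
#' Multiscale blob detection on the (pile-up-corrected) average image:
#' scale-normalized LoG responses are computed on a grid of scales, local
#' maxima over (x, y, scale) above the response threshold are kept, and
#' overlapping detections are pruned (the weaker of two blobs whose disks
#' of radius `sigma * sqrt(2)` overlap by more than `overlap` is dropped).
#' Peak positions are refined to sub-pixel precision by quadratic
#' interpolation of the response.
#'
#' Defaults are the operating point for 100 nm pixels: `sigma` in
#' \[1, 5\] px, response threshold 1 on the corrected photon-count scale,
#' overlap 0.9.
#'
#' @param mean_image Numeric matrix: the corrected average of the first ~10
#'   gate-0 frames (see [analyze_stack()]).
#' @param sigma_min,sigma_max Blob scale range (px).
#' @param n_sigma Number of scales on the linear grid.
#' @param threshold Minimum scale-normalized LoG response.
#' @param overlap Maximum allowed pairwise disk overlap fraction.
#' @return data.frame with 0-based sub-pixel `x`, `y`, plus `sigma` and
#'   `response`; zero rows when nothing is found.
#' @export
detect_molecules <- function(mean_image, sigma_min = 1, sigma_max = 5,
                             n_sigma = 10, threshold = 1, overlap = 0.9) {
  stopifnot(is.matrix(mean_image))
  empty <- data.frame(x = numeric(), y = numeric(),
                      sigma = numeric(), response = numeric())
  if (length(mean_image) == 0 || all(mean_image == 0)) return(empty)
  sigmas <- seq(sigma_min, sigma_max, length.out = n_sigma)
  nr <- nrow(mean_image); nc <- ncol(mean_image)
  resp <- array(0, dim = c(nr, nc, n_sigma))
  for (s in seq_len(n_sigma)) resp[, , s] <- log_response(mean_image, sigmas[s])

  # local maxima over a 3 x 3 x 3 neighborhood
  blobs <- empty
  for (s in seq_len(n_sigma)) {
    sl <- resp[, , s]
    cand <- which(sl > threshold, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      v <- sl[r, c]
      rr <- max(1, r - 1):min(nr, r + 1)
      cc <- max(1, c - 1):min(nc, c + 1)
      ss <- max(1, s - 1):min(n_sigma, s + 1)
      nb <- resp[rr, cc, ss, drop = FALSE]
      if (v < max(nb)) next
      if (sum(nb == v) > 1 && (s > 1 || r > 1 || c > 1)) {
        # plateau: keep only the lexicographically first voxel
        w <- which(nb == v, arr.ind = TRUE)
        first <- w[order(w[, 3], w[, 1], w[, 2])[1], ]
        if (!(rr[first[1]] == r && cc[first[2]] == c && ss[first[3]] == s)) next
      }
      dx <- if (c > 1 && c < nc) quad_offset(sl[r, c - 1], v, sl[r, c + 1]) else 0
      dy <- if (r > 1 && r < nr) quad_offset(sl[r - 1, c], v, sl[r + 1, c]) else 0
      blobs <- rbind(blobs, data.frame(
        x = (c - 1) + dx, y = (r - 1) + dy,
        sigma = sigmas[s], response = v))
    }
  }
  if (nrow(blobs) <= 1) return(blobs)

  # prune overlapping blobs, strongest first
  blobs <- blobs[order(-blobs$response), ]
  keep <- rep(TRUE, nrow(blobs))
  for (i in seq_len(nrow(blobs) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(blobs)) {
      if (!keep[j]) next
      d <- sqrt((blobs$x[i] - blobs$x[j])^2 + (blobs$y[i] - blobs$y[j])^2)
      if (disk_overlap(d, blobs$sigma[i] * sqrt(2),
                       blobs$sigma[j] * sqrt(2)) > overlap)
        keep[j] <- FALSE
    }
  }
  out <- blobs[keep, ]
  rownames(out) <- NULL
  out
}
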