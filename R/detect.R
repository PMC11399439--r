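#' Detect spots in an intensity image
#'
#' Gaussian-smooths each channel, finds local intensity maxima above a
#' threshold, suppresses peaks closer than a minimum separation
#' (keeping the brighter one) and optionally refines each peak to the
#' intensity-weighted centroid of its 3 x 3 neighborhood, yielding
#' subpixel coordinates. The detector is deliberately simple: upstream
#' object detection is a pluggable step and any coordinate list can be
#' fed to the matcher instead.
#'
#' @param img an `intensity_image` or a single numeric matrix.
#' @param sigma smoothing sigma in pixels.
#' @param threshold absolute intensity threshold on the smoothed image;
#'   default NULL estimates median + 8 * mad per channel, which is
#'   conservative against isolated Poisson background peaks.
#' @param min_sep minimum peak separation in pixels (>= 1).
#' @param refine subpixel centroid refinement on/off.
#' @return a [point_cloud_set()] in pixel units (for an
#'   `intensity_image`), or an n x 2 coordinate matrix (for a single
#'   matrix). Coordinates are 0-based (row, col).
#' @export
detect_spots <- function(img, sigma = 0.7, threshold = NULL,
                         min_sep = 2, refine = TRUE) {
  stopifnot(sigma >= 0, min_sep >= 1)
  if (inherits(img, "intensity_image")) {
    coords <- lapply(img$channels, detect_spots_matrix,
                     sigma = sigma, threshold = threshold,
                     min_sep = min_sep, refine = refine)
    return(point_cloud_set(coords, unit = "px",
                           pixel_size_nm = img$pixel_size_nm))
  }
  detect_spots_matrix(img, sigma, threshold, min_sep, refine)
}

detect_spots_matrix <- function(img, sigma, threshold, min_sep, refine) {
  img <- as.matrix(img)
  stopifnot(all(img >= 0))
  sm <- gaussian_smooth(img, sigma)
  if (is.null(threshold)) {
    threshold <- median(sm) + 8 * mad(sm)
  }
  peaks <- local_maxima(sm, threshold)
  if (nrow(peaks) == 0) return(matrix(numeric(0), 0, 2))
  # non-maximum suppression, brightest first
  vals <- sm[peaks]
  ord <- order(-vals, peaks[, 1], peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(peaks))) {
    p <- peaks[r, ]
    if (nrow(kept) == 0 ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= min_sep^2) {
      kept <- rbind(kept, p)
    }
  }
  out <- kept - 1 # 0-based
  if (refine) {
    nr <- nrow(sm); nc <- ncol(sm)
    for (r in seq_len(nrow(kept))) {
      i <- kept[r, 1]; j <- kept[r, 2]
      ii <- max(1, i - 1):min(nr, i + 1)
      jj <- max(1, j - 1):min(nc, j + 1)
      w <- sm[ii, jj, drop = FALSE]
      w <- w - min(w) # local background removal before weighting
      if (sum(w) > 0) {
        out[r, 1] <- sum(outer(ii, rep(1, length(jj))) * w) / sum(w) - 1
        out[r, 2] <- sum(outer(rep(1, length(ii)), jj) * w) / sum(w) - 1
      }
    }
  }
  dimnames(out) <- NULL
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# separable Gaussian convolution; uses EBImage::gblur when installed
# (identical kernel), else a base-R fallback with edge renormalization
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(as.matrix(EBImage::gblur(img, sigma = sigma)))
  }
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv1 <- function(m) { # along rows, renormalized at the borders
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (o in seq(-half, half)) {
      w <- kern[o + half + 1]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + w * m[src, , drop = FALSE]
      wt <- wt + w
    }
    out / wt
  }
  t(conv1(t(conv1(img))))
}

# strict local maxima above threshold among the 8-neighborhood
local_maxima <- function(sm, threshold) {
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3) return(matrix(integer(0), 0, 2))
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  ok <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & core > sm[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(idx[, 1] + 1L, idx[, 2] + 1L)
}
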