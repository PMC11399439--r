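#' Simulation scenario for STED-like chain point patterns
#'
#' Describes a ground-truth configuration of chain structures on a
#' square pixel grid, mirroring the three-color nanoruler imaging setup:
#' 400 x 400 px frames at 25 nm/px, chains with ~70 nm (2.8 px) links,
#' rendered with a 40 nm FWHM Gaussian spot profile.
#'
#' @param counts named vector of true structure counts, names being
#'   contiguous structure names (e.g. c(ABC = 100, AB = 50, A = 50)).
#' @param k number of channels; default inferred from the highest
#'   channel letter used in `counts`.
#' @param geometry "near_linear" draws the two outer triplet partners on
#'   approximately opposite sides of the middle particle (the three-color
#'   study design); "curled" draws every link angle independently and
#'   uniformly (the four-color study design).
#' @param t_true_nm true link length in nm (mean of the normal link
#'   distribution; sd is 0.5 px).
#' @param image_size image side in pixels.
#' @param pixel_size_nm physical pixel size.
#' @param fwhm_nm full width at half maximum of the rendered spot
#'   profile.
#' @param noise_scale multiplier on the Poisson background (1 = low
#'   noise; 10 = the high-noise four-color setting).
#' @param efficiencies per-channel labeling efficiencies used when
#'   thinning.
#' @param peak_signal expected photon count at a particle's center
#'   pixel.
#' @param background expected background photon count per pixel (before
#'   `noise_scale`).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(counts, k = NULL,
                         geometry = c("near_linear", "curled"),
                         t_true_nm = 70, image_size = 400L,
                         pixel_size_nm = 25, fwhm_nm = 40,
                         noise_scale = 1, efficiencies = 1,
                         peak_signal = 100, background = 1) {
  geometry <- match.arg(geometry)
  stopifnot(!is.null(names(counts)), all(counts >= 0), t_true_nm > 0)
  if (is.null(k)) {
    k <- max(match(unlist(strsplit(names(counts), "")), LETTERS))
  }
  for (nm in names(counts)) structure_span(nm, k) # validate names
  if (length(efficiencies) == 1) efficiencies <- rep(efficiencies, k)
  stopifnot(length(efficiencies) == k,
            all(efficiencies > 0), all(efficiencies <= 1))
  structure(list(counts = counts, k = k, geometry = geometry,
                 t_true_nm = t_true_nm, image_size = as.integer(image_size),
                 pixel_size_nm = pixel_size_nm, fwhm_nm = fwhm_nm,
                 noise_scale = noise_scale, efficiencies = efficiencies,
                 peak_signal = peak_signal, background = background),
            class = "sim_scenario")
}

#' Simulate ground-truth chain coordinates
#'
#' Draws each structure instance on the pixel grid: the anchor particle
#' (channel B when the span contains it, else the span's first channel)
#' is uniform on the frame; each link length is N(t_true, sd 0.5) in
#' pixels; in "near_linear" geometry the two outer partners of a triplet
#' sit at angles alpha and alpha + pi + eps (eps ~ N(0, 0.2)) of the
#' middle particle, otherwise every link angle is uniform on [0, 2 pi).
#' Coordinates are rounded to the integer pixel grid; an instance with
#' any particle off the frame is redrawn entirely. Rounding may create
#' coincident particles; they are kept (distance 0 matches at any t).
#'
#' @param sc a [sim_scenario()].
#' @return object of class `ground_truth`: data.frame `points` with
#'   columns structure, struct_id, channel (integer), x, y (0-based
#'   pixels).
#' @export
simulate_chain_points <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  t_px <- sc$t_true_nm / sc$pixel_size_nm
  size <- sc$image_size
  rows <- vector("list", sum(sc$counts))
  ri <- 0L
  sid <- 0L
  for (nm in names(sc$counts)) {
    span <- structure_span(nm, sc$k)
    len <- span[2] - span[1] + 1L
    channels <- span[1]:span[2]
    anchor_pos <- if (2L %in% channels) match(2L, channels) else 1L
    for (inst in seq_len(sc$counts[[nm]])) {
      sid <- sid + 1L
      repeat {
        pts <- draw_instance(len, anchor_pos, t_px, size, sc$geometry)
        pts <- round(pts)
        if (all(pts >= 0) && all(pts <= size - 1L)) break
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(structure = nm, struct_id = sid,
                               channel = channels,
                               x = pts[, 1], y = pts[, 2])
    }
  }
  points <- if (ri > 0) do.call(rbind, rows) else
    data.frame(structure = character(0), struct_id = integer(0),
               channel = integer(0), x = numeric(0), y = numeric(0))
  structure(list(points = points, k = sc$k, scenario = sc),
            class = "ground_truth")
}

# one structure instance: len x 2 matrix of unrounded pixel coordinates
draw_instance <- function(len, anchor_pos, t_px, size, geometry) {
  pts <- matrix(NA_real_, len, 2)
  pts[anchor_pos, ] <- runif(2, 0, size)
  link <- function() {
    ang <- runif(1, 0, 2 * pi)
    c(cos(ang), sin(ang)) * rnorm(1, t_px, 0.5)
  }
  if (geometry == "near_linear" && len == 3 && anchor_pos == 2) {
    alpha <- runif(1, 0, 2 * pi)
    d1 <- rnorm(1, t_px, 0.5)
    pts[1, ] <- pts[2, ] + c(cos(alpha), sin(alpha)) * d1
    beta <- alpha + pi + rnorm(1, 0, 0.2)
    d2 <- rnorm(1, t_px, 0.5)
    pts[3, ] <- pts[2, ] + c(cos(beta), sin(beta)) * d2
    return(pts)
  }
  # walk left from the anchor, then right (each link angle uniform)
  if (anchor_pos > 1) {
    for (a in seq(anchor_pos - 1L, 1L)) pts[a, ] <- pts[a + 1L, ] + link()
  }
  if (anchor_pos < len) {
    for (a in seq(anchor_pos + 1L, len)) pts[a, ] <- pts[a - 1L, ] + link()
  }
  pts
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth: ", nrow(x$points), " particles, ",
      length(unique(x$points$struct_id)), " structures, k = ", x$k,
      "\n", sep = "")
  invisible(x)
}

#' Bernoulli thinning by labeling efficiency
#'
#' Keeps each particle independently with its channel's efficiency;
#' structure membership labels are preserved on survivors, so a thinned
#' ground truth still knows which true structure each particle came
#' from.
#'
#' @param gt a [simulate_chain_points()] result.
#' @param s per-channel efficiencies (scalar recycled).
#' @return thinned `ground_truth`.
#' @export
apply_labeling_efficiency <- function(gt, s) {
  stopifnot(inherits(gt, "ground_truth"))
  if (length(s) == 1) s <- rep(s, gt$k)
  stopifnot(length(s) == gt$k, all(s > 0), all(s <= 1))
  pts <- gt$points
  keep <- rbinom(nrow(pts), 1, s[pts$channel]) == 1
  gt$points <- pts[keep, , drop = FALSE]
  gt
}

#' Point clouds of a ground truth
#'
#' @param gt a `ground_truth`.
#' @return a [point_cloud_set()] in pixel units.
#' @export
ground_truth_clouds <- function(gt) {
  coords <- lapply(seq_len(gt$k), function(ch) {
    p <- gt$points[gt$points$channel == ch, c("x", "y")]
    as.matrix(p)
  })
  point_cloud_set(coords, unit = "px",
                  pixel_size_nm = gt$scenario$pixel_size_nm)
}

#' True abundance vector of a ground truth's scenario
#'
#' @param gt a `ground_truth` (pre-thinning counts are the scenario's).
#' @return named integer vector over all structure names.
#' @export
true_abundances <- function(gt) {
  nms <- structure_names(gt$k)
  out <- setNames(integer(length(nms)), nms)
  out[names(gt$scenario$counts)] <- as.integer(gt$scenario$counts)
  out
}

#' Draw observed abundances from the misdetection model
#'
#' Samples, for each true structure, a multinomial over its detection
#' patterns and aggregates pattern runs into observed structure counts
#' (a detected A and C of a true triplet count as two singlets). This
#' validates the correction machinery without any imaging step.
#'
#' @param n true abundance vector (named by structure, or canonical
#'   order).
#' @param model a [substructure_model()] (or efficiencies `s` via
#'   `k`/`s`).
#' @param draws number of independent replicates.
#' @return matrix (structures x draws) of observed counts W; a named
#'   vector if draws = 1.
#' @export
simulate_misdetection_counts <- function(n, model, draws = 1) {
  stopifnot(inherits(model, "substructure_model"))
  n <- canonical_w(n, model)
  stopifnot(all(n >= 0))
  npat <- length(model$patterns)
  raw <- matrix(0, npat, draws)
  for (i in seq_along(n)) {
    if (n[i] == 0) next
    raw <- raw + rmultinom(draws, size = n[i], prob = model$mu[, i])
  }
  W <- model$theta %*% raw
  rownames(W) <- model$structures
  if (draws == 1) W[, 1] else W
}

#' Render STED-like intensity images
#'
#' Every particle contributes an isotropic Gaussian spot of the
#' scenario's FWHM (sigma = FWHM / (2 sqrt(2 ln 2))) with fixed peak
#' amplitude, evaluated per pixel center; pixel values are Poisson draws
#' around signal + background * noise_scale.
#'
#' @param gt a `ground_truth`.
#' @param noiseless if TRUE return the expected signal without Poisson
#'   noise or background.
#' @return object of class `intensity_image`: list of per-channel
#'   matrices (image_size x image_size) plus pixel size metadata.
#' @export
render_sted_image <- function(gt, noiseless = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  sc <- gt$scenario
  size <- sc$image_size
  sigma <- sc$fwhm_nm / (2 * sqrt(2 * log(2))) / sc$pixel_size_nm
  win <- ceiling(4 * sigma)
  channels <- vector("list", gt$k)
  for (ch in seq_len(gt$k)) {
    img <- matrix(0, size, size)
    p <- gt$points[gt$points$channel == ch, , drop = FALSE]
    for (r in seq_len(nrow(p))) {
      x0 <- p$x[r]; y0 <- p$y[r]
      xs <- max(0, floor(x0) - win):min(size - 1, ceiling(x0) + win)
      ys <- max(0, floor(y0) - win):min(size - 1, ceiling(y0) + win)
      patch <- sc$peak_signal *
        exp(-(outer((xs - x0)^2, (ys - y0)^2, "+")) / (2 * sigma^2))
      img[xs + 1, ys + 1] <- img[xs + 1, ys + 1] + patch
    }
    if (!noiseless) {
      lam <- img + sc$background * sc$noise_scale
      img <- matrix(rpois(length(lam), lam), size, size)
    }
    channels[[ch]] <- img
  }
  structure(list(channels = channels, pixel_size_nm = sc$pixel_size_nm,
                 image_size = size),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat("intensity_image: ", length(x$channels), " channels, ",
      x$image_size, "x", x$image_size, " px, ",
      x$pixel_size_nm, " nm/px\n", sep = "")
  invisible(x)
}
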