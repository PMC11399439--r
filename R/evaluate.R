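#' Canonical simulation scenarios
#'
#' The three three-color scenarios of the simulation study (near-linear
#' triplets, low noise) and the two four-color scenarios (curled chains,
#' tenfold background):
#' * "1": 50 A, B and C singlets
#' * "2": 50 AB and BC pairs plus 50 A, B, C singlets
#' * "3": 100 ABC triplets, 50 AB and BC pairs, 50 A, B, C singlets
#' * "I4": 50 ABCD, 30 ABC, 20 AB, 30 C and 30 D singlets
#' * "II4": 100 ABCD quadruplets only
#'
#' @param name scenario name.
#' @param ... overrides passed on to [sim_scenario()].
#' @return a [sim_scenario()].
#' @export
canonical_scenario <- function(name = c("1", "2", "3", "I4", "II4"), ...) {
  name <- match.arg(name)
  switch(name,
    "1" = sim_scenario(c(A = 50, B = 50, C = 50),
                       k = 3, geometry = "near_linear", ...),
    "2" = sim_scenario(c(AB = 50, BC = 50, A = 50, B = 50, C = 50),
                       k = 3, geometry = "near_linear", ...),
    "3" = sim_scenario(c(ABC = 100, AB = 50, BC = 50,
                         A = 50, B = 50, C = 50),
                       k = 3, geometry = "near_linear", ...),
    "I4" = sim_scenario(c(ABCD = 50, ABC = 30, AB = 20, C = 30, D = 30),
                        k = 4, geometry = "curled", noise_scale = 10, ...),
    "II4" = sim_scenario(c(ABCD = 100), k = 4, geometry = "curled",
                         noise_scale = 10, ...))
}

#' Simulate, image, detect and match one frame
#'
#' Full pipeline for a single simulated image: draw ground truth, thin
#' by the scenario's efficiencies, render, detect spots, and match with
#' each requested mode at threshold `t_px`.
#'
#' @param sc a [sim_scenario()].
#' @param t_px colocalization threshold in pixels.
#' @param modes matching modes to run.
#' @param scale_channel channel whose detected count scales relative
#'   abundances (default 2, channel B).
#' @return list: `truth` (named counts), `true_particles` per channel,
#'   `detected` per channel, and per mode the abundance vector.
#' @export
run_simulated_frame <- function(sc, t_px = 5, modes = c("I", "II"),
                                scale_channel = 2L) {
  gt <- simulate_chain_points(sc)
  n_true <- vapply(seq_len(sc$k), function(ch)
    sum(gt$points$channel == ch), integer(1))
  if (any(sc$efficiencies < 1)) {
    gt <- apply_labeling_efficiency(gt, sc$efficiencies)
  }
  img <- render_sted_image(gt)
  clouds <- detect_spots(img)
  res <- list(truth = true_abundances(gt), true_particles = n_true,
              detected = clouds$counts)
  for (mode in modes) {
    cfg <- match_config(t = t_px, mode = mode,
                        scale_channel = scale_channel)
    res[[paste0("mode", mode)]] <- match_chains(clouds, cfg)$abundance
  }
  res
}

#' Signed relative-abundance errors over a batch of simulated images
#'
#' Repeats [run_simulated_frame()] and reports, per image, mode and
#' structure, the detected relative abundance (scaled by the detected
#' particle count of `scale_channel`) minus the true relative abundance
#' (scaled by the true particle count of that channel).
#'
#' @param sc a [sim_scenario()].
#' @param n_images number of independent frames.
#' @param t_px threshold in pixels.
#' @param modes modes to evaluate.
#' @param scale_channel scaling channel (default B).
#' @return data.frame image, mode, structure, detected, true_count,
#'   detected_rel, true_rel, error.
#' @export
evaluate_scenario <- function(sc, n_images, t_px = 5,
                              modes = c("I", "II"), scale_channel = 2L) {
  nms <- structure_names(sc$k)
  out <- list()
  for (im in seq_len(n_images)) {
    fr <- run_simulated_frame(sc, t_px = t_px, modes = modes,
                              scale_channel = scale_channel)
    true_rel <- fr$truth / fr$true_particles[scale_channel]
    for (mode in modes) {
      w <- fr[[paste0("mode", mode)]]
      det_rel <- w / fr$detected[scale_channel]
      out[[length(out) + 1L]] <- data.frame(
        image = im, mode = mode, structure = nms,
        detected = as.integer(w), true_count = as.integer(fr$truth),
        detected_rel = as.numeric(det_rel),
        true_rel = as.numeric(true_rel),
        error = as.numeric(det_rel - true_rel), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Per-structure error summary of an evaluation batch
#'
#' @param errors an [evaluate_scenario()] result (possibly several,
#'   row-bound, with a `scenario` column added).
#' @return data.frame with median error and IQR per grouping.
#' @export
summarize_errors <- function(errors) {
  grp <- intersect(c("scenario", "mode", "structure"), names(errors))
  agg <- function(f) aggregate(errors["error"], errors[grp], f)
  med <- agg(median)
  names(med)[names(med) == "error"] <- "median_error"
  iqr <- agg(function(x) diff(quantile(x, c(0.25, 0.75))))
  med$iqr <- iqr$error
  med
}
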