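#' Abundance curve over a colocalization-threshold grid
#'
#' Reruns the configured matching mode for every threshold of a strictly
#' increasing grid. The matching incentive lambda is re-derived per
#' threshold unless fixed in the config. Relative abundances divide all
#' counts by the particle count of `cfg$scale_channel` (the convention of
#' the nanoruler analyses, which scale by the channel-B count).
#'
#' @param clouds a [point_cloud_set()].
#' @param t_grid strictly increasing nonnegative thresholds.
#' @param cfg a [match_config()]; its `t` is ignored in favor of the grid.
#' @return data.frame with columns t, structure, count and (when a scale
#'   channel is set) relative; class `abundance_curve`.
#' @export
abundance_curve <- function(clouds, t_grid, cfg) {
  stopifnot(inherits(clouds, "point_cloud_set"))
  stopifnot(all(t_grid >= 0), all(diff(t_grid) > 0))
  sc <- cfg$scale_channel
  scale_n <- NA_real_
  if (!is.null(sc)) {
    stopifnot(sc <= clouds$k)
    scale_n <- clouds$counts[sc]
    if (scale_n == 0) {
      warning("scale channel ", sc,
              " has zero particles; relative abundances undefined (NA)")
    }
  }
  out <- lapply(t_grid, function(tt) {
    cfg_t <- match_config(t = tt, lambda = cfg$lambda, mode = cfg$mode,
                          priority = cfg$priority, scale_channel = sc)
    w <- match_chains(clouds, cfg_t)$abundance
    df <- data.frame(t = tt, structure = names(w),
                     count = as.integer(w), row.names = NULL)
    if (!is.null(sc)) {
      df$relative <- if (scale_n > 0) df$count / scale_n else NA_real_
    }
    df
  })
  res <- do.call(rbind, out)
  class(res) <- c("abundance_curve", "data.frame")
  attr(res, "mode") <- cfg$mode
  attr(res, "k") <- clouds$k
  res
}

# abundance vector (named, canonical structure order) from a curve at one t
curve_w_at <- function(curve, tt) {
  sub <- curve[curve$t == tt, ]
  setNames(sub$count, sub$structure)[structure_names(attr(curve, "k"))]
}
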