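#' Matching configuration
#'
#' @param t colocalization threshold in the cloud's distance unit; either
#'   a single value or a vector of per-adjacent-pair thresholds
#'   t_{j,j+1} (length k - 1). Edge admission is inclusive (d <= t).
#' @param lambda matching incentive; every matched chain's cost is reduced
#'   by lambda. Default NULL derives lambda = (k'-1) * m * max(t) + 1 per
#'   solved sub-problem (m the transportable mass min_j n_j), the
#'   smallest bound that provably makes maximal matchings always
#'   preferred; it is re-derived for every threshold of an abundance
#'   curve. Results are identical for any lambda above this bound.
#' @param mode "I" (chain-first multi-marginal matching with leftover
#'   re-matching in priority order) or "II" (independent adjacent-pair
#'   matchings coupled through shared particles).
#' @param priority Mode I leftover priority: character vector of
#'   contiguous structure names (e.g. c("AB", "BC")); default is
#'   longest-first, left-to-right over all sub-spans.
#' @param scale_channel channel index whose detected particle count scales
#'   relative abundances (the middle channel, B, in the three-color
#'   nanoruler analyses).
#' @return object of class `match_config`.
#' @export
match_config <- function(t, lambda = NULL, mode = c("I", "II"),
                         priority = NULL, scale_channel = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t), all(t >= 0))
  if (!is.null(lambda)) stopifnot(lambda >= 0)
  if (!is.null(scale_channel)) stopifnot(scale_channel >= 1)
  structure(list(t = t, lambda = lambda, mode = mode,
                 priority = priority, scale_channel = scale_channel),
            class = "match_config")
}

# thresholds for the adjacent pairs inside a span (absolute channels
# span[1]..span[2]) of a k-channel problem
span_thresholds <- function(t, k, span) {
  if (length(t) == 1) {
    rep(t, span[2] - span[1])
  } else {
    stopifnot(length(t) == k - 1)
    t[span[1]:(span[2] - 1)]
  }
}

# smallest incentive that provably prefers larger matchings: growing a
# matching from c to c+1 chains can force re-routing every chain, adding
# up to (k'-1) * (c+1) * max(t) distance, and c+1 is at most the
# transportable mass m = min_j n_j; anything above (k'-1) * m * max(t)
# therefore makes each extra chain worthwhile. A per-chain bound like
# (k'-1) * max(t) is NOT sufficient.
default_lambda <- function(t_span, m) {
  length(t_span) * max(m, 1) * max(t_span) + 1
}
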