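#' Substructure detection model for incomplete labeling efficiencies
#'
#' Each particle of channel i is detected independently with probability
#' s_i. Conditional on a true structure (a contiguous chain), the
#' detected subset of its particles follows independent Bernoulli draws;
#' a detected subset decomposes into maximal contiguous runs, each of
#' which is observed as the corresponding shorter structure (a detected
#' A and C of a true ABC triplet are counted as an A and a C singlet).
#' The model assembles, for k channels:
#'
#' * the detection-pattern space (all subsets of the k channels, ordered
#'   by decreasing size, contiguous spans first),
#' * `mu`, the 2^k x S matrix whose columns are the pattern probability
#'   vectors of each true structure (S = k(k+1)/2 contiguous structures),
#' * `theta`, the S x 2^k aggregation matrix crediting each pattern's
#'   runs to observed structure counts,
#' * `inverse_map` = (theta mu)^-1, the unbiased correction matrix.
#'
#' For k = 3 these reproduce the classical closed-form three-color
#' transformation,
#' probability stack and inverse entrywise.
#'
#' @param k number of channels.
#' @param s per-channel labeling efficiencies in (0, 1]; recycled if
#'   scalar.
#' @return object of class `substructure_model`.
#' @export
substructure_model <- function(k, s) {
  stopifnot(k >= 2)
  if (length(s) == 1) s <- rep(s, k)
  stopifnot(length(s) == k)
  if (any(s <= 0)) {
    stop("all labeling efficiencies must be positive: ",
         "s_i = 0 makes the aggregated pattern map singular ",
         "(structures of channel i are never observable)")
  }
  stopifnot(all(s <= 1))
  structs <- structure_names(k)
  pats <- detection_patterns(k)
  mu <- vapply(structs, function(nm) {
    substructure_probabilities(nm, k, s, pats)
  }, numeric(length(pats)))
  theta <- build_theta(k, pats, structs)
  theta_mu <- theta %*% mu
  inverse_map <- solve(theta_mu)
  structure(list(k = k, s = s, structures = structs, patterns = pats,
                 mu = mu, theta = theta, theta_mu = theta_mu,
                 inverse_map = inverse_map),
            class = "substructure_model")
}

#' @export
print.substructure_model <- function(x, ...) {
  cat("substructure_model: k = ", x$k, ", s = (",
      paste(format(x$s), collapse = ", "), ")\n", sep = "")
  cat("  ", length(x$structures), " structures, ",
      length(x$patterns), " detection patterns\n", sep = "")
  invisible(x)
}

# detection patterns: all subsets of channels 1..k as index vectors,
# ordered by decreasing size; within a size contiguous spans first
# (left-to-right), then non-contiguous subsets lexicographically; the
# empty pattern last. For k = 3: ABC, AB, BC, AC, A, B, C, {}.
detection_patterns <- function(k) {
  subs <- list(integer(0))
  for (ch in seq_len(k)) {
    subs <- c(subs, lapply(subs, function(s) c(s, ch)))
  }
  size <- vapply(subs, length, integer(1))
  contig <- vapply(subs, function(s) {
    length(s) > 0 && (length(s) == 1 || all(diff(s) == 1L))
  }, logical(1))
  start <- vapply(subs, function(s) if (length(s)) s[1] else 0L, integer(1))
  lex <- vapply(subs, function(s) paste(LETTERS[s], collapse = ""),
                character(1))
  ord <- order(-size, !contig, start, lex)
  pats <- subs[ord]
  names(pats) <- vapply(pats, function(s) {
    if (length(s) == 0) "none" else paste(LETTERS[s], collapse = "")
  }, character(1))
  pats
}

# maximal contiguous runs of a pattern (list of spans)
pattern_runs <- function(pat) {
  if (length(pat) == 0) return(list())
  breaks <- c(0, which(diff(pat) != 1L), length(pat))
  lapply(seq_len(length(breaks) - 1L), function(r) {
    pat[(breaks[r] + 1L):breaks[r + 1L]]
  })
}

#' Detection-pattern probabilities of a true structure
#'
#' Probability of each detection pattern conditional on one true
#' structure: independent Bernoulli detection per particle of the
#' structure's span; patterns reaching outside the span have probability
#' zero. Entries sum to one.
#'
#' @param structure structure name (contiguous span, e.g. "AB").
#' @param k number of channels.
#' @param s efficiencies (length k).
#' @param patterns pattern list (defaults to the canonical order).
#' @return named probability vector over patterns.
#' @export
substructure_probabilities <- function(structure, k, s,
                                       patterns = detection_patterns(k)) {
  span <- structure_span(structure, k)
  members <- span[1]:span[2]
  vapply(patterns, function(pat) {
    if (!all(pat %in% members)) return(0)
    prod(ifelse(members %in% pat, s[members], 1 - s[members]))
  }, numeric(1))
}

build_theta <- function(k, pats, structs) {
  theta <- matrix(0, length(structs), length(pats),
                  dimnames = list(structs, names(pats)))
  for (p in seq_along(pats)) {
    for (run in pattern_runs(pats[[p]])) {
      nm <- span_name(run[1], run[length(run)])
      theta[nm, p] <- theta[nm, p] + 1
    }
  }
  theta
}

#' Unbiased true-abundance estimator
#'
#' Applies the inverse aggregated pattern map to observed structure
#' counts: n-hat = (theta mu)^-1 W. Unbiased under the multinomial
#' misdetection model; entries can be negative and are reported raw
#' (clipping would reintroduce bias).
#'
#' @param W observed abundance vector, named by structure or in the
#'   model's canonical structure order.
#' @param model a [substructure_model()].
#' @return object of class `abundance_estimate`: `n_hat`, `W`, and the
#'   model.
#' @export
estimate_true_abundances <- function(W, model) {
  stopifnot(inherits(model, "substructure_model"))
  W <- canonical_w(W, model)
  n_hat <- drop(model$inverse_map %*% W)
  names(n_hat) <- model$structures
  structure(list(n_hat = n_hat, W = W, model = model),
            class = "abundance_estimate")
}

canonical_w <- function(W, model) {
  if (!is.null(names(W))) {
    missing <- setdiff(model$structures, names(W))
    if (length(missing) > 0) {
      stop("W lacks structures: ", paste(missing, collapse = ", "))
    }
    W <- W[model$structures]
  } else if (length(W) != length(model$structures)) {
    stop("W has length ", length(W), ", expected ",
         length(model$structures))
  }
  as.numeric(W)
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("abundance_estimate (k = ", x$model$k, "):\n", sep = "")
  print(round(rbind(W = x$W, n_hat = x$n_hat), 3))
  invisible(x)
}

#' Plug-in covariance of the pattern counts
#'
#' Sigma(n) = sum_i n_i (diag(p_i) - p_i p_i^T) over true structures,
#' the sum of the multinomial covariances. For the plug-in at n-hat,
#' negative entries are floored at zero (only here; the estimate itself
#' stays raw) so Sigma remains positive semidefinite.
#'
#' @param n_hat abundance vector (estimate or truth), named or canonical
#'   order.
#' @param model a [substructure_model()].
#' @return 2^k x 2^k covariance matrix over detection patterns.
#' @export
covariance_sigma <- function(n_hat, model) {
  n_plug <- pmax(canonical_w(n_hat, model), 0)
  P <- model$mu
  sig <- matrix(0, nrow(P), nrow(P))
  for (i in seq_along(n_plug)) {
    p <- P[, i]
    sig <- sig + n_plug[i] * (diag(p) - tcrossprod(p))
  }
  dimnames(sig) <- list(names(model$patterns), names(model$patterns))
  sig
}

# rank-revealing inverse of theta Sigma theta^T; pseudoinverse when
# singular (relative singular-value tolerance 1e-10)
metric_inverse <- function(M, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * max(sv$d, 0)
  r <- sum(pos)
  if (r == 0) return(list(inv = matrix(0, nrow(M), ncol(M)), rank = 0L,
                          singular = TRUE))
  inv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(inv = inv, rank = as.integer(r), singular = r < nrow(M))
}

#' Chi-squared test statistic for hypothesized abundances
#'
#' Xi = (n-hat - n0)^T (theta mu)^T (theta Sigma theta^T)^-1
#' (theta mu) (n-hat - n0), asymptotically chi-squared with as many
#' degrees of freedom as observable structures (6 for k = 3), or with
#' rank(theta Sigma theta^T) degrees when the metric is singular and its
#' pseudoinverse is used.
#'
#' @param est an [estimate_true_abundances()] result.
#' @param n0 hypothesized abundance vector.
#' @param sigma optional covariance (defaults to the plug-in at n-hat).
#' @return list(xi, df, quad): the statistic, its degrees of freedom, and
#'   the quadratic-form matrix Q with Xi = d^T Q d.
#' @export
xi_statistic <- function(est, n0, sigma = NULL) {
  stopifnot(inherits(est, "abundance_estimate"))
  model <- est$model
  n0 <- canonical_w(n0, model)
  if (is.null(sigma)) sigma <- covariance_sigma(est$n_hat, model)
  Q <- xi_quadform(model, sigma)
  d <- est$n_hat - n0
  list(xi = drop(t(d) %*% Q$Q %*% d), df = Q$df, quad = Q$Q)
}

xi_quadform <- function(model, sigma) {
  tm <- model$theta_mu
  mid <- model$theta %*% sigma %*% t(model$theta)
  mi <- metric_inverse(mid)
  df <- if (mi$singular) mi$rank else length(model$structures)
  Q <- t(tm) %*% mi$inv %*% tm
  list(Q = (Q + t(Q)) / 2, df = df)
}

#' Joint confidence region and per-structure intervals
#'
#' The region is the ellipsoid of abundance vectors n0 whose Xi
#' statistic stays below the upper-alpha chi-squared critical value.
#' Per-structure intervals are axis-aligned slices through the estimate
#' (all other abundances fixed at their estimated values):
#' half-width_j = sqrt(chi2_crit / Q_jj).
#'
#' @param est an [estimate_true_abundances()] result.
#' @param alpha significance level in (0, 1); the region has asymptotic
#'   coverage 1 - alpha.
#' @return list with the quadratic form `Q`, degrees of freedom `df`,
#'   critical value `crit`, and `intervals` (data.frame structure,
#'   estimate, lower, upper).
#' @export
confidence_region <- function(est, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  model <- est$model
  sigma <- covariance_sigma(est$n_hat, model)
  Q <- xi_quadform(model, sigma)
  crit <- qchisq(1 - alpha, df = Q$df)
  qdiag <- diag(Q$Q)
  half <- ifelse(qdiag > 0, sqrt(crit / qdiag), Inf)
  intervals <- data.frame(structure = model$structures,
                          estimate = est$n_hat,
                          lower = est$n_hat - half,
                          upper = est$n_hat + half,
                          row.names = NULL)
  list(Q = Q$Q, df = Q$df, crit = crit, alpha = alpha,
       intervals = intervals)
}

#' Efficiency-corrected abundance curve with confidence bands
#'
#' Applies the unbiased estimator and the confidence-region slices
#' pointwise over the thresholds of an abundance curve. Bands are
#' pointwise in t (no multiplicity adjustment).
#'
#' @param curve an [abundance_curve()] result.
#' @param s per-channel efficiencies.
#' @param alpha significance level for the bands.
#' @return data.frame t, structure, w, n_hat, ci_low, ci_high.
#' @export
corrected_abundance_curve <- function(curve, s, alpha = 0.1) {
  k <- attr(curve, "k")
  stopifnot(!is.null(k))
  model <- substructure_model(k, s)
  out <- lapply(unique(curve$t), function(tt) {
    W <- curve_w_at(curve, tt)
    est <- estimate_true_abundances(W, model)
    cr <- confidence_region(est, alpha)
    data.frame(t = tt, structure = model$structures, w = as.numeric(W),
               n_hat = est$n_hat, ci_low = cr$intervals$lower,
               ci_high = cr$intervals$upper, row.names = NULL)
  })
  do.call(rbind, out)
}
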