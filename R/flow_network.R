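# distances are discretized to integer costs at this scale before they
# enter the flow solver; the induced total-cost error is below
# 1e-6 * (number of matched links)
COST_SCALE <- 1e6

#' Build the matching flow network for a channel span
#'
#' Encodes the unbalanced multi-marginal transport problem with chain
#' costs as a min-cost flow network: every particle becomes a split node
#' pair (v, v-hat) joined by an edge of cost -lambda/k' and capacity 1;
#' admissible adjacent-channel pairs (d <= t) become edges carrying the
#' distance as cost (inadmissible pairs are omitted rather than given
#' infinite cost); the source feeds the first channel layer, the last
#' layer drains into the target, and a direct (S, T) edge of cost 0 and
#' unbounded capacity keeps the problem feasible for any requested flow
#' m = min_j n_j.
#'
#' Integer costs: internally all costs are scaled by `1e6 * k'` so that
#' the -lambda/k' split costs stay integral; `cost_unscale` converts a
#' solver objective back to distance units.
#'
#' @param clouds a [point_cloud_set()] (possibly a subset/span view).
#' @param cfg a [match_config()].
#' @param span channel span (start, end) within `clouds`' own channels;
#'   default the full span.
#' @return object of class `flow_network`.
#' @export
build_flow_network <- function(clouds, cfg, span = c(1L, clouds$k)) {
  stopifnot(inherits(clouds, "point_cloud_set"), inherits(cfg, "match_config"))
  span <- as.integer(span)
  if (span[2] - span[1] < 1) stop("span must cover at least two channels")
  kprime <- span[2] - span[1] + 1L
  channels <- span[1]:span[2]
  counts <- clouds$counts[channels]
  t_span <- span_thresholds(cfg$t, clouds$k, span)
  m <- min(counts)
  lambda <- if (is.null(cfg$lambda)) default_lambda(t_span, m) else cfg$lambda

  S <- 1L; T <- 2L
  scale <- COST_SCALE * kprime

  if (m == 0L) {
    edges <- data.frame(from = S, to = T, cap = 1, cost = 0,
                        type = "st", ch = NA_integer_,
                        i = NA_integer_, j = NA_integer_)
    return(structure(list(n_nodes = 2L, edges = edges, S = S, T = T,
                          m = 0, kprime = kprime, channels = channels,
                          counts = counts, lambda = lambda,
                          scale = scale),
                     class = "flow_network"))
  }

  # node ids: channel-major, index-minor; v = base + 2l - 1, vhat = base + 2l
  base <- 2L + c(0L, cumsum(2L * counts))[seq_len(kprime)]
  v_id    <- function(a, l) base[a] + 2L * l - 1L
  vhat_id <- function(a, l) base[a] + 2L * l
  n_nodes <- 2L + sum(2L * counts)

  ef <- list(); et <- list(); ecap <- list(); ecost <- list()
  etype <- list(); ech <- list(); ei <- list(); ej <- list()
  push <- function(from, to, cap, cost, type, ch, i, j) {
    n <- length(ef) + 1L
    ef[[n]] <<- from; et[[n]] <<- to; ecap[[n]] <<- cap; ecost[[n]] <<- cost
    etype[[n]] <<- rep(type, length(from))
    ech[[n]] <<- ch; ei[[n]] <<- i; ej[[n]] <<- j
  }

  # direct source-target edge: feasibility at zero cost
  push(S, T, m, 0, "st", NA_integer_, NA_integer_, NA_integer_)
  # source -> first layer, last layer -> target
  l1 <- seq_len(counts[1])
  push(rep(S, counts[1]), v_id(1L, l1), rep(1, counts[1]), rep(0, counts[1]),
       "source", rep(channels[1], counts[1]), l1, rep(NA_integer_, counts[1]))
  lk <- seq_len(counts[kprime])
  push(vhat_id(kprime, lk), rep(T, counts[kprime]), rep(1, counts[kprime]),
       rep(0, counts[kprime]), "sink", rep(channels[kprime], counts[kprime]),
       lk, rep(NA_integer_, counts[kprime]))
  # split edges, cost -lambda/k' (times scale => -lambda * COST_SCALE)
  split_cost <- -round(lambda * COST_SCALE)
  for (a in seq_len(kprime)) {
    la <- seq_len(counts[a])
    if (counts[a] == 0) next
    push(v_id(a, la), vhat_id(a, la), rep(1, counts[a]),
         rep(split_cost, counts[a]), "split",
         rep(channels[a], counts[a]), la, rep(NA_integer_, counts[a]))
  }
  # admissible inter-channel edges only (d <= t)
  for (a in seq_len(kprime - 1L)) {
    D <- pairwise_distances(clouds, channels[a])
    adm <- which(D <= t_span[a], arr.ind = TRUE)
    if (nrow(adm) > 0) {
      dvals <- D[adm]
      push(vhat_id(a, adm[, 1]), v_id(a + 1L, adm[, 2]),
           rep(1, nrow(adm)), round(dvals * COST_SCALE) * kprime,
           "inter", rep(channels[a], nrow(adm)), adm[, 1], adm[, 2])
    }
  }

  edges <- data.frame(from = unlist(ef), to = unlist(et),
                      cap = unlist(ecap), cost = unlist(ecost),
                      type = unlist(etype), ch = unlist(ech),
                      i = unlist(ei), j = unlist(ej))
  structure(list(n_nodes = n_nodes, edges = edges, S = S, T = T, m = m,
                 kprime = kprime, channels = channels, counts = counts,
                 lambda = lambda, scale = scale),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat("flow_network: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges, m = ", x$m, ", channels ",
      paste(LETTERS[x$channels], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Solve a matching flow network exactly
#'
#' Successive-shortest-paths min-cost flow on integer costs; integrality
#' of the returned flow is guaranteed by construction (all capacities are
#' integral), matching the total-unimodularity argument for the transport
#' linear program.
#'
#' @param net a [build_flow_network()] result.
#' @return object of class `integer_flow`: per-edge flow, the objective in
#'   distance units (sum of matched distances minus lambda per chain), and
#'   the flow value.
#' @export
solve_min_cost_flow <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  e <- net$edges
  res <- .mcf_solve(net$n_nodes, e$from - 1L, e$to - 1L,
                    as.numeric(e$cap), as.numeric(e$cost),
                    net$S - 1L, net$T - 1L, net$m)
  if (!identical(res$status, "optimal")) {
    stop("min-cost flow solver failed with status '", res$status,
         "'; the network should always be feasible via the (S,T) edge")
  }
  flow <- res$flow
  if (any(abs(flow - round(flow)) > 1e-9)) {
    stop("solver returned a fractional flow") # cannot happen by construction
  }
  structure(list(flow = as.integer(round(flow)),
                 total_cost = res$total_cost / net$scale,
                 total_cost_scaled = res$total_cost,
                 flow_value = res$flow_value),
            class = "integer_flow")
}
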