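#' Exhaustive matching oracle
#'
#' Computes the optimal full-span chain matching (maximal number of
#' pairwise-disjoint chains with all consecutive distances <= t; minimal
#' summed distance among maximal matchings) by exhaustive enumeration:
#' for each candidate chain count c, every subset of starting particles
#' and every injective layer-to-layer assignment is enumerated, keeping
#' the cheapest completion per endpoint subset. Because the transport
#' linear program's constraint matrix is totally unimodular, this integer
#' optimum equals the LP optimum of the unbalanced multi-marginal
#' problem, so the oracle doubles as an independent check of the flow
#' solver's objective. Intended for small instances (n_j up to ~8).
#'
#' @param clouds a [point_cloud_set()].
#' @param t threshold (scalar or per adjacent pair).
#' @param max_n refuse instances with any channel larger than this.
#' @return list(max_chain_count, min_cost).
#' @export
brute_force_matching_oracle <- function(clouds, t, max_n = 12L) {
  k <- clouds$k
  if (any(clouds$counts > max_n)) {
    stop("instance too large for exhaustive enumeration")
  }
  t_all <- if (length(t) == 1) rep(t, k - 1L) else t
  stopifnot(length(t_all) == k - 1L)
  D <- lapply(seq_len(k - 1L), function(j) pairwise_distances(clouds, j))
  n <- clouds$counts
  m_max <- min(n)
  if (m_max == 0) return(list(max_chain_count = 0L, min_cost = 0))

  subsets_of_size <- function(nn, c) {
    if (c == 0) return(list(integer(0)))
    cmb <- utils::combn(nn, c)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  # all injective admissible assignments of `members` (indices in layer j)
  # into layer j+1; returns list of list(targets, cost)
  assignments <- function(members, j) {
    if (length(members) == 0) return(list(list(targets = integer(0), cost = 0)))
    res <- list()
    recurse <- function(pos, used, targets, cost) {
      if (pos > length(members)) {
        res[[length(res) + 1L]] <<- list(targets = targets, cost = cost)
        return(invisible())
      }
      i <- members[pos]
      for (mm in seq_len(n[j + 1])) {
        if (!used[mm] && D[[j]][i, mm] <= t_all[j]) {
          used[mm] <- TRUE
          recurse(pos + 1L, used, c(targets, mm), cost + D[[j]][i, mm])
          used[mm] <- FALSE
        }
      }
      invisible()
    }
    recurse(1L, logical(n[j + 1]), integer(0), 0)
    res
  }

  for (c in seq(m_max, 1L)) {
    # states: endpoint subset at current layer -> min cost
    states <- new.env(parent = emptyenv())
    for (s in subsets_of_size(n[1], c)) {
      assign(paste(s, collapse = ","), 0, envir = states)
    }
    for (j in seq_len(k - 1L)) {
      nxt <- new.env(parent = emptyenv())
      for (key in ls(states)) {
        members <- as.integer(strsplit(key, ",")[[1]])
        base_cost <- get(key, envir = states)
        for (a in assignments(members, j)) {
          nk <- paste(sort(a$targets), collapse = ",")
          nc <- base_cost + a$cost
          old <- get0(nk, envir = nxt, ifnotfound = Inf)
          if (nc < old) assign(nk, nc, envir = nxt)
        }
      }
      states <- nxt
      if (length(ls(states)) == 0) break
    }
    finals <- ls(states)
    if (length(finals) > 0) {
      costs <- vapply(finals, function(key) get(key, envir = states),
                      numeric(1))
      return(list(max_chain_count = c, min_cost = min(costs)))
    }
  }
  list(max_chain_count = 0L, min_cost = 0)
}
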