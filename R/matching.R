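#' Extract the chain matching encoded by an optimal flow
#'
#' Follows unit flows through the network layers: the transport plan
#' entry for a tuple is the product of the inter-channel edge flows along
#' its path, so every unit of flow that enters the particle layers traces
#' exactly one chain over the network's channel span.
#'
#' @param flow an [solve_min_cost_flow()] result (must be integral).
#' @param net the network it solved.
#' @return object of class `chain_matching` for the network's span:
#'   `chains` is an integer matrix (one row per chain, one column per
#'   channel of the span, particle indices local to the network's
#'   clouds), `cost` the summed matched distance (from the scaled solver
#'   objective plus lambda per chain).
#' @export
extract_chain_matching <- function(flow, net) {
  stopifnot(inherits(flow, "integer_flow"), inherits(net, "flow_network"))
  e <- net$edges
  kprime <- net$kprime
  chan <- net$channels
  if (net$m == 0 || kprime == 0) {
    return(structure(list(chains = matrix(integer(0), 0, kprime),
                          channels = chan, cost = 0),
                     class = "chain_matching"))
  }
  f <- flow$flow
  inter <- e$type == "inter" & f == 1L
  # next_idx[[a]]: map particle i in span position a -> matched j in a+1
  next_idx <- vector("list", kprime - 1L)
  for (a in seq_len(kprime - 1L)) {
    sel <- inter & e$ch == chan[a]
    nx <- rep(NA_integer_, net$counts[a])
    nx[e$i[sel]] <- e$j[sel]
    next_idx[[a]] <- nx
  }
  start_sel <- e$type == "split" & e$ch == chan[1] & f == 1L
  starts <- sort(e$i[start_sel])
  chains <- matrix(NA_integer_, length(starts), kprime)
  if (length(starts) > 0) {
    chains[, 1] <- starts
    for (a in seq_len(kprime - 1L)) {
      chains[, a + 1L] <- next_idx[[a]][chains[, a]]
    }
    if (anyNA(chains)) stop("flow conservation violated during extraction")
  }
  n_chains <- nrow(chains)
  cost <- flow$total_cost + net$lambda * n_chains
  structure(list(chains = chains, channels = chan, cost = cost),
            class = "chain_matching")
}

#' @export
print.chain_matching <- function(x, ...) {
  cat("chain_matching: ", nrow(x$chains), " chains over channels ",
      paste(LETTERS[x$channels], collapse = ""),
      ", summed distance ", format(x$cost), "\n", sep = "")
  invisible(x)
}

# solve one span of a cloud set and return chains in the clouds' own
# particle indexing
match_span <- function(clouds, cfg, span) {
  net <- build_flow_network(clouds, cfg, span)
  fl <- solve_min_cost_flow(net)
  extract_chain_matching(fl, net)
}

#' Match chain structures in a point cloud set
#'
#' Runs the configured matching mode and tallies structure abundances.
#'
#' **Mode I** first solves the full k-marginal problem, which yields the
#' maximal number of full chains (smallest summed distance among maximal
#' matchings); matched particles are removed, then each structure in the
#' priority order (default: longest first, left-to-right) is matched on
#' the leftovers by the same flow construction restricted to its span.
#' Unmatched particles are reported as singlets.
#'
#' **Mode II** solves the k - 1 adjacent-pair problems independently on
#' the full clouds and couples pairs sharing a particle into maximal
#' chains (an AB and a BC pair occupying the same B particle become an
#' ABC triplet).
#'
#' @param clouds a [point_cloud_set()].
#' @param cfg a [match_config()].
#' @return list with `structures` (data.frame: chain_id, structure,
#'   channel, particle_index, coordinate columns), `abundance` (named
#'   integer vector over all structure names incl. singlets) and
#'   `total_cost` (summed matched distances over all multi-particle
#'   structures).
#' @export
match_chains <- function(clouds, cfg) {
  stopifnot(inherits(clouds, "point_cloud_set"), inherits(cfg, "match_config"))
  if (length(cfg$t) != 1 && length(cfg$t) != clouds$k - 1) {
    stop("t must be scalar or give one threshold per adjacent channel pair")
  }
  if (cfg$mode == "I") match_mode1(clouds, cfg) else match_mode2(clouds, cfg)
}

#' @rdname match_chains
#' @export
match_mode1 <- function(clouds, cfg) {
  k <- clouds$k
  priority <- cfg$priority
  if (is.null(priority)) priority <- default_priority(k)
  spans <- lapply(priority, structure_span, k = k) # validates contiguity
  # ensure the full chain is matched first
  full <- vapply(spans, function(s) s[1] == 1 && s[2] == k, logical(1))
  if (!any(full)) {
    spans <- c(list(c(1L, k)), spans)
  } else {
    spans <- c(spans[full][1], spans[!full])
  }

  avail <- lapply(clouds$counts, seq_len)
  assigned <- list() # per structure: matrix of original indices
  total_cost <- 0
  for (s in spans) {
    if (any(vapply(avail[s[1]:s[2]], length, integer(1)) == 0)) next
    sub <- subset_clouds(clouds, avail)
    subspan <- span_clouds(sub, s)
    cm <- match_span(subspan, cfg_for_span(cfg, k, s), c(1L, s[2] - s[1] + 1L))
    if (nrow(cm$chains) > 0) {
      # map back: subspan indices -> original indices
      orig <- matrix(NA_integer_, nrow(cm$chains), ncol(cm$chains))
      for (a in seq_len(ncol(cm$chains))) {
        orig[, a] <- subspan$orig_index[[a]][cm$chains[, a]]
      }
      nm <- span_name(s[1], s[2])
      assigned[[nm]] <- rbind(assigned[[nm]], orig)
      total_cost <- total_cost + cm$cost
      for (a in seq_len(ncol(orig))) {
        ch <- s[1] + a - 1L
        avail[[ch]] <- setdiff(avail[[ch]], orig[, a])
      }
    }
  }
  finalize_matching(clouds, assigned, avail, total_cost, cfg)
}

# a span-restricted config: per-pair thresholds sliced, lambda re-derived
# for the span length unless fixed by the user
cfg_for_span <- function(cfg, k, span) {
  t_span <- span_thresholds(cfg$t, k, span)
  match_config(t = t_span, lambda = cfg$lambda, mode = cfg$mode,
               priority = cfg$priority, scale_channel = cfg$scale_channel)
}

#' @rdname match_chains
#' @export
match_mode2 <- function(clouds, cfg) {
  k <- clouds$k
  # independent two-marginal problems per adjacent pair
  pair_matches <- vector("list", k - 1L)
  total_cost <- 0
  for (j in seq_len(k - 1L)) {
    cm <- match_span(clouds, cfg_for_span(cfg, k, c(j, j + 1L)),
                     c(j, j + 1L))
    pair_matches[[j]] <- cm$chains
    total_cost <- total_cost + cm$cost
  }
  # union-find over (channel, index) coupling pairs that share a particle
  node_id <- function(ch, i) paste0(ch, ".", i)
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (p != x) {
      p <- find(p)
      assign(x, p, envir = parent)
    }
    p
  }
  union <- function(x, y) assign(find(x), find(y), envir = parent)
  members <- new.env(parent = emptyenv())
  for (j in seq_len(k - 1L)) {
    ch <- pair_matches[[j]]
    for (r in seq_len(nrow(ch))) {
      union(node_id(j, ch[r, 1]), node_id(j + 1L, ch[r, 2]))
    }
  }
  # collect components
  comp <- list()
  for (j in seq_len(k - 1L)) {
    ch <- pair_matches[[j]]
    for (r in seq_len(nrow(ch))) {
      for (col in 1:2) {
        chan <- j + col - 1L
        idx <- ch[r, col]
        root <- find(node_id(chan, idx))
        comp[[root]] <- unique(rbind(comp[[root]], c(chan, idx)))
      }
    }
  }
  assigned <- list()
  used <- lapply(clouds$counts, function(n) logical(n))
  for (cc in comp) {
    cc <- cc[order(cc[, 1]), , drop = FALSE]
    s <- c(cc[1, 1], cc[nrow(cc), 1])
    stopifnot(nrow(cc) == s[2] - s[1] + 1) # coupled pairs form a path
    nm <- span_name(s[1], s[2])
    assigned[[nm]] <- rbind(assigned[[nm]], cc[, 2])
    for (r in seq_len(nrow(cc))) used[[cc[r, 1]]][cc[r, 2]] <- TRUE
  }
  avail <- lapply(seq_len(k), function(ch) which(!used[[ch]]))
  finalize_matching(clouds, assigned, avail, total_cost, cfg)
}

# assemble abundance vector + long-format structure table
finalize_matching <- function(clouds, assigned, avail, total_cost, cfg) {
  k <- clouds$k
  nms <- structure_names(k)
  abundance <- setNames(integer(length(nms)), nms)
  for (nm in names(assigned)) {
    abundance[nm] <- nrow(assigned[[nm]])
  }
  for (ch in seq_len(k)) {
    abundance[LETTERS[ch]] <- length(avail[[ch]])
  }
  rows <- list()
  chain_id <- 0L
  dimnames_xyz <- c("x", "y", "z")[seq_len(clouds$dim)]
  for (nm in names(assigned)) {
    s <- structure_span(nm, k)
    mat <- assigned[[nm]]
    for (r in seq_len(nrow(mat))) {
      chain_id <- chain_id + 1L
      for (a in seq_len(ncol(mat))) {
        ch <- s[1] + a - 1L
        idx <- mat[r, a]
        co <- clouds$coords[[ch]][idx, ]
        rows[[length(rows) + 1L]] <- data.frame(
          chain_id = chain_id, structure = nm, channel = LETTERS[ch],
          particle_index = idx,
          as.list(setNames(co, dimnames_xyz)))
      }
    }
  }
  for (ch in seq_len(k)) {
    for (idx in avail[[ch]]) {
      chain_id <- chain_id + 1L
      co <- clouds$coords[[ch]][idx, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = chain_id, structure = LETTERS[ch], channel = LETTERS[ch],
        particle_index = idx,
        as.list(setNames(co, dimnames_xyz)))
    }
  }
  structures <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chain_id = integer(0), structure = character(0),
               channel = character(0), particle_index = integer(0))
  list(structures = structures, abundance = abundance,
       total_cost = total_cost, mode = cfg$mode, t = cfg$t)
}

#' Greedy nearest-neighbor baseline matching
#'
#' For each adjacent channel pair, repeatedly matches the globally
#' closest unmatched pair with distance <= t (ties broken by channel,
#' then row, then column index), then couples shared particles exactly
#' like Mode II. Locally optimal pairing is known to break chains that
#' the global matching preserves, underestimating full-chain counts in
#' dense fields.
#'
#' @param clouds a [point_cloud_set()].
#' @param t colocalization threshold (scalar or per pair).
#' @return same shape as [match_chains()].
#' @export
nearest_neighbor_matching <- function(clouds, t) {
  k <- clouds$k
  t_all <- if (length(t) == 1) rep(t, k - 1L) else t
  stopifnot(length(t_all) == k - 1L)
  pair_matches <- vector("list", k - 1L)
  total_cost <- 0
  for (j in seq_len(k - 1L)) {
    D <- pairwise_distances(clouds, j)
    adm <- which(D <= t_all[j], arr.ind = TRUE)
    sel <- matrix(integer(0), 0, 2)
    if (nrow(adm) > 0) {
      dv <- D[adm]
      ord <- order(dv, adm[, 1], adm[, 2])
      adm <- adm[ord, , drop = FALSE]
      dv <- dv[ord]
      used_i <- logical(nrow(D)); used_j <- logical(ncol(D))
      for (r in seq_len(nrow(adm))) {
        i <- adm[r, 1]; jj <- adm[r, 2]
        if (!used_i[i] && !used_j[jj]) {
          used_i[i] <- TRUE; used_j[jj] <- TRUE
          sel <- rbind(sel, c(i, jj))
          total_cost <- total_cost + dv[r]
        }
      }
    }
    pair_matches[[j]] <- sel
  }
  couple_pairs(clouds, pair_matches, total_cost)
}

# shared Mode II-style coupling used by the greedy baseline
couple_pairs <- function(clouds, pair_matches, total_cost) {
  k <- clouds$k
  node_key <- function(ch, i) ch * (max(clouds$counts) + 1L) + i
  # simple iterative union-find over integer keys
  parent <- integer(0); keys <- integer(0)
  key_pos <- function(key) {
    p <- match(key, keys)
    if (is.na(p)) {
      keys[length(keys) + 1L] <<- key
      parent[length(parent) + 1L] <<- length(parent) + 1L
      p <- length(parent)
    }
    p
  }
  find <- function(p) {
    while (parent[p] != p) p <- parent[p]
    p
  }
  comp_members <- list()
  for (j in seq_len(k - 1L)) {
    ch <- pair_matches[[j]]
    for (r in seq_len(nrow(ch))) {
      p1 <- key_pos(node_key(j, ch[r, 1]))
      p2 <- key_pos(node_key(j + 1L, ch[r, 2]))
      parent[find(p1)] <- find(p2)
    }
  }
  if (length(keys) > 0) {
    roots <- vapply(seq_along(keys), find, integer(1))
    base <- max(clouds$counts) + 1L
    for (g in split(seq_along(keys), roots)) {
      cc <- cbind(keys[g] %/% base, keys[g] %% base)
      comp_members[[length(comp_members) + 1L]] <- cc
    }
  }
  assigned <- list()
  used <- lapply(clouds$counts, function(n) logical(n))
  for (cc in comp_members) {
    cc <- cc[order(cc[, 1]), , drop = FALSE]
    s <- c(cc[1, 1], cc[nrow(cc), 1])
    nm <- span_name(s[1], s[2])
    assigned[[nm]] <- rbind(assigned[[nm]], cc[, 2])
    for (r in seq_len(nrow(cc))) used[[cc[r, 1]]][cc[r, 2]] <- TRUE
  }
  avail <- lapply(seq_len(k), function(ch) which(!used[[ch]]))
  finalize_matching(clouds, assigned, avail, total_cost,
                    match_config(t = 0, mode = "II"))
}
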