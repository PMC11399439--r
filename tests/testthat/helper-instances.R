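# build a point_cloud_set from a list of x/y coordinate vectors
make_clouds <- function(..., unit = "px") {
  coords <- lapply(list(...), function(p) {
    matrix(unlist(p), ncol = 2, byrow = TRUE)
  })
  point_cloud_set(coords, unit = unit)
}

# random small matching instance; channels may be empty
random_clouds <- function(k, n_max = 5, box = 10) {
  n <- sample(0:n_max, k, replace = TRUE)
  point_cloud_set(lapply(n, function(m) {
    matrix(runif(2 * m, 0, box), ncol = 2)
  }))
}

# disjointness + per-channel conservation of a match_chains() result
expect_valid_matching <- function(res, clouds, t) {
  df <- res$structures
  for (ch in channel_letters(clouds$k)) {
    idx <- df$particle_index[df$channel == ch]
    expect_false(any(duplicated(idx)), info = paste("channel", ch))
    expect_equal(length(idx), clouds$counts[match(ch, LETTERS)])
  }
  # every multi-particle structure is a valid chain: consecutive
  # distances at or below the (per-pair) threshold
  k <- clouds$k
  t_all <- if (length(t) == 1) rep(t, k - 1) else t
  multi <- df[nchar(df$structure) > 1, ]
  for (id in unique(multi$chain_id)) {
    part <- multi[multi$chain_id == id, ]
    part <- part[order(match(part$channel, LETTERS)), ]
    for (r in seq_len(nrow(part) - 1)) {
      ch <- match(part$channel[r], LETTERS)
      d <- sqrt(sum((unlist(part[r, c("x", "y")]) -
                       unlist(part[r + 1, c("x", "y")]))^2))
      expect_lte(d, t_all[ch] + 1e-9)
    }
  }
  invisible(res)
}

# abundance of full-span chains
full_count <- function(res, k) unname(res$abundance[structure_names(k)[1]])

# frozen three-color reference matrices (hand-derived closed forms of
# the detection model): aggregation matrix, triplet pattern probabilities
# and the inverse correction map
ref_theta <- rbind(
  c(1, 0, 0, 0, 0, 0, 0, 0),
  c(0, 1, 0, 0, 0, 0, 0, 0),
  c(0, 0, 1, 0, 0, 0, 0, 0),
  c(0, 0, 0, 1, 1, 0, 0, 0),
  c(0, 0, 0, 0, 0, 1, 0, 0),
  c(0, 0, 0, 1, 0, 0, 1, 0))

ref_p_abc <- function(s) {
  sA <- s[1]; sB <- s[2]; sC <- s[3]
  c(sA * sB * sC, sA * sB * (1 - sC), (1 - sA) * sB * sC,
    sA * (1 - sB) * sC, sA * (1 - sB) * (1 - sC),
    (1 - sA) * sB * (1 - sC), (1 - sA) * (1 - sB) * sC,
    (1 - sA) * (1 - sB) * (1 - sC))
}

ref_inverse <- function(s) {
  sA <- s[1]; sB <- s[2]; sC <- s[3]
  rbind(
    c(1 / (sA * sB * sC), 0, 0, 0, 0, 0),
    c((sC - 1) / (sA * sB * sC), 1 / (sA * sB), 0, 0, 0, 0),
    c((sA - 1) / (sA * sB * sC), 0, 1 / (sB * sC), 0, 0, 0),
    c((sB - 1) / (sA * sB), (sB - 1) / (sA * sB), 0, 1 / sA, 0, 0),
    c((1 - sA) * (1 - sC) / (sA * sB * sC), (sA - 1) / (sA * sB),
      (sC - 1) / (sB * sC), 0, 1 / sB, 0),
    c((sB - 1) / (sB * sC), 0, (sB - 1) / (sB * sC), 0, 0, 1 / sC))
}
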