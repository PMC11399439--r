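test_that("Mode I prefers a full chain over two pairs", {
  # triplet A-B-C plus a second C nearby: the chain wins even though
  # matching two pairs through the extra C would be locally cheaper
  cl <- make_clouds(c(0, 0), c(1, 0), list(c(2, 0), c(1.4, 0.4)))
  res <- match_chains(cl, match_config(t = 1.5, mode = "I"))
  expect_equal(unname(res$abundance),
               c(ABC = 1L, AB = 0L, BC = 0L, A = 0L, B = 0L, C = 1L),
               ignore_attr = TRUE)
  orc <- brute_force_matching_oracle(cl, 1.5)
  expect_equal(full_count(res, 3), orc$max_chain_count)
})

test_that("well-separated simulated triplets are all recovered", {
  # 10 triplets with 1-px links, 100 px apart: matching is unique
  centers <- cbind(seq(0, 900, by = 100), 0)
  cl <- point_cloud_set(list(centers, sweep(centers, 2, c(1, 0), "+"),
                             sweep(centers, 2, c(2, 0), "+")))
  res <- match_chains(cl, match_config(t = 1.5, mode = "I"))
  expect_equal(full_count(res, 3), 10L)
  expect_equal(sum(res$abundance), 10L)
})

test_that("empty input gives all-zero abundances in both modes", {
  cl <- point_cloud_set(replicate(3, matrix(numeric(0), 0, 2),
                                  simplify = FALSE))
  for (mode in c("I", "II")) {
    res <- match_chains(cl, match_config(t = 2, mode = mode))
    expect_true(all(res$abundance == 0L))
  }
})

test_that("Mode I equals the exhaustive oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    k <- sample(2:4, 1)
    cl <- random_clouds(k)
    t <- runif(1, 0, 12)
    cfg <- match_config(t = t, mode = "I")
    res <- match_chains(cl, cfg)
    orc <- brute_force_matching_oracle(cl, t)
    expect_equal(full_count(res, k), orc$max_chain_count)
    expect_valid_matching(res, cl, t)
    # the flow objective equals the optimum of the transport linear
    # program (computed independently by enumeration; they coincide by
    # total unimodularity)
    net <- build_flow_network(cl, cfg)
    if (net$m > 0) {
      fl <- solve_min_cost_flow(net)
      expect_true(all(fl$flow == round(fl$flow)))
      expect_equal(fl$total_cost,
                   orc$min_cost - net$lambda * orc$max_chain_count,
                   tolerance = 1e-4)
      cm <- extract_chain_matching(fl, net)
      expect_equal(nrow(cm$chains), orc$max_chain_count)
      expect_equal(cm$cost, orc$min_cost, tolerance = 1e-4)
    }
  }
})

test_that("results are insensitive to lambda above the bound", {
  set.seed(77)
  for (rep in 1:10) {
    cl <- random_clouds(3)
    t <- runif(1, 0, 8)
    m <- min(cl$counts)
    base <- 2 * m * t + 1
    r1 <- match_chains(cl, match_config(t = t, lambda = base))
    r2 <- match_chains(cl, match_config(t = t, lambda = 10 * base + 5))
    expect_equal(r1$abundance, r2$abundance)
  }
})

test_that("Mode II couples pairs through shared particles", {
  # isolated triplet: identical to Mode I
  cl <- make_clouds(c(0, 0), c(1, 0), c(2, 0))
  r1 <- match_chains(cl, match_config(t = 1.5, mode = "I"))
  r2 <- match_chains(cl, match_config(t = 1.5, mode = "II"))
  expect_equal(r1$abundance, r2$abundance)

  # a four-channel chain becomes one quadruplet via AB + BC + CD
  cl4 <- make_clouds(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  r4 <- match_chains(cl4, match_config(t = 1.5, mode = "II"))
  expect_equal(unname(r4$abundance["ABCD"]), 1L)
  expect_equal(sum(r4$abundance), 1L)
})

test_that("pairwise optima can split a chain that Mode I preserves", {
  # two B candidates: the AB problem alone prefers the closer B, which
  # breaks the only triplet; the multi-marginal problem keeps it
  cl <- point_cloud_set(list(
    matrix(c(0, 0), 1, 2),                       # A
    matrix(c(1, 0, -0.5, 0), 2, 2, byrow = TRUE), # B1, B2
    matrix(c(1.9, 0), 1, 2)))                    # C
  t <- 1.2
  r1 <- match_chains(cl, match_config(t = t, mode = "I"))
  r2 <- match_chains(cl, match_config(t = t, mode = "II"))
  expect_equal(unname(r1$abundance["ABC"]), 1L)
  expect_equal(unname(r2$abundance["ABC"]), 0L)
  expect_equal(unname(r2$abundance[c("AB", "BC")]), c(1L, 1L))
  # each mode is internally consistent with its own oracle
  expect_equal(full_count(r1, 3),
               brute_force_matching_oracle(cl, t)$max_chain_count)
})

test_that("greedy nearest-neighbor matching underestimates chains", {
  # one isolated pair: greedy agrees with the transport matching
  cl <- make_clouds(c(0, 0), c(1, 0))
  expect_equal(nearest_neighbor_matching(cl, 1.5)$abundance,
               match_chains(cl, match_config(t = 1.5))$abundance)

  # the globally closest A-B pair uses the B that the triplet needs
  cl3 <- point_cloud_set(list(
    matrix(c(0, 0), 1, 2),                        # A
    matrix(c(1, 0, -0.6, 0), 2, 2, byrow = TRUE), # B1 (chain), B2 (decoy)
    matrix(c(2, 0), 1, 2)))                       # C
  nn <- nearest_neighbor_matching(cl3, 1.2)
  ot <- match_chains(cl3, match_config(t = 1.2, mode = "I"))
  expect_lt(unname(nn$abundance["ABC"]), unname(ot$abundance["ABC"]))

  # empty input
  cl0 <- point_cloud_set(replicate(2, matrix(numeric(0), 0, 2),
                                   simplify = FALSE))
  expect_true(all(nearest_neighbor_matching(cl0, 1)$abundance == 0L))
})

test_that("per-pair thresholds gate edge admission independently", {
  cl <- make_clouds(c(0, 0), c(1, 0), c(3, 0))
  res <- match_chains(cl, match_config(t = c(1.5, 1), mode = "I"))
  expect_equal(unname(res$abundance["ABC"]), 0L)
  expect_equal(unname(res$abundance["AB"]), 1L)
  res2 <- match_chains(cl, match_config(t = c(1.5, 2.5), mode = "I"))
  expect_equal(unname(res2$abundance["ABC"]), 1L)
})

test_that("non-contiguous priority structures are rejected", {
  cl <- make_clouds(c(0, 0), c(1, 0), c(2, 0))
  expect_error(match_chains(cl, match_config(t = 1.5, priority = c("AC"))),
               "contiguous")
})

test_that("Mode I solves exactly the leftover structures in the priority list", {
  # B and C could pair, but a priority list without BC leaves them as
  # singlets; the default priority matches them
  cl <- make_clouds(c(10, 10), c(0, 0), c(1, 0))
  only_ab <- match_chains(cl, match_config(t = 1.5, priority = c("AB")))
  expect_equal(unname(only_ab$abundance[c("BC", "B", "C")]), c(0L, 1L, 1L))
  default <- match_chains(cl, match_config(t = 1.5))
  expect_equal(unname(default$abundance[c("BC", "B", "C")]), c(1L, 0L, 0L))
})
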