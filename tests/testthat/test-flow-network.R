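test_that("network construction follows the split-node recipe", {
  cl <- make_clouds(c(0, 0), c(1, 0), c(2, 0))
  net <- build_flow_network(cl, match_config(t = 1.5))
  expect_equal(net$n_nodes, 8L) # S, T, and a split pair per particle
  expect_equal(nrow(net$edges), 8L)
  expect_equal(sum(net$edges$type == "split"), 3L)
  expect_equal(sum(net$edges$type == "inter"), 2L)
  expect_equal(sum(net$edges$type %in% c("source", "sink", "st")), 3L)
  # split edges carry -lambda/k' (scaled); capacities 1 except (S,T)
  split <- net$edges[net$edges$type == "split", ]
  expect_true(all(split$cost == -round(net$lambda * 1e6)))
  expect_true(all(net$edges$cap[net$edges$type != "st"] == 1))
})

test_that("degenerate networks stay valid", {
  # an empty channel leaves only the (S,T) edge
  cl <- point_cloud_set(list(matrix(numeric(0), 0, 2), matrix(0, 1, 2)))
  net <- build_flow_network(cl, match_config(t = 1))
  expect_equal(net$n_nodes, 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$m, 0)
  res <- match_chains(cl, match_config(t = 1))
  expect_equal(unname(res$abundance), c(0L, 0L, 1L))

  # t = 0 with distinct points admits no inter-channel edges; all flow
  # crosses the zero-cost (S,T) edge
  cl <- make_clouds(list(c(0, 0), c(5, 5)), c(1, 1), list(c(2, 2), c(6, 6)))
  net <- build_flow_network(cl, match_config(t = 0))
  expect_equal(sum(net$edges$type == "inter"), 0L)
  fl <- solve_min_cost_flow(net)
  expect_equal(fl$total_cost, 0)
  st_flow <- fl$flow[net$edges$type == "st"]
  expect_equal(st_flow, as.integer(net$m))
})

test_that("a single in-range triplet yields one unit of chain flow", {
  cl <- make_clouds(c(0, 0), c(1, 0), c(2, 0))
  net <- build_flow_network(cl, match_config(t = 1.5))
  fl <- solve_min_cost_flow(net)
  expect_equal(fl$total_cost, 2 - net$lambda, tolerance = 1e-6)
  expect_true(all(fl$flow == round(fl$flow))) # integrality
  cm <- extract_chain_matching(fl, net)
  expect_equal(cm$chains, matrix(1L, 1, 3))
  expect_equal(cm$cost, 2, tolerance = 1e-6)
})

test_that("coincident particles match at any threshold", {
  cl <- make_clouds(c(2, 2), c(2, 2))
  res <- match_chains(cl, match_config(t = 0))
  expect_equal(unname(res$abundance["AB"]), 1L)
})
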