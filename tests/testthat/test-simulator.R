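test_that("simulation is reproducible under a fixed seed", {
  sc <- canonical_scenario("2")
  set.seed(17); gt1 <- simulate_chain_points(sc)
  set.seed(17); gt2 <- simulate_chain_points(sc)
  expect_identical(gt1$points, gt2$points)
  set.seed(17); im1 <- render_sted_image(gt1)
  set.seed(17); im2 <- render_sted_image(gt2)
  expect_identical(im1$channels, im2$channels)
})

test_that("ground truth respects structure counts and the pixel grid", {
  sc <- sim_scenario(c(ABC = 20, AB = 10, C = 5), k = 3)
  set.seed(29)
  gt <- simulate_chain_points(sc)
  p <- gt$points
  expect_equal(sum(p$structure == "ABC"), 60L)
  expect_equal(sum(p$structure == "AB"), 20L)
  expect_equal(sum(p$structure == "C"), 5L)
  expect_equal(sum(p$channel == 1), 30L) # 20 ABC + 10 AB
  expect_true(all(p$x == round(p$x) & p$y == round(p$y)))
  expect_true(all(p$x >= 0 & p$x <= 399 & p$y >= 0 & p$y <= 399))

  empty <- simulate_chain_points(sim_scenario(c(ABC = 0), k = 3))
  expect_equal(nrow(empty$points), 0L)
})

test_that("link lengths center on 70 nm = 2.8 px", {
  set.seed(37)
  sc <- sim_scenario(c(ABC = 2000), k = 3)
  gt <- simulate_chain_points(sc)
  p <- gt$points
  d <- numeric(0)
  for (ch in 1:2) {
    a <- p[p$channel == ch, ]
    b <- p[p$channel == ch + 1, ]
    stopifnot(all(a$struct_id == b$struct_id))
    d <- c(d, sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
  }
  # mean link length ~ N(2.8, 0.5) plus grid rounding
  expect_equal(mean(d), 2.8, tolerance = 0.05)
})

test_that("near-linear triplets are approximately straight", {
  set.seed(38)
  gt <- simulate_chain_points(sim_scenario(c(ABC = 500), k = 3))
  p <- gt$points
  a <- p[p$channel == 1, c("x", "y")]
  b <- p[p$channel == 2, c("x", "y")]
  cc <- p[p$channel == 3, c("x", "y")]
  ac <- sqrt(rowSums((a - cc)^2))
  # outer particles sit on opposite sides of B: A-C spans ~2 links
  expect_gt(mean(ac), 4.5)
})

test_that("labeling-efficiency thinning is Bernoulli per channel", {
  set.seed(43)
  sc <- sim_scenario(c(A = 4000, B = 4000, C = 4000), k = 3)
  gt <- simulate_chain_points(sc)
  thin <- apply_labeling_efficiency(gt, 0.95)
  kept <- nrow(thin$points) / nrow(gt$points)
  se <- sqrt(0.95 * 0.05 / nrow(gt$points))
  expect_lt(abs(kept - 0.95), 3 * se)
  # s = 1 leaves the ground truth untouched
  expect_identical(apply_labeling_efficiency(gt, 1)$points, gt$points)
  # intact-triplet survival ~ sA sB sC
  set.seed(44)
  gt3 <- simulate_chain_points(sim_scenario(c(ABC = 3000), k = 3))
  th3 <- apply_labeling_efficiency(gt3, c(0.9, 0.8, 0.95))
  intact <- sum(table(th3$points$struct_id) == 3)
  p_full <- 0.9 * 0.8 * 0.95
  se3 <- sqrt(p_full * (1 - p_full) / 3000)
  expect_lt(abs(intact / 3000 - p_full), 3 * se3)
})

test_that("misdetection counts follow the multinomial model", {
  m1 <- substructure_model(3, 1)
  n_true <- c(ABC = 10, AB = 4, BC = 3, A = 2, B = 1, C = 5)
  expect_equal(simulate_misdetection_counts(n_true, m1),
               setNames(as.numeric(n_true), names(n_true)))
  set.seed(47)
  m <- substructure_model(3, 0.95)
  W <- simulate_misdetection_counts(c(1000, 0, 0, 0, 0, 0), m, draws = 400)
  expect_true(all(W >= 0), all(W == round(W)))
  mean_abc <- mean(W["ABC", ])
  se <- stats::sd(W["ABC", ]) / sqrt(400)
  expect_lt(abs(mean_abc - 1000 * 0.95^3), 3 * se + 1e-9)
})

test_that("rendering places Gaussian spots with Poisson noise", {
  sc <- sim_scenario(c(A = 0, B = 0), k = 2, image_size = 64,
                     background = 0)
  gt <- simulate_chain_points(sc)
  img <- render_sted_image(gt)
  expect_true(all(img$channels[[1]] == 0))

  # a single particle: the noiseless argmax is its pixel
  sc1 <- sim_scenario(c(A = 1, B = 0), k = 2, image_size = 64)
  set.seed(53)
  gt1 <- simulate_chain_points(sc1)
  gt1$points$x <- 20; gt1$points$y <- 30 # keep the spot well interior
  sig <- render_sted_image(gt1, noiseless = TRUE)$channels[[1]]
  pk <- which(sig == max(sig), arr.ind = TRUE)
  expect_equal(unname(pk[1, ] - 1),
               c(gt1$points$x[1], gt1$points$y[1]))
  # superposition: expected signal scales linearly with particle count
  gt2 <- gt1
  gt2$points <- rbind(gt1$points, transform(gt1$points, x = x + 20))
  sig2 <- render_sted_image(gt2, noiseless = TRUE)$channels[[1]]
  expect_equal(sum(sig2), 2 * sum(sig), tolerance = 1e-6)
  # rendered counts are nonnegative integers
  set.seed(54)
  noisy <- render_sted_image(gt1)$channels[[1]]
  expect_true(all(noisy >= 0), all(noisy == round(noisy)))
})
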