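test_that("the three-color model matches its hand-derived closed form entrywise", {
  set.seed(31)
  for (rep in 1:5) {
    s <- runif(3, 0.3, 1)
    m <- substructure_model(3, s)
    expect_equal(unname(m$theta), ref_theta)
    expect_equal(unname(m$mu[, "ABC"]), ref_p_abc(s))
    expect_equal(unname(m$inverse_map), ref_inverse(s), tolerance = 1e-12)
    expect_equal(m$inverse_map[1, 1], 1 / prod(s))
    # every p vector is a probability distribution
    expect_equal(unname(colSums(m$mu)), rep(1, 6))
  }
})

test_that("pattern probabilities follow independent Bernoulli detection", {
  p <- substructure_probabilities("AB", 3, c(0.5, 0.5, 0.9))
  expect_equal(unname(p[c("AB", "A", "B", "none")]),
               c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(p), 1)
  expect_equal(unname(p["ABC"]), 0) # a pair can never look like a triplet
  expect_error(substructure_probabilities("AC", 3, rep(0.9, 3)),
               "contiguous")
})

test_that("full efficiency reduces the estimator to the identity", {
  m <- substructure_model(3, 1)
  W <- c(ABC = 7, AB = 3, BC = 2, A = 5, B = 1, C = 4)
  est <- estimate_true_abundances(W, m)
  expect_equal(est$n_hat, setNames(as.numeric(W), names(W)))
  # degenerate multinomials: zero covariance everywhere
  expect_true(all(covariance_sigma(est$n_hat, m) == 0))
})

test_that("a single observed triplet is corrected by the closed-form inverse", {
  m <- substructure_model(3, 0.95)
  est <- estimate_true_abundances(c(ABC = 1, AB = 0, BC = 0,
                                    A = 0, B = 0, C = 0), m)
  expect_equal(unname(est$n_hat["ABC"]), 1 / 0.95^3, tolerance = 1e-9)
  expect_equal(unname(est$n_hat["AB"]), (0.95 - 1) / 0.95^3,
               tolerance = 1e-9)
})

test_that("zero efficiencies are rejected with a clear message", {
  expect_error(substructure_model(3, c(0.9, 0, 0.9)), "singular")
})

test_that("the estimator is unbiased under the multinomial model", {
  set.seed(41)
  for (k in 2:3) {
    s <- runif(k, 0.5, 1)
    m <- substructure_model(k, s)
    n_true <- round(runif(length(m$structures), 20, 500))
    draws <- 5000
    W <- simulate_misdetection_counts(n_true, m, draws = draws)
    n_hat <- m$inverse_map %*% W
    se <- apply(n_hat, 1, stats::sd) / sqrt(draws)
    expect_true(all(abs(rowMeans(n_hat) - n_true) <= 3 * se + 1e-9),
                info = paste("k =", k))
  }
})

test_that("the pattern covariance matches Monte-Carlo estimates", {
  set.seed(43)
  m <- substructure_model(3, 0.95)
  n_true <- c(500, 50, 50, 50, 50, 50)
  draws <- 4000
  raw <- matrix(0, 8, draws)
  for (i in seq_along(n_true)) {
    raw <- raw + rmultinom(draws, n_true[i], m$mu[, i])
  }
  W <- m$theta %*% raw
  emp <- stats::cov(t(W))
  theo <- m$theta %*% covariance_sigma(n_true, m) %*% t(m$theta)
  expect_lt(max(abs(emp - theo)) / max(abs(theo)), 0.1)
})

test_that("the xi statistic behaves like a squared distance", {
  set.seed(47)
  m <- substructure_model(3, 0.9)
  W <- simulate_misdetection_counts(c(400, 60, 60, 40, 40, 40), m)
  est <- estimate_true_abundances(W, m)
  expect_equal(xi_statistic(est, est$n_hat)$xi, 0, tolerance = 1e-9)
  for (rep in 1:10) {
    n0 <- est$n_hat + rnorm(6, 0, 20)
    out <- xi_statistic(est, n0)
    expect_gte(out$xi, 0)
    expect_equal(out$df, 6L)
  }
})

test_that("confidence slices follow the closed form of the ellipsoid", {
  set.seed(53)
  m <- substructure_model(3, 0.9)
  W <- simulate_misdetection_counts(c(400, 60, 60, 40, 40, 40), m)
  est <- estimate_true_abundances(W, m)
  cr <- confidence_region(est, alpha = 0.1)
  expect_equal(cr$crit, qchisq(0.9, 6))
  for (j in 1:6) {
    half <- cr$intervals$upper[j] - cr$intervals$estimate[j]
    # moving to the interval edge along one axis exhausts the budget
    n0 <- est$n_hat
    n0[j] <- n0[j] + half
    expect_equal(xi_statistic(est, n0)$xi, cr$crit, tolerance = 1e-6)
    expect_true(cr$intervals$lower[j] <= est$n_hat[j],
                cr$intervals$upper[j] >= est$n_hat[j])
  }
  expect_error(confidence_region(est, alpha = 1.2), "alpha")
})

test_that("the confidence region covers at its nominal level", {
  set.seed(59)
  m <- substructure_model(3, 0.95)
  n_true <- c(500, 50, 50, 50, 50, 50)
  draws <- 2000
  W <- simulate_misdetection_counts(n_true, m, draws = draws)
  n_hat <- m$inverse_map %*% W
  crit <- qchisq(0.9, 6)
  inside <- vapply(seq_len(draws), function(i) {
    est <- estimate_true_abundances(W[, i], m)
    xi_statistic(est, n_true)$xi <= crit
  }, logical(1))
  expect_gt(mean(inside), 0.87)
  expect_lt(mean(inside), 0.93)
})

test_that("corrected curves reduce to the input at full efficiency", {
  set.seed(61)
  cl <- random_clouds(3, n_max = 5)
  curve <- abundance_curve(cl, c(1, 3, 6), match_config(t = 0))
  corrected <- corrected_abundance_curve(curve, s = 1, alpha = 0.1)
  expect_equal(corrected$n_hat, as.numeric(corrected$w))
  expect_true(all(corrected$ci_low <= corrected$n_hat + 1e-9))
  expect_true(all(corrected$ci_high >= corrected$n_hat - 1e-9))
})
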