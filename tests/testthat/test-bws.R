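test_that("beta-value conversion clamps negatives and stays in [0, 1)", {
  expect_equal(beta_value(100, 100), 100 / 300)
  expect_equal(beta_value(0, 500), 0)
  expect_equal(beta_value(-5, 50), 0)
  expect_error(beta_value(NA, 1), "finite")
  set.seed(1)
  b <- beta_value(rnorm(100, 500, 400), rnorm(100, 500, 400))
  expect_true(all(b >= 0 & b < 1))
})

test_that("pooled ranks use mid-ranks and conserve the rank sum", {
  expect_equal(pooled_ranks(c(1, 2), c(3, 4)), list(G = c(1, 2), H = c(3, 4)))
  # three values tied at rank positions 1-3 share mid-rank 2
  expect_equal(pooled_ranks(c(1, 1), c(1, 2)), list(G = c(2, 2), H = c(2, 4)))
  expect_error(pooled_ranks(5, c(1, 2)), "at least 2")
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- round(runif(n1), 1); y <- round(runif(n2), 1)  # force ties
    r <- pooled_ranks(x, y)
    N <- n1 + n2
    expect_equal(sum(r$G) + sum(r$H), N * (N + 1) / 2)
  }
})

test_that("one-sided BWS statistic matches hand-derived values and the formula oracle", {
  s <- bws_statistic(c(1, 2), c(3, 4))
  expect_equal(s$B1, -2.8125)
  expect_equal(s$B2, 0.5625)
  expect_equal(s$B, -1.6875)
  expect_equal(s$D, 1.6875)
  set.seed(2)
  for (i in 1:30) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    if (i %% 3 == 0) { x <- round(x, 1); y <- round(y, 1) }  # with ties
    expect_equal(bws_statistic(x, y)$B, oracle_bws_B(x, y), tolerance = 1e-12)
  }
})

test_that("BWS statistic is antisymmetric and rank-invariant", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1))
    expect_equal(bws_statistic(x, y)$B, -bws_statistic(y, x)$B)
    # strictly increasing transform leaves ranks, hence B, unchanged
    expect_equal(bws_statistic(exp(x), exp(y))$B, bws_statistic(x, y)$B)
  }
  # mean of B over all 6 equally likely splits of ranks {1..4} is 0
  splits <- utils::combn(4, 2)
  Bs <- apply(splits, 2, function(idx)
    bws_statistic(seq_len(4)[idx], seq_len(4)[-idx])$B)
  expect_equal(mean(Bs), 0)
})

test_that("piecewise-exponential tail reproduces the published pieces", {
  expect_equal(tail_probability(0), exp(-0.699))
  expect_equal(tail_probability(1.5), exp(-0.895 - 1.153 * 1.5 + 0.0173 * 1.5^2))
  expect_equal(tail_probability(10), exp(-2.895 - 0.786 * 10))
  # reflection for negative arguments
  expect_equal(tail_probability(-2), 1 - tail_probability(2))
  # monotone non-increasing on a dense grid
  grid <- seq(0, 20, by = 0.01)
  expect_true(all(diff(tail_probability(grid)) <= 0))
  # clamped away from 0 and 1
  expect_gt(tail_probability(1e4), 0)
  expect_lt(tail_probability(-1e4), 1)
})

test_that("one-sided BWS p-values pair up and follow the statistic's direction", {
  res <- bws_test(c(1, 2), c(3, 4))
  expect_equal(res$p_right, exp(-0.895 - 1.153 * 1.6875 + 0.0173 * 1.6875^2))
  expect_equal(res$p_left + res$p_right, 1)
  # swapping arms exchanges left and right
  swapped <- bws_test(c(3, 4), c(1, 2))
  expect_equal(swapped$p_left, res$p_right)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  a <- bws_test(x, y); b <- bws_test(y, x)
  expect_equal(a$p_left, b$p_right)
})

test_that("fitted formula agrees with the exhaustive permutation null as n grows", {
  # exact small-sample check: package statistic reproduces the enumeration
  # oracle's permutation p-value inputs for n1 = n2 <= 6
  set.seed(5)
  for (n in c(4, 6)) {
    x <- rnorm(n); y <- rnorm(n) + 0.5
    D_pkg <- bws_statistic(x, y)$D
    expect_equal(D_pkg, -oracle_bws_B(x, y))
    p_exact <- oracle_perm_p_right(x, y)
    expect_gte(p_exact, 0)
    expect_lte(p_exact, 1)
  }
  # tiny-n worked case: all 6 splits of {1,2,3,4}; exact one-sided p = 1/6
  expect_equal(oracle_perm_p_right(c(1, 2), c(3, 4)), 1 / 6)
  # at n = 30 the formula tail matches a Monte-Carlo permutation tail
  set.seed(6)
  B_perm <- bwsmethyl:::bws_perm_null_cpp(30L, 30L, 200000L)
  for (d in c(0.5, 1, 1.5, 2, 3)) {
    p_mc <- mean(-B_perm >= d)  # D = -B, symmetric null
    expect_lt(abs(tail_probability(d) - p_mc), 0.01)
  }
})

test_that("null p-values are approximately uniform at moderate sample size", {
  set.seed(7)
  p <- replicate(2000, bws_test(rnorm(50), rnorm(50))$p_right)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("permutation refit is deterministic and close to the reference fit", {
  f1 <- fit_null_tail(30, 30, n_perm = 5e4, seed = 99)
  f2 <- fit_null_tail(30, 30, n_perm = 5e4, seed = 99)
  expect_identical(f1$coef, f2$coef)
  expect_match(f1$provenance, "refit")
  grid <- seq(0, 3, by = 0.05)
  expect_lt(max(abs(tail_probability(grid, f1) - tail_probability(grid))), 0.02)
  # refits at different sample sizes agree with each other (rank statistic
  # stabilises quickly in n)
  f3 <- fit_null_tail(10, 10, n_perm = 5e4, seed = 100)
  expect_lt(max(abs(tail_probability(grid, f3) - tail_probability(grid, f1))),
            0.02)
  # refit tails are monotone non-increasing up to node-jump tolerance
  g2 <- seq(0, 12, by = 0.01)
  expect_true(all(diff(tail_probability(g2, f1)) <= 1e-3))
  expect_error(fit_null_tail(1, 30), "n1, n2 >= 2")
  expect_error(fit_null_tail(30, 30, n_perm = 100), "n_perm")
})
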