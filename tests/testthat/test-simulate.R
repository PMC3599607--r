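test_that("truncated normal sampler matches closed-form moments and support", {
  set.seed(40)
  x <- sample_truncated_normal(1e5, 0.5, 0.05, 0.1, 0.9)
  expect_true(all(x > 0.1 & x < 0.9))
  expect_lt(abs(mean(x) - 0.5), 3 * 0.05 / sqrt(1e5))
  # asymmetric window: closed-form truncated mean
  y <- sample_truncated_normal(1e5, 0.3, 0.1, 0.1, 0.9)
  m <- oracle_truncnorm_mean(0.3, 0.1, 0.1, 0.9)
  expect_lt(abs(mean(y) - m), 3 * sd(y) / sqrt(1e5))
  expect_error(sample_truncated_normal(10, 0, 1, 2, 1), "below")
  expect_error(sample_truncated_normal(10, 0, 0.001, 50, 51), "mass")
})

test_that("mixture draws respect component occupancy and support", {
  set.seed(41)
  pars <- mixture_params(0.3, 0.5, 0.2, tau1 = 0.1, tau2 = 0.9,
                         mu = 0.3, sigma = 0.1)
  x <- sample_mixture_group(pars, k = 1, arm = "control",
                            family = "mixture-null", n = 1e5)
  expect_true(all(x >= 0 & x <= 1))
  occ <- c(mean(x < 0.1), mean(x >= 0.1 & x <= 0.9), mean(x > 0.9))
  se <- sqrt(c(0.3, 0.5, 0.2) * c(0.7, 0.5, 0.8) / 1e5)
  expect_true(all(abs(occ - c(0.3, 0.5, 0.2)) < 3 * se + 1e-3))
})

test_that("null mixture family draws both arms from the same distribution", {
  set.seed(42)
  pars <- mixture_params(0.3, 0.5, 0.2, delta_mu = 0.05)
  rejections <- replicate(100, {
    a <- sample_mixture_group(pars, 3, "control", "mixture-null", 200)
    b <- sample_mixture_group(pars, 3, "case", "mixture-null", 200)
    suppressWarnings(ks.test(a, b)$p.value) < 0.01
  })
  expect_lte(mean(rejections), 0.05)
})

test_that("scenario families shift the intended arm and group", {
  set.seed(43)
  pars <- mixture_params(0.3, 0.5, 0.2, mu = 0.3, sigma = 0.1, delta_mu = 0.05)
  ctl <- sample_mixture_group(pars, 6, "control", "mixture-mean-shift", 2e4)
  cas <- sample_mixture_group(pars, 6, "case", "mixture-mean-shift", 2e4)
  # only the truncated-normal component (weight 0.5) moves: mean difference
  # is 0.5 * k * delta_mu at k = 6
  expect_lt(abs((mean(cas) - mean(ctl)) - 0.5 * 6 * 0.05), 0.01)
  tpars <- mixture_params(0.45, 0.1, 0.45, mu = 0.5, sigma = 0.05,
                          delta_tau = 0.03)
  tc <- sample_mixture_group(tpars, 6, "control", "mixture-threshold-shift", 5e4)
  tk <- sample_mixture_group(tpars, 6, "case", "mixture-threshold-shift", 5e4)
  # symmetric threshold widening: means equal, case variance smaller
  expect_lt(abs(mean(tk) - mean(tc)), 0.01)
  expect_lt(var(tk), var(tc))
  expect_error(
    scenario_spec("mixture-threshold-shift",
                  mixture_params(0.45, 0.1, 0.45, delta_tau = 0.09)),
    "cross")
})

test_that("beta scenario has the stated moments and mean differences", {
  set.seed(44)
  p0 <- beta_scenario_params(lambda = 0)
  cas <- sample_beta_group(p0, 1, "case", 1e5)       # Beta(4, 4)
  ctl <- sample_beta_group(p0, 1, "control", 1e5)    # Beta(20, 20)
  expect_lt(abs(mean(cas) - 0.5), 3 * sqrt(1 / 36 / 1e5))
  expect_lt(abs(mean(ctl) - 0.5), 3 * sqrt(1 / 164 / 1e5))
  expect_lt(abs(var(cas) - 1 / 36), 3e-3)
  expect_lt(abs(var(ctl) - 1 / 164), 1e-3)
  # default: delta only in the case arm, mean difference delta / (s1 + s2)
  p1 <- beta_scenario_params(lambda = 0.2)
  d3 <- -1 * 0.2  # group 3 multiplier is -1
  cas3 <- sample_beta_group(p1, 3, "case", 1e5)
  ctl3 <- sample_beta_group(p1, 3, "control", 1e5)
  expect_lt(abs((mean(cas3) - mean(ctl3)) - d3 / 8), 2e-3)
  # shared-offset variant: mean difference 4*delta / (5*(s1+s2))
  p2 <- beta_scenario_params(lambda = 0.2, delta_in_control = TRUE)
  cas3b <- sample_beta_group(p2, 3, "case", 1e5)
  ctl3b <- sample_beta_group(p2, 3, "control", 1e5)
  expect_lt(abs((mean(cas3b) - mean(ctl3b)) - 4 * d3 / 40), 2e-3)
  # shape positivity at the extreme group
  p3 <- beta_scenario_params(lambda = 0.25)
  expect_silent(sample_beta_group(p3, 1, "case", 10))  # shapes (3.25, 4.75)
  expect_error(beta_scenario_params(lambda = 2), "non-positive")
})

test_that("rejection-rate estimation is deterministic under a fixed seed", {
  sp <- scenario_spec("mixture-null", mixture_params(0.3, 0.5, 0.2),
                      K = 2, n_control = 10, n_case = 10)
  r1 <- estimate_rejection_rate(sp, c("bws", "t"), n_reps = 100, seed = 9)
  r2 <- estimate_rejection_rate(sp, c("bws", "t"), n_reps = 100, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$mc_stderr,
               sqrt(r1$rejection_rate * (1 - r1$rejection_rate) / 100))
})

test_that("power increases with effect size in both alternative families", {
  pw <- function(sp, seed) estimate_rejection_rate(
    sp, "bws", n_reps = 400, seed = seed)$rejection_rate
  p_small <- pw(mean_shift_scenario(0.01), 50)
  p_mid <- pw(mean_shift_scenario(0.03), 51)
  p_big <- pw(mean_shift_scenario(0.05), 52)
  slack <- 2 * sqrt(0.25 / 400)
  expect_gte(p_mid, p_small - slack)
  expect_gte(p_big, p_mid - slack)
  b0 <- pw(beta_power_scenario(0), 53)
  b1 <- pw(beta_power_scenario(0.1), 54)
  b2 <- pw(beta_power_scenario(0.2), 55)
  expect_gte(b1, b0 - slack)
  expect_gte(b2, b1 - slack)
})

test_that("scale-only alternatives separate BWS power from mean-based tests", {
  r <- estimate_rejection_rate(beta_power_scenario(0), c("bws", "t", "wilcoxon"),
                               n_reps = 500, seed = 60)
  rates <- setNames(r$rejection_rate, r$method)
  expect_gte(rates["bws"] - rates["t"], 0.4)
  expect_gte(rates["bws"] - rates["wilcoxon"], 0.4)
})
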