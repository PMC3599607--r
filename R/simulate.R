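#' Truncated normal sampler
#'
#' Inverse-CDF sampling of Normal(mu, sigma^2) conditioned on
#' `(lower, upper)`; draws are strictly inside the window.
#'
#' @param n number of draws.
#' @param mu,sigma location and scale of the parent normal (`sigma > 0`).
#' @param lower,upper truncation window, `lower < upper`.
#' @return numeric vector of length `n`.
#' @export
sample_truncated_normal <- function(n, mu, sigma, lower, upper) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (lower >= upper) stop("`lower` must be below `upper`", call. = FALSE)
  plo <- pnorm(lower, mu, sigma)
  phi <- pnorm(upper, mu, sigma)
  if (phi - plo < 1e-12)
    stop("truncation window carries no probability mass for these parameters",
         call. = FALSE)
  x <- qnorm(runif(n, plo, phi), mu, sigma)
  eps <- 1e-12 * max(1, abs(lower), abs(upper))
  pmin(pmax(x, lower + eps), upper - eps)
}

#' Parameters of the three-component beta-value mixture
#'
#' The mixture places probability `pi1` on Uniform(0, tau1) (unmethylated
#' loci), `pi2` on a normal with mean `mu` and sd `sigma` truncated to
#' `(tau1, tau2)` (partially methylated), and `pi3` on Uniform(tau2, 1)
#' (fully methylated) — components in location order across `[0, 1]`.
#' `delta_mu` is the per-age-group shift of the truncated-normal mean and
#' `delta_tau` the per-age-group inward shift of the thresholds used by the
#' scenario families.
#'
#' @param pi1,pi2,pi3 component probabilities in location order (low uniform,
#'   truncated normal, high uniform), summing to 1.
#' @param tau1,tau2 thresholds with `0 < tau1 < tau2 < 1`.
#' @param mu,sigma truncated-normal location and scale.
#' @param delta_mu,delta_tau per-age-group mean / threshold increments.
#' @return object of class `mixture_params`.
#' @export
mixture_params <- function(pi1, pi2, pi3, tau1 = 0.1, tau2 = 0.9,
                           mu = 0.3, sigma = 0.1,
                           delta_mu = 0, delta_tau = 0) {
  p <- c(pi1, pi2, pi3)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("component probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  if (!(0 < tau1 && tau1 < tau2 && tau2 < 1))
    stop("need 0 < tau1 < tau2 < 1", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(list(pi = p, tau1 = tau1, tau2 = tau2, mu = mu, sigma = sigma,
                 delta_mu = delta_mu, delta_tau = delta_tau),
            class = "mixture_params")
}

#' Parameters of the beta-distribution scenario
#'
#' Case beta-values in age group `k` are drawn from
#' `Beta(s1 + delta_k, s2 - delta_k)` with
#' `delta_k = delta_multipliers[k] * lambda`; control beta-values come from
#' the five-fold more concentrated reference `Beta(5*s1, 5*s2)`, identical
#' across age groups. The arms therefore differ in variance in every group
#' (including at `lambda = 0`) and in mean by `delta_k / (s1 + s2)`
#' (`delta_k / 8` at the defaults).
#'
#' `delta_in_control = TRUE` instead shifts the control shapes along with the
#' case (`Beta(5*s1 + delta_k, 5*s2 - delta_k)`), which shrinks the mean
#' difference to `4*delta_k / (5*(s1+s2))`.
#'
#' @param s1,s2 positive base shape parameters.
#' @param lambda nonnegative effect scale.
#' @param delta_multipliers per-age-group multipliers of `lambda`.
#' @param delta_in_control also apply the shape offset to the control arm.
#' @return object of class `beta_scenario_params`.
#' @export
beta_scenario_params <- function(s1 = 4, s2 = 4, lambda = 0,
                                 delta_multipliers = c(-3, -2, -1, 0.5, 1, 1.5),
                                 delta_in_control = FALSE) {
  if (s1 <= 0 || s2 <= 0) stop("shape parameters must be positive", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  d <- delta_multipliers * lambda
  bad <- which(s1 + d <= 0 | s2 - d <= 0 |
                 (delta_in_control & (5 * s1 + d <= 0 | 5 * s2 - d <= 0)))
  if (length(bad))
    stop("non-positive beta shape in age group(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(s1 = s1, s2 = s2, lambda = lambda,
                 delta_multipliers = delta_multipliers,
                 delta_in_control = isTRUE(delta_in_control)),
            class = "beta_scenario_params")
}

#' Simulation scenario specification
#'
#' Bundles a generative family, its parameters and the design (number of age
#' groups and per-arm sample sizes). Families:
#' \describe{
#'   \item{`mixture-null`}{both arms share the mixture with truncated-normal
#'     mean `mu + k*delta_mu` in age group `k`.}
#'   \item{`mixture-mean-shift`}{control mean fixed at `mu`, case mean
#'     `mu + k*delta_mu`.}
#'   \item{`mixture-threshold-shift`}{control thresholds fixed at
#'     `(tau1, tau2)`, case thresholds `(tau1 + k*delta_tau,
#'     tau2 - k*delta_tau)`; the shifted thresholds set all three component
#'     boundaries for the case arm, and the truncated-normal mean is `mu` in
#'     both arms.}
#'   \item{`beta`}{the beta-distribution scenario of
#'     [beta_scenario_params()].}
#' }
#'
#' @param family one of the four family labels above.
#' @param params a [mixture_params()] or [beta_scenario_params()] object.
#' @param K number of age groups.
#' @param n_control,n_case per-group arm sizes.
#' @param scenario_id optional label carried into reports.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(family = c("mixture-null", "mixture-mean-shift",
                                     "mixture-threshold-shift", "beta"),
                          params, K = 6L, n_control = 50L, n_case = 50L,
                          scenario_id = NULL) {
  family <- match.arg(family)
  if (family == "beta") {
    if (!inherits(params, "beta_scenario_params"))
      stop("`params` must be beta_scenario_params for the beta family",
           call. = FALSE)
    if (K > length(params$delta_multipliers))
      stop("need a delta multiplier for each of the K age groups", call. = FALSE)
  } else if (!inherits(params, "mixture_params")) {
    stop("`params` must be mixture_params for the mixture families",
         call. = FALSE)
  }
  if (K < 1L || n_control < 2L || n_case < 2L)
    stop("need K >= 1 and at least 2 samples per arm per group", call. = FALSE)
  if (family == "mixture-threshold-shift") {
    ks <- seq_len(K)
    if (any(params$tau1 + ks * params$delta_tau >=
            params$tau2 - ks * params$delta_tau))
      stop("shifted thresholds cross for some age group", call. = FALSE)
  }
  structure(list(family = family, params = params, K = as.integer(K),
                 n_control = as.integer(n_control), n_case = as.integer(n_case),
                 scenario_id = if (is.null(scenario_id)) family else scenario_id),
            class = "scenario_spec")
}

#' Draw one arm of one age group from the mixture model
#'
#' @param params a [mixture_params()] object.
#' @param k age-group index, 1-based.
#' @param arm `"control"` or `"case"`.
#' @param family mixture family label (see [scenario_spec()]).
#' @param n number of draws.
#' @return beta-values in `[0, 1]`.
#' @export
sample_mixture_group <- function(params, k, arm = c("control", "case"),
                                 family = c("mixture-null",
                                            "mixture-mean-shift",
                                            "mixture-threshold-shift"),
                                 n = 50L) {
  arm <- match.arg(arm)
  family <- match.arg(family)
  t1 <- params$tau1; t2 <- params$tau2; m <- params$mu
  if (family == "mixture-null") {
    m <- params$mu + k * params$delta_mu
  } else if (family == "mixture-mean-shift") {
    if (arm == "case") m <- params$mu + k * params$delta_mu
  } else {  # threshold shift: case component boundaries move inward
    if (arm == "case") {
      t1 <- params$tau1 + k * params$delta_tau
      t2 <- params$tau2 - k * params$delta_tau
      if (t1 >= t2) stop("shifted thresholds cross in age group ", k,
                         call. = FALSE)
    }
  }
  if (m <= t1 || m >= t2)
    stop("truncated-normal mean outside its window in age group ", k,
         call. = FALSE)
  comp <- sample.int(3L, n, replace = TRUE, prob = params$pi)
  out <- numeric(n)
  n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
  if (n1) out[comp == 1L] <- runif(n1, 0, t1)
  if (n2) out[comp == 2L] <- sample_truncated_normal(n2, m, params$sigma, t1, t2)
  if (n3) out[comp == 3L] <- runif(n3, t2, 1)
  out
}

#' Draw one arm of one age group from the beta-distribution scenario
#'
#' @param params a [beta_scenario_params()] object.
#' @param k age-group index, 1-based.
#' @param arm `"control"` or `"case"`.
#' @param n number of draws.
#' @return beta-values in `(0, 1)`.
#' @export
sample_beta_group <- function(params, k, arm = c("control", "case"), n = 50L) {
  arm <- match.arg(arm)
  d <- params$delta_multipliers[k] * params$lambda
  sh <- if (arm == "case") c(params$s1 + d, params$s2 - d)
        else if (params$delta_in_control)
          c(5 * params$s1 + d, 5 * params$s2 - d)
        else c(5 * params$s1, 5 * params$s2)
  if (any(sh <= 0))
    stop("non-positive beta shape in age group ", k, call. = FALSE)
  rbeta(n, sh[1], sh[2])
}

#' Generate all strata of one simulated study replicate
#'
#' @param spec a [scenario_spec()].
#' @return list of `K` strata, each `list(control =, case =)`.
#' @export
simulate_strata <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  lapply(seq_len(spec$K), function(k) {
    if (spec$family == "beta") {
      list(control = sample_beta_group(spec$params, k, "control", spec$n_control),
           case = sample_beta_group(spec$params, k, "case", spec$n_case))
    } else {
      list(control = sample_mixture_group(spec$params, k, "control",
                                          spec$family, spec$n_control),
           case = sample_mixture_group(spec$params, k, "case",
                                       spec$family, spec$n_case))
    }
  })
}

# p-value of one simulated locus under a given method; strata come from
# simulate_strata().
locus_p_value <- function(strata, method, fit = bws_null_fit()) {
  if (method == "regression") {
    y <- unlist(lapply(strata, function(s) c(s$control, s$case)),
                use.names = FALSE)
    tr <- unlist(lapply(strata, function(s)
      rep(c(0, 1), c(length(s$control), length(s$case)))), use.names = FALSE)
    ag <- rep(seq_along(strata), vapply(strata, function(s)
      length(s$control) + length(s$case), integer(1)))
    return(regression_p(y, tr, ag))
  }
  test <- stratum_test_fun(method, fit)
  p_r <- clamp_p(vapply(strata, function(s)
    test(s$control, s$case)$p_right, numeric(1)))
  p_l <- clamp_p(1 - p_r)
  T_stat <- max(fisher_statistic(p_l), fisher_statistic(p_r))
  min(1, 2 * pchisq(T_stat, df = 2 * length(strata), lower.tail = FALSE))
}

#' Monte-Carlo rejection rate of a method under a scenario
#'
#' Repeatedly simulates a full `K`-group study from `spec`, applies the
#' requested method(s) and reports the fraction of replicates with p-value
#' below `alpha_level` (the type-I error rate under a null family, the power
#' otherwise). All requested methods are evaluated on the same simulated data
#' within each replicate; the combined methods use the analytic `2*alpha`
#' calibration, and `"regression"` pools all strata into one age-adjusted
#' design.
#'
#' @param spec a [scenario_spec()].
#' @param method one or more of `"bws"`, `"t"`, `"wilcoxon"`,
#'   `"regression"`.
#' @param n_reps number of replicates (>= 100).
#' @param alpha_level rejection level.
#' @param seed integer seed; each replicate uses a substream derived from
#'   `(seed, replicate)`.
#' @param fit null-tail fit for the BWS stratum test.
#' @return data frame with one row per method: `scenario_id`, `method`,
#'   `n_reps`, `alpha`, `rejection_rate`, `mc_stderr`, `seed`.
#' @export
estimate_rejection_rate <- function(spec, method = "bws", n_reps = 2000L,
                                    alpha_level = 0.05, seed = 1L,
                                    fit = bws_null_fit()) {
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- match.arg(method, c("bws", "t", "wilcoxon", "regression"),
                       several.ok = TRUE)
  if (n_reps < 100L) stop("need n_reps >= 100", call. = FALSE)
  hits <- matrix(FALSE, n_reps, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    set.seed(replicate_seed(seed, r))
    strata <- simulate_strata(spec)
    for (m in methods)
      hits[r, m] <- locus_p_value(strata, m, fit) < alpha_level
  }
  rate <- colMeans(hits)
  data.frame(scenario_id = spec$scenario_id, method = methods,
             n_reps = as.integer(n_reps), alpha = alpha_level,
             rejection_rate = unname(rate),
             mc_stderr = unname(sqrt(rate * (1 - rate) / n_reps)),
             seed = as.integer(seed), row.names = NULL)
}

#' Preset scenarios of the simulation study
#'
#' Convenience constructors for the study conditions of the type-I-error and
#' power experiments: five null mixture settings (shared thresholds
#' `tau = (0.1, 0.9)` and age trend `delta_mu = 0.05` in both arms), the
#' mean-shift and threshold-shift alternatives, and the beta-distribution
#' scenario, all with 6 age groups and 50 cases + 50 controls per group.
#'
#' @param setting null mixture setting 1..5: `(pi1, pi2, pi3, mu, sigma)` =
#'   (0.3,0.5,0.2,0.3,0.1), (0.4,0.5,0.1,0.2,0.1), (0.4,0.5,0.1,0.3,0.2),
#'   (0.5,0.1,0.4,0.3,0.2), (0.4,0.2,0.4,0.2,0.1).
#' @return a [scenario_spec()].
#' @name preset_scenarios
NULL

#' @rdname preset_scenarios
#' @export
null_mixture_scenario <- function(setting = 1L) {
  tab <- cbind(pi1 = c(0.3, 0.4, 0.4, 0.5, 0.4),
               pi2 = c(0.5, 0.5, 0.5, 0.1, 0.2),
               pi3 = c(0.2, 0.1, 0.1, 0.4, 0.4),
               mu  = c(0.3, 0.2, 0.3, 0.3, 0.2),
               sigma = c(0.1, 0.1, 0.2, 0.2, 0.1))
  s <- tab[setting, ]
  scenario_spec("mixture-null",
                mixture_params(s["pi1"], s["pi2"], s["pi3"],
                               tau1 = 0.1, tau2 = 0.9,
                               mu = s["mu"], sigma = s["sigma"],
                               delta_mu = 0.05),
                scenario_id = paste0("null-setting-", setting))
}

#' @rdname preset_scenarios
#' @param delta_mu per-age-group case mean shift of the truncated normal.
#' @export
mean_shift_scenario <- function(delta_mu = 0.03) {
  scenario_spec("mixture-mean-shift",
                mixture_params(0.3, 0.5, 0.2, tau1 = 0.1, tau2 = 0.9,
                               mu = 0.3, sigma = 0.1, delta_mu = delta_mu),
                scenario_id = paste0("mean-shift-", delta_mu))
}

#' @rdname preset_scenarios
#' @param delta_tau per-age-group inward threshold shift of the case arm.
#' @export
threshold_shift_scenario <- function(delta_tau = 0.03) {
  scenario_spec("mixture-threshold-shift",
                mixture_params(0.45, 0.1, 0.45, tau1 = 0.1, tau2 = 0.9,
                               mu = 0.5, sigma = 0.05, delta_tau = delta_tau),
                scenario_id = paste0("threshold-shift-", delta_tau))
}

#' @rdname preset_scenarios
#' @param lambda effect scale of the beta-distribution scenario.
#' @export
beta_power_scenario <- function(lambda = 0) {
  scenario_spec("beta", beta_scenario_params(s1 = 4, s2 = 4, lambda = lambda),
                scenario_id = paste0("beta-lambda-", lambda))
}
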