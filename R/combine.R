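#' Fisher combination statistic
#'
#' `-2 * sum(log(p))` for a vector of independent p-values; under independent
#' Uniform(0,1) p-values it follows a chi-square distribution with `2K`
#' degrees of freedom, `K = length(p)`.
#'
#' @param p p-values in `(0, 1]`; callers must clamp zeros first.
#' @return nonnegative combination statistic.
#' @examples
#' fisher_statistic(rep(1, 6))     # 0
#' fisher_statistic(rep(0.05, 6))  # -12 * log(0.05)
#' @export
fisher_statistic <- function(p) {
  if (length(p) < 1L || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]; clamp before combining", call. = FALSE)
  -2 * sum(log(p))
}

#' Two-sided combined p-value from the left/right Fisher statistics
#'
#' The combined statistic is `T = max(T_l, T_r)`. With
#' `alpha = Pr(chisq_{2K} > T)`, the exact two-sided tail satisfies
#' `2*alpha - alpha^2 <= Pr(T > x) <= 2*alpha`, and for small `alpha` the
#' upper bound is used: `p = min(1, 2*alpha)`.
#'
#' @param T_l,T_r nonnegative Fisher statistics of the left- and right-sided
#'   stratum p-values.
#' @param K number of strata (age groups).
#' @return object of class `bws_combined` with `T_l`, `T_r`, `T`, `alpha`,
#'   `p_value`, `K`.
#' @export
combined_two_sided_p <- function(T_l, T_r, K) {
  if (!is.finite(T_l) || !is.finite(T_r) || T_l < 0 || T_r < 0)
    stop("T_l and T_r must be finite and nonnegative", call. = FALSE)
  if (K < 1) stop("need at least one stratum", call. = FALSE)
  T_stat <- max(T_l, T_r)
  alpha <- pchisq(T_stat, df = 2 * K, lower.tail = FALSE)
  structure(list(T_l = T_l, T_r = T_r, T = T_stat, alpha = alpha,
                 p_value = min(1, 2 * alpha), K = as.integer(K),
                 method_label = NA_character_, calibration = "approx-2alpha"),
            class = "bws_combined")
}

#' @export
print.bws_combined <- function(x, ...) {
  cat("Combined ", if (is.na(x$method_label)) "test" else x$method_label,
      " across K = ", x$K, " strata (", x$calibration, ")\n", sep = "")
  cat(sprintf("  T_l = %.4f, T_r = %.4f, T = %.4f, alpha = %.4g\n",
              x$T_l, x$T_r, x$T, x$alpha))
  cat(sprintf("  two-sided p-value = %.4g\n", x$p_value))
  invisible(x)
}

# Resolve a per-stratum one-sided test to a function(control, case) ->
# list(p_left, p_right).
stratum_test_fun <- function(method, fit) {
  if (is.function(method)) return(method)
  switch(match.arg(method, c("bws", "t", "wilcoxon")),
         bws = function(control, case) bws_test(control, case, fit = fit),
         t = t_test_one_sided,
         wilcoxon = wilcoxon_one_sided)
}

validate_strata <- function(strata, small_strata) {
  if (!is.list(strata) || length(strata) == 0L)
    stop("`strata` must be a non-empty list of list(control=, case=)",
         call. = FALSE)
  ok <- vapply(strata, function(s) {
    is.list(s) && is.numeric(s$control) && is.numeric(s$case) &&
      length(s$control) >= 2L && length(s$case) >= 2L
  }, logical(1))
  if (!all(ok)) {
    if (small_strata == "error")
      stop("strata ", paste(which(!ok), collapse = ", "),
           " have fewer than 2 observations per arm", call. = FALSE)
    warning("dropping ", sum(!ok), " strata with fewer than 2 observations per arm",
            call. = FALSE)
    strata <- strata[ok]
    if (length(strata) == 0L)
      stop("no usable strata left after dropping small ones", call. = FALSE)
  }
  strata
}

#' Age-stratified combined two-sided test
#'
#' Runs a one-sided two-sample test within each stratum (age group), combines
#' the `K` left-sided and `K` right-sided p-values with Fisher's method into
#' `T_l` and `T_r`, and converts `T = max(T_l, T_r)` to a two-sided p-value.
#'
#' With `calibration = "approx"` the analytic bound `p = min(1, 2*alpha)` is
#' used (`alpha` from the chi-square with `2K` df); it is exact enough for
#' small `alpha` and conservative otherwise. With `calibration =
#' "permutation"` the case/control labels are permuted independently within
#' each stratum, the full `T` is recomputed `n_perm` times, and
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)`.
#'
#' @param strata list of strata, each `list(control =, case =)` numeric
#'   vectors with at least 2 observations per arm.
#' @param method per-stratum one-sided test: `"bws"`, `"t"`, `"wilcoxon"`, or
#'   a function `(control, case) -> list(p_left, p_right)`.
#' @param calibration `"approx"` (analytic `2*alpha` bound) or
#'   `"permutation"`.
#' @param n_perm permutations for `calibration = "permutation"`.
#' @param seed optional integer seed for the permutation calibration.
#' @param fit null-tail fit passed to the BWS stratum test.
#' @param small_strata `"error"` (default) or `"drop"` (drop undersized
#'   strata with a warning).
#' @return object of class `bws_combined`; also carries the per-stratum
#'   `p_left`/`p_right` vectors.
#' @examples
#' strata <- replicate(3, list(list(control = rnorm(20), case = rnorm(20))))
#' combined_test(strata, method = "bws")
#' @export
combined_test <- function(strata, method = "bws",
                          calibration = c("approx", "permutation"),
                          n_perm = 2000, seed = NULL, fit = bws_null_fit(),
                          small_strata = c("error", "drop")) {
  calibration <- match.arg(calibration)
  small_strata <- match.arg(small_strata)
  strata <- validate_strata(strata, small_strata)
  test <- stratum_test_fun(method, fit)

  one_T <- function(strata) {
    ps <- lapply(strata, function(s) test(s$control, s$case))
    p_l <- clamp_p(vapply(ps, `[[`, numeric(1), "p_left"))
    p_r <- clamp_p(vapply(ps, `[[`, numeric(1), "p_right"))
    list(T_l = fisher_statistic(p_l), T_r = fisher_statistic(p_r),
         p_left = p_l, p_right = p_r)
  }

  obs <- one_T(strata)
  K <- length(strata)
  res <- combined_two_sided_p(obs$T_l, obs$T_r, K)
  res$method_label <- if (is.function(method)) "custom" else method
  res$p_left <- obs$p_left
  res$p_right <- obs$p_right

  if (calibration == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    n_ctl <- vapply(strata, function(s) length(s$control), integer(1))
    pooled <- lapply(strata, function(s) c(s$control, s$case))
    T_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- lapply(seq_along(strata), function(k) {
        v <- sample(pooled[[k]])
        list(control = v[seq_len(n_ctl[k])], case = v[-seq_len(n_ctl[k])])
      })
      T_perm[b] <- with(one_T(perm), max(T_l, T_r))
    }
    res$p_value <- (1 + sum(T_perm >= res$T)) / (1 + n_perm)
    res$calibration <- "permutation"
    res$n_perm <- n_perm
  }
  res
}
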