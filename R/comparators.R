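#' One-sided two-sample t-test as paired p-values
#'
#' Pooled-variance (Student) t-test by default; `p_right` is the upper-tail
#' probability of the t statistic (small when the case mean exceeds the
#' control mean) and `p_left = 1 - p_right`. When the pooled variance is zero
#' both p-values are 0.5 with a warning.
#'
#' @inheritParams pooled_ranks
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled-variance one.
#' @return list with `p_left`, `p_right`.
#' @export
t_test_one_sided <- function(control, case, welch = FALSE) {
  check_two_sample(control, case)
  res <- tryCatch(
    t.test(case, control, alternative = "greater", var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$p.value)) {
    warning("zero pooled variance; returning p_left = p_right = 0.5",
            call. = FALSE)
    return(list(p_left = 0.5, p_right = 0.5))
  }
  p_r <- unname(res$p.value)
  list(p_left = 1 - p_r, p_right = p_r)
}

#' One-sided Wilcoxon rank-sum test as paired p-values
#'
#' Mid-ranks for ties; `p_right` tests "case stochastically larger" and
#' `p_left = 1 - p_right`. By default the exact null distribution is used for
#' `n1 + n2 <= 12` without ties, and otherwise the normal approximation with
#' tie-corrected variance and continuity correction. When every observation
#' is tied both p-values are 0.5 with a warning.
#'
#' @inheritParams pooled_ranks
#' @param exact logical or `NULL` (auto: exact when `n1 + n2 <= 12` and
#'   tie-free).
#' @return list with `p_left`, `p_right`.
#' @export
wilcoxon_one_sided <- function(control, case, exact = NULL) {
  check_two_sample(control, case)
  if (length(unique(c(control, case))) == 1L) {
    warning("degenerate rank-sum (all observations tied); returning 0.5",
            call. = FALSE)
    return(list(p_left = 0.5, p_right = 0.5))
  }
  ties <- anyDuplicated(c(control, case)) > 0L
  if (is.null(exact)) exact <- (length(control) + length(case) <= 12L) && !ties
  p_r <- suppressWarnings(
    wilcox.test(case, control, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p_r)) {
    warning("degenerate rank-sum (all observations tied); returning 0.5",
            call. = FALSE)
    return(list(p_left = 0.5, p_right = 0.5))
  }
  p_r <- unname(min(max(p_r, 0), 1))
  list(p_left = 1 - p_r, p_right = p_r)
}

#' Age-adjusted linear regression p-value for the treatment effect
#'
#' Ordinary least squares of the response on a case/control indicator plus
#' age-group terms, returning the two-sided p-value of the treatment
#' coefficient. Age enters as a categorical factor by default (one
#' coefficient per group); `age_as = "numeric"` fits a single linear age
#' slope instead. With a single age group the model reduces to the classical
#' two-sample (pooled) t-test.
#'
#' @param response numeric vector of beta-values.
#' @param treatment case/control indicator: 0/1, logical, or a
#'   factor/character with levels `control`/`case`.
#' @param age_group per-sample age-group label.
#' @param age_as `"factor"` or `"numeric"`.
#' @return two-sided p-value of the treatment coefficient.
#' @export
regression_p <- function(response, treatment, age_group,
                         age_as = c("factor", "numeric")) {
  age_as <- match.arg(age_as)
  if (is.character(treatment) || is.factor(treatment))
    treatment <- as.character(treatment) == "case"
  treatment <- as.numeric(treatment)
  if (length(response) != length(treatment) ||
      length(response) != length(age_group))
    stop("`response`, `treatment` and `age_group` must have equal length",
         call. = FALSE)
  if (length(unique(treatment)) < 2L)
    stop("both treatment levels must be present", call. = FALSE)
  ag <- if (age_as == "factor") factor(age_group) else as.numeric(age_group)
  fit <- if (is.factor(ag) && nlevels(ag) < 2L) lm(response ~ treatment)
         else lm(response ~ treatment + ag)
  if (anyNA(coef(fit)))
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  ct <- summary(fit)$coefficients
  p <- ct["treatment", 4L]
  if (!is.finite(p))  # perfect fit: zero residual variance
    p <- if (abs(ct["treatment", 1L]) < 1e-12) 1 else 0
  unname(p)
}

#' Combined comparator test across age strata
#'
#' Delegates to [combined_test()] with the chosen benchmark one-sided
#' per-stratum test: the combined t-test or the combined Wilcoxon test.
#'
#' @inheritParams combined_test
#' @param method `"t"` or `"wilcoxon"`.
#' @param ... passed on to [combined_test()].
#' @return object of class `bws_combined`.
#' @export
combined_comparator_test <- function(strata, method = c("t", "wilcoxon"),
                                     ...) {
  method <- match.arg(method)
  combined_test(strata, method = method, ...)
}
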