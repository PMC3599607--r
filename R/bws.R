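#' Methylation beta-value from allele signal intensities
#'
#' Converts methylated/unmethylated signal intensities to the beta-value scale
#' used by Illumina methylation assays: negative intensities are clamped to
#' zero and an offset of 100 stabilises low-intensity probes, so the result is
#' always in `[0, 1)`.
#'
#' @param M numeric vector of methylated-allele intensities.
#' @param U numeric vector of unmethylated-allele intensities.
#' @return `max(M,0) / (max(M,0) + max(U,0) + 100)`, elementwise.
#' @examples
#' beta_value(100, 100)  # 1/3
#' beta_value(-5, 50)    # 0: negative intensity clamped
#' @export
beta_value <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U) ||
      any(!is.finite(M)) || any(!is.finite(U)))
    stop("`M` and `U` must be finite numeric intensities", call. = FALSE)
  pmax(M, 0) / (pmax(M, 0) + pmax(U, 0) + 100)
}

#' Pooled mid-ranks of a two-sample stratum
#'
#' Ranks the pooled `c(control, case)` sample with mid-ranks for ties and
#' returns each group's ranks sorted ascending, ready for the order-statistic
#' weights of the BWS sums.
#'
#' @param control,case numeric vectors, at least 2 observations each.
#' @return list with ascending rank vectors `G` (control) and `H` (case).
#' @examples
#' pooled_ranks(c(1, 2), c(3, 4))   # G = 1:2, H = 3:4
#' pooled_ranks(c(1, 1), c(1, 2))   # mid-ranks: G = c(2, 2), H = c(2, 4)
#' @export
pooled_ranks <- function(control, case) {
  check_two_sample(control, case)
  r <- rank(c(control, case), ties.method = "average")
  i1 <- seq_along(control)
  list(G = sort(r[i1]), H = sort(r[-i1]))
}

#' One-sided Baumgartner-Weiss-Schindler statistic
#'
#' Computes the signed BWS statistic comparing the case and control empirical
#' distributions of one stratum. `B1` accumulates the signed squared rank
#' discrepancies of the control order statistics, `B2` those of the cases, and
#' `B = (B1 - B2) / 2`. The direction-normalised statistic `D = -B` is
#' positive when the case arm is stochastically larger than the control arm.
#'
#' Ties receive mid-ranks. Swapping the two arms negates `B` (and `D`)
#' exactly, and any strictly increasing transform of the pooled observations
#' leaves the statistic unchanged.
#'
#' @inheritParams pooled_ranks
#' @return list with components `B1`, `B2`, `B`, `D`.
#' @examples
#' bws_statistic(c(1, 2), c(3, 4))  # B = -1.6875, D = 1.6875
#' @export
bws_statistic <- function(control, case) {
  check_two_sample(control, case)
  bws_stat_cpp(as.numeric(control), as.numeric(case))
}

#' Piecewise-exponential null tail of the one-sided BWS statistic
#'
#' Container for the null upper-tail function `P(b) = Pr(B >= b)` of the
#' one-sided BWS statistic, represented as `exp(c0 + c1*b + c2*b^2)` on each
#' of three intervals cut at `nodes`. Called with no arguments it returns the
#' reference fit obtained from 1e7 permutations at 30 observations per arm,
#' with pieces
#' \deqn{P(b) = e^{-0.699 - 1.255 b},\; 0 \le b < 1.5}
#' \deqn{P(b) = e^{-0.895 - 1.153 b + 0.0173 b^2},\; 1.5 \le b < 9}
#' \deqn{P(b) = e^{-2.895 - 0.786 b},\; b \ge 9}
#' and the reflection `P(-b) = 1 - P(b)`. This fit is recommended for strata
#' with more than about 10 observations per arm; see [fit_null_tail()] to
#' refit at other sample sizes.
#'
#' @param coef 3 x 3 numeric matrix, one row per piece, columns `c0, c1, c2`.
#' @param nodes ascending positive breakpoints (length 2).
#' @param provenance `"default"`, `"refit"` or `"refit-extrapolated"`.
#' @param n_perm permutation count behind the fit.
#' @return object of class `bws_null_fit`.
#' @seealso [tail_probability()], [fit_null_tail()]
#' @export
bws_null_fit <- function(coef = NULL, nodes = c(1.5, 9),
                         provenance = "default", n_perm = 1e7) {
  if (is.null(coef)) {
    coef <- rbind(c(-0.699, -1.255, 0),
                  c(-0.895, -1.153, 0.0173),
                  c(-2.895, -0.786, 0))
  }
  coef <- as.matrix(coef)
  if (!is.numeric(coef) || any(dim(coef) != c(3L, 3L)))
    stop("`coef` must be a 3 x 3 numeric matrix (pieces x polynomial degree)",
         call. = FALSE)
  nodes <- as.numeric(nodes)
  if (length(nodes) != 2L || any(!is.finite(nodes)) || any(nodes <= 0) ||
      diff(nodes) <= 0)
    stop("`nodes` must be two ascending positive breakpoints", call. = FALSE)
  dimnames(coef) <- list(paste0("piece", 1:3), c("c0", "c1", "c2"))
  structure(list(coef = coef, nodes = nodes, provenance = provenance,
                 n_perm = n_perm),
            class = "bws_null_fit")
}

#' @export
print.bws_null_fit <- function(x, ...) {
  cat("Piecewise-exponential BWS null tail (", x$provenance, ")\n", sep = "")
  cat("  nodes:", paste(x$nodes, collapse = ", "),
      " permutations:", format(x$n_perm, big.mark = ","), "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Upper-tail null probability of the one-sided BWS statistic
#'
#' Evaluates `Pr(B >= b)` under the null from a piecewise-exponential fit.
#' Negative arguments use the reflection `P(-b) = 1 - P(b)` of the symmetric
#' null. Results are clamped to `(1e-300, 1 - 1e-300)`.
#'
#' @param b numeric vector of statistic values.
#' @param fit a [bws_null_fit()] object.
#' @return upper-tail probabilities, same length as `b`.
#' @examples
#' tail_probability(0)     # exp(-0.699), about 0.497
#' tail_probability(-2)    # 1 - tail_probability(2)
#' @export
tail_probability <- function(b, fit = bws_null_fit()) {
  if (!inherits(fit, "bws_null_fit"))
    stop("`fit` must be a bws_null_fit object", call. = FALSE)
  b <- as.numeric(b)
  bb <- abs(b)
  piece <- findInterval(bb, fit$nodes) + 1L
  co <- fit$coef
  p <- exp(co[piece, 1L] + co[piece, 2L] * bb + co[piece, 3L] * bb * bb)
  p <- clamp_p(p)
  clamp_p(ifelse(b < 0, 1 - p, p))
}

#' One-sided BWS test for a single stratum
#'
#' Computes the direction-normalised statistic `D` and converts it to paired
#' one-sided p-values with the piecewise-exponential null tail:
#' `p_right = P(D)` is small when the case arm is stochastically larger, and
#' `p_left = 1 - p_right`.
#'
#' @inheritParams pooled_ranks
#' @param fit a [bws_null_fit()] object.
#' @return list with `p_left`, `p_right` and the `statistic` list.
#' @examples
#' bws_test(c(1, 2), c(3, 4))$p_right
#' @export
bws_test <- function(control, case, fit = bws_null_fit()) {
  s <- bws_statistic(control, case)
  p_r <- tail_probability(s$D, fit)
  list(p_left = 1 - p_r, p_right = p_r, statistic = s)
}

#' Refit the BWS null tail by permutation
#'
#' Draws `n_perm` random assignments of the pooled ranks `1..(n1+n2)` to the
#' two groups (the statistic is rank-based, so this is the permutation null
#' for any continuous parent distribution), computes `B` for each, and fits
#' the log empirical upper tail piecewise by unweighted least squares on the
#' grid of observed statistic values: linear on the first and third pieces,
#' quadratic on the middle piece, matching the functional form of the
#' reference fit. Pieces are fitted independently (no continuity constraint;
#' the reference pieces themselves are slightly discontinuous at the nodes).
#'
#' If fewer than 10 permuted statistics land beyond the second node the third
#' piece is extrapolated from the middle piece and the provenance is flagged
#' `"refit-extrapolated"`.
#'
#' @param n1,n2 per-arm sample sizes (>= 2).
#' @param n_perm number of permutations (>= 1e4).
#' @param nodes ascending positive breakpoints.
#' @param seed optional integer seed.
#' @return a [bws_null_fit()] object with provenance `"refit"` (or
#'   `"refit-extrapolated"`).
#' @export
fit_null_tail <- function(n1, n2, n_perm = 1e6, nodes = c(1.5, 9),
                          seed = NULL) {
  if (n1 < 2 || n2 < 2) stop("need n1, n2 >= 2", call. = FALSE)
  if (n_perm < 1e4) stop("need n_perm >= 1e4 to populate the tail", call. = FALSE)
  nodes <- as.numeric(nodes)
  if (length(nodes) != 2L || any(nodes <= 0) || diff(nodes) <= 0)
    stop("`nodes` must be two ascending positive breakpoints", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  B <- bws_perm_null_cpp(as.integer(n1), as.integer(n2), as.integer(n_perm))
  bf <- sort(B)
  u <- unique(bf[bf >= 0])
  # empirical upper tail at each observed value: (# B >= u) / n_perm
  n_less <- findInterval(u, bf, left.open = TRUE)
  lp <- log((n_perm - n_less) / n_perm)
  piece <- findInterval(u, nodes) + 1L

  fit_piece <- function(sel, quadratic) {
    x <- u[sel]; y <- lp[sel]
    X <- if (quadratic) cbind(1, x, x^2) else cbind(1, x)
    cf <- qr.coef(qr(X), y)
    if (quadratic) cf else c(cf, 0)
  }
  coef <- matrix(0, 3L, 3L)
  coef[1L, ] <- fit_piece(piece == 1L, quadratic = FALSE)
  coef[2L, ] <- fit_piece(piece == 2L, quadratic = TRUE)
  provenance <- "refit"
  if (sum(piece == 3L) >= 10L) {
    coef[3L, ] <- fit_piece(piece == 3L, quadratic = FALSE)
  } else {
    coef[3L, ] <- coef[2L, ]
    provenance <- "refit-extrapolated"
  }
  bws_null_fit(coef = coef, nodes = nodes, provenance = provenance,
               n_perm = n_perm)
}
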