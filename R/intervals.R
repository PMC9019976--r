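#' Paired 2x2x2 count table
#'
#' Cell counts of a paired comparative accuracy study, cross-classifying the
#' two index tests within each disease stratum. Among the diseased, "1"
#' means a (correct) positive result: `d11` = both tests true positive,
#' `d10` = experimental TP / comparator FN, `d01` = experimental FN /
#' comparator TP, `d00` = both FN. Among the non-diseased, "1" means a
#' (false) positive: `nd11` = both FP, `nd10` = experimental FP /
#' comparator TN, `nd01` = experimental TN / comparator FP, `nd00` = both
#' TN.
#'
#' @param d11,d10,d01,d00 Counts among the diseased.
#' @param nd11,nd10,nd01,nd00 Counts among the non-diseased.
#' @return An object of class `paired_count_table` with derived stratum
#'   sizes `n_d`, `n_nd` and total `n`.
#' @export
paired_count_table <- function(d11, d10, d01, d00, nd11, nd10, nd01, nd00) {
  counts <- c(d11 = d11, d10 = d10, d01 = d01, d00 = d00,
              nd11 = nd11, nd10 = nd10, nd01 = nd01, nd00 = nd00)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all cell counts must be nonnegative integers")
  out <- as.list(counts)
  out$n_d <- d11 + d10 + d01 + d00
  out$n_nd <- nd11 + nd10 + nd01 + nd00
  out$n <- out$n_d + out$n_nd
  structure(out, class = "paired_count_table")
}

new_conf_int <- function(lower, upper, level, estimate, method) {
  structure(list(lower = lower, upper = upper, level = level,
                 estimate = estimate, method = method),
            class = "copriss_ci")
}

#' @export
print.copriss_ci <- function(x, ...) {
  cat(sprintf("%g%% %s confidence interval for a difference of proportions\n",
              100 * x$level, x$method))
  cat(sprintf("  estimate %.4f, interval [%.4f, %.4f]\n",
              x$estimate, x$lower, x$upper))
  invisible(x)
}

#' Wald interval for the difference of two independent proportions
#'
#' `p1 - p2 +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`. Provided for
#' comparison; it is not range preserving and its coverage near the
#' boundaries is poor, which is why the score interval is used for the
#' final analysis.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param level Confidence level.
#' @return A `copriss_ci`.
#' @export
wald_ci_diff_independent <- function(x1, n1, x2, n2, level = 0.95) {
  check_counts(x1, n1)
  check_counts(x2, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  new_conf_int(p1 - p2 - z * se, p1 - p2 + z * se, level, p1 - p2, "Wald")
}

#' Score interval for the difference of two independent proportions
#'
#' Inverts the score test of `H0: p1 - p2 = delta` with the variance
#' evaluated at the restricted maximum-likelihood estimates under the
#' constraint (Farrington-Manning closed form), optionally inflated by the
#' Miettinen-Nurminen factor `N/(N-1)` (the default). The interval is the
#' set of `delta` whose two-sided score statistic stays below the normal
#' critical value; its endpoints are found by bisection and are always
#' inside `[-1, 1]`, including for boundary counts `x = 0` or `x = n`.
#'
#' @inheritParams wald_ci_diff_independent
#' @param inflate Apply the `N/(N-1)` variance inflation (Miettinen-Nurminen
#'   variant); `FALSE` gives the plain restricted-MLE (Mee) variant.
#' @param tol Bisection tolerance on the interval endpoints.
#' @return A `copriss_ci`.
#' @examples
#' score_ci_diff_independent(42, 50, 33, 50)
#' @export
score_ci_diff_independent <- function(x1, n1, x2, n2, level = 0.95,
                                      inflate = TRUE, tol = 1e-8) {
  check_counts(x1, n1)
  check_counts(x2, n2)
  est <- x1 / n1 - x2 / n2
  zfun <- function(d) score_stat_independent(x1, n1, x2, n2, d, inflate)
  ep <- invert_score(zfun, est, stats::qnorm(1 - (1 - level) / 2), tol)
  method <- if (inflate) "score (Miettinen-Nurminen)" else "score (Mee)"
  new_conf_int(ep[1], ep[2], level, est, method)
}

# score statistic for H0: p1 - p2 = d, decreasing in d;
# restricted MLEs from the Farrington-Manning cubic
score_stat_independent <- function(x1, n1, x2, n2, d, inflate) {
  num <- x1 / n1 - x2 / n2 - d
  n <- n1 + n2
  l3 <- n
  l2 <- (n1 + 2 * n2) * d - n - (x1 + x2)
  l1 <- (n2 * d - n - 2 * x2) * d + x1 + x2
  l0 <- x2 * d * (1 - d)
  q <- l2^3 / (3 * l3)^3 - l1 * l2 / (6 * l3^2) + l0 / (2 * l3)
  p <- sqrt(max(l2^2 / (3 * l3)^2 - l1 / (3 * l3), 0))
  if (p == 0) {
    p2t <- -l2 / (3 * l3)
  } else {
    a <- (pi + acos(max(-1, min(1, q / p^3)))) / 3
    p2t <- 2 * p * cos(a) - l2 / (3 * l3)
  }
  p2t <- max(0, min(1, p2t))
  p1t <- max(0, min(1, p2t + d))
  v <- p1t * (1 - p1t) / n1 + p2t * (1 - p2t) / n2
  if (inflate) v <- v * n / (n - 1)
  if (v <= 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sqrt(v)
}

#' Tango asymptotic score interval for a paired difference of proportions
#'
#' For matched binary data with `b` discordant pairs favoring the
#' experimental test, `c` favoring the comparator and `n` pairs in total,
#' inverts the score test of `H0: p_E - p_C = delta` with the nuisance
#' discordant-cell probability profiled at its restricted MLE:
#' \deqn{Z(\delta) = \frac{b - c - n\delta}
#'   {\sqrt{n(2\tilde q_{21} + \delta(1 - \delta))}}}
#' At `delta = 0` the statistic reduces to the McNemar statistic. The
#' interval is range preserving and remains a proper interval containing 0
#' even when `b = c = 0`.
#'
#' @param b Discordant pairs in which only the experimental test is correct.
#' @param c Discordant pairs in which only the comparator test is correct.
#' @param n Total number of pairs in the stratum.
#' @param level Confidence level.
#' @param tol Bisection tolerance on the interval endpoints.
#' @return A `copriss_ci`.
#' @examples
#' tango_ci_diff_paired(b = 12, c = 4, n = 120)
#' @export
tango_ci_diff_paired <- function(b, c, n, level = 0.95, tol = 1e-8) {
  stopifnot(n >= 1, b >= 0, c >= 0, b + c <= n,
            b == round(b), c == round(c), n == round(n))
  est <- (b - c) / n
  zfun <- function(d) tango_stat(b, c, n, d)
  ep <- invert_score(zfun, est, stats::qnorm(1 - (1 - level) / 2), tol)
  new_conf_int(ep[1], ep[2], level, est, "Tango score")
}

tango_stat <- function(b, c, n, d) {
  num <- b - c - n * d
  aa <- 2 * n
  bb <- (2 * n - b + c) * d - b - c
  cc <- -c * d * (1 - d)
  disc <- max(bb^2 - 4 * aa * cc, 0)
  q21 <- (sqrt(disc) - bb) / (2 * aa)
  q21 <- max(0, min(1, q21))
  v <- n * (2 * q21 + d * (1 - d))
  if (v <= 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sqrt(v)
}

# endpoints of {d : |zfun(d)| <= zcrit} for zfun decreasing in d,
# by bisection on [-1, 1]; range-preserving by construction
invert_score <- function(zfun, est, zcrit, tol) {
  bisect <- function(lo, hi, f) {
    flo <- f(lo)
    fhi <- f(hi)
    if (flo <= 0) return(lo)   # target already satisfied at the range edge
    if (fhi > 0) return(hi)
    it <- 0L
    while (hi - lo > tol && it < 200L) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      it <- it + 1L
    }
    if (hi - lo > tol)
      stop("score interval endpoint search failed to converge")
    (lo + hi) / 2
  }
  # lower endpoint: smallest d with zfun(d) <= zcrit
  lower <- bisect(-1, est, function(d) zfun(d) - zcrit)
  # upper endpoint: largest d with zfun(d) >= -zcrit; mirror via -zfun
  upper <- -bisect(-1, -est, function(d) -zfun(-d) - zcrit)
  c(lower, upper)
}

#' Intersection-Union decision on the co-primary endpoints
#'
#' The global superiority null is the union of the per-endpoint nulls and is
#' rejected only if both endpoint nulls are rejected simultaneously: the
#' lower confidence bound for the sensitivity difference and the lower
#' bound for the specificity difference must both exceed their margins
#' (0 for superiority).
#'
#' @param ci_se,ci_sp `copriss_ci` objects (or lists with a `lower` field)
#'   for the sensitivity and specificity differences (experimental minus
#'   comparator).
#' @param margin_se,margin_sp Margins; 0 for superiority.
#' @return `TRUE` iff both lower bounds exceed their margins.
#' @export
iut_decision <- function(ci_se, ci_sp, margin_se = 0, margin_sp = 0) {
  isTRUE(ci_se$lower > margin_se) && isTRUE(ci_sp$lower > margin_sp)
}

check_counts <- function(x, n) {
  if (n < 1) stop("number of trials must be at least 1")
  if (x < 0 || x > n || x != round(x))
    stop("successes must be an integer in [0, n]")
  invisible(TRUE)
}
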