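#' Design specification for a comparative diagnostic accuracy trial
#'
#' Bundles the global design choices of a confirmatory comparative accuracy
#' study: whether participants receive both index tests (paired) or are
#' randomized to one of them (unpaired), the two-sided significance level
#' applied to each co-primary endpoint, and the target overall power of the
#' Intersection-Union test. Sensitivity and specificity are co-primary: the
#' global null is rejected only if both endpoint nulls are rejected, so the
#' overall power is the product of the endpoint-specific powers.
#'
#' @param design "paired" or "unpaired".
#' @param alpha Two-sided significance level per endpoint, in (0, 1).
#' @param power_overall Target overall (product) power, in (0, 1).
#' @return An object of class `copriss_design`.
#' @examples
#' design_spec("paired", alpha = 0.05, power_overall = 0.8)
#' @export
design_spec <- function(design = c("paired", "unpaired"), alpha = 0.05,
                        power_overall = 0.8) {
  design <- match.arg(design)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(power_overall), length(power_overall) == 1L,
            power_overall > 0, power_overall < 1)
  structure(list(design = design, alpha = alpha,
                 power_overall = power_overall, hypothesis = "superiority"),
            class = "copriss_design")
}

#' Accuracy assumptions of a planned comparison
#'
#' The marginal accuracies of the comparator (C) and experimental (E) test
#' and the disease prevalence. Superiority sizing divides by the squared
#' difference of accuracies, so equal sensitivities or equal specificities
#' are rejected here with an informative error.
#'
#' @param se_c,se_e Sensitivity of the comparator / experimental test.
#' @param sp_c,sp_e Specificity of the comparator / experimental test.
#' @param prevalence Proportion of diseased individuals among all recruited.
#' @return An object of class `copriss_accuracy`.
#' @examples
#' accuracy_params(se_c = 0.81, se_e = 0.90, sp_c = 0.66, sp_e = 0.80,
#'                 prevalence = 0.47)
#' @export
accuracy_params <- function(se_c, se_e, sp_c, sp_e, prevalence) {
  p <- c(se_c = se_c, se_e = se_e, sp_c = sp_c, sp_e = sp_e,
         prevalence = prevalence)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("all accuracy parameters and the prevalence must lie strictly in (0, 1)")
  if (se_c == se_e)
    stop("superiority sizing requires se_e != se_c (zero sensitivity difference)")
  if (sp_c == sp_e)
    stop("superiority sizing requires sp_e != sp_c (zero specificity difference)")
  structure(as.list(p), class = "copriss_accuracy")
}

#' Discordance assumptions for a paired design
#'
#' Proportions of discordant test results between the two index tests among
#' the diseased (`psi_d`) and non-diseased (`psi_nd`) populations. Whether
#' a value is admissible depends on the assumed accuracies (see
#' [psi_bounds()]); that check is performed where the accuracies are known.
#'
#' @param psi_d,psi_nd Discordance proportions in \[0, 1\].
#' @return An object of class `copriss_dependence`.
#' @export
paired_dependence <- function(psi_d, psi_nd) {
  stopifnot(is.numeric(psi_d), is.numeric(psi_nd),
            psi_d >= 0, psi_d <= 1, psi_nd >= 0, psi_nd <= 1)
  structure(list(psi_d = psi_d, psi_nd = psi_nd),
            class = "copriss_dependence")
}

#' Type-II error for specificity given the sensitivity type-II error
#'
#' With co-primary endpoints the overall power is the product of the
#' endpoint powers, `(1 - beta_se) * (1 - beta_sp) = power_overall`.
#' Given `beta_se` this returns the `beta_sp` that satisfies the constraint
#' exactly: `beta_sp = 1 - power_overall / (1 - beta_se)`.
#'
#' @param beta_se Type-II error for the sensitivity endpoint.
#' @param power_overall Target overall power.
#' @return The implied type-II error for the specificity endpoint.
#' @examples
#' complement_beta(0.1, 0.8)  # 1 - 0.8/0.9
#' @export
complement_beta <- function(beta_se, power_overall) {
  stopifnot(beta_se >= 0, beta_se < 1,
            power_overall > 0, power_overall < 1)
  if (1 - beta_se <= power_overall)
    stop("infeasible split: the sensitivity power (1 - beta_se) must exceed ",
         "the overall power, otherwise the specificity power would have to ",
         "exceed 1")
  1 - power_overall / (1 - beta_se)
}

#' Solve the optimal power split equalizing the endpoint sample sizes
#'
#' The optimal calculation allocates the overall power between the two
#' endpoints so that the endpoint-specific total sample sizes coincide,
#' making the final size the smallest total achieving the target overall
#' power. The equalizing split has no closed form; it is found by bisection
#' on the sensitivity power over the feasible interval
#' (`power_overall`, 1). The difference `n_se - n_sp` is strictly increasing
#' in the sensitivity power there (the sensitivity requirement grows, the
#' specificity requirement shrinks), so the bracket is guaranteed whenever
#' both kernels are finite on the interval interior.
#'
#' Bisection is used rather than a derivative-based method because normal
#' quantiles diverge at the interval edges (the re-estimated example study
#' has its root essentially at the lower boundary) and a guaranteed bracket
#' is worth more than quadratic convergence here.
#'
#' @param n_se Function of `beta_se` returning the unrounded total sample
#'   size required by the sensitivity endpoint.
#' @param n_sp Function of `beta_sp` returning the unrounded total for the
#'   specificity endpoint.
#' @param power_overall Target overall power in (0, 1).
#' @param tol Bisection tolerance on the sensitivity power.
#' @param eps Offset defining the open feasible interval
#'   `[power_overall + eps, 1 - eps]`.
#' When one endpoint dominates over the entire feasible interval (e.g. a
#' very low prevalence makes the diseased requirement larger than the
#' non-diseased one at every admissible split), no interior crossing
#' exists and the minimal total is attained at the interval edge: the
#' dominating endpoint keeps the overall power, the other endpoint's power
#' is driven to 1. The returned split then has `boundary` set to `"se"` or
#' `"sp"` and the totals are not equalized (the dominating one is binding).
#'
#' @return A list of class `power_split` with elements `beta_se`, `beta_sp`,
#'   `power_se`, `power_sp`, `n_se`, `n_sp` (unrounded totals at the
#'   solution), `gap` (their difference) and `boundary`
#'   (`"none"`, `"se"` or `"sp"`).
#' @export
solve_power_split <- function(n_se, n_sp, power_overall,
                              tol = 1e-10, eps = 1e-9) {
  stopifnot(is.function(n_se), is.function(n_sp),
            power_overall > 0, power_overall < 1)
  g <- function(power_se) {
    n_se(1 - power_se) - n_sp(1 - power_overall / power_se)
  }
  lo <- power_overall + eps
  hi <- 1 - eps
  glo <- g(lo)
  ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi))
    stop("sample size kernels are not finite on the feasible power interval")
  if (glo >= 0) return(boundary_split(lo, power_overall, n_se, n_sp, "se"))
  if (ghi <= 0) return(boundary_split(hi, power_overall, n_se, n_sp, "sp"))
  maxit <- 200L
  it <- 0L
  while (hi - lo > tol && it < maxit) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  if (hi - lo > tol)
    stop("power-split bisection failed to converge within ", maxit,
         " iterations")
  power_se <- (lo + hi) / 2
  beta_se <- 1 - power_se
  beta_sp <- complement_beta(beta_se, power_overall)
  nse <- n_se(beta_se)
  nsp <- n_sp(beta_sp)
  structure(list(beta_se = beta_se, beta_sp = beta_sp,
                 power_se = power_se, power_sp = 1 - beta_sp,
                 n_se = nse, n_sp = nsp, gap = nse - nsp,
                 boundary = "none"),
            class = "power_split")
}

# degenerate split when one endpoint dominates over the whole feasible
# interval: the minimal total is attained at the edge, where the dominated
# endpoint's power is driven (numerically) to 1 and the product constraint
# still holds exactly
boundary_split <- function(power_se, power_overall, n_se, n_sp, which) {
  beta_se <- 1 - power_se
  beta_sp <- complement_beta(beta_se, power_overall)
  nse <- n_se(beta_se)
  nsp <- n_sp(beta_sp)
  structure(list(beta_se = beta_se, beta_sp = beta_sp,
                 power_se = power_se, power_sp = 1 - beta_sp,
                 n_se = nse, n_sp = nsp, gap = nse - nsp,
                 boundary = which),
            class = "power_split")
}

#' @export
print.copriss_design <- function(x, ...) {
  cat(sprintf(
    "Comparative diagnostic accuracy design (%s, superiority)\n", x$design))
  cat(sprintf("  alpha per endpoint (two-sided): %g\n", x$alpha))
  cat(sprintf("  target overall power:           %g\n", x$power_overall))
  invisible(x)
}

#' @export
print.power_split <- function(x, ...) {
  cat("Optimal power split (co-primary endpoints)\n")
  cat(sprintf("  power Se: %.6f (beta_se = %.6f)\n", x$power_se, x$beta_se))
  cat(sprintf("  power Sp: %.6f (beta_sp = %.6f)\n", x$power_sp, x$beta_sp))
  cat(sprintf("  equalized totals: N_Se = %.3f, N_Sp = %.3f (gap %.2e)\n",
              x$n_se, x$n_sp, x$gap))
  invisible(x)
}

# ceiling with guard against floating-point overshoot: 132.99999999 and
# 133.0000000001 both map to 133
ceil_n <- function(x, fuzz = 1e-8) as.integer(ceiling(x - fuzz))
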