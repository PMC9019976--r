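#' Paired-design group size for one endpoint (Miettinen formula)
#'
#' Number of diseased individuals needed to detect a sensitivity difference
#' between two index tests applied to the same participants, based on the
#' discordance proportion `psi_d`:
#' \deqn{n_D = \frac{\left(z_{1-\alpha/2}\,\psi_D + z_{1-\beta}
#'   \sqrt{\psi_D^2 - \tfrac14 (Se_C - Se_E)^2 (3 + \psi_D)}\right)^2}
#'   {\psi_D (Se_C - Se_E)^2}}
#' The value is returned unrounded; rounding happens once, after the
#' prevalence scaling (see [conventional_sample_size()]).
#'
#' @param se_c,se_e Sensitivities of comparator and experimental test.
#' @param psi_d Discordance proportion among the diseased; must lie in the
#'   admissible interval of [psi_bounds()] for the given accuracies.
#' @param alpha Two-sided significance level.
#' @param beta Type-II error for this endpoint.
#' @return Unrounded number of diseased individuals.
#' @examples
#' n_diseased_paired(0.81, 0.90, psi_d = 0.09, alpha = 0.05, beta = 0.10)
#' @export
n_diseased_paired <- function(se_c, se_e, psi_d, alpha, beta) {
  paired_group_size(se_c, se_e, psi_d, alpha, beta, endpoint = "sensitivity")
}

#' Paired-design group size for the specificity endpoint
#'
#' Specificity analogue of [n_diseased_paired()]: the number of non-diseased
#' individuals needed to detect a specificity difference, given the
#' discordance proportion `psi_nd` among the non-diseased.
#'
#' @param sp_c,sp_e Specificities of comparator and experimental test.
#' @param psi_nd Discordance proportion among the non-diseased.
#' @param alpha Two-sided significance level.
#' @param beta Type-II error for this endpoint.
#' @return Unrounded number of non-diseased individuals.
#' @examples
#' n_nondiseased_paired(0.66, 0.80, psi_nd = 0.14, alpha = 0.05, beta = 0.10)
#' @export
n_nondiseased_paired <- function(sp_c, sp_e, psi_nd, alpha, beta) {
  paired_group_size(sp_c, sp_e, psi_nd, alpha, beta, endpoint = "specificity")
}

paired_group_size <- function(p_c, p_e, psi, alpha, beta, endpoint) {
  diff2 <- (p_c - p_e)^2
  if (diff2 == 0)
    stop("zero ", endpoint, " difference: the paired sample size formula ",
         "divides by (", endpoint, " difference)^2")
  rad <- psi^2 - 0.25 * diff2 * (3 + psi)
  if (rad < 0)
    stop("invalid dependence for the ", endpoint, " endpoint: psi = ", psi,
         " makes the radicand negative; psi must lie in [",
         signif(abs(p_c - p_e), 6), ", ", signif(p_c + p_e - 2 * p_c * p_e, 6),
         "]")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(1 - beta)
  (z_a * psi + z_b * sqrt(rad))^2 / (psi * diff2)
}

#' Variance of a difference of two independent proportions
#'
#' `p1 (1 - p1) + p2 (1 - p2)`, the per-observation variance of the
#' difference of two independent binomial proportions; used at the
#' alternative in the unpaired sample size formula.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return The variance, in \[0, 0.5\].
#' @export
unpaired_variance <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  p1 * (1 - p1) + p2 * (1 - p2)
}

#' Unpaired-design group size for one endpoint
#'
#' Per-arm number of diseased individuals needed to detect a sensitivity
#' difference between two independent proportions:
#' \deqn{n_D = \frac{\left(z_{1-\alpha/2}\sqrt{V_0} +
#'   z_{1-\beta}\sqrt{V_A}\right)^2}{(Se_C - Se_E)^2}}
#' where \eqn{V_A} is [unpaired_variance()] at the alternative and
#' \eqn{V_0 = 2\bar p(1-\bar p)} uses the pooled proportion
#' \eqn{\bar p = (Se_C + Se_E)/2} under the null, the standard
#' two-independent-proportions convention. The same formula sizes the
#' specificity endpoint when called with specificities.
#'
#' @param se_c,se_e Sensitivities (or specificities) of the two tests.
#' @param alpha Two-sided significance level.
#' @param beta Type-II error for this endpoint.
#' @return Unrounded per-arm number of diseased (resp. non-diseased)
#'   individuals.
#' @export
n_diseased_unpaired <- function(se_c, se_e, alpha, beta) {
  diff2 <- (se_c - se_e)^2
  if (diff2 == 0)
    stop("zero difference: the unpaired sample size formula divides by the ",
         "squared difference of proportions")
  pbar <- (se_c + se_e) / 2
  v0 <- 2 * pbar * (1 - pbar)
  va <- unpaired_variance(se_c, se_e)
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(1 - beta)
  (z_a * sqrt(v0) + z_b * sqrt(va))^2 / diff2
}

#' Admissible interval for a paired discordance proportion
#'
#' For marginal accuracies `p_c`, `p_e` of the two tests within one disease
#' stratum, the proportion of discordant results is constrained to
#' `[|p_c - p_e|, p_c + p_e - 2 p_c p_e]`: the lower edge corresponds to
#' maximal dependence between the tests, the upper edge to independence.
#'
#' @param p_c,p_e Marginal accuracies in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' psi_bounds(0.81, 0.90)  # c(0.09, 0.252)
#' @export
psi_bounds <- function(p_c, p_e) {
  stopifnot(p_c > 0, p_c < 1, p_e > 0, p_e < 1)
  c(lower = abs(p_c - p_e), upper = p_c + p_e - 2 * p_c * p_e)
}

#' Minimal admissible discordance proportion
#'
#' The lower edge of [psi_bounds()]: `|p_c - p_e|`, attained under maximal
#' dependence between the two tests. The minimal paired sample size is
#' computed at this value.
#'
#' @param p_c,p_e Marginal accuracies.
#' @return `|p_c - p_e|`.
#' @export
psi_min <- function(p_c, p_e) abs(p_c - p_e)

new_sample_size_result <- function(method, design, n_d_raw, n_nd_raw,
                                   n_se_total, n_sp_total, split,
                                   power_se, power_sp) {
  structure(list(
    method = method,
    design = design,
    n_diseased_raw = n_d_raw,
    n_nondiseased_raw = n_nd_raw,
    n_diseased = ceil_n(n_d_raw),
    n_nondiseased = ceil_n(n_nd_raw),
    n_se_total = n_se_total,
    n_sp_total = n_sp_total,
    n_final = ceil_n(max(n_se_total, n_sp_total)),
    power_se = power_se,
    power_sp = power_sp,
    split = split
  ), class = "sample_size_result")
}

#' Conventional (maximum-based) co-primary sample size
#'
#' The conventional calculation sizes each endpoint at its own power,
#' scales the diseased requirement by the prevalence and the non-diseased
#' requirement by its complement, and recruits the maximum of the two
#' totals. Per-status sizes are kept unrounded through the prevalence
#' scaling; the ceiling is taken once on the totals (per-status sizes are
#' displayed as ceilings only). In the unpaired design all sizes are per
#' randomized arm.
#'
#' @param spec A [design_spec()].
#' @param params An [accuracy_params()].
#' @param dep A [paired_dependence()]; required iff `spec$design == "paired"`.
#' @param power_se,power_sp Per-endpoint powers (defaults 0.9 each, which
#'   targets roughly 0.81 overall).
#' @return A `sample_size_result` with unrounded per-status sizes
#'   (`n_diseased_raw`, `n_nondiseased_raw`), their displayed ceilings,
#'   the endpoint totals (`n_se_total`, `n_sp_total`) and the final size
#'   `n_final = ceiling(max(totals))`.
#' @examples
#' spec <- design_spec("paired", alpha = 0.05, power_overall = 0.8)
#' par <- accuracy_params(0.81, 0.90, 0.66, 0.80, prevalence = 0.47)
#' dep <- paired_dependence(0.09, 0.14)
#' conventional_sample_size(spec, par, dep)  # final N = 157
#' @export
conventional_sample_size <- function(spec, params, dep = NULL,
                                     power_se = 0.9, power_sp = 0.9) {
  check_design_inputs(spec, params, dep)
  kern <- design_kernels(spec, params, dep)
  n_d <- kern$n_se(1 - power_se)
  n_nd <- kern$n_sp(1 - power_sp)
  pi <- params$prevalence
  new_sample_size_result(
    method = "conventional", design = spec$design,
    n_d_raw = n_d, n_nd_raw = n_nd,
    n_se_total = n_d / pi, n_sp_total = n_nd / (1 - pi),
    split = NULL, power_se = power_se, power_sp = power_sp)
}

#' Optimal (equalized) co-primary sample size
#'
#' Splits the target overall power between sensitivity and specificity so
#' that the two endpoint-specific totals coincide (see
#' [solve_power_split()]), avoiding the overpowering that the maximum rule
#' of [conventional_sample_size()] induces when the prevalence is
#' unbalanced. The final size is the ceiling of the equalized unrounded
#' total.
#'
#' @inheritParams conventional_sample_size
#' @return A `sample_size_result`; `split` holds the solved `power_split`.
#' @examples
#' spec <- design_spec("paired", alpha = 0.05, power_overall = 0.8)
#' par <- accuracy_params(0.81, 0.90, 0.66, 0.80, prevalence = 0.47)
#' optimal_sample_size(spec, par, paired_dependence(0.09, 0.14))  # N = 133
#' @export
optimal_sample_size <- function(spec, params, dep = NULL) {
  check_design_inputs(spec, params, dep)
  kern <- design_kernels(spec, params, dep)
  pi <- params$prevalence
  split <- solve_power_split(
    n_se = function(b) kern$n_se(b) / pi,
    n_sp = function(b) kern$n_sp(b) / (1 - pi),
    power_overall = spec$power_overall)
  n_se_total <- split$n_se
  n_sp_total <- split$n_sp
  res <- new_sample_size_result(
    method = "optimal", design = spec$design,
    n_d_raw = n_se_total * pi, n_nd_raw = n_sp_total * (1 - pi),
    n_se_total = n_se_total, n_sp_total = n_sp_total,
    split = split, power_se = split$power_se, power_sp = split$power_sp)
  # interior solutions equalize the totals to solver tolerance; at a
  # boundary split the binding endpoint's total is the maximum
  res$n_final <- ceil_n(max(n_se_total, n_sp_total))
  res
}

#' Minimal paired sample size (maximal-dependence discordance)
#'
#' The optimal paired size evaluated at the minimal admissible discordance
#' proportions `psi_min(se_c, se_e)` and `psi_min(sp_c, sp_e)`. Because the
#' paired total is monotone increasing in both discordance proportions,
#' this is a lower bound over all admissible dependence assumptions; it is
#' the initial size and the internal-pilot size of the blinded adaptive
#' paired design.
#'
#' @inheritParams conventional_sample_size
#' @return A `sample_size_result` with `method = "minimal"`.
#' @export
minimal_sample_size_paired <- function(spec, params) {
  stopifnot(spec$design == "paired")
  dep <- paired_dependence(psi_min(params$se_c, params$se_e),
                           psi_min(params$sp_c, params$sp_e))
  res <- optimal_sample_size(spec, params, dep)
  res$method <- "minimal"
  res
}

check_design_inputs <- function(spec, params, dep) {
  stopifnot(inherits(spec, "copriss_design"),
            inherits(params, "copriss_accuracy"))
  if (spec$design == "paired") {
    if (is.null(dep))
      stop("the paired design requires a paired_dependence object")
    stopifnot(inherits(dep, "copriss_dependence"))
    check_psi <- function(psi, p_c, p_e, what) {
      b <- psi_bounds(p_c, p_e)
      if (psi < b[["lower"]] - 1e-12)
        stop(what, " = ", psi, " is below the admissible lower bound ",
             signif(b[["lower"]], 6), " for the assumed accuracies")
    }
    check_psi(dep$psi_d, params$se_c, params$se_e, "psi_d")
    check_psi(dep$psi_nd, params$sp_c, params$sp_e, "psi_nd")
  } else if (!is.null(dep)) {
    stop("paired_dependence is only meaningful in the paired design")
  }
  invisible(TRUE)
}

# per-status kernels as functions of the endpoint type-II error
design_kernels <- function(spec, params, dep) {
  if (spec$design == "paired") {
    list(
      n_se = function(b) n_diseased_paired(params$se_c, params$se_e,
                                           dep$psi_d, spec$alpha, b),
      n_sp = function(b) n_nondiseased_paired(params$sp_c, params$sp_e,
                                              dep$psi_nd, spec$alpha, b))
  } else {
    list(
      n_se = function(b) n_diseased_unpaired(params$se_c, params$se_e,
                                             spec$alpha, b),
      n_sp = function(b) n_diseased_unpaired(params$sp_c, params$sp_e,
                                             spec$alpha, b))
  }
}

#' @export
print.sample_size_result <- function(x, ...) {
  per <- if (x$design == "unpaired") " (per randomized arm)" else ""
  cat(sprintf("Co-primary sample size, %s design, %s method%s\n",
              x$design, x$method, per))
  cat(sprintf("  diseased / non-diseased required: %d / %d (raw %.2f / %.2f)\n",
              x$n_diseased, x$n_nondiseased,
              x$n_diseased_raw, x$n_nondiseased_raw))
  cat(sprintf("  endpoint totals: N_Se = %.2f, N_Sp = %.2f\n",
              x$n_se_total, x$n_sp_total))
  cat(sprintf("  per-endpoint power: Se %.4f, Sp %.4f\n",
              x$power_se, x$power_sp))
  cat(sprintf("  final sample size: %d\n", x$n_final))
  invisible(x)
}
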