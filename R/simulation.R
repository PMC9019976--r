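#' Convert a discordance proportion to a joint-success probability
#'
#' For two tests with marginal accuracies `se_e`, `se_c` within a stratum,
#' the probability that both are simultaneously correct (TPPR among the
#' diseased, TNNR among the non-diseased) relates to the discordance
#' proportion by `TPPR = (se_e + se_c - psi_d) / 2`. All four joint-cell
#' probabilities implied by the marginals and the joint success must be
#' nonnegative, otherwise the dependence is invalid.
#'
#' @param se_e,se_c Marginal accuracies of the two tests.
#' @param psi_d Discordance proportion.
#' @return The joint-success probability.
#' @examples
#' psi_to_tppr(0.90, 0.81, 0.09)  # 0.81, the maximal TPPR
#' @export
psi_to_tppr <- function(se_e, se_c, psi_d) {
  tppr <- (se_e + se_c - psi_d) / 2
  cells <- joint_cell_probs(se_e, se_c, tppr)
  if (any(cells < -1e-12))
    stop("invalid dependence: psi = ", psi_d, " implies a negative joint ",
         "cell probability for marginals (", se_e, ", ", se_c, ")")
  tppr
}

#' Convert a joint-success probability to a discordance proportion
#'
#' Algebraic inverse of [psi_to_tppr()]: `psi = se_e + se_c - 2 * tppr`.
#'
#' @param se_e,se_c Marginal accuracies.
#' @param tppr Joint-success probability.
#' @return The discordance proportion.
#' @export
tppr_to_psi <- function(se_e, se_c, tppr) se_e + se_c - 2 * tppr

# cells ordered: both correct, E-only correct, C-only correct, both incorrect
joint_cell_probs <- function(p_e, p_c, joint) {
  c(both = joint, e_only = p_e - joint, c_only = p_c - joint,
    none = 1 - p_e - p_c + joint)
}

#' Draw a paired count table from correlated binary test results
#'
#' Generates one paired trial of size `n`: the number of diseased
#' individuals is binomial with the true prevalence, then within each
#' stratum the four joint test-outcome cells are drawn from a multinomial
#' whose cell probabilities are determined by the marginal accuracies and
#' the discordance proportions (a bivariate binary law parameterized via
#' the joint success probability). Uses R's active RNG stream.
#'
#' @param params_true Data-generating [accuracy_params()].
#' @param dep_true True [paired_dependence()].
#' @param n Total sample size to draw.
#' @return A [paired_count_table()].
#' @export
sample_paired_counts <- function(params_true, dep_true, n) {
  stopifnot(n >= 0)
  tppr <- psi_to_tppr(params_true$se_e, params_true$se_c, dep_true$psi_d)
  tnnr <- psi_to_tppr(params_true$sp_e, params_true$sp_c, dep_true$psi_nd)
  pd <- pmax(joint_cell_probs(params_true$se_e, params_true$se_c, tppr), 0)
  pnd <- pmax(joint_cell_probs(params_true$sp_e, params_true$sp_c, tnnr), 0)
  n_d <- stats::rbinom(1, n, params_true$prevalence)
  d <- as.vector(stats::rmultinom(1, n_d, pd))
  nd <- as.vector(stats::rmultinom(1, n - n_d, pnd))
  # diseased: "correct" = positive; non-diseased: "correct" = negative, so
  # the correctness cells map to the positivity-indexed table accordingly
  paired_count_table(d11 = d[1], d10 = d[2], d01 = d[3], d00 = d[4],
                     nd11 = nd[4], nd10 = nd[3], nd01 = nd[2], nd00 = nd[1])
}

#' Draw unpaired per-arm counts
#'
#' Each randomized arm recruits `n_per_arm` participants; disease status is
#' binomial with the true prevalence independently per arm, true positives
#' are binomial in the diseased with the arm's sensitivity, true negatives
#' binomial in the non-diseased with the arm's specificity.
#'
#' @param params_true Data-generating [accuracy_params()].
#' @param n_per_arm Participants per randomized arm.
#' @return A list of class `unpaired_counts` with arms `e` and `c`, each
#'   holding `n`, `n_d`, `n_nd`, `tp`, `tn`.
#' @export
sample_unpaired_counts <- function(params_true, n_per_arm) {
  stopifnot(n_per_arm >= 0)
  draw_arm <- function(se, sp) {
    n_d <- stats::rbinom(1, n_per_arm, params_true$prevalence)
    list(n = n_per_arm, n_d = n_d, n_nd = n_per_arm - n_d,
         tp = stats::rbinom(1, n_d, se),
         tn = stats::rbinom(1, n_per_arm - n_d, sp))
  }
  structure(list(e = draw_arm(params_true$se_e, params_true$sp_e),
                 c = draw_arm(params_true$se_c, params_true$sp_c)),
            class = "unpaired_counts")
}

#' Monte-Carlo half-width of a simulated proportion
#'
#' `1.96 * sqrt(p (1 - p) / n_runs)`, the half-width of the asymptotic 95%
#' interval for a rejection (or coverage) proportion estimated from
#' `n_runs` simulation runs.
#'
#' @param p The proportion.
#' @param n_runs Number of simulation runs.
#' @return The half-width.
#' @examples
#' monte_carlo_halfwidth(0.05^2, 10000)  # 0.00098
#' @export
monte_carlo_halfwidth <- function(p, n_runs) {
  stopifnot(n_runs >= 1, p >= 0, p <= 1)
  1.96 * sqrt(p * (1 - p) / n_runs)
}

#' Simulation scenario configuration
#'
#' Defines one operating-characteristics scenario: the data-generating
#' truth, the planning assumptions, the design settings and the number of
#' runs. The defaults are the initial scenario of the operating
#' characteristics study: a paired design with comparator accuracies
#' 0.8 / 0.7, experimental accuracies 0.1 higher on both endpoints, true
#' prevalence 0.2 assumed at 0.3, true discordance proportions 0.11 / 0.14
#' assumed at 0.18 / 0.24, alpha 0.05 per endpoint and overall power 0.8.
#'
#' For a type-I-error scenario set the *true* experimental accuracies equal
#' to the comparator's while leaving the assumed ones at the planning
#' alternative (sizing at a zero difference is undefined). A true
#' discordance proportion below its admissible lower bound `|difference|`
#' for the true accuracies is raised to that bound (the rule that turns
#' 0.11 into 0.15 when the true difference is 0.15).
#'
#' @param design "paired" or "unpaired".
#' @param se_c,sp_c Comparator accuracies (true and assumed).
#' @param se_e,sp_e True experimental accuracies.
#' @param se_e_assumed,sp_e_assumed Planning experimental accuracies;
#'   default to the true values.
#' @param pi_true,pi_assumed True and assumed prevalence.
#' @param psi_d_true,psi_nd_true True discordance proportions (paired).
#' @param psi_d_assumed,psi_nd_assumed Assumed discordance proportions.
#' @param alpha Two-sided per-endpoint significance level.
#' @param power_overall Target overall power.
#' @param n_runs Number of simulation runs.
#' @param seed Integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(design = "paired",
                            se_c = 0.8, sp_c = 0.7,
                            se_e = se_c + 0.1, sp_e = sp_c + 0.1,
                            se_e_assumed = se_e, sp_e_assumed = sp_e,
                            pi_true = 0.2, pi_assumed = pi_true + 0.1,
                            psi_d_true = 0.11, psi_nd_true = 0.14,
                            psi_d_assumed = 0.18, psi_nd_assumed = 0.24,
                            alpha = 0.05, power_overall = 0.8,
                            n_runs = 10000, seed = 1L) {
  spec <- design_spec(design, alpha, power_overall)
  params_assumed <- accuracy_params(se_c, se_e_assumed, sp_c, sp_e_assumed,
                                    pi_assumed)
  adjusted <- c(psi_d = FALSE, psi_nd = FALSE)
  if (design == "paired") {
    # enforce admissibility of the true dependence for the true accuracies
    lo_d <- psi_min(se_c, se_e)
    lo_nd <- psi_min(sp_c, sp_e)
    if (psi_d_true < lo_d) { psi_d_true <- lo_d; adjusted["psi_d"] <- TRUE }
    if (psi_nd_true < lo_nd) { psi_nd_true <- lo_nd; adjusted["psi_nd"] <- TRUE }
    psi_to_tppr(se_e, se_c, psi_d_true)     # validates joint cells
    psi_to_tppr(sp_e, sp_c, psi_nd_true)
  }
  structure(list(
    design = design, spec = spec,
    se_c = se_c, sp_c = sp_c, se_e = se_e, sp_e = sp_e,
    se_e_assumed = se_e_assumed, sp_e_assumed = sp_e_assumed,
    pi_true = pi_true, pi_assumed = pi_assumed,
    psi_d_true = psi_d_true, psi_nd_true = psi_nd_true,
    psi_d_assumed = psi_d_assumed, psi_nd_assumed = psi_nd_assumed,
    params_assumed = params_assumed,
    psi_adjusted = adjusted,
    alpha = alpha, power_overall = power_overall,
    n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "scenario_config")
}

# data-generating truth as accuracy_params; experimental accuracies may
# equal the comparator's (null scenarios), which accuracy_params forbids,
# so truth is carried as a plain list with the same fields
true_params <- function(config) {
  structure(list(se_c = config$se_c, se_e = config$se_e,
                 sp_c = config$sp_c, sp_e = config$sp_e,
                 prevalence = config$pi_true), class = "copriss_accuracy_true")
}

#' Run one operating-characteristics scenario
#'
#' Simulates `n_runs` trials under the scenario's truth. With
#' `adaptive = TRUE` each trial follows the blinded adaptive procedure of
#' [run_adaptive_trial()]; with `adaptive = FALSE` the fixed design recruits
#' the optimal sample size computed once from the planning assumptions and
#' analyses at the end. Reported metrics: the rejection rate of the
#' Intersection-Union test (type-I error under a null truth, power under an
#' alternative), the mean and median realized final sample size, the
#' root-mean-squared error about `n_true` (the optimal size at the true
#' nuisance parameters and planning effect sizes), the relative bias of the
#' blinded interim estimates (adaptive only) and the Monte-Carlo half-width
#' of the rejection rate. The re-estimated size is a convex function of the
#' interim estimates, so its mean typically sits above `n_true` while its
#' median tracks it; both are reported.
#'
#' @param config A [scenario_config()].
#' @param adaptive Use the blinded adaptive design (`TRUE`) or the fixed
#'   design (`FALSE`).
#' @return A list of class `scenario_result`.
#' @export
run_scenario <- function(config, adaptive = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  spec <- config$spec
  truth <- true_params(config)
  paired <- config$design == "paired"
  dep_true <- if (paired)
    paired_dependence(config$psi_d_true, config$psi_nd_true) else NULL
  dep_assumed <- if (paired)
    paired_dependence(config$psi_d_assumed, config$psi_nd_assumed) else NULL

  # reference size at the true nuisance parameters, planning effect sizes
  params_ref <- config$params_assumed
  params_ref$prevalence <- config$pi_true
  dep_ref <- if (paired) {
    paired_dependence(
      max(config$psi_d_true, psi_min(params_ref$se_c, params_ref$se_e)),
      max(config$psi_nd_true, psi_min(params_ref$sp_c, params_ref$sp_e)))
  } else NULL
  n_true <- optimal_sample_size(spec, params_ref, dep_ref)$n_final

  n_fixed <- if (!adaptive)
    optimal_sample_size(spec, config$params_assumed, dep_assumed)$n_final

  reject <- logical(config$n_runs)
  n_final <- numeric(config$n_runs)
  pi_hat <- psi_d_hat <- psi_nd_hat <- rep(NA_real_, config$n_runs)
  failures <- 0L
  redraws <- 0L

  for (i in seq_len(config$n_runs)) {
    res <- tryCatch({
      if (adaptive) {
        tr <- run_adaptive_trial(spec, truth, config$params_assumed,
                                 dep_true = dep_true)
        pi_hat[i] <- tr$estimates$pi_hat
        if (paired) {
          psi_d_hat[i] <- tr$estimates$psi_d_hat
          psi_nd_hat[i] <- tr$estimates$psi_nd_hat
        }
        redraws <- redraws + tr$redraws
        list(reject = tr$reject, n = tr$n_final)
      } else {
        list(reject = analyze_fixed(spec, truth, dep_true, n_fixed, paired),
             n = n_fixed)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      reject[i] <- NA
      n_final[i] <- NA
    } else {
      reject[i] <- res$reject
      n_final[i] <- res$n
    }
  }

  ok <- !is.na(reject)
  rate <- mean(reject[ok])
  rel_bias <- function(hat, true)
    if (all(is.na(hat)) || is.null(true)) NA_real_
    else (mean(hat, na.rm = TRUE) - true) / true
  structure(list(
    adaptive = adaptive,
    rejection_rate = rate,
    n_true = n_true,
    n_mean = mean(n_final[ok]),
    n_median = stats::median(n_final[ok]),
    rmse_n = sqrt(mean((n_final[ok] - n_true)^2)),
    bias = c(pi = rel_bias(pi_hat, config$pi_true),
             psi_d = rel_bias(psi_d_hat,
                              if (paired) config$psi_d_true else NULL),
             psi_nd = rel_bias(psi_nd_hat,
                               if (paired) config$psi_nd_true else NULL)),
    mc_halfwidth = monte_carlo_halfwidth(rate, sum(ok)),
    n_runs = config$n_runs, n_failures = failures, n_redraws = redraws,
    config = config), class = "scenario_result")
}

# final analysis of a fixed-design trial of size n (per arm if unpaired)
analyze_fixed <- function(spec, truth, dep_true, n, paired) {
  lvl <- 1 - spec$alpha
  if (paired) {
    tab <- sample_paired_counts(truth, dep_true, n)
    ci_se <- tango_ci_diff_paired(tab$d10, tab$d01, max(tab$n_d, 1L), lvl)
    ci_sp <- tango_ci_diff_paired(tab$nd01, tab$nd10, max(tab$n_nd, 1L), lvl)
  } else {
    cnt <- sample_unpaired_counts(truth, n)
    ci_se <- score_ci_diff_independent(cnt$e$tp, max(cnt$e$n_d, 1L),
                                       cnt$c$tp, max(cnt$c$n_d, 1L), lvl)
    ci_sp <- score_ci_diff_independent(cnt$e$tn, max(cnt$e$n_nd, 1L),
                                       cnt$c$tn, max(cnt$c$n_nd, 1L), lvl)
  }
  iut_decision(ci_se, ci_sp)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario result (%s %s design, %d runs, %d failures)\n",
              if (x$adaptive) "adaptive" else "fixed",
              x$config$design, x$n_runs, x$n_failures))
  cat(sprintf("  rejection rate: %.4f (MC half-width %.4f)\n",
              x$rejection_rate, x$mc_halfwidth))
  cat(sprintf("  N_true %d, N_mean %.1f, RMSE %.1f\n",
              x$n_true, x$n_mean, x$rmse_n))
  if (x$adaptive)
    cat(sprintf("  relative bias: pi %.3f, psi_d %s, psi_nd %s\n",
                x$bias[["pi"]],
                format(x$bias[["psi_d"]], digits = 3),
                format(x$bias[["psi_nd"]], digits = 3)))
  invisible(x)
}
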