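#' Blinded maximum-likelihood estimate of the prevalence
#'
#' `pi_hat = n_d / n`, the binomial MLE of the disease prevalence from the
#' reference-standard results of the interim sample. Disease status does
#' not reveal either test's accuracy, so the estimate is blinded.
#'
#' @param n_d Number of diseased individuals at interim.
#' @param n Interim sample size.
#' @return Estimated prevalence in \[0, 1\].
#' @export
estimate_prevalence <- function(n_d, n) {
  stopifnot(n >= 1, n_d >= 0, n_d <= n)
  n_d / n
}

#' Blinded estimates of the discordance proportions
#'
#' Multinomial MLEs of the discordant-result proportions from a paired
#' interim count table: `psi_d_hat = (d10 + d01) / n_d` and
#' `psi_nd_hat = (nd10 + nd01) / n_nd`. Only the *pattern* of agreement
#' between the two tests is used, never which test was correct more often,
#' so the estimates are invariant to swapping the test labels and the
#' interim look is blinded.
#'
#' @param table A [paired_count_table()] with at least one diseased and one
#'   non-diseased individual.
#' @return List with `psi_d_hat` and `psi_nd_hat`.
#' @export
estimate_discordance <- function(table) {
  stopifnot(inherits(table, "paired_count_table"))
  if (table$n_d < 1)
    stop("cannot estimate psi_d: the diseased stratum is empty")
  if (table$n_nd < 1)
    stop("cannot estimate psi_nd: the non-diseased stratum is empty")
  list(psi_d_hat = (table$d10 + table$d01) / table$n_d,
       psi_nd_hat = (table$nd10 + table$nd01) / table$n_nd)
}

#' Container for blinded interim estimates
#'
#' @param pi_hat Estimated prevalence.
#' @param n_interim Interim sample size the estimates are based on.
#' @param psi_d_hat,psi_nd_hat Estimated discordance proportions (paired
#'   design only).
#' @return An object of class `interim_estimates`.
#' @export
interim_estimates <- function(pi_hat, n_interim,
                              psi_d_hat = NULL, psi_nd_hat = NULL) {
  stopifnot(pi_hat >= 0, pi_hat <= 1, n_interim >= 1)
  if (!is.null(psi_d_hat))
    stopifnot(psi_d_hat >= 0, psi_d_hat <= 1, psi_nd_hat >= 0, psi_nd_hat <= 1)
  structure(list(pi_hat = pi_hat, psi_d_hat = psi_d_hat,
                 psi_nd_hat = psi_nd_hat, n_interim = as.integer(n_interim)),
            class = "interim_estimates")
}

#' Size of the internal pilot study
#'
#' In the unpaired design the interim look happens after half of the
#' initially calculated per-arm sample size (rounded up). In the paired
#' design the initial size already equals the minimal sample size (computed
#' at the minimal discordance proportions), and the interim analysis uses
#' all of it.
#'
#' @param spec A [design_spec()].
#' @param initial The initial `sample_size_result` (for the paired design,
#'   from [minimal_sample_size_paired()]).
#' @return Integer interim sample size.
#' @export
interim_size <- function(spec, initial) {
  stopifnot(inherits(spec, "copriss_design"),
            inherits(initial, "sample_size_result"))
  if (spec$design == "unpaired")
    as.integer(ceiling(initial$n_final / 2))
  else
    initial$n_final
}

#' Blinded sample size re-estimation
#'
#' Recomputes the optimal sample size with the nuisance parameters replaced
#' by their blinded interim estimates while the accuracy assumptions (the
#' effect sizes) are kept at their planning values. The prevalence is
#' replaced by `pi_hat`; in the paired design the discordance proportions
#' are replaced by `psi_d_hat`, `psi_nd_hat`. An interim discordance
#' estimate below the minimal value compatible with the assumed accuracies
#' (where the sizing radicand turns negative) is clamped up to that minimum,
#' with a warning unless `warn = FALSE`. The recruitment target never drops
#' below the interim size: data already observed are not discarded.
#'
#' @param spec A [design_spec()].
#' @param params_assumed The planning [accuracy_params()]; only its
#'   prevalence is overridden.
#' @param est An [interim_estimates()] object.
#' @param warn Emit a warning when an interim discordance estimate is
#'   clamped to its admissible minimum.
#' @return A `sample_size_result` with additional fields `n_interim`,
#'   `n_recommended = max(n_final, n_interim)`, `estimates` and `clamped`.
#' @examples
#' spec <- design_spec("paired", alpha = 0.05, power_overall = 0.8)
#' par <- accuracy_params(0.81, 0.90, 0.66, 0.80, prevalence = 0.47)
#' est <- interim_estimates(pi_hat = 0.44, n_interim = 133,
#'                          psi_d_hat = 0.11, psi_nd_hat = 0.14)
#' reestimate_sample_size(spec, par, est)$n_final  # 200
#' @export
reestimate_sample_size <- function(spec, params_assumed, est, warn = TRUE) {
  stopifnot(inherits(spec, "copriss_design"),
            inherits(params_assumed, "copriss_accuracy"),
            inherits(est, "interim_estimates"))
  if (est$pi_hat <= 0 || est$pi_hat >= 1)
    stop("interim prevalence estimate of ", est$pi_hat,
         " does not permit sizing both endpoints")
  params <- params_assumed
  params$prevalence <- est$pi_hat
  clamped <- c(psi_d = FALSE, psi_nd = FALSE)
  if (spec$design == "paired") {
    if (is.null(est$psi_d_hat))
      stop("paired re-estimation requires interim discordance estimates")
    clamp <- function(psi, p_c, p_e, what) {
      lo <- psi_min(p_c, p_e)
      if (psi < lo) {
        if (warn)
          warning("interim ", what, " estimate ", signif(psi, 4),
                  " is below the minimum ", signif(lo, 4),
                  " compatible with the assumed accuracies; clamped")
        return(lo)
      }
      psi
    }
    psi_d <- clamp(est$psi_d_hat, params$se_c, params$se_e, "psi_d")
    psi_nd <- clamp(est$psi_nd_hat, params$sp_c, params$sp_e, "psi_nd")
    clamped <- c(psi_d = psi_d != est$psi_d_hat,
                 psi_nd = psi_nd != est$psi_nd_hat)
    dep <- paired_dependence(psi_d, psi_nd)
    res <- optimal_sample_size(spec, params, dep)
  } else {
    res <- optimal_sample_size(spec, params)
  }
  res$n_interim <- est$n_interim
  res$n_recommended <- max(res$n_final, est$n_interim)
  res$estimates <- est
  res$clamped <- clamped
  res
}

#' Simulate one blinded adaptive comparative accuracy trial
#'
#' Runs the five-phase adaptive procedure end to end on simulated data:
#' (1) initial sizing — minimal paired size, or the optimal size in the
#' unpaired design; (2) recruitment to the interim size; (3) blinded
#' estimation of the nuisance parameters (prevalence; plus discordance
#' proportions in the paired design); (4) re-estimation of the sample size
#' with accuracy assumptions unchanged, never de-escalating below the data
#' already observed; (5) recruitment of the remainder and the final
#' Intersection-Union analysis on all recruited participants, using Tango
#' intervals (paired) or score intervals (unpaired) at the unadjusted
#' per-endpoint level. Because the interim uses only blinded quantities,
#' the type-I error of the final analysis is not inflated.
#'
#' Interim samples with an empty disease stratum cannot provide estimates
#' and are redrawn (the number of redraws is recorded).
#'
#' @param spec A [design_spec()].
#' @param params_true Data-generating [accuracy_params()].
#' @param params_assumed Planning [accuracy_params()] used for all sizing.
#' @param dep_true True [paired_dependence()] (paired design only).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `adaptive_trial` with the initial, interim,
#'   re-estimated and final sizes, the interim estimates, the final count
#'   data, both confidence intervals and the IUT decision `reject`.
#' @export
run_adaptive_trial <- function(spec, params_true, params_assumed,
                               dep_true = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$design == "paired")
    run_adaptive_paired(spec, params_true, params_assumed, dep_true)
  else
    run_adaptive_unpaired(spec, params_true, params_assumed)
}

run_adaptive_paired <- function(spec, params_true, params_assumed, dep_true) {
  stopifnot(inherits(dep_true, "copriss_dependence"))
  initial <- minimal_sample_size_paired(spec, params_assumed)
  n0 <- interim_size(spec, initial)

  redraws <- 0L
  repeat {
    interim_tab <- sample_paired_counts(params_true, dep_true, n0)
    if (interim_tab$n_d >= 1 && interim_tab$n_nd >= 1) break
    redraws <- redraws + 1L
    if (redraws > 1000L)
      stop("interim sample repeatedly produced an empty disease stratum")
  }
  disc <- estimate_discordance(interim_tab)
  est <- interim_estimates(
    pi_hat = estimate_prevalence(interim_tab$n_d, n0), n_interim = n0,
    psi_d_hat = disc$psi_d_hat, psi_nd_hat = disc$psi_nd_hat)
  re <- reestimate_sample_size(spec, params_assumed, est, warn = FALSE)
  n_final <- re$n_recommended

  extra <- n_final - n0
  tab <- interim_tab
  if (extra > 0) {
    add <- sample_paired_counts(params_true, dep_true, extra)
    tab <- add_paired_tables(interim_tab, add)
  }
  ci_se <- tango_ci_diff_paired(tab$d10, tab$d01, max(tab$n_d, 1L),
                                level = 1 - spec$alpha)
  ci_sp <- tango_ci_diff_paired(tab$nd01, tab$nd10, max(tab$n_nd, 1L),
                                level = 1 - spec$alpha)
  structure(list(
    design = "paired", n_initial = initial$n_final, n_interim = n0,
    estimates = est, n_reestimated = re$n_final, n_final = n_final,
    clamped = re$clamped, redraws = redraws, counts = tab,
    ci_se = ci_se, ci_sp = ci_sp,
    reject = iut_decision(ci_se, ci_sp)), class = "adaptive_trial")
}

run_adaptive_unpaired <- function(spec, params_true, params_assumed) {
  initial <- optimal_sample_size(spec, params_assumed)
  n0 <- interim_size(spec, initial)   # per arm

  redraws <- 0L
  repeat {
    interim <- sample_unpaired_counts(params_true, n0)
    n_d_tot <- interim$e$n_d + interim$c$n_d
    if (n_d_tot >= 1 && n_d_tot < 2 * n0) break
    redraws <- redraws + 1L
    if (redraws > 1000L)
      stop("interim sample repeatedly produced an empty disease stratum")
  }
  est <- interim_estimates(pi_hat = estimate_prevalence(n_d_tot, 2 * n0),
                           n_interim = n0)
  re <- reestimate_sample_size(spec, params_assumed, est, warn = FALSE)
  n_final <- re$n_recommended

  extra <- n_final - n0
  cnt <- interim
  if (extra > 0) {
    add <- sample_unpaired_counts(params_true, extra)
    cnt <- list(e = add_arm(interim$e, add$e), c = add_arm(interim$c, add$c))
  }
  lvl <- 1 - spec$alpha
  ci_se <- score_ci_diff_independent(cnt$e$tp, max(cnt$e$n_d, 1L),
                                     cnt$c$tp, max(cnt$c$n_d, 1L), lvl)
  ci_sp <- score_ci_diff_independent(cnt$e$tn, max(cnt$e$n_nd, 1L),
                                     cnt$c$tn, max(cnt$c$n_nd, 1L), lvl)
  structure(list(
    design = "unpaired", n_initial = initial$n_final, n_interim = n0,
    estimates = est, n_reestimated = re$n_final, n_final = n_final,
    clamped = re$clamped, redraws = redraws, counts = cnt,
    ci_se = ci_se, ci_sp = ci_sp,
    reject = iut_decision(ci_se, ci_sp)), class = "adaptive_trial")
}

add_paired_tables <- function(a, b) {
  paired_count_table(a$d11 + b$d11, a$d10 + b$d10, a$d01 + b$d01,
                     a$d00 + b$d00, a$nd11 + b$nd11, a$nd10 + b$nd10,
                     a$nd01 + b$nd01, a$nd00 + b$nd00)
}

add_arm <- function(a, b) {
  list(n = a$n + b$n, n_d = a$n_d + b$n_d, n_nd = a$n_nd + b$n_nd,
       tp = a$tp + b$tp, tn = a$tn + b$tn)
}
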