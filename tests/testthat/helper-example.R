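# Example-study and scenario builders shared across tests.

# PET/CT vs CT pancreatic-cancer example study planning parameters
example_spec <- function(power_overall = 0.8)
  design_spec("paired", alpha = 0.05, power_overall = power_overall)

example_params <- function(prevalence = 0.47)
  accuracy_params(se_c = 0.81, se_e = 0.90, sp_c = 0.66, sp_e = 0.80,
                  prevalence = prevalence)

example_dep <- function() paired_dependence(psi_d = 0.09, psi_nd = 0.14)

# data-generating truth for simulations; unlike accuracy_params() this
# permits equal accuracies (null configurations)
truth_list <- function(se_c, se_e, sp_c, sp_e, prevalence)
  structure(list(se_c = se_c, se_e = se_e, sp_c = sp_c, sp_e = sp_e,
                 prevalence = prevalence), class = "copriss_accuracy_true")

# random admissible paired planning set (assumes set.seed() upstream)
random_paired_setup <- function() {
  repeat {
    se <- sort(runif(2, 0.55, 0.95))
    sp <- sort(runif(2, 0.55, 0.95))
    if (se[2] - se[1] > 0.03 && sp[2] - sp[1] > 0.03) break
  }
  bd <- psi_bounds(se[1], se[2])
  bn <- psi_bounds(sp[1], sp[2])
  list(
    params = accuracy_params(se[1], se[2], sp[1], sp[2],
                             prevalence = runif(1, 0.25, 0.75)),
    dep = paired_dependence(runif(1, bd[1], bd[2]), runif(1, bn[1], bn[2])))
}
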