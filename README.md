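# copriss

Sample size calculation and blinded re-estimation for **comparative
diagnostic accuracy trials** with sensitivity and specificity as co-primary
endpoints.

## The problem

A confirmatory diagnostic accuracy trial compares an experimental index test
against a comparator, with a reference standard defining true disease
status. The trial succeeds only if the experimental test is superior on
**both** sensitivity and specificity — a union null
$H_0 : \mathrm{Se}_E = \mathrm{Se}_C \cup \mathrm{Sp}_E = \mathrm{Sp}_C$
tested by the Intersection-Union principle: reject iff both endpoint nulls
are rejected at level $\alpha$ each, so the overall power is the product of
the endpoint powers.

Two inefficiencies plague the standard planning workflow:

1. **The maximum rule overpowers one endpoint.** The conventional
   calculation sizes each endpoint at its own power (typically 0.9), scales
   by the prevalence $\pi$ — $N_{Se} = n_D/\pi$, $N_{Sp} = n_{ND}/(1-\pi)$ —
   and recruits $\max(N_{Se}, N_{Sp})$. Unless the prevalence happens to
   balance the two requirements, one endpoint is heavily overpowered.
   The *optimal* calculation instead splits the overall power between the
   endpoints under $(1-\beta_{Se})(1-\beta_{Sp}) = \mathrm{Power}_{\mathrm{overall}}$
   so that $N_{Se} = N_{Sp}$: the smallest total reaching the target overall
   power. The split has no closed form and is found by bisection.

2. **Nuisance parameters are guesses.** The required size depends on the
   prevalence and — in the paired design, where every participant receives
   both tests — on the discordance proportions $\psi_D, \psi_{ND}$
   (probabilities that the two tests disagree within a disease stratum).
   The package implements a **blinded internal-pilot design**: recruit to an
   interim, estimate $\hat\pi = n_D/n$ and
   $\hat\psi = (n_{10}+n_{01})/n$ from disease status and the
   agreement pattern only (never from which test was right — so the look is
   blinded and the type-I error is not inflated), re-compute the optimal
   size, and continue recruitment. The paired diseased-group kernel is the
   matched-pairs formula

   $$n_D = \frac{\left(z_{1-\alpha/2}\psi_D + z_{1-\beta}\sqrt{\psi_D^2 -
   \tfrac14(\mathrm{Se}_C-\mathrm{Se}_E)^2(3+\psi_D)}\right)^2}
   {\psi_D(\mathrm{Se}_C-\mathrm{Se}_E)^2}.$$

The final analysis uses score-type intervals (Miettinen–Nurminen for
independent proportions, Tango for matched ones) rather than Wald, for
coverage and range preservation, and a Monte-Carlo engine computes operating
characteristics (type-I error, power, sample-size distribution, estimator
bias) of fixed versus adaptive designs.

## Worked example

The running example is a paired trial of PET/CT (experimental) against CT
(comparator) for pancreatic cancer: $\mathrm{Se}_C = 0.81$,
$\mathrm{Se}_E = 0.90$, $\mathrm{Sp}_C = 0.66$, $\mathrm{Sp}_E = 0.80$,
prevalence 0.47, discordance 0.09 / 0.14, $\alpha = 0.05$ two-sided per
endpoint.

```r
library(copriss)
spec   <- design_spec("paired", alpha = 0.05, power_overall = 0.8)
params <- accuracy_params(se_c = 0.81, se_e = 0.90,
                          sp_c = 0.66, sp_e = 0.80, prevalence = 0.47)

conventional_sample_size(spec, params, paired_dependence(0.09, 0.14),
                         power_se = 0.9, power_sp = 0.9)
#> Co-primary sample size, paired design, conventional method
#>   diseased / non-diseased required: 74 / 47 (raw 73.46 / 46.60)
#>   endpoint totals: N_Se = 156.29, N_Sp = 87.92
#>   per-endpoint power: Se 0.9000, Sp 0.9000
#>   final sample size: 157
```

The conventional plan needs 157 participants: 74 diseased drive
$N_{Se} = 157$ while the specificity endpoint would need only 88 — it is
overpowered. The optimal calculation at the *minimal* admissible discordance
(the internal-pilot size of the adaptive design) needs only 133:

```r
minimal_sample_size_paired(spec, params)
#> Co-primary sample size, paired design, minimal method
#>   diseased / non-diseased required: 63 / 71 (raw 62.36 / 70.32)
#>   endpoint totals: N_Se = 132.68, N_Sp = 132.68
#>   per-endpoint power: Se 0.8045, Sp 0.9945
#>   final sample size: 133
```

Both endpoint totals are equalized at 132.7 (power split 0.805 × 0.994
= 0.8 overall). After recruiting those 133 participants, the blinded interim
look yields $\hat\pi = 0.44$, $\hat\psi_D = 0.11$, $\hat\psi_{ND} = 0.14$,
and the re-estimation raises the target to 200:

```r
est <- interim_estimates(pi_hat = 0.44, n_interim = 133,
                         psi_d_hat = 0.11, psi_nd_hat = 0.14)
reestimate_sample_size(spec, params, est)
#> Co-primary sample size, paired design, optimal method
#>   diseased / non-diseased required: 88 / 112 (raw 87.81 / 111.75)
#>   endpoint totals: N_Se = 199.56, N_Sp = 199.56
#>   per-endpoint power: Se 0.8000, Sp 1.0000
#>   final sample size: 200
```

At the end of the trial each endpoint is analyzed with a score-type
interval; the trial succeeds iff both lower bounds exceed 0:

```r
tango_ci_diff_paired(b = 12, c = 4, n = 120)   # Se_E - Se_C, matched pairs
#> 95% Tango score confidence interval for a difference of proportions
#>   estimate 0.0667, interval [0.0015, 0.1392]
```

Operating characteristics of a whole design come from the simulation
engine, e.g.
`run_scenario(scenario_config(n_runs = 10000, seed = 1), adaptive = TRUE)`.

A thin command-line front end is installed under the package's `exec/`
directory: `copriss size --config plan.yaml`,
`copriss reestimate --config plan.yaml --interim estimates.json`,
`copriss ci --design paired --counts counts.json`,
`copriss simulate --scenario scen.yaml`. `make_fixtures()` writes example
configuration files.

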