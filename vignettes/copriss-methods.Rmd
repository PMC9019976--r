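---
title: "Co-primary sample size and blinded re-estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-primary sample size and blinded re-estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copriss)
```

## The statistical setting

A confirmatory comparative diagnostic accuracy trial evaluates an
experimental index test against an established comparator, with a reference
standard defining the true disease status. Sensitivity (Se) and specificity
(Sp) are *co-primary* endpoints: the trial succeeds only if the experimental
test is shown superior on **both**. Formally the global null is the union of
the two endpoint nulls,

$$H_0 : \mathrm{Se}_E = \mathrm{Se}_C \;\cup\; \mathrm{Sp}_E = \mathrm{Sp}_C,$$

tested by the Intersection-Union principle: reject globally iff both
endpoint nulls are rejected at the unadjusted two-sided level $\alpha$ each.
Because the diseased and non-diseased strata are disjoint, the overall power
is (approximately) the product of the endpoint powers, and the global type-I
error is at most the product of the endpoint levels — the IUT needs no
multiplicity adjustment.

Two designs are covered. In the *paired* design every participant receives
both index tests and the reference standard; the endpoint comparisons are
matched, and the key nuisance parameters are the discordance proportions
$\psi_D$ (among diseased) and $\psi_{ND}$ (among non-diseased) — the
probabilities that the two tests disagree. In the *unpaired* design each
participant is randomized to one index test; the comparisons are between
independent proportions and the only nuisance parameter is the prevalence
$\pi$.

## Sample size calculations

### Endpoint kernels

For the paired design the diseased-group requirement uses the matched-pairs
formula driven by the discordance proportion:

$$n_D = \frac{\left(z_{1-\alpha/2}\,\psi_D + z_{1-\beta}
\sqrt{\psi_D^2 - \tfrac14(\mathrm{Se}_C-\mathrm{Se}_E)^2(3+\psi_D)}\right)^2}
{\psi_D\,(\mathrm{Se}_C-\mathrm{Se}_E)^2},$$

and analogously $n_{ND}$ with $(\mathrm{Sp}, \psi_{ND})$. The admissible
range of a discordance proportion given the two marginal accuracies
$p_C, p_E$ is $[\,|p_C-p_E|,\; p_C+p_E-2p_Cp_E\,]$ (maximal dependence up to
independence); `psi_bounds()` exposes it and the kernels reject values that
make the radicand negative.

For the unpaired design the per-arm requirement is the classical
two-independent-proportions formula
$n = (z_{1-\alpha/2}\sqrt{V_0} + z_{1-\beta}\sqrt{V_A})^2/(p_C-p_E)^2$ with
$V_A = p_C(1-p_C) + p_E(1-p_E)$ at the alternative. The variance under the
null is not pinned down by the matched-pairs literature we follow, so we
adopt the standard pooled convention $V_0 = 2\bar p(1-\bar p)$ with
$\bar p = (p_C+p_E)/2$. We consistently use the *upper-tail* quantiles
$z_{1-\alpha/2}, z_{1-\beta}$ in both designs; this convention is the one
that reproduces the worked example's printed group sizes (74 and 47).

### Conventional versus optimal

The conventional calculation sizes each endpoint at its own power (0.9 each
by default), converts to totals by $N_{Se} = n_D/\pi$ and
$N_{Sp} = n_{ND}/(1-\pi)$, and recruits $\max(N_{Se}, N_{Sp})$. Whenever the
prevalence is unbalanced one endpoint is grossly overpowered and the maximum
rule wastes participants.

The optimal calculation instead treats the per-endpoint type-II errors as
free parameters under the single constraint
$(1-\beta_{Se})(1-\beta_{Sp}) = \text{Power}_{\text{overall}}$ and chooses
the split at which $N_{Se} = N_{Sp}$, so no maximum needs to be taken and
the total is the smallest one reaching the target overall power. The
equalizing split has no closed form; `solve_power_split()` finds it by
bisection on the sensitivity power over the feasible interval
$(\text{Power}_{\text{overall}},\, 1)$, on which the difference
$N_{Se}-N_{Sp}$ is strictly increasing. Bisection (tolerance $10^{-10}$ on
the power, interval offset $10^{-9}$) was chosen over derivative-based
root-finders because the normal quantiles diverge at both interval edges and
a guaranteed bracket matters more than convergence order at these problem
sizes. The example study's re-estimated configuration has its root within
$10^{-5}$ of the lower edge, so this hardening is exercised in practice.

**Boundary splits.** When the prevalence is extreme, one endpoint can
require the larger total at *every* feasible split; the difference then has
no interior zero and the constrained optimum sits at the interval edge:
the dominating endpoint keeps the full overall power and the other
endpoint's power is driven to 1. `solve_power_split()` returns this
degenerate split (flagged `boundary = "se"` or `"sp"`) with the product
constraint still holding exactly, and the final size is the binding
endpoint's total. This case is not an error: it arises routinely during
blinded re-estimation when the interim prevalence estimate is small, and
refusing it would make the adaptive procedure fail on realistic data.

### Rounding convention

Per-status requirements are kept *unrounded* through the prevalence
scaling; a single ceiling is applied to the final total (and per-status
values are displayed as ceilings only). This convention reproduces all the
example study's printed values ($73.46 \to 74$, $46.60 \to 47$,
$73.46/0.47 = 156.3 \to 157$, $46.60/0.53 = 87.9 \to 88$); ceiling the
group sizes before dividing by the prevalence would give $74/0.47 = 157.4
\to 158$ instead. The ceiling uses a $10^{-8}$ fuzz so that totals that are
integers up to solver tolerance are not bumped to the next integer.

## Confidence intervals and the final analysis

Although the sample size formulas are Wald-type, the analysis uses
score-type intervals, whose coverage is closer to nominal and which are
range preserving:

* **Unpaired:** the score interval for a difference of two independent
  proportions, with the variance evaluated at the restricted MLEs under
  $p_1 - p_2 = \delta$ (computed by the closed-form cubic) and inflated by
  $N/(N-1)$ — the Miettinen–Nurminen variant. The inflation factor is an
  argument (`inflate = FALSE` gives the plain Mee variant) because the
  literature does not pin the variant down; the default follows the most
  common practice. No continuity correction is applied.
* **Paired:** Tango's asymptotic score interval for a difference of matched
  proportions, with the nuisance discordant-cell probability profiled at
  its restricted MLE; at $\delta = 0$ the statistic reduces exactly to the
  McNemar statistic (a unit test asserts this against
  `stats::mcnemar.test`).

Interval endpoints are obtained by bisection on $\delta \in [-1, 1]$ with
tolerance $10^{-8}$; boundary counts ($x = 0$ or $x = n$, including zero
discordant pairs) go through the same inversion with no ad-hoc
substitution, so degenerate zero-width intervals cannot occur. The test
suite validates both intervals against independent oracles that maximize
the constrained likelihoods numerically and invert the tests on a grid.

The global decision is `iut_decision()`: reject iff both lower confidence
bounds exceed their margins (0 for superiority).

## The blinded adaptive procedure

Planning assumptions about nuisance parameters — the prevalence, and in the
paired design the discordance proportions — are often wrong, and the sample
size is sensitive to them. The adaptive design proceeds in five phases:

1. **Initial size.** Paired: the *minimal* sample size, i.e. the optimal
   size evaluated at the minimal admissible discordance proportions
   $\psi_{D,\min} = |\mathrm{Se}_C - \mathrm{Se}_E|$ and
   $\psi_{ND,\min} = |\mathrm{Sp}_C - \mathrm{Sp}_E|$ (the total is monotone
   increasing in both $\psi$'s, so this is a lower bound over all
   dependence assumptions). Unpaired: the optimal size at the assumed
   prevalence.
2. **Recruit to the interim.** Paired: the interim uses the full initial
   (minimal) sample. Unpaired: half of the initial per-arm size, rounded up.
3. **Blinded estimation.** $\hat\pi = n_D/n$ (binomial MLE from the
   reference standard) and, paired, $\hat\psi_D = (n_{D10}+n_{D01})/n_D$,
   $\hat\psi_{ND} = (n_{ND10}+n_{ND01})/n_{ND}$ (multinomial MLEs). These
   use only disease status and the *pattern* of agreement between the
   tests — never which test was right — so they are invariant under
   swapping the test labels (asserted by a test) and the look is blinded.
4. **Re-estimate.** The optimal size is recomputed with the nuisance
   estimates substituted and the accuracy assumptions left untouched. An
   interim $\hat\psi$ below the minimum compatible with the assumed
   accuracies is clamped up to that minimum (with a warning); the
   recruitment target never drops below the interim size, the standard
   internal-pilot convention.
5. **Final analysis.** All recruited participants — interim data included —
   are analyzed with the fixed-design intervals at the unadjusted
   per-endpoint $\alpha$. Because the interim used only blinded
   quantities, the type-I error is not inflated; the simulation tests
   confirm the global rate stays below the product bound.

Interim samples in which a disease stratum is empty cannot provide
estimates; such samples are redrawn in simulation and the redraws counted.
An interim prevalence estimate of exactly 0 or 1 is an error in direct API
use.

## The data generator

`sample_paired_counts()` draws the number of diseased participants
binomially at the true prevalence and then, within each stratum, the four
joint test-outcome cells from a multinomial. The dependence between the two
tests is parameterized by the joint success probability (the proportion of
simultaneously correct results, TPPR among diseased / TNNR among
non-diseased), related to discordance by
$\psi = p_E + p_C - 2\,\mathrm{TPPR}$; `psi_to_tppr()` converts and
validates that all four induced cells are nonnegative.
`sample_unpaired_counts()` draws disease status and test results
independently per randomized arm.

The generator emulates exactly what the sizing formulas assume:
cross-sectional sampling with binomial disease status, a perfect reference
standard applied to everyone, homogeneous accuracies, and exchangeable
participants. It does **not** emulate verification bias, an imperfect or
missing reference standard, reader or center effects, correlated repeat
testing, or drift in prevalence over recruitment — so passing operating
characteristics demonstrate the procedure's behavior under its own
assumptions, not robustness to those violations.

Scenario defaults in `scenario_config()` are the initial scenario of the
operating-characteristics study: comparator accuracies 0.8/0.7,
experimental accuracies 0.1 higher, true prevalence 0.2 assumed at 0.3,
true discordance 0.11/0.14 assumed at 0.18/0.24, $\alpha = 0.05$ per
endpoint, overall power 0.8. A true discordance below its admissible lower
bound for the true accuracies is raised to the bound automatically. Null
configurations set the *true* experimental accuracies equal to the
comparator's while the sizing keeps the planning alternative — sizing at a
zero difference is undefined, which is why the scenario carries assumed
experimental accuracies separately.

Reproducibility uses R's own RNG: one seed per scenario, sequential draws
per run; `run_adaptive_trial()` additionally accepts a per-call seed.

## Problem sizes and runtime choices

The packaged test suite runs the operating-characteristics checks at 2,000
simulation runs per scenario and the coverage checks at 2,000 replicates
per configuration; these sizes keep the Monte-Carlo half-width of a
rejection rate near 0.8 at about $\pm 0.018$ while the whole suite stays at
desk scale. `run_scenario()` itself defaults to 10,000 runs, matching the
scale of the published study, and remains feasible on one CPU.

## Known limitations

* **Variance of the re-estimated size.** The blinded estimates are
  unbiased (the tests verify relative bias below 5% and in practice find it
  below 1%), but the re-estimated total is a convex function of them, and
  in the paired initial scenario the internal pilot contains only a few
  dozen diseased participants. The re-estimated $N$ therefore has a heavy
  right tail: its *median* tracks the true requirement closely while its
  *mean* exceeds it noticeably, and because the power curve is concave the
  averaged power falls a few points short of the target when the true
  discordance is well above its minimum. The operating-characteristics
  tests compute these rejection rates; the shortfall is a property of
  re-estimating from a small blinded pilot, not of the implementation —
  the fixed design sized at the *true* nuisance parameters hits the target
  within Monte-Carlo error in the same harness.
* Sizing formulas and analysis intervals are asymptotic and not derived
  from one another; with very small strata the score intervals are
  conservative.
* Only superiority hypotheses are implemented; non-inferiority and mixed
  hypotheses, unblinded adaptation and early stopping are out of scope.
* In the unpaired design the returned sizes are per randomized arm (1:1
  allocation); callers needing the total across arms should double them,
  as the print method notes.
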