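---
title: "Bayesian design and monitoring of small randomized comparative trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian design and monitoring of small randomized comparative trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srctdesign)
```

## The problem

Small randomized comparative trials — typically 20 to 60 patients across 2
to 4 arms — are used in early-phase oncology to screen experimental
treatments or doses against a standard of care using binary early endpoints:
response (`Res`) and severe toxicity (`Tox`). With such small samples,
frequentist asymptotics are unreliable and point estimates like "8/20
responded" are misleading without an accompanying measure of uncertainty.
srctdesign implements a fully conjugate Bayesian workflow for these trials:
posterior estimation, between-arm comparison, posterior-probability stopping
rules, operating characteristics, and restricted randomization.

## Model and assumptions

Each arm's event probability $\theta$ carries a beta prior
$\theta \sim \mathrm{beta}(a, b)$ with mean $a/(a+b)$ and effective sample
size $\mathrm{ESS} = a+b$. Observing $X$ events in $n$ patients gives the
posterior $\mathrm{beta}(a+X,\, b+n-X)$, whose mean

$$\frac{X+a}{n+a+b} \;=\; \frac{n}{n+a+b}\cdot\frac{X}{n} \;+\;
  \frac{a+b}{n+a+b}\cdot\frac{a}{a+b}$$

shrinks the empirical rate toward the prior mean with weight
$\mathrm{ESS}/(n+\mathrm{ESS})$. Operational priors are elicited by fixing
the mean at the clinician's expectation and the ESS at 1 (at most 2), so
that 10–20 patients dominate the prior; `prior_from_mean(0.40, 1)` gives
beta(0.40, 0.60). Degenerate prior means of exactly 0 or 1 are rejected
rather than clamped — an interior mean is always available from
elicitation, and endpoint pseudo-counts would break conjugate updating.

Arms are modeled as statistically independent: patients are randomized,
each arm has its own prior, and no hierarchical borrowing is attempted.
Every reported interval is **equal-tailed** (quantile-based), not highest
posterior density; the two conventions differ visibly for the skewed
posteriors small trials produce, and all worked examples in the package
round-trip under the equal-tailed convention. Event times (for preliminary
median PFS estimation) use the conjugate exponential–gamma pair:
$\lambda \sim \mathrm{gamma}(s, r)$ updated to
$\mathrm{gamma}(s+d,\, r+T)$ after $d$ events over total follow-up $T$,
with the median-time interval obtained by the monotone transform
$\log 2/\lambda$.

## Comparing arms

The comparative estimand is $\theta_E - \theta_S$. For independent beta
posteriors its CDF is

$$\Pr(\theta_E - \theta_S \le d)
  = \int_0^1 F_E\!\big(Q_S(u) + d\big)\, du,$$

where $F_E$ is the experimental posterior's CDF and $Q_S$ the reference
posterior's quantile function. The quantile substitution makes the
integrand smooth and bounded on $[0,1]$ even when non-informative priors
put infinite density at the support endpoints, so adaptive quadrature
(`stats::integrate`, absolute tolerance $10^{-10}$) evaluates it to
effectively full precision. Interval endpoints are solved by bisection on
$[-1, 1]$ to $10^{-7}$; improvement probabilities
$\Pr(\theta_E > \theta_S + \delta \mid \mathrm{data})$ are one minus the
CDF at $\delta$, with default margins $\delta = 0.15$ and $0.20$ — the
smallest improvements usually considered clinically meaningful for response
rates.

Quadrature, not Monte Carlo, is the primary route: it is deterministic,
reproducible without seed bookkeeping, and faster at the accuracy needed.
Monte Carlo appears in two places only — as the independent oracle in the
test suite (paired beta draws), and for post-stratified weighted
differences, where the weighted sum of several independent beta differences
has no similarly convenient one-dimensional representation. There, $10^6$
seeded draws give interval endpoints accurate to about $10^{-3}$, ample for
2-decimal reporting.

```{r compare}
j <- beta_params(0.5, 0.5)
e <- update_beta(j, "7/15"); s <- update_beta(j, "3/15")
difference_interval(e, s)
improvement_probability(e, s, 0.20)
```

## Stopping rules and their integer boundaries

A safety rule stops accrual to an arm when
$\Pr(\theta_{Tox} > \theta^* \mid \mathrm{data}) > c$, where $\theta^*$ is
the largest acceptable toxicity probability; a futility rule uses
$\Pr(\theta_{Res} < \theta^* \mid \mathrm{data}) > c$ for the smallest
acceptable response probability. The inequality is strict — a criterion
exactly at the cutoff does not stop — following the standard formulation.
A random-comparator variant replaces the fixed $\theta^*$ with a highly
informative beta distribution of the same mean (e.g. beta(200, 800) for
0.20), evaluated with the same difference quadrature at margin zero; the
comparator is never updated by trial data.

When a rule's prior is not stated separately, the package defaults to
`prior_from_mean(limit, 1)` — the ESS-1 prior centered at $\theta^*$. This
convention reproduces the reference trigger sets for both rule families we
use as fixtures (3/4, 5/8, 6/12 for the fixed-limit rule with
$\theta^* = 0.30$, $c = 0.90$, looks at 4, 8, 12 of 16; and 4/8, 6/16 for
the comparator rule with $\theta^* = 0.20$, looks at 8, 16 of 24), which
was the criterion for freezing it.

Because the posterior criterion is monotone in the observed event count,
each rule is exactly equivalent to integer trigger counts per look;
`boundary_table()` derives them by scanning counts, and the test suite
verifies rule/boundary equivalence exhaustively. Looks are interim only:
a design that wants a final-analysis stopping look must list `n_max`
among its looks explicitly.

Cutoffs may be constant or follow the sample-size-adaptive family
$\alpha (n/N)^\beta$; `calibrate_cutoff()` selects, from a user grid, the
specification with the largest stopping probability at the unacceptable
event rate $\theta^{**}$ subject to a cap on the stopping probability at
$\theta^*$, breaking ties toward the larger cutoff (fewer unwanted stops).
Infeasible constraints return the closest member with a warning rather
than failing, so design exploration can proceed.

```{r boundary}
rule <- safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16))
boundary_table(rule)
```

## Operating characteristics

Single-arm operating characteristics are computed **exactly** by a dynamic
program over (look, cumulative event count) with binomial cohort
increments — simulation noise would be pointless for a quantity a small DP
yields to machine precision. The attained-sample-size distribution puts the
stopping mass at each look and the remaining mass at $n_{\max}$; quartiles
are the smallest attainable sizes whose cumulative probability reaches
0.25, 0.50, 0.75.

One consequence of computing exactly: for the fixed-limit rule above, the
cumulative stopping probability by $n=8$ at true toxicity 0.40 is
0.2499789 — a knife-edge $2\times10^{-5}$ below 0.25 — so the exact first
quartile is 12, where a simulation-based table will report 8 about half
the time. Similarly, at true toxicity 0.60 the total stopping probability
0.864 already exceeds 0.75 by $n=12$, fixing the upper quartile at 12
under any cumulative-probability quantile convention. The unit tests
freeze the exact values.

Full-trial behaviour — enrichment and final selection — couples the arms,
so `simulate_trial()` uses seeded Monte Carlo. Patients accrue through
permuted blocks; outcomes are treated as immediately evaluable, and each
monitored arm is checked when its evaluated count reaches a scheduled look
(no accrual/assessment lag is modeled). On a stop, the remaining positions
are re-blocked evenly over the surviving arms with the block size scaled to
the surviving arm count (blocks of 6 over 3 arms become blocks of 4 over
2), preserving the total planned sample size; a final partial block is the
truncated prefix of one more permuted block. If no experimental arm
survives, the trial terminates with none selected; otherwise the surviving
experimental arm with the larger posterior mean response probability (under
a beta(0.5, 0.5) prior) is selected, ties going to the earlier-listed —
typically lower-dose — arm, the safety-conservative choice. Per-simulation
RNG streams are drawn from the root seed by counter, so the $i$-th
replicate is identical whatever `n_sims` is, and adjacent root seeds do not
share streams.

`generate_trial_dataset()` runs one such trial and returns the
patient-level table (id, block, arm, tox, res) — the package's synthetic
fixture generator. Default study conditions in the examples mirror the
three-arm cell-therapy design: N = 48, n = 16 per arm, blocks of 6, safety
looks at 4, 8, 12, limit 0.30, cutoff 0.90. What the generator emulates is
binary outcomes under block randomization with monitoring-driven
truncation; it does not model accrual times, evaluation lag, missing
outcomes, or covariate-driven heterogeneity — so passing tests demonstrate
the computational machinery, not robustness to those real-data features.

## Randomization

`permuted_blocks()` draws each block as an independent uniform random
permutation of the balanced multiset (the mechanism behind "randomly
scrambled" sequences), guaranteeing equal per-arm counts at every block
boundary — exactly where the monitoring looks are placed. Stratified
variants run an independent plan per stratum with distinct derived
sub-seeds; pooled cross-stratum counts are not balanced at arbitrary cuts,
which the tests exhibit by construction. Plans are generated up front in
full, as trial protocols pre-specify them, not lazily per enrollment.

## Numerical choices and problem sizes

* Beta quantiles come from `stats::qbeta`; interval coverage is verified to
  $10^{-9}$.
* Difference-CDF quadrature: absolute tolerance $10^{-10}$, up to 500
  subdivisions; bisection tolerance $10^{-7}$, 200-step cap (reached only
  if the CDF were non-monotone, which it cannot be).
* Reported tables round to 2 decimals; machine CSVs keep full precision.
* Test-suite problem sizes were chosen to keep the default run around half
  a minute while leaving oracle noise well below the tolerances tested:
  $2\times10^5$ paired draws for the routine Monte-Carlo cross-checks
  ($10^6$ in the end-to-end suite), exhaustive $2^{12}$ path enumeration
  against the dynamic program, $10^5$ blocks for permutation uniformity,
  and 3000 simulated trials for the simulator-versus-exact comparison.

## Known limitations

* No non-conjugate priors, MCMC, or covariate regression; post-stratified
  weighted differences are the only heterogeneity adjustment offered.
* Monitoring assumes outcomes are evaluable by the time a look is reached.
* Selection uses posterior mean response only; no response/toxicity
  trade-off utilities and no multiplicity adjustment across pairwise
  comparisons (none is standard in this setting).
* The simulator does not implement outcome-adaptive randomization or
  predictive-probability (as opposed to posterior-probability) futility
  rules.
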