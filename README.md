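# srctdesign

Bayesian design, monitoring and analysis of **small randomized comparative
trials** (SRCTs): early-phase studies with 20–60 patients across 2–4 arms
that compare experimental treatments or doses against a standard of care
using binary early endpoints — response (Res) and severe toxicity (Tox).

At these sample sizes, frequentist asymptotics are unreliable and a bare
"8/20 responded" conveys false certainty. srctdesign provides the conjugate
Bayesian toolkit a trial statistician needs for this setting:

* **Beta-binomial inference.** θ ~ beta(a, b) with mean a/(a+b) and
  effective sample size ESS = a+b; posterior beta(a+X, b+n−X) after X
  events in n patients. Operational priors are elicited from a mean and
  ESS = 1 (`prior_from_mean`), so the data dominate. Equal-tailed credible
  intervals, tail probabilities, shrinkage weights, and exponential–gamma
  updates for median event times.
* **Between-arm comparison.** The exact posterior distribution of
  θ_E − θ_S for independent beta posteriors, by deterministic quadrature:
  credible intervals for the difference and improvement probabilities
  Pr(θ_E > θ_S + δ | data) for clinically meaningful margins (δ = 0.15,
  0.20), plus multi-arm comparison tables and post-stratified weighted
  differences.
* **Monitoring rules.** Posterior-probability safety and futility stopping
  criteria Pr(θ_Tox > θ* | data) > c and Pr(θ_Res < θ* | data) > c (fixed
  or random beta comparator; constant or α(n/N)^β cutoffs), converted to
  their exactly equivalent integer trigger boundaries per look
  (`boundary_table`).
* **Operating characteristics.** Exact early-stopping probabilities and
  attained-sample-size distributions by dynamic programming
  (`exact_arm_oc`), cutoff calibration against them (`calibrate_cutoff`),
  and seeded Monte-Carlo simulation of full multi-arm trials with
  enrichment and final arm selection (`simulate_trial`), plus a
  patient-level synthetic trial generator (`generate_trial_dataset`).
* **Randomization.** Permuted-block plans balanced at every monitoring
  look, stratified variants, and enrichment re-planning after an arm drops
  (`permuted_blocks`, `stratified_plan`, `enrichment_replan`).

## Worked example

A trial observes 8 responses in 20 patients under a non-informative
beta(0.5, 0.5) prior:

```r
library(srctdesign)
j <- beta_params(0.5, 0.5)
post <- update_beta(j, "8/20")
post
#> beta(8.5, 12.5)  mean = 0.4048  ESS = 21
credible_interval(post)
#> 95% CrI [0.21, 0.62]
```

The posterior mean 0.405 is the empirical rate 0.40 shrunk slightly toward
the prior mean 0.5, and the interval says the response probability could
plausibly be anywhere from 0.21 to 0.62 — the honest statement behind
"40% responded (n = 20)".

Comparing arms with 7/15 responses on E versus 3/15 on S:

```r
e <- update_beta(j, "7/15"); s <- update_beta(j, "3/15")
improvement_probability(e, s, 0)     # Pr(thetaE > thetaS)        = 0.94
improvement_probability(e, s, 0.20)  # Pr(thetaE > thetaS + 0.20) = 0.63
difference_interval(e, s)
#> 95% CrI [-0.07, 0.55]
```

E is very likely better than S (0.94), but a 0.20 improvement is far from
established (0.63): exactly the nuance a small trial should report.

A safety rule for a 16-patient arm — stop if
Pr(θ_Tox > 0.30 | data) > 0.90, checked after 4, 8 and 12 evaluated
patients — reduces to integer triggers, whose operating characteristics
are computed exactly:

```r
rule <- safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16))
boundary_table(rule)
#> safety boundary (stop if events >= trigger):
#>  look_n trigger criterion
#>       4       3 0.9532976
#>       8       5 0.9627594
#>      12       6 0.9132362
#> stop if >= 3/4, 5/8, 6/12

exact_arm_oc(boundary_table(rule), true_p = 0.50)
#> Pr(stop early) = 0.658 at true p = 0.5
#> attained sample size distribution:
#>     4     8    12    16
#> 0.313 0.133 0.213 0.342
#> quartiles: 4, 12, 16
```

An arm with a true 50% toxicity rate is stopped early two times in three,
typically after only 4–12 patients.

## Command line

A thin wrapper over the same functions lives at `inst/cli/srct-design.R`:

```sh
Rscript inst/cli/srct-design.R boundary --config design.json --out-dir out/
Rscript inst/cli/srct-design.R simulate --config design.json --seed 7 --out-dir out/
```

Subcommands: `posterior`, `compare`, `boundary`, `oc`, `simulate`,
`calibrate`, `randomize`, `explore`, `generate-data`, `report`. Stochastic
subcommands require an explicit `--seed`; every run writes full-precision
CSVs, a human-readable report, and a `run.log` with the config hash and
seed.

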