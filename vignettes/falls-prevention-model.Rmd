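---
title: "Methods: a falls-prevention microsimulation with efficiency and equity layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a falls-prevention microsimulation with efficiency and equity layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallscea)
```

## The decision problem

Community-based falls prevention in older adults can be commissioned through
three parallel pathways: **reactive** (R), referral to multifactorial
intervention after a fall requiring medical attention (an "MA fall");
**proactive** (P), referral after risk screening at routine GP contact; and
**self-referred** (SR), voluntary enrolment. A commissioner can scale up any
subset of the three from current-practice ("usual") levels to
guideline-recommended levels, giving eight strategies: UC (none scaled up),
R, P, SR, R+P, R+SR, P+SR, and RC (all three).

`fallscea` evaluates these strategies with an individual-level annual-cycle
simulation of a 60+ community-dwelling population, then layers on:

1. a **societal cost-utility analysis** (CUA) — dominance and
   extended-dominance frontier, sequential ICERs, and net-benefit measures;
2. **probabilistic sensitivity analysis** (PSA) — cost-effectiveness
   acceptability curves (CEAC) and frontier (CEAF);
3. **distributional cost-effectiveness analysis** (DCEA) — Atkinson and Kolm
   equally-distributed-equivalent (EDE) net health benefit across
   socioeconomic-status (SES) quartiles;
4. deterministic **±20% alternative scenarios** averaged over ten seeds.

## The simulation model

Each simulated person carries age, sex, SES quartile (1 = least deprived,
4 = most deprived), falls history in the previous year, a 0–100 cumulative
deficit frailty index, and binary markers for low physical activity,
cognitive impairment, fear of falling and abnormal gait/balance. A baseline
cohort (default 20 000) enters at cycle 0; a fresh cohort of 60-year-olds
(default 3% of baseline) enters each subsequent cycle. The default horizon
is 40 annual cycles, near-lifetime for the baseline cohort.

Within a cycle the event order is fixed:

1. **Intervention assignment.** Reactive eligibility requires an MA fall in
   the immediately preceding cycle; proactive eligibility requires a GP
   contact draw at the SES-adjusted access rate plus a positive screen
   (falls history *and* abnormal gait/balance by default — a configuration
   switch allows the disjunction); everyone may self-refer. A pathway is
   received when its supply and demand draws both succeed; at recommended
   level supply is 1 (no supply constraint). When several pathways qualify,
   precedence is R > P > SR, mirroring clinical urgency. Receipt applies the
   pathway's relative risk as a fall-odds multiplier for its effect duration
   (no decay), and accrues the pathway's public cost, copayment and
   participant/caregiver time costs.
2. **Mortality**: a fatal-fall draw (logistic in age and frailty), then
   other-cause death at an age/sex Gompertz-type schedule scaled by frailty
   and the SES mortality gradient.
3. **Nonfatal falls** for survivors: fall probability is a logistic
   regression over the person's characteristics; fallers draw one of four
   nonfatal faller types (single non-MA, single MA, recurrent non-MA,
   recurrent with MA). Recurrent-with-MA fallers carry one or two MA falls
   (probability of two: 0.3, configurable); each MA fall is independently
   hospitalised with probability **0.28**, keyed to hip-fracture admission.
4. **Outcome accrual**, discounted at 3.5%/year to cycle 0 (accrual at cycle
   start, no half-cycle correction; cycle 0 undiscounted). Cycle utility is
   an age/sex EQ-5D-3L baseline scaled by the SES utility gradient, minus a
   frailty decrement and the faller type's acute loss, floored at 0 (the
   floor is configurable down to −0.594). Public sector cost combines an
   all-cause base in age and frailty with the directly fall-related cost,
   which is also recorded separately inside the all-cause total. Nonpublic
   streams — out-of-pocket expenditure, informal care, copayments, time
   costs, and paid/unpaid productivity value — are tracked per category.
5. **Frailty progression** (age-band base increment plus a faller-type
   add-on, clamped to [0, 100]) and time-varying updates: falls history,
   absorbing cognitive impairment, fear-of-falling onset (raised in
   fallers), absorbing gait/balance impairment, activity transitions,
   ageing.
6. **Long-term care admission** (logistic in age and frailty) — an
   absorbing exit, like death; LTC residents accrue no further outcomes and
   no terminal-cycle cost.

### Common random numbers

Every stochastic event draws one uniform per present person from a stream
keyed by (master seed, cycle, event); persons occupy a contiguous id window
so the draws are id-aligned across strategies. Incremental comparisons are
therefore paired: a null intervention (relative risk 1, zero costs) makes
all eight strategies **bit-identical**, a property asserted in the test
suite. PSA runs additionally share the individual-level seed, so run-to-run
variation isolates parameter (second-order) uncertainty, and a degenerate
PSA specification collapses all runs onto the point estimate.

### What the synthetic defaults do and do not emulate

The default parameterisation is synthetic. It is constructed so that about
30% of the 60+ population has falls history, fall risk rises with age and
frailty, and quartile 4 is strictly worse off than quartile 1 on baseline
frailty, fall risk, utility, mortality and GP access — giving the DCEA layer
genuine inequality to measure. Entry cohorts default to 3% of baseline per
cycle, which replaces exits (deaths plus LTC admissions) at the baseline
population composition; exact stationarity over 40 years is not attainable
with a constant entry size because the simulated population ages. Passing
tests demonstrate internal coherence of the model mechanics and analysis
layers, not calibration to any real locality: absolute QALY and cost levels
have no empirical warrant, which is why the worked cost-effectiveness
example is driven by a published incrementals table rather than by the
simulator.

## Societal cost-utility analysis

Incremental nonpublic costs are converted to QALY equivalents at the
societal threshold λ_soc = £60 000/QALY and netted off health QALYs:

> societal QALYs = health QALYs − (net nonpublic cost) / λ_soc,

where net nonpublic cost = out-of-pocket + informal care + copayment + time
costs − productivity value (productivity enters the societal ledger as a
negative cost). ICERs are incremental *public sector* cost per societal
QALY gained, reported to the nearest pound. The frontier first removes
strongly dominated strategies (another strategy no more costly and no less
effective, at least one strict; exact ties keep the lexicographically first
name), then iteratively removes extendedly dominated ones until sequential
ICERs strictly increase. INMB = λ_pub·ΔQ − ΔC and INHB = ΔQ − ΔC/λ_pub at
public thresholds λ_pub ∈ {20 000, 30 000}.

```{r table1}
tab <- read_table1()
dominance_frontier(data.frame(strategy = tab$strategy,
                              public_cost = tab$incremental_public_cost,
                              societal_qalys = tab$incremental_societal_qaly))
```

## Probabilistic sensitivity analysis

Each distributed input gets a second-order distribution whose mean equals
the point estimate, with a default coefficient of variation of 0.2: beta
for probabilities, utilities and relative risks (the (0,1] support keeps
relative risks inside their admissible range), gamma for costs, lognormal
for positive rate-like quantities, normal for log-odds coefficients. The
reference analysis size is 800 runs; scaled-down runs (smaller populations,
fewer runs) are a configuration choice. Per run and threshold λ, net
monetary benefit is NMB_s = λ·societal QALYs_s − public cost_s; the CEAC is
the fraction of runs each strategy attains maximal NMB (exact ties split
equally, so rows sum to one) and the CEAF marks the strategy with the
highest expected NMB. On degenerate (all-runs-equal) inputs the CEAF switch
thresholds coincide with the frontier's sequential ICERs — asserted in the
tests using the published incrementals.

## Distributional cost-effectiveness analysis

The equity outcome is per-capita societal net health benefit by SES
quartile:

> NHB_g = (QALYs_g − nonpublic_g/λ_soc − public_g/λ_pub) / persons_g.

The EDE level under relative inequality aversion ε is the Atkinson form
(Σ w_g x_g^(1−ε))^(1/(1−ε)), with the weighted mean at ε = 0 and the
geometric-mean limit at ε = 1 (handled explicitly to avoid the 1/(1−ε)
singularity); under absolute aversion α it is the Kolm form
−(1/α)·log(Σ w_g e^(−α·x_g)). ε = 11 and α = 0.15 are the aversion levels
elicited from the English general public; the default grids are
ε ∈ {0, 5, 11, 15, 20, 30} and α = 0.15, at both public thresholds.
Quartile weights default to equal quarters (configurable to person-count
shares). Non-positive NHB under Atkinson with ε > 0 is a hard error rather
than a silent shift — any shift changes relative-inequality rankings — with
the Kolm index as the sanctioned alternative. The strategy with the highest
EDE NHB per (index, threshold) is optimal on efficiency and equity jointly;
incremental EDE NHB versus a comparator and a strict-monotonicity
progressivity classification (increasing incremental NHB with deprivation =
unambiguously progressive) complete the layer.

Numerical notes: the Atkinson power form factors out the largest value and
the Kolm form shifts by the smallest before exponentiating, so neither
overflows at large aversion; both agree with direct formula evaluation to
1e-10 relative and with frozen 50-digit reference evaluations at spot
points.

## Alternative scenarios

Ten named scenarios multiply one knob by 0.8 or 1.2: each individual's
baseline frailty draw (clamped at draw time — a multiplicative reading of
"baseline frailty ±20%", chosen over rescaling the distribution parameters
as the simplest auditable contract), the annual frailty-progression
increments, the cognitive-impairment incidence probability (capped at 1),
recommended-level intervention demand (usual-care rates never change), and
the GP access rate (capped at 1). Scenario runs are deterministic at point
estimates, averaged over ten seeds derived from the same master-seed
streams as the main scenario, and reported through the relative-inequality
(Atkinson) DCEA by default.

## Problem sizes and reproducibility

The test suite exercises the full pipeline at reduced sizes chosen for a
desk run: riskless closed cohorts for exact person-year accounting,
5 000-person populations for the bit-identical null-intervention check,
50 000 persons × 10 seeds for the scenario-direction check, and a
50-run × 2 000-person PSA demonstration. Every generator, simulation and
analysis function is a pure function of its arguments and a single integer
master seed; sub-seeds are derived through named hash streams so adding one
draw never perturbs the others, and a rerun with the same seed reproduces
every output file byte-for-byte (manifest timestamps aside).

## Known limitations

- No intra-year event timing, no half-cycle correction, no supply-capacity
  queueing; effect of an intervention ends abruptly after its duration.
- The faller-type mixture is fixed conditional on falling; fall counts
  beyond two MA falls per year are not represented.
- SES quartile is the only equity delineator; social-welfare families other
  than Atkinson/Kolm are out of scope.
- Absolute outputs are only as meaningful as the synthetic inputs; the
  package is a framework for evaluating strategy *contrasts* under a
  user-supplied parameterisation.
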