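# fallscea

Efficiency and equity evaluation of community-based falls-prevention
strategies in adults aged 60+, for health-economic modellers and
commissioning analysts.

Three falls-prevention pathways operate in parallel in a UK-style community
setting: **reactive** (R, referral after a medically attended fall),
**proactive** (P, referral after risk screening at GP contact) and
**self-referred** (SR, voluntary enrolment). Scaling up any subset from
usual-care to recommended levels gives eight strategies — UC, R, P, SR,
R+P, R+SR, P+SR, RC. `fallscea` compares them with:

- an **individual-level annual-cycle microsimulation** (falls, frailty
  progression, long-term-care admission, mortality, costs and EQ-5D-3L
  utilities, SES-quartile gradients) under common random numbers;
- a **societal cost-utility layer**: societal QALYs
  `Q_soc = Q_health − C_nonpublic / λ_soc` (λ_soc = £60 000/QALY), strong and
  extended dominance, sequential ICERs `ΔC_public / ΔQ_soc`, and net-benefit
  measures `INMB = λ·ΔQ − ΔC`, `INHB = ΔQ − ΔC/λ`;
- **probabilistic sensitivity analysis** with CEAC/CEAF over a threshold
  grid;
- **distributional cost-effectiveness analysis**: per-capita societal net
  health benefit by SES quartile, Atkinson EDE
  `(Σ w_g x_g^(1−ε))^(1/(1−ε))` and Kolm EDE `−(1/α)·ln Σ w_g e^(−α x_g)`,
  with the public-elicited aversion levels ε = 11 and α = 0.15;
- deterministic **±20% scenario analyses** (baseline frailty, frailty
  progression, cognitive-impairment incidence, intervention demand, GP
  access) averaged over ten seeds.

The bundled default parameterisation is synthetic (documented and fully
overridable via YAML/JSON); the methods vignette
(`vignettes/falls-prevention-model.Rmd`) describes the model, its
assumptions and its limits.

## Worked example

The package ships the published worked example of the eight strategies'
incremental public sector costs and incremental societal QALYs versus usual
care (`inst/extdata/table1.csv`). Running the dominance frontier on it:

```r
library(fallscea)
tab <- read_table1()
dominance_frontier(data.frame(strategy = tab$strategy,
                              public_cost = tab$incremental_public_cost,
                              societal_qalys = tab$incremental_societal_qaly))
```

prints (columns abridged):

```
  strategy public_cost societal_qalys       classification comparator  icer
1       UC           0            0.0          on-frontier       <NA>    NA
2        R     5609678         2371.6          on-frontier         UC  2365
3       SR    54293886         9915.1 extendedly dominated       <NA>    NA
4     R+SR    60993792        12413.0          on-frontier          R  5516
5        P   246878182        10386.3    strongly dominated       <NA>    NA
6      R+P   249448665        12230.0    strongly dominated       <NA>    NA
7     P+SR   280980595        17319.5 extendedly dominated       <NA>    NA
8       RC   284401514        18934.3          on-frontier       R+SR 34258
```

Reading: R is cost-effective at £2365 per societal QALY gained versus UC,
R+SR at £5516 versus R; moving all the way to RC costs £34 258 per QALY
gained versus R+SR, so RC only becomes attractive above a ~£30 000 public
threshold — or once health-inequality aversion enters through the DCEA
layer. The same check is available from a shell:

```sh
Rscript inst/cli/fallscea table1-check
```

End-to-end simulation runs go through the same CLI (`simulate`, `evaluate`,
`psa`, `dcea`, `scenario`) or directly through `run_strategy()`,
`run_psa()`, `dcea_table()` and `deterministic_scenario_run()`.

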