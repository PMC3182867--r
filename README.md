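# swarmtaxis

Agent-based simulation of collective chemotactic navigation on complex
terrains, for researchers studying collective motion, swarm robotics and
microbial behaviour.

Groups of bacteria-inspired agents climb a static chemical concentration
field shaped like a two-dimensional diffusion bowl — `A_K·K0(κr)` around the
target, with `K0` the modified Bessel function of the second kind — overlaid
with periodic mountains and valleys (`A_p·sin(k_x x)·sin(k_y y)`) that create
local optima and bottlenecks. Each agent is a run-and-tumble walker: it moves
at constant speed and, at the end of each run, tumbles by a Gaussian angle
whose variance shrinks with the concentration gain measured along its own
path,

    sigma^2(g) = sigma_min^2 + (sigma_max^2 - sigma_min^2) / (1 + exp(g/g0)),

so successful directions persist and unsuccessful ones re-randomise. Agents
also interact through the classical zonal rules of collective motion —
repulsion from neighbours closer than `R_r`, velocity alignment within
`R_o`, attraction within `R_a` — and mix the resulting group direction with
their own heading through a weight `w`:

    d_i = normalize( w·u(theta_i) + (1 - w)·d_group,i ).

Three interaction policies are compared throughout: **independent** (no
interactions), **fixed** (constant `w`), and **adaptive** — a hard-limit
two-state rule in which an agent that just measured a concentration increase
sets `w = 0.5` (trust itself) and otherwise sets `w = 0` (follow the group).
Group performance is summarised by the median path length (navigation time
of the median-arriving agent times speed), the error fraction
`(L - D)/D` relative to the straight start-to-target distance, the polar
order parameter as alignment, and cluster counts on the interaction graph.

The inner simulation loop is compiled (Rcpp); a 900-step run of 20 agents
takes a few milliseconds, so the shipped ensembles and sweeps run in
seconds to minutes. All results come back as tibbles, fitted objects have
`tidy()`/`glance()` methods, and each result type has a ggplot2
`autoplot()`.

## Worked example

```r
library(swarmtaxis)

cfg <- default_config("adaptive")   # the frozen calibrated configuration
tr  <- run_simulation(cfg, seed = 1)
tr
#> <swarm_trajectory> N = 20, 440 step(s), 20/20 arrived, alignment 0.928
summarize_run(tr)
#>   mechanism seed n_agents n_arrived median_path_length censored error_fraction
#> 1  adaptive    1       20        20               34.5    FALSE          0.148
#>   alignment n_clusters mean_weight p90_path_length
#> 1     0.928          1       0.445            43.1
```

All 20 agents reached the target within 440 of the allowed 900 steps; the
median agent's path was 34.5 length units against a straight-line distance
of 30 (error fraction 0.148 — this particular seed is an easy one), the
group stayed a single cluster, and the average interaction weight 0.445
means agents measured an improving concentration on about 89% of steps
(weight levels are 0 and 0.5).

Comparing the three mechanisms on matched seeds:

```r
mc <- mechanism_comparison(default_config("fixed"), n_rounds = 50, base_seed = 1)
glance(mc)[, c("mechanism", "mean_median_path", "mean_error_fraction", "mean_alignment")]
#>     mechanism mean_median_path mean_error_fraction mean_alignment
#> 1    adaptive             43.0               0.434          0.925
#> 2       fixed             49.7               0.656          0.787
#> 3 independent             67.2               1.241          0.462
mc$tests
#>     faster      slower statistic  p_value median_faster median_slower
#> 1 adaptive       fixed       570 1.40e-06          42.4          48.7
#> 2    fixed independent        64 1.51e-16          48.7          67.8
#> 3 adaptive independent        19 1.10e-17          42.4          67.8
```

Adaptive swarms navigate with roughly half the relative path excess of
fixed-weight swarms (0.43 vs 0.66), and both beat independent search
decisively (one-sided rank-sum tests on the median path lengths). Parameter
sweeps (`sweep_parameter()` over the fixed weight, group size, internal
noise, interaction radii or run-length heterogeneity) and
`validate_config()` diagnostics round out the experiment surface; see the
vignette in `vignettes/swarm-navigation-model.Rmd` for the model details and
the calibration rationale.

A command-line wrapper is installed at `inst/cli/swarmtaxis`
(`run`, `sweep`, `compare`, `validate`, `terrain` subcommands over JSON
configuration files).

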