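# branchdyn

Branch-resolved analysis of single-cell mRNA count dynamics along a
developmental trajectory with one bifurcation.

## The problem

During differentiation, cells move along a pseudo-time trajectory that splits
at a branch point into two fates. A gene's mRNA count distribution — observed
across the cells of a pseudo-time *window* — can change shape along that
trajectory: unimodal at one stage, bimodal or trimodal at another. Those
shapes, and the transcriptional burst kinetics behind them, carry mechanistic
information about fate determination. `branchdyn` provides the toolchain for
this analysis:

- **Windowing**: cells are rank-ordered by pseudotime within each branch
  segment (`pre`, `branch_point`, `branch1`, `branch2`) and split into
  equal-frequency windows, optionally overlapping for smooth trend series
  (`assign_windows()`, `empirical_distribution()`).
- **Mechanistic distribution fitting**: the stationary law of the two-state
  (telegraph) model — promoter switching OFF→ON at rate α, ON→OFF at rate β,
  transcribing at rate μ, mRNA degrading at rate δ = 1 — is, in the bursty
  regime, a Gamma density with shape α and rate β̃ = β/μ. Windowed count
  distributions are fitted with one, two or three (location-shiftable) Gamma
  components by minimizing the Kullback–Leibler divergence
  KL(p_data ‖ p_model) on the integer grid (`fit_mixture()`), and the
  modality m ∈ {1,2,3} is selected by BIC (`select_modality()`).
  Per-component statistics use the closed forms mean = loc + α/β̃,
  var = α/β̃², skewness = 2/√α, excess kurtosis = 6/α (`mixture_stats()`).
- **Burst kinetics**: counts follow the Beta–Poisson law
  X ~ Poisson(s·k_syn·p), p ~ Beta(k_on, k_off), with s the cell size factor.
  Maximum likelihood over (k_on, k_off, k_syn) via Gauss–Jacobi quadrature
  gives burst size BS = k_syn/k_off and burst frequency BF = k_on per window,
  and their monotone trends per segment (`fit_burst_params()`,
  `burst_trajectory()`).
- **Marker screening**: highly-variable-gene ranking (top-30 standardized
  dispersion) intersected with a significant pre/post-branch
  Kolmogorov–Smirnov distribution shift at BH FDR 0.05 (`select_markers()`).
- **Gene-pair analyses**: 2D kernel joint densities (`joint_density()`),
  per-window tree-ensemble regulation strength (`regulation_strength_series()`),
  exact 1-Wasserstein distance matrices between gene×stage expression laws
  (`wasserstein_matrix()`), and Spearman trend classification
  (`trend_classification()`).
- **Synthetic branching data**: `simulate_branching_dataset()` draws a full
  cells×genes count matrix plus trajectory annotation from stage-dependent
  two-state kinetics (with Gamma-mixture stages for trimodal programs and
  log-normal cell sizes), so every stage of the pipeline is testable without
  any download.

All user-facing functions take data frames / matrices in and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(branchdyn)

# simulate a 9-stage branching world: 540 cells, 3 genes, one gene ("gx")
# programmed bimodal before the branch and trimodal on branch2
sched <- default_stage_schedule(cells_per_stage = 60, branch_stages = 2)
prog <- gene_program(sched, c("g1", "g2", "gx"), k_on = 1, k_off = 3, k_syn = 60)
prog <- set_stage_mixture(prog, "gx", 1:4,
  gamma_components(c(0.6, 0.4), c(16, 900), c(4, 30)))        # modes ~3.8, 30
prog <- set_stage_mixture(prog, "gx", c(8, 9),
  gamma_components(rep(1/3, 3), c(64, 900, 4900), c(8, 30, 70))) # 8, 30, 70
sim <- simulate_branching_dataset(
  simulation_config(sched, prog, size_sdlog = 0.1, seed = 1))

# modality before the branch vs on branch2
pre <- segment_counts(sim$counts, sim$annotation, "gx", "pre")
b2  <- segment_counts(sim$counts, sim$annotation, "gx", "branch2")
select_modality(pre, seed = 1)$m
#> [1] 2
select_modality(b2, seed = 1)$m
#> [1] 3

# the fitted two-component law before the branch, in broom form
fit <- fit_mixture(pre, m = 2, seed = 1)
tidy(fit)
#> # A tibble: 2 × 10
#>   component weight shape  rate   loc  mean variance skewness ex_kurtosis  peak
#>       <int>  <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl>    <dbl>       <dbl> <dbl>
#> 1         1  0.517  11.3  2.74     0  4.14     1.51    0.594      0.529   3.77
#> 2         2  0.483  87.7  2.93     0 30.0     10.2     0.214      0.0684 29.6
```

The fit recovers the programmed law: a component of weight ~0.5 with mean
4.1 (programmed 0.6 / mean 4) and one of weight ~0.5 with mean 30.0
(programmed 0.4 / mean 30) — the KL-fitted mixture read back in the
shape/rate convention, with the closed-form moments alongside. Burst
kinetics along the whole tree:

```r
bt <- burst_trajectory(sim$counts, sim$annotation, "g1",
                       windows_per_segment = 8, sizes = sim$sizes, seed = 1)
burst_trends(bt)      # per-segment monotone-trend labels for BS and BF
autoplot(bt)          # BS / BF against pseudotime, coloured by branch
```

## Acceptance script

`scripts/acceptance.R` simulates the default branching world from a given
seed, runs the full pipeline (`run_pipeline()`: marker screening, modality
selection per segment, burst trajectories, regulation-strength series,
Wasserstein matrix) end to end, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
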