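---
title: "Models and methods behind branchdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind branchdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchdyn)
```

# The model

## Two-state transcription and its stationary law

`branchdyn` analyses mRNA count distributions under the two-state (telegraph)
model: a promoter switches OFF→ON at rate $k_{on}$ and ON→OFF at rate
$k_{off}$, transcribes at rate $k_{syn}$ while ON, and transcripts degrade at
rate $\delta$, fixed to 1 so all rates are per mRNA lifetime. The stationary
count law is Beta–Poisson,
$$X \sim \mathrm{Poisson}(s\,k_{syn}\,p), \qquad p \sim \mathrm{Beta}(k_{on}, k_{off}),$$
with $s$ a per-cell size factor. In the bursty regime this law is well
approximated by a Gamma density with shape $\alpha = k_{on}$ and rate
$\tilde\beta = k_{off}/k_{syn}$; burst size is $BS = k_{syn}/k_{off}$ and
burst frequency $BF = k_{on}$.

**Parameter convention.** All Gamma parameters in this package are
shape/*rate*. The component mean is $loc + \alpha/\tilde\beta$, variance
$\alpha/\tilde\beta^2$, skewness $2/\sqrt\alpha$, excess kurtosis $6/\alpha$.
This convention is forced by internal consistency of the published component
tables this methodology reproduces: a component with shape 408.27 and
parameter 19.49 has mean 20.95 only under the rate reading (the scale reading
would give ~7957). The package uses shape/rate everywhere and documents any
interface in those terms.

## Windowed empirical distributions

Every "pseudo-time point" is really a pseudo-time *window*: cells of one
branch segment, rank-ordered by pseudotime, grouped into equal-frequency
windows. Equal-frequency (quantile) edges rather than equal-width intervals
make window occupancy robust to uneven pseudotime density. Windows may
overlap by a configurable member fraction: trend series (burst kinetics,
regulation strength) default to 50% overlap for smoothness; distribution fits
use disjoint windows so fits are independent. Segment-level ("before branch",
"at branching point", "after branch") distributions pool all cells of the
corresponding stages. Defaults: `windows_per_segment` sized for roughly 30–50
cells per window on a ~400-cell dataset, `min_cells = 10`.

## KL-divergence mixture fitting

A windowed count distribution is fitted with a mixture of $m \in \{1,2,3\}$
(optionally location-shifted) Gamma components by minimizing
$$\mathrm{KL}(p_{data} \,\|\, q_\vartheta) = \sum_{k \in \mathrm{support}} p_{data}(k)\, \log \frac{p_{data}(k)}{q_\vartheta(k)},$$
where the model probability at integer $k$ integrates the mixture density
over $[k-\tfrac12, k+\tfrac12)$ — the standard continuity correction — and is
renormalized over the observed support. Model probabilities are floored at
$10^{-12}$ so an observation far outside the model yields a large finite
penalty rather than an infinite one.

The optimizer is multi-start BFGS on unconstrained coordinates: log shapes,
log rates, logit-simplex weights. The first start is a seeded k-means split
of the samples with method-of-moments per cluster; the remaining starts are
log-normal perturbations of it, plus (for $m > 1$) a "collapsed" start of $m$
near-identical copies of the single-component moment fit so the search space
always nests the simpler model — this keeps the achieved KL monotone
non-increasing in $m$ in practice. Multi-start stops early once additional
starts stop improving the best objective (at least five starts are always
tried); the default is 10 starts. Location shifts are off by default:
shifted Gamma fits are ill-conditioned (the shift trades off against shape at
small shape), and the package enables them only on request, bounded above by
the sample minimum.

## Modality selection

KL always improves with more components, so the selection statistic is BIC
computed from the discretized model log-likelihood,
$\mathrm{BIC}_m = (3m-1)\log n - 2\,\ell_m$. The simplest adequate model
wins: a richer model must beat the simpler one by more than `delta_bic = 2`
(the conventional "positive evidence" margin), otherwise the smaller $m$ is
kept. Two-state mechanisms can produce unimodal and bimodal laws but not
trimodal ones, so trimodal windows are modelled phenomenologically as
three-component mixtures; no promoter model with more than two states is
considered.

## Burst-kinetics inference

Burst parameters are fitted by direct maximum likelihood of the Beta–Poisson
law — a deliberate method substitution for neural likelihood-free inference:
desk-scale, deterministic, and unit-testable. The integral
$P(X = k) = \int_0^1 \mathrm{Poisson}(k; s k_{syn} p)\,\mathrm{Beta}(p; k_{on}, k_{off})\,dp$
is evaluated by Gauss–Jacobi quadrature, whose weight function absorbs the
Beta kernel exactly (including the integrable endpoint singularities when
$k_{on} < 1$ or $k_{off} < 1$). Nodes and weights come from the analytic
Jacobi three-term recurrence via Golub–Welsch. The standalone pmf
auto-escalates the order (64, 128, … 1024) until two successive orders agree
within $10^{-9}$; the likelihood uses a fixed order of 40, which is accurate
to ~$10^{-12}$ for per-lifetime rates up to ~150 (checked against a
$10^5$-point trapezoid oracle).

The likelihood is maximized on the log scale by Nelder–Mead from 8
moment-matched starts, with box bounds
$k_{on}, k_{off} \in [10^{-3}, 10^3]$, $k_{syn} \in [10^{-2}, 10^5]$ enforced
by a soft penalty. The search optimizes the *offset* from each start so the
whole path is exactly invariant under log-scale translations — doubling every
cell size halves the fitted $k_{syn}$ exactly and leaves $k_{on}$, $k_{off}$
bit-identical. Identical (count, size) pairs are aggregated before
evaluation. The published normalization of these rates by an effective decay
$(\Phi_i + \alpha)$ is self-referential as printed; the package treats all
fitted rates as already expressed per effective mRNA decay time
(`phi = 1`, no growth correction), so BS and BF are dimensionless.

Cell sizes are estimated as total counts over the median total
(`estimate_cell_sizes()`): simple, robust, median 1 by construction.
Alternative size estimators are out of scope.

## Marker screening

A marker gene must (i) be a highly variable gene — ranked by per-gene
dispersion (variance/mean of log-normalized expression) z-scored within
equal-frequency bins of mean expression (20 bins, automatically reduced so
each bin keeps ≥ ~10 genes), with a top-30 rank cutoff — and (ii) change its
expression distribution across the branch. "Significant difference" is
deliberately a two-sample Kolmogorov–Smirnov test (distribution-level, not
mean-level, sensitivity — matching the modality-change framing) of the pooled
pre-branch cells against each post-branch segment, Benjamini–Hochberg
corrected across all gene×branch tests at FDR 0.05; a gene passes if
significant on at least one branch. The marker set is the intersection of the
two criteria. Modality calls per gene×segment are available behind
`modality = TRUE` (off by default: three multi-start mixture fits per gene
are expensive and rarely needed at screening time).

## Gene-pair analyses

*Regulation strength* reimplements the tree-ensemble importance idea in
miniature so the package stays self-contained and seed-deterministic: per
window, 100 CART-style regression trees (bootstrap resampling, square-root
feature subsampling, minimum node size 5) predict the target gene's
log-normalized expression from all other genes; a regulator's strength is its
share of the total variance reduction, normalized to sum to 1 across
candidate regulators. How the original tree-ensemble analysis was windowed
along the trajectory is unspecified in the source methodology; the per-window
scheme here is this package's design choice.

*Wasserstein distances* use the exact 1-Wasserstein (order 1; the order is
otherwise unspecified) integral of the absolute difference of empirical
quantile functions over the merged quantile breakpoints — no binning, so the
translation property $W_1(u, u+c) = |c|$ holds exactly.

*Joint densities* are Gaussian-kernel 2D KDEs with Scott's-rule bandwidth per
axis on a 64×64 grid; a zero-variance axis falls back to a 1D density times a
point mass.

*Trend classification* uses Spearman rank correlation of the series against
window order: `increasing` / `decreasing` when $|\rho| \ge 0.6$ with
$p < 0.05$, `constant` when $|\rho| < 0.6$ and the relative range of the
series is under 10%, otherwise `non-monotone`. The source analysis asserts
monotonicity only qualitatively; the 0.6/0.05 defaults are this package's
operationalization. Note that with few windows the $p$-value gate is strict —
at six windows only near-perfect orderings reach $p < 0.05$ — so trend series
benefit from 8–12 windows per segment.

# The synthetic world

`simulate_branching_dataset()` generates the world every test runs against.
Stationary Beta–Poisson sampling replaces stochastic simulation of promoter
switching: only stationary distributions are analysed, so time integration
would add cost without information. Design of the default world:

- **Topology**: four pre-branch stages, one branch-point stage, and one or
  more stages per post-branch segment; 60 cells per stage by default (420
  cells, echoing a small mouse-embryo-scale dataset of ~440 cells × ~50
  genes). Pseudotime is uniform within each stage's sub-interval of $[0,1]$,
  stages contiguous; the trunk occupies the first portion, both branches
  share the remainder. No pseudotime scale is specified by the source
  methodology, so this uniform-per-stage choice is ours.
- **Cell sizes**: log-normal, `sdlog = 0.2` (mild, plate-scale depth
  variation), median-normalized to 1, applied as Poisson rate multipliers.
- **Trimodal stages**: a single two-state gene cannot be trimodal, so
  trimodal stage programs are specified directly as three-component Gamma
  mixtures whose size-scaled draws are rounded to integer counts. Because
  size scaling smears every mode by roughly `mode × sdlog`, multimodal
  recovery experiments use `sdlog = 0.1` and mode separations larger than the
  smeared widths — chosen from that relation up front, not tuned afterwards.
  Clean *bimodal* programs are likewise specified as two-component mixtures:
  the telegraph law with slow switching is bimodal but carries substantial
  between-mode mass (the Beta occupancy density is U-shaped, not two-spiked),
  so it is the wrong instrument for a crisp two-mode recovery experiment.
- **Burst-trend world** (used by the trend-recovery studies): burst size
  ramps 12→6 across the pre-branch stages, 7→14 on branch1 ($k_{on} = 0.5$,
  $k_{off} = 10$) and 6→3 on branch2 with $k_{on} = 2$ — that branch raises
  its burst frequency while burst size decays, keeping mean counts in the
  range where BS stays statistically identifiable (at mean counts below ~2,
  the BS estimator's noise roughly doubles). Stage size (800 cells) and
  window count (10 per segment) come from a power analysis of the BS
  estimator's sampling noise (sd of $\log \widehat{BS} \approx 0.25$ at 200
  cells, $\approx 0.10\text{–}0.15$ at ~580 in these regimes) against the
  Spearman gate, done before the acceptance runs, not tuned afterwards.

What the generator does **not** emulate: dropout/zero-inflation beyond the
model's own zeros, gene–gene correlation except where a test programs it,
doublets, batch effects, or trajectory-inference error (pseudotime and branch
labels are taken as given — trajectory reconstruction is out of scope). A
green test therefore establishes correctness of the statistical machinery on
data generated by the assumed mechanism, not robustness to annotation error.

# Numerical choices

- KL model probabilities floored at $10^{-12}$; mixture pdf normalization is
  verified to $10^{-6}$ by quadrature in the test suite.
- BFGS with relative tolerance $10^{-8}$, at most 150 iterations per start
  for mixture fits; ties in modality selection break toward smaller $m$.
- Degenerate inputs: all-constant samples raise a degeneracy error advising
  point-mass handling; all-zero counts are unidentifiable for burst fitting
  and raise an error; undersized windows are skipped with a message in trend
  series and are an error in windowing.
- All stochastic steps take explicit integer seeds (default 0) and are
  bit-reproducible; `run_pipeline()` run twice with the same seed returns
  identical objects.

# Known limitations

- Burst size and frequency are weakly identified at window sizes below ~100
  cells; trend series on small datasets will often classify as
  `non-monotone` simply for lack of power.
- The KL fit's support renormalization conditions the model on the observed
  support; for very small windows this can mask tail mismatch.
- The marker screen's KS test treats cells as exchangeable within segments;
  pseudotime-driven drift within a segment inflates the shift statistic
  slightly.
- Only one bifurcation is modelled. Datasets with several bifurcations are
  handled by relabelling per bifurcation and running the pipeline per event.
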