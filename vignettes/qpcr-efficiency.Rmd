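---
title: "Estimating qPCR efficiency and its imprecision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating qPCR efficiency and its imprecision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcreff)
```

## The statistical model

A qPCR reaction starting from $N_0$ template molecules contains
$N_x = N_0 (1+E)^x$ amplicons after $x$ cycles, where the efficiency
$E \in (0, 1]$ is the fraction of molecules copied per cycle. If the
template is single stranded (cDNA), the first cycle synthesises the
complement, so the exponent is $x - 1$. All reactions of one assay are
read at a common fluorescence threshold; at threshold they contain the
same number of amplicons, so the fluorescence-per-amplicon constant
cancels and

$$\mathrm{Cq} = \text{const} - \frac{\log_{10} c}{\log_{10}(1+E)},$$

with $c$ the *relative* template concentration. Absolute concentrations
are never needed: `qpcreff` codes the stock as $\log_{10} c = 6$ by
default and each 10-fold dilution subtracts 1. A standard curve is the
ordinary least-squares fit of Cq on $\log_{10} c$, and

$$E = 10^{-1/\text{slope}} - 1, \qquad
  \mathrm{SE}(E) = \mathrm{SE}(\text{slope}) \cdot
  \frac{(1+E)\ln 10}{\text{slope}^2},$$

the latter by the first-order delta method (the package's tests verify it
against a finite-difference derivative). The confidence interval is
$E \pm t_{1-\alpha/2,\,n-2}\,\mathrm{SE}(E)$.

**Fitting choices.** The regression uses every individual replicate
reaction, not per-concentration means. For balanced complete designs the
slope is identical either way, but individual points give the residual
degrees of freedom ($n - 2$) on which the t interval rests. Missing Cq
values (reactions that never crossed threshold) are excluded listwise and
reported — never imputed, because silently filling or dropping them
understates exactly the scatter the analysis is meant to measure. A
non-negative fitted slope is flagged as likely inverted concentration
coding rather than raised as an error, since the arithmetic is still
well defined.

**Interval width conventions.** Imprecision is quoted as
`ci_width_pct` $= 100(\mathrm{ci_{high}} - \mathrm{ci_{low}})$,
i.e. the full interval width in efficiency percentage points. Because
both full-width and half-width conventions circulate in assay-validation
reports, the half-width is always emitted alongside.

## Replicate subsampling

How much precision do $k$ technical replicates per concentration buy?
`subsample_efficiencies()` draws, independently at each concentration,
$k$ of the available non-missing replicates without replacement, fits a
standard curve to the pooled draw, and repeats (default 1000 resamples).
Duplicate subsets across resamples are allowed — this is simple Monte
Carlo. `enumerate_all_subsets()` is the exact counterpart: one fit per
distinct combination of per-concentration subsets
($\prod_c \binom{m_c}{k}$ fits, refused above a configurable cap of
$10^6$), against which the Monte Carlo version is tested for convergence.
Concentrations with fewer than $k$ surviving replicates contribute all
they have, so dropout-affected series are handled without imputation.

Summaries report the mean, the $n-1$ sample SD, and a percentile interval
using linear interpolation between order statistics (quantile type 7,
recorded in the output). The min–max range is reported alongside, since
an extreme-value convention is also plausible for small resample sets.
Each resample records the replicate indices it drew, so any entry of the
distribution can be refitted and audited; reproducibility comes from one
master seed from which per-resample substreams are derived.

## ANCOVA across instruments or other factors

Whether efficiency is stable across a factor (instrument, plate,
reagent lot) is tested with the separate-slopes analysis of covariance

$$\mathrm{Cq}_{ij} = \delta_i + \beta_i \log_{10}(c)_{ij} + e_{ij},$$

one intercept and one slope per level, no global intercept. Terms are
tested with Type II sums of squares by explicit model comparison,
respecting marginality: the factor against the common-intercept model,
the covariate against the intercepts-only model, and the interaction —
the scientifically relevant test of slope (efficiency) heterogeneity —
against the common-slope ANCOVA model. F statistics use the full-model
residual mean square on $n - 2L$ degrees of freedom. The test suite
checks the table against `car::Anova(type = 2)` to four significant
digits and verifies the interaction SS equals the extra sum of squares
from two direct regressions; under a common-slope null the interaction
test holds its nominal 5% size in simulation. p-values are stored at full
precision and displayed as "<0.0001" below that threshold.

Per-level efficiency estimates and intervals use each level's own
independent regression (slope, SE, $n_\ell - 2$ df) — with separate
intercepts and slopes the full-model slopes coincide with the per-level
fits, and per-level residual errors avoid pooling variance across
instruments whose scatter may differ.

## The dilution-series simulator

`simulate_dilution_series()` generates Cq tables by modelling the three
mechanisms that corrupt real serial dilutions:

1. **Pipetting error**: each transferred volume is
   $v(1+\varepsilon)$, $\varepsilon \sim N(0, \mathrm{cv})$, so the
   realized dilution factor is $\text{total}/(v(1+\varepsilon))$ and
   errors compound multiplicatively down the series — the carry-over that
   makes long serial dilutions risky.
2. **Poisson sampling of the transferred aliquot**: the number of
   molecules actually carried tube-to-tube is Poisson with mean
   concentration × realized volume. Its mean scales with the transfer
   volume, which is the entire reason volume matters: at fixed dilution
   factor the *expected* copy number per reaction is volume-invariant,
   but small transfers make the realized concentration heterogeneous
   across series, and since the dropout probability $e^{-\lambda}$ is
   convex in $\lambda$, heterogeneity raises the average missing-data
   rate (Jensen's inequality). This is the mechanism behind the advantage
   of large transfer volumes.
3. **Poisson sampling of the reaction aliquot**: each reaction receives
   $m \sim \text{Poisson}(\lambda_s)$ template molecules. $m = 0$ means
   no amplification — a missing Cq. Otherwise
   $\mathrm{Cq} = [\text{ss}] + \log(N_\text{thr}/m)/\log(1+E) +
   N(0, \sigma_\text{Cq})$, where $[\text{ss}]$ is the one-cycle
   single-stranded offset (default on, as for cDNA).

Molecule counts are Poisson on expected copies rather than
hypergeometric from finite tubes, because tube totals vastly exceed
aliquot counts at every relevant step. Amplification given $m$ is
deterministic: per-cycle branching-process noise and baseline artefacts
are subsumed into the Gaussian Cq noise term rather than modelled
explicitly. Setting `poisson_sampling = FALSE` replaces counts by their
expectations — the deterministic limit in which (with zero pipette CV and
Cq noise) simulated Cq values are exactly linear and the fitted slope
recovers the generating efficiency exactly; the tests use this limit as
an anchor.

**Defaults and their rationale.** The default design mirrors common
validation practice: 10-fold dilutions, 6 concentrations (5 steps),
4 replicates (16 for sampling-error studies), true efficiency 0.95,
Cq noise SD 0.15 cycles (typical replicate scatter at high copy number),
stock at $10^6$ expected copies per reaction, threshold at $10^{10}$
amplicon copies (stock Cq ≈ 15), and a 2 µl template aliquot per
reaction. The pipette CV default of 2% is an assumption, not a measured
value: conventional air-displacement pipettes achieve roughly 1–3%
random error at single-digit microlitre volumes (ISO 8655-2 gives the
error-limit framework), and no single CV captures its volume dependence —
users comparing volumes with volume-dependent pipette quality should set
`pipette_cv` per scenario.

**What the simulator does not emulate**: fluorescence-curve shape and
baseline subtraction, reverse-transcription yield and its variability,
inhibition and matrix effects, inter-run calibration drift, or
instrument-specific Cq-calling algorithms. Passing simulation-based tests
therefore demonstrates the statistical machinery under the stated
stochastic mechanisms, not that any particular laboratory's error budget
matches the defaults.

## Fold-change propagation

Relative quantification turns a Cq difference into
$(1+E)^{\Delta\mathrm{Cq}}$, so using an assumed efficiency when the
truth differs multiplies the result by
$\left[(1+E_\text{assumed})/(1+E_\text{true})\right]^{\Delta\mathrm{Cq}}$
— exactly exponential in $\Delta$Cq. The exponent convention is
configurable (`exponent_offset = 1` for the single-stranded convention
in which $\Delta$Cq − 1 doublings separate the conditions); the default
uses $\Delta$Cq, the common practice. `fold_change_table()` tabulates the
error over user-chosen grids rather than hard-coding any particular
figure.

## Numerical and testing choices

Resampling fits use the closed-form least-squares slope on
per-concentration subset sums, vectorized over combinations — fitting
46656 six-point regressions via `lm()` would be needlessly slow; the
closed form is verified against `lm()` to $10^{-10}$. Poisson draws with
means above $10^7$ use the normal approximation to stay within integer
range; the relative error there is below $10^{-3}$ SDs. JSON reports
preserve full double precision (round-trip to $10^{-12}$); printed
reports round to two decimals.

The test suite's simulation sizes are chosen for statistical power at
reasonable cost: 500 null simulations for the 5%-size check of the
interaction test (binomial SE ≈ 1 point), 200 seeds for efficiency
recovery within ±0.02, 200 series of 16 replicates for the Poisson
dropout check (three binomial SEs), and 4000 simulated series per
transfer volume for the monotone missing-data trend, where the
Rao-Blackwellized estimator $\overline{e^{-\lambda}}$ is used instead of
raw dropout counts because it removes the binomial noise component and
resolves the small 5 µl → 10 µl difference.

## Known limitations

* The efficiency CI is first-order (delta method); for very short curves
  ($n \lesssim 8$) the nonlinearity of the slope→E transform makes the
  interval slightly asymmetric in truth, which the percentile interval
  from resampling captures but the analytic one does not.
* Weighted regression, outlier rejection and linear-range (limit of
  quantification) determination are out of scope; curves should be
  restricted to their linear range before fitting.
* The ANCOVA treats instruments as fixed levels; random-effect
  formulations and multiple-testing correction across targets are not
  provided — each target is tested separately.
* The simulator's pipette CV is volume-independent unless varied by the
  user, so it understates the real-world penalty of very small transfer
  volumes.
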