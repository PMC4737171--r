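---
title: "Digital efficiency, reaction speed, and how many devices you need"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital efficiency, reaction speed, and how many devices you need}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digilamp)
```

## The measurement problem

Isothermal amplification reactions (RT-LAMP and relatives) are usually
optimized the way qPCR is: pick the primers or conditions that reach the
fluorescence threshold fastest. That criterion silently assumes that a
faster reaction also amplifies a larger fraction of the template
molecules it is given. In a digital (partitioned) format the assumption
can be tested directly: a sample is distributed over many nanoliter
wells so that each well holds 0 or 1 template, every well that amplifies
is counted, and the fraction of loaded molecules that actually produced
signal — the **digital efficiency** — is measured separately from the
time the signal took to appear. The two can, and do, vary independently:
a condition can be slower yet amplify far more of its templates. This
package implements the statistical machinery for that style of
experiment: Poisson quantification from well counts, efficiency
comparison between conditions, replicate-number planning, time-to-positive
extraction from real-time traces, a detection/LOD model, and a stochastic
simulator that generates all of the above with known ground truth.

## Poisson quantification and its uncertainty

With $n$ wells of volume $\nu$ ml at concentration $\lambda$
molecules/ml, the number of templates per well is Poisson($\nu\lambda$),
so a well is occupied with probability $1 - e^{-\nu\lambda}$. Observing
$k$ positive wells of $n$ inverts to the most-probable-number estimate

$$\hat\lambda = -\ln(1 - k/n)\,/\,\nu,$$

whose natural-log-scale standard deviation, by binomial sampling of $k$
propagated through the estimator, is

$$\sigma = \frac{1}{\lambda\nu\sqrt{n/(e^{\nu\lambda}-1)}}.$$

```{r}
dev <- slipchip()                      # 1280 wells x 3 nl
sigma_ln_lambda(5e4, dev)              # ~0.075 at occupancy 0.15
est <- estimate_lambda(digital_count(178, 1280), dev)
est
```

Confidence intervals are lognormal, $\exp(\ln\hat\lambda \pm z\sigma)$,
with $\sigma$ evaluated at $\hat\lambda$ (plug-in). Two boundaries need
conventions. A device with zero positives reports $\hat\lambda = 0$ with
the exact binomial one-sided upper bound $-\ln(\alpha)/(n\nu)$, which
keeps blanks usable. A fully positive device is a saturation error, not
an infinite estimate: the digital regime assumes wells hold 0 or 1
template, and a saturated device simply was not in it.

Dividing $\hat\lambda$ by the concentration actually loaded gives the
digital efficiency of the condition; per-device efficiencies are
averaged per condition and normalized to a designated reference, whose
mean is treated as a fixed scale constant (its own sampling error is not
propagated — the flag `normalized` records this choice). Replicate-level
comparisons between conditions use Welch's unequal-variance t-test, with
a degenerate exact fallback when both groups have zero variance.
Efficiency standard errors reflect between-device replication by
default; within-device Poisson noise is available separately through
`sigma_ln_lambda()` and is what the planning calculus below uses.

## How many devices resolve an efficiency difference?

A relative efficiency difference $d$ (condition B amplifies a fraction
$1-d$ of what A does) is a target difference
$TD = -\ln(1-d)$ on the ln scale, where the measurement error is
approximately constant. The standardized difference is $SD = TD/\sigma$
and the minimum number of replicates per condition is

$$N = \frac{2}{SD^2}\,C_{p,\mathrm{power}},
\qquad C_{p,\mathrm{power}} = (z_{1-\alpha/2} + z_{\mathrm{power}})^2,$$

the known-variance two-sample sample-size formula; at $\alpha = 0.05$
and 95% power the constant is 12.99, conventionally quoted as 13.0.
`c_constant()` computes it from normal quantiles rather than hard-coding
the rounded value, so other $\alpha$/power pairs work unchanged.

```{r}
plan_digital_experiment(0.20, dev, 5e4, power_spec(c_constant = 13.0))
plan_multiwell_experiment(0.20, 10, 0.01, 1, power_spec(c_constant = 13.0))
```

Three 1280-well devices per condition resolve a 20% efficiency
difference; the same question asked of 10-well plates of 10 µl loaded at
about one copy per reaction needs 90 trials — 900 reactions per
condition — because with $n = 10$ wells at occupancy $\nu\lambda = 1$
the per-trial $\sigma$ is 0.41 rather than 0.075. That two-orders-of-
magnitude gap is the planning argument for doing optimization digitally.

Conventions worth stating. The "20% difference" is read multiplicatively
($E_B = 0.8\,E_A$), the only reading consistent with $SD = TD/\sigma =
2.98$ at $\sigma = 0.075$. $\sigma$ is evaluated at the reference
concentration, not the midpoint; at occupancies below 0.3 the choice
moves $N$ by under 2%. $N$ is reported raw and ceiled; planning uses the
ceiling. The test implied by the constant is a two-sided z-comparison
with $\sigma$ known from the formula — with 3 replicates per arm a
variance-estimating t-test would be far below nominal power, which is
precisely why the calculus supplies $\sigma$ analytically.
`simulate_power()` checks the chain by Monte Carlo:

```{r}
simulate_power(0.20, 3, dev, 5e4, reps = 2000, seed = 42)
```

Across seeds the empirical rate settles just below the nominal 95%
(about 94.5% at 10⁴ replicates): the
formula evaluates $\sigma$ only at the reference concentration, while
the lower-efficiency arm, having fewer positive wells, carries a
slightly larger $\sigma$ (0.083 at occupancy 0.12). The back-of-envelope
answer $N = 3$ is still the right integer; the approximation costs about
half a percentage point of power.

## Time to positive from real-time traces

Per-well fluorescence traces are called deterministically, mirroring a
manual procedure: background = mean of the first `background_frames`
(default 3) intensities; threshold = `threshold_fraction` (default 0.5)
of the background-corrected maximum; the time to positive is the
linearly interpolated first upward crossing. Two guards matter. A signal
floor (default 5 standard deviations of the background frames) keeps the
fractional rule from calling flat noisy traces positive — with only 3
background frames that noise estimate is itself noisy, so analyses that
know their noise scale should pass an explicit `signal_floor`; it is
expressed in corrected units, which together with the fractional
threshold makes calls invariant under affine intensity transforms. Only
the first upward crossing counts; later dips and re-crossings are
ignored, because amplification curves are monotone in this model.

A device's reported time to positive is the earliest positive well
**promptly confirmed by others**: the earliest $t^*$ with at least
`m_subsequent` (default 2) further wells positive within `window_min`
(default 3) minutes, ties at $t^*$ counting as simultaneous firsts.
Single-molecule start times are heterogeneous, so an isolated early well
is not representative; if no well qualifies the earliest time is
returned with an explicit fallback flag. The defaults are a
formalization of a qualitative rule ("immediately followed by a series
of signals"), chosen conservative and configurable because no numeric
rule is canonical.

## Detection probability and LOD

Poisson loading thinned by per-molecule efficiency $E$ gives the
probability that a bulk reaction with mean load $c$ copies detects
anything: $P = 1 - e^{-cE}$, hence
$\mathrm{LOD}_{95} = \ln(20)/E \approx 3/E$ copies per reaction, and the
LOD ratio of two conditions is the inverse of their efficiency ratio —
digital efficiency and analytical sensitivity are two views of one
parameter. `estimate_lod_from_series()` fits $E$ to dilution-series
counts by maximum likelihood (the one-parameter likelihood is unimodal
in $\ln E$; a bounded search with tolerance $10^{-8}$ suffices), and
refuses all-negative or all-positive series, where $E$ is not
identifiable. Copies per reaction are treated as Poisson means, not
fixed integers, matching dilution physics near one copy per reaction.

There is also a purely combinatorial speed dividend in the digital
format: if only a fraction $f$ of wells receives template, all templates
sit in that fraction of the volume, at $1/f$ times the bulk
concentration — five-fold at 20% occupancy — which is why digital
readouts come up earlier than bulk reactions of the same solution.

## The simulator and what it does (and does not) emulate

`simulate_device()` draws per-well template counts Poisson($\nu\lambda$),
gives each template an independent Bernoulli($E$) fate, assigns each
successful template a start delay `offset + Gamma(shape, scale)`
(defaults 10 min + Gamma(4, 2), i.e. delays of roughly 12–25 min,
emulating the heterogeneity of single-molecule start times), sets the
well's time to positive to its first winner, and optionally renders
logistic fluorescence curves (amplitude 100 AU over background 50 AU,
steepness 1.5 min$^{-1}$, Gaussian noise SD 1 AU, frames every 0.5 min
for 60 min). `simulate_bulk_reaction()` models winner-takes-all bulk
kinetics: the earliest successful molecule's delay plus
$\ln(c_{\mathrm{ref}}/c)/r$, with $c$ the successful-template
concentration, $c_{\mathrm{ref}} = 1/\nu$ the single-molecule-in-a-well
concentration and $r$ the growth-rate surrogate (the curve steepness).
The default loading, $5\times10^4$ molecules/ml on 1280 × 3 nl wells
(occupancy 0.15), matches the regime the uncertainty formula's worked
examples use; all randomness flows from one integer seed and scenario
manifests record every parameter.

`generate_scenario()` packages four two-condition studies:
`decoupled_fip` (same rates, efficiencies 1.0 vs 0.6), `loop_primer`
(slower rates, same efficiency), `enzyme_swap` (slower but twice as
efficient) and `null` (identical conditions). These reproduce the
qualitative phenomena — speed and fate decoupled in every direction —
with known ground truth for parameter-recovery tests.

Two honest limitations surfaced by the simulator itself. First, the
device-level first-positive time is an extreme order statistic, so it
shifts slightly (about 0.2 min here) when one condition simply has more
positive wells; with 8 devices per condition a Welch test picks that up
in roughly 15% of runs. "Same rate model" therefore does not mean
*identically distributed* first-positive times — a caveat worth
remembering when using first-positive readouts as a speed metric at very
different efficiencies. Second, in the single-rate winner-takes-all bulk
model an efficiency ratio of 0.6 shifts the bulk time deterministically
by $\ln(1/0.6)/r \approx 0.34$ min: small against the ~12 min reaction
timescale and against between-condition rate effects of minutes, but not
literally zero. Both are properties of the model, stated rather than
hidden; neither affects the efficiency axis, which recovers the
configured fates to within 0.02 at these settings.

The simulator is phenomenological on purpose: it does not model LAMP
reaction networks, primer chemistry, inhibition, chip defects,
well-loading failures, or photobleaching. Passing tests show that the
estimators and rules recover the parameters of *this* generative model;
they do not certify performance on real images or real enzymes.

## Problem sizes and reproducibility

The bundled analyses and tests run at deliberately modest sizes: 2000
simulated devices for validating the uncertainty formula (empirical SD
of $\ln\hat\lambda$ within 10% of 0.075), 5000–10000 replicate
experiments for power estimates (Monte-Carlo SE below 0.4 percentage
points), 8 devices per condition and ~50–100 seeds for scenario-level
rates, and 96-reaction × 4-level dilution series for LOD recovery. Every
script and test fixes its seeds; `scripts/acceptance.R` recomputes the
headline numbers from scratch at any seed passed on the command line.
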