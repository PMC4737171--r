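# digilamp

Statistics for digital single-molecule amplification experiments.

When an isothermal amplification reaction (e.g. RT-LAMP) is run in a
digital format — the sample partitioned over ~10³ nanoliter wells so
each well holds 0 or 1 template molecule — two properties of the
reaction become separately measurable that a bulk tube conflates:

- **speed**: the time for a well (or the device, or a bulk reaction) to
  reach its fluorescence threshold, and
- **digital efficiency**: the fraction of loaded template molecules that
  actually amplify to a detectable signal.

These can vary independently — a slower reaction can amplify far more
of its templates — so picking primers or enzymes by speed alone, qPCR
style, can select a *less* sensitive assay. `digilamp` provides the
statistical layer for running and planning such comparisons:

- **Poisson (MPN) quantification** from positive-well counts:
  λ̂ = −ln(1 − k/n)/ν with ln-scale standard deviation
  σ = 1/(λν√(n/(e^{νλ}−1))), lognormal CIs, exact handling of
  zero-count and saturated devices (`estimate_lambda()`,
  `sigma_ln_lambda()`).
- **Efficiency comparison** between reaction conditions: per-device
  efficiencies, reference normalization, Welch tests
  (`digital_efficiency()`, `normalize_efficiencies()`,
  `compare_conditions()`).
- **Replicate-number planning**: TD = −ln(1−d), SD = TD/σ,
  N = 2/SD² · C_{p,power} with C = (z_{1−α/2}+z_power)² ≈ 13.0 at
  α = 0.05 / 95% power, for digital devices and multi-molecule well
  plates, plus Monte-Carlo validation (`plan_digital_experiment()`,
  `plan_multiwell_experiment()`, `simulate_power()`).
- **Real-time trace analysis**: background correction, half-max
  thresholding, interpolated time to positive per well, and the
  first-positive-confirmed-by-a-series rule per device (`call_well()`,
  `device_time_to_positive()`, `plate_time_to_positive()`).
- **Detection & LOD**: the Poisson–Bernoulli model P(detect) = 1−e^{−cE},
  LOD95 = ln(20)/E, maximum-likelihood fits to dilution series
  (`detection_probability()`, `lod95()`, `estimate_lod_from_series()`).
- **A stochastic simulator** with explicit fate (efficiency) and rate
  (start-time) parameters, per-well fluorescence curves, winner-takes-all
  bulk reactions, and packaged two-condition scenarios with ground-truth
  manifests (`simulate_device()`, `simulate_bulk_reaction()`,
  `generate_scenario()`).

## Worked example

A 1280-well × 3 nl device shows 178 positive wells:

```r
library(digilamp)
dev <- slipchip()                       # 1280 wells x 3 nl
est <- estimate_lambda(digital_count(178, 1280), dev)
est
#> Concentration estimate: 4.991e+04 molecules/ml (178/1280 wells)
#>   95% CI [4.309e+04, 5.782e+04], sigma(ln lambda) = 0.07502
```

About 5×10⁴ molecules/ml were loaded, so this condition's digital
efficiency is ~1.0; a condition whose device shows ~110 positives would
come out near 0.6. How many devices per condition to resolve a 20%
efficiency difference with p < 0.05 at 95% power?

```r
plan_digital_experiment(0.20, dev, 5e4, power_spec(c_constant = 13.0))
#> Replicates required: N = 2.93 (use 3) at SD = 2.98 (alpha 0.05, power 0.95)
```

Three devices — because at occupancy νλ = 0.15 a single device already
pins ln λ to σ = 0.075. The same question in a well-plate format at ~1
template copy per reaction:

```r
plan_multiwell_experiment(0.20, 10, 0.01, 1, power_spec(c_constant = 13.0))
#> Multi-molecule plan: sigma/trial 0.415, SD 0.538 -> 90 trials (89.7 raw), 900 reactions per condition
```

900 reactions instead of 3 devices. Monte-Carlo check of the N = 3
claim (z-comparison with the formula's σ):

```r
simulate_power(0.20, 3, dev, 5e4, reps = 2000, seed = 42)
#> [1] 0.9275  (attributes: n_saturated 0, reps 2000, method "z")
```

## Analysis workflow

Numbered drivers under `analysis/` run the full synthetic study and
write tables under `results/`:

1. `01_simulate.R` — generate the four scenarios (same-speed /
   different-efficiency, different-speed / same-efficiency, slower-but-
   more-efficient, null) as counts, traces and dilution CSVs with
   ground-truth manifests;
2. `02_quantify.R` — well calls, MPN concentrations, efficiencies;
3. `03_compare.R` — side-by-side speed and efficiency comparisons via
   `run_pipeline()`;
4. `04_power.R` — the replicate-number table and empirical power;
5. `05_lod.R` — detection-model fits and LOD95 per condition.

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

The methods vignette (`vignettes/digital-efficiency.Rmd`) documents the
model, the conventions (multiplicative reading of "20% difference",
σ at the reference concentration, ceiling of N, known-σ z-comparison),
the trace-calling and device-timing rules, and what the simulator does
and does not emulate.

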