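# apcpulse

Tools for studying the transient, partial inactivation of the APC/C
ubiquitin ligase (APC/C<sup>CDH1</sup>) during cell-cycle entry from
quiescence, and for analysing the single-cell biosensor traces in which it
is observed.

Cells leaving quiescence need APC/C<sup>CDH1</sup> active (to keep origin
licensing permissive) and simultaneously need a glycolytic burst that the
same ligase suppresses by degrading glycolytic enzymes. The resolution is
an **incoherent feedforward loop**: mitogens rapidly activate mTOR, which
phosphorylates the APC/C coactivator CDH1 and partially inactivates the
ligase, while delayed protein-phosphatase activity removes the
phosphorylation hours later and restores full activity. The result is a
pulse — a dip in APC/C activity and a matching transient accumulation of
APC/C substrates such as geminin.

`apcpulse` provides, for audiences working on cell-cycle signalling
dynamics or single-cell live-imaging analysis:

* **The IFFL model** — five ODEs with Hill-function drives,

  τ<sub>X</sub> dX/dt = drive<sub>X</sub>(S, upstream) − X,

  for mTOR, phosphatase (PP), phosphorylated CDH1, APC/C activity, and
  substrate level, integrated with LSODA piecewise between drive
  discontinuities; perturbation scenarios for rapamycin, phosphatase
  inhibition and non-phosphorylatable CDH1 (T129A); closed-form steady
  states; pulse metrics.
* **A synthetic single-cell trace generator** emulating live-cell
  degron-reporter and CDK2-activity recordings: 12-min sampling, lognormal
  cell-to-cell rate variability, multiplicative measurement noise,
  per-cell ground-truth metadata, and an exact degron-reporter mechanics
  mode (constant synthesis, APC/C-proportional degradation) that supports
  MG132 proteasome-inhibition experiments.
* **Trace analytics** — windowed least-squares slope fits, the MG132
  slope-ratio percent-inactivation statistic
  `100 * (1 − slope_pre / slope_post)`, transient/sustained trace
  classification, population fractions with control normalisation,
  pointwise median traces, divergence-time estimation, and CDK2-based
  cycling/quiescent classification.
* **A reproducible experiment runner** (`run_experiment()` plus a thin
  CLI in `inst/scripts/apcpulse_suite.R`) chaining model → generator →
  analytics for named scenario suites from a YAML configuration, with
  byte-reproducible CSV outputs and a JSON manifest.

## Worked example

```r
library(apcpulse)

# 1. Simulate the default scenario: published constants, S = 3 applied at
#    t = 0, phosphatase onset at 4 h.
traj <- iffl_simulate(t_end = 12, output_dt = 0.05)
pulse_metrics(traj, "apc", "minimum")[c("extremum_value", "extremum_time",
                                        "recovery_value")]
#> $extremum_value
#> [1] 0.515328
#> $extremum_time
#> [1] 4.05
#> $recovery_value
#> [1] 0.9604073
```

APC/C activity dips to 0.515 at 4.05 h — a *partial* inactivation, unlike
the switch-like shutdown at the G1/S transition — and recovers to 0.96 by
12 h.

```r
# 2. Synthetic reporter population with MG132 at 5 h, then the slope-ratio
#    percent-inactivation statistic per cell (accumulation window 1-5 h).
rp  <- reporter_parameters(mg132_time = 5)
cfg <- population_config(n_cells = 200, noise_sd = 0.05, duration = 12,
                         seed = 1, generator_mode = "reporter_mechanics")
pop <- generate_population(rp = rp, cfg = cfg)
est <- analyze_cells(pop, mg132_time = 5)
median(est$percent_inactivation)
#> 81.6
```

Under the model's activity trace, reporter accumulation in the 1–5 h
window runs at about 18% of the post-MG132 (synthesis-only) rate, giving a
median percent-inactivation statistic of 81.6% for this population.

```r
# 3. Control vs phosphatase-inhibitor populations: classification and
#    divergence timing of the median traces.
ctrl <- generate_population(cfg = population_config(n_cells = 200, seed = 1))
ppi  <- generate_population(
  protocol = stimulus_protocol(phosphatase_inhibitor_time = 0),
  cfg = population_config(n_cells = 200, seed = 2, scenario = "ppi"))
fraction_transient(analyze_cells(ctrl)$label)  # 1.00
fraction_transient(analyze_cells(ppi)$label)   # 0.00

mc <- median_trace(ctrl); mp <- median_trace(ppi)
divergence_time(mc$time_h, mc$value, mp$value,
                epsilon = 0.05 * diff(range(mc$value)),
                sustain_points = 3)$divergence_time
#> 4.6
```

Every control cell shows a transient substrate pulse, every
phosphatase-inhibited cell a sustained rise, and the two median traces
peel apart just after the 4-h phosphatase onset (detection lags onset
because the perturbation propagates through the pCDH1 → APC/C → substrate
cascade).

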