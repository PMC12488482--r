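---
title: "Modelling transient APC/C inactivation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transient APC/C inactivation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcpulse)
```

## The biological problem

A quiescent cell re-entering the cell cycle faces two requirements that are
mutually exclusive at face value. The ubiquitin ligase APC/C^CDH1^ must stay
active through G1 to keep origin-licensing conditions permissive, yet the
same ligase degrades rate-limiting glycolytic enzymes (notably PFKFB3),
while cell-cycle entry demands a burst of glycolysis. The resolution is
temporal: after mitogen stimulation the APC/C is *partially and
transiently* inactivated — mTORC1 rapidly phosphorylates the coactivator
CDH1, weakening its engagement with the core complex, and delayed protein
phosphatase activity later removes the phosphorylation and restores full
activity. Fast activation of an inhibitor plus delayed activation of its
remover is an incoherent feedforward loop (IFFL), the canonical
pulse-generating motif.

`apcpulse` packages three things: a five-variable ODE model of this loop,
a synthetic single-cell biosensor trace generator emulating live-cell
imaging of a geminin-degron APC/C reporter and a CDK2 activity reporter,
and the trace analytics used on such recordings.

## The model

Five dimensionless variables — mTOR activity, protein phosphatase activity
(PP), phosphorylated CDH1 (pCDH1), APC/C activity, and the APC/C-substrate
level (geminin, standing in for any degron reporter) — each relax
first-order towards a Hill-function drive:

$$
\begin{aligned}
\tau_{\mathrm{mTOR}}\,\dot{M} &= \frac{S^{n_1}}{k_1^{n_1}+S^{n_1}} - M \\
\tau_{\mathrm{PP}}\,\dot{P} &= \frac{S^{n_2}}{k_2^{n_2}+S^{n_2}}\,
  \mathbf{1}[t \ge t_{\mathrm{PP}}] - P \\
\tau_{\mathrm{pCDH1}}\,\dot{C} &= \frac{M^{n_3}}{k_3^{n_3}+M^{n_3}}\cdot
  \frac{k_4^{n_4}}{k_4^{n_4}+P^{n_4}} - C \\
\tau_{\mathrm{APC}}\,\dot{A} &= \frac{k_5^{n_5}}{k_5^{n_5}+C^{n_5}} - A \\
\tau_{\mathrm{GEM}}\,\dot{G} &= \frac{k_6^{n_6}}{k_6^{n_6}+A^{n_6}} - G
\end{aligned}
$$

Every drive is a Hill fraction in $[0,1]$, so the dynamics map the unit
hypercube into itself; boundedness is a structural property, not a solver
accident. The defaults of `kinetic_parameters()` are the published
constants ($k_1{=}0.2, n_1{=}1, \tau_{\mathrm{mTOR}}{=}0.5$; $k_2{=}0.2,
n_2{=}1, \tau_{\mathrm{PP}}{=}0.5$; $k_3{=}0.3, n_3{=}1,
\tau_{\mathrm{pCDH1}}{=}0.5$; $k_4{=}0.2, n_4{=}2, \tau_{\mathrm{APC}}{=}0.5$;
$k_5{=}0.8, n_5{=}1, \tau_{\mathrm{GEM}}{=}0.3$; $k_6{=}0.4, n_6{=}3$),
with mitogen level $S = 3$ applied at $t = 0$ and the PP drive held at zero
until $t_{\mathrm{PP}} = 4$ h.

**Time units.** The model constants carry no explicit time unit; we use
hours throughout. This is forced by internal consistency:
a 4-h phosphatase delay combined with sub-hour relaxation constants is
exactly what produces the observed 1–6 h inactivation pulse.

**Initial conditions.** The published initial state is $(M, P, C, A, G) =
(0, 0, 0, 1, 0)$ and `initial_state()` returns exactly that, even though
$G = 0$ is not the quiescent fixed point of the substrate equation (which
is $k_6^{n_6}/(k_6^{n_6}+1) \approx 0.0602$). The small initial transient
in $G$ this causes relaxes with $\tau_{\mathrm{GEM}} = 0.3$ h and is gone
well before the analysis windows open.

**Perturbation scenarios** (`stimulus_protocol()`):

* *Rapamycin* zeroes the mTOR **drive** from the addition time; existing
  mTOR activity then decays with $\tau_{\mathrm{mTOR}}$. We model the drug
  as blocking kinase activation rather than erasing existing activity;
  `rapamycin_mode = "clamp"` exposes the instantaneous alternative for
  sensitivity checks.
* *Phosphatase inhibitor* zeroes the PP drive from the addition time. With
  addition at $t = 0$ this leaves PP identically zero, so the inhibited
  trajectory coincides with the control until the 4-h onset — the
  structural fact behind divergence-time estimation.
* *CDH1 phosphorylation block* (the dominant-negative, non-phosphorylatable
  T129A scenario) forces the pCDH1 drive to zero for all time, so the APC/C
  never dips.
* The phosphomimetic T129D co-expression condition is deliberately **not**
  modelled: no model term is published for it, and experimentally it does
  not alter the transient.

**Numerics.** The stiffness-switching LSODA method (via \pkg{deSolve})
integrates each ODE system at `rtol = 1e-8`, `atol = 1e-10`. All drive
switches are step discontinuities; the integrator is run piecewise between
switch times with the drive regime frozen per segment, so the adaptive
solver never steps across a discontinuity. Output grids are 0.05 h for
model-only runs and 0.2 h (the 12-min imaging cadence) when feeding the
trace generator. The test suite holds the adaptive solution to within
$10^{-4}$ sup-norm of an independently coded fixed-step fourth-order
Runge–Kutta integration at $\Delta t = 10^{-4}$ h across the full scenario
matrix; because the cascade admits a closed-form fixed point by forward
substitution (`iffl_steady_state()`), long integrations are also checked
against it to $10^{-6}$.

With the defaults the model produces the characteristic IFFL signature:
APC/C activity dips to a unique interior minimum (about 0.515 near 4.1 h,
i.e. partial, not switch-like, inactivation), recovers above 0.95 by 12 h,
and the substrate pulses to about 0.317 shortly after 4 h before decaying.

## The synthetic trace generator

The generator stands in for segmented, background-corrected single-cell
fluorescence traces: per-cell time series on a common 0.2-h grid (images
every 12 min), over 24 h by default, with cell-to-cell parameter
variability and measurement noise. It emulates *traces*, not images —
segmentation, tracking errors, photobleaching, background structure and
mitosis/lineage effects are out of scope, so recovery results on synthetic
data bound what the analytics can do under idealised acquisition, not
under all real-world failure modes.

Two generator modes exist because the model's substrate variable and the
physical biosensor are not the same object:

* `model_direct` emits the model substrate (geminin) series scaled per
  cell. It is the right mode for pulse-shape, classification and
  divergence questions, but the published substrate equation has no term
  for proteasome inhibition, so requesting MG132 here is a configuration
  error rather than a silent approximation.
* `reporter_mechanics` integrates the reporter balance
  $\dot{R} = s - d\,A(t)\,R$ — constant synthesis $s$ from a constitutive
  promoter, degradation proportional to current APC/C activity — exactly
  (piecewise-constant $A$ between grid points has an exponential
  closed-form update). MG132 sets the degradation term to zero from the
  addition time, making the post-MG132 accumulation slope equal $s$
  exactly; this is the mechanism the slope-ratio statistic exploits.

**Heterogeneity and noise.** Per-cell rates are scaled by lognormal
multipliers with unit mean and coefficient of variation 0.15 (fluorescence
scale factors are positive and right-skewed; no variability model is
published, so this is the package's choice). Measurement noise is
multiplicative Gaussian with SD 5% of signal, truncated at zero — again a
package default in the range typical of nuclear-mask fluorescence
quantification. Both are configurable.

**Reproducibility.** One root seed; each cell draws from a substream
seeded deterministically from (root seed, cell index), so enlarging a
population never reshuffles earlier cells, and identical (config, seed)
reproduces trace tables byte-for-byte.

**CDK2 traces** are phenomenological: quiescent cells sit at activity 0.5;
cycling cells ramp as $q + (p-q)(1 - e^{-r(t - t_0)})$ towards a plateau
of 1.5, with onset drawn from a clamped normal (mean 6 h, SD 2 h) and rate
1/h. No reference classification pipeline is available to emulate, so the
shape encodes only the qualitative distinction the classifier needs: persistent
low activity versus a sustained rise.

## Trace analytics

All windows are half-open $[t_0, t_1)$ so adjacent windows partition the
grid.

* **Slope fits** (`fit_slope()`) are ordinary least squares on in-window
  samples; the accumulation slope of a constitutively expressed degron
  reporter reads out relative APC/C activity.
* **Percent inactivation** (`percent_inactivation()`) is
  $100\,(1 - s_{\mathrm{pre}}/s_{\mathrm{post}})$, comparing the
  accumulation slope in the default window 1–5 h after stimulation with
  the post-MG132 slope (complete inhibition reference). The source text
  fits "between 1 and 5 h" while a figure legend describes accumulation
  "between 1 and 6 h"; we adopt $[1, 5)$ as the fit window and read the
  1–6 h span as the extent of the pulse, not the fit range — the window is
  an explicit argument, so the alternative is one keystroke away. The
  post window is not published; we start it 0.5 h after MG132 addition
  (equilibration gap) and span 2 h. The statistic is computed per cell
  (paired slopes within the same cell); population summaries take medians
  afterwards.
* **Transient/sustained classification** (`classify_trace()`) smooths with
  a 5-sample moving median, then requires a rise of at least
  `min_prominence` above the starting baseline (default: 3× the median
  absolute deviation of the first differences, a robust per-trace noise
  scale); a prominent interior peak whose terminal value has decayed below
  baseline + 0.5 × prominence is *transient*, a prominent non-decaying
  trace is *sustained*, anything below prominence is *none*. The
  published criteria live in unpublished analysis scripts; these defaults
  are documented, configurable choices validated against generator ground
  truth.
* **Median traces** use the lower of the two middle values at even counts,
  so the median is always an observed value and bit-reproducible.
* **Divergence time** (`divergence_time()`) is the earliest grid time at
  which two aligned median traces differ by at least $\varepsilon$
  (default 5% of the control dynamic range) for 3 consecutive samples.
  Estimated divergence necessarily lags the configured phosphatase onset
  slightly, because the perturbation propagates through the
  pCDH1 → APC/C → substrate cascade before it is visible in the reporter.
* **Cycling classification** (`classify_cdk2()`) calls a cell cycling when
  activity holds at or above threshold (default 1.0, midway between the
  generator's quiescent level and plateau) for 3 consecutive samples.

No hypothesis-testing machinery is attached: the package reports
estimates and fractions; inference across experimental replicates is out
of scope.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: Hill
algebra against hand-computed values; the adaptive solver against the
fixed-step Runge–Kutta reference and against closed forms in decoupled
regimes; fixed points against 200-h integrations; the reporter mechanics
against linear-ODE closed forms; generator moments against lognormal and
binomial calculations; and the estimators against generator ground truth.
Estimator-recovery checks use populations of 200 cells (500 for the CDK2
mixture) at the default variability (CV 0.15) and noise (5%) — large
enough that binomial fluctuations are small against the stated margins,
small enough that the whole suite runs in about a minute. The same
recovery quantities are recomputed end to end by `scripts/acceptance.R`.

## Known limitations

* The model keeps the mTOR drive constant after stimulation; a slight
  late increase in mTOR activity reported alongside the phosphatase
  mechanism is not modelled, so any co-regulation through transient mTOR
  kinetics is outside the model class.
* Parameters are fixed at their published values; no fitting to
  experimental traces is provided.
* The generator's noise model (multiplicative Gaussian) and heterogeneity
  model (lognormal rate scaling) are idealisations; classifier accuracy on
  real traces with tracking artefacts will be lower than on synthetic
  data.
* The deterministic model has no intrinsic stochasticity (no
  Langevin/Gillespie variant); cell-to-cell variability enters only
  through parameter scaling and measurement noise.
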