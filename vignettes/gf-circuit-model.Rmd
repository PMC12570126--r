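---
title: "The GF circuit model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GF circuit model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfsynapse)
```

## The model

The *Drosophila* Giant Fiber (GF) drives the jump motoneuron (TTMn) through a
mixed electrochemical synapse whose electrical component is built from
shaking-B innexin gap junctions. `gfsynapse` models this pathway as four
Hodgkin–Huxley compartments in a chain: compartment 0 receives the stimulus,
compartments 0–1 and 1–2 are coupled by a symmetric axial conductance
(representing axial spread along the GF axon), and the 2→3 link is the mixed
synapse onto the postsynaptic compartment.

Each compartment obeys

$$C_m \frac{dV}{dt} = -(I_{Na} + I_K + I_L + I_{syn}) + I_{stim},$$

with gating variables $x = n, m, h$ following
$dx/dt = (x_\infty(V) - x)/\tau_x(V)$, Boltzmann steady states
$x_\infty(V) = 1/(1+e^{(V_{1/2}-V)/k})$ at $(V_{1/2}, k)$ = (−53, 15) for
$n$, (−40, 15) for $m$, (−62, −7) for $h$, and Gaussian-bell time constants
$\tau_n = 1.1 + 4.7\,e^{-((-79-V)/50)^2}$,
$\tau_m = 0.04 + 0.46\,e^{-((-38-V)/30)^2}$,
$\tau_h = 1.2 + 7.4\,e^{-((-67-V)/20)^2}$ (ms). Reversal potentials are
+65 mV (Na), −74 mV (K) and −85 mV (leak).

The chemical synaptic current is $I_{chem} = g_{syn}\, s\,(V_{post}-V_{syn})$
with $V_{syn} = 0$ mV (excitatory) and gate dynamics

$$\frac{ds}{dt} = \frac{1+\tanh(V_{pre}/4)}{2}\cdot\frac{1-s}{\tau_{rise}} -
\frac{s}{\tau_{decay}},$$

$\tau_{rise} = 0.1$ ms, $\tau_{decay} = 3$ ms, $g_{syn} = 0.1$. The
electrical current is ohmic with the gate fully open,
$I_{gap} = g_{gap}(V_{post}-V_{pre})$ applied to the postsynaptic side and
its negative to the presynaptic side. Biologically the GF junction
rectifies; the model form is ohmic, and a rectified mode
(`gf_circuit(rectified = TRUE)`) is provided but off by default because the
ohmic form is what the model equations state.

### The occupancy → conductance sigmoid

The link between anatomy and physiology is the map from the percentage $p$
of presynaptic terminal volume occupied by gap-junction label to the
coupling conductance:

$$g_{gap}(p) = L_{min} + \frac{L_{max}-L_{min}}{1+e^{-k(p-x_0)}},$$

with two exact overrides: $g_{gap}(0) = 0$ (no junctions, no electrical
coupling — without this override the sigmoid would leak a small conductance
at zero anatomy) and $g_{gap}(p) = L_{max}$ for $p > 10\%$ (saturation). At
exactly $p = 10\%$ the sigmoid value is used: the saturation override is a
strict inequality by a literal reading of the model description.

## Choices where the model description is silent

Several constants needed for a working model are not published. They are
declared here once and shipped as package defaults; all are configurable.

* **Ionic current forms.** The canonical $m^3h$ (Na) and $n^4$ (K) exponents
  with a linear leak. Only the gating curves, time constants and reversal
  potentials are published; the exponents follow the standard
  Hodgkin–Huxley formalism that conductance-based GF models use.
* **Maximal conductances and capacitance** (`membrane_params()`): $g_{Na} =
  120$, $g_K = 36$, $C_m = 1$, $g_L = 1$ (model units). The first three are
  the textbook squid-axon ratios. The leak is larger than the textbook 0.3
  because the shallow Boltzmann activation curves above produce a sizeable
  sodium window current: with $g_L = 0.3$ the only stable equilibrium is
  depolarized (≈ −51 mV) with sodium inactivated, and the model cannot
  spike. $g_L = 1$ restores a hyperpolarized rest (−81.5 mV, near the leak
  reversal) and robust spiking. `resting_state()` deliberately selects the
  most hyperpolarized equilibrium, since the system admits more than one.
* **Axial coupling** $g_{axial} = 2$, **pulse amplitude** 80, **pulse width**
  0.5 ms, and the sigmoid constants $L_{min} = 0.01$, $L_{max} = 0.6$,
  $k = 0.9$, $x_0 = 5$ (%): produced by the package's own calibration search
  (`gf_calibrate()`), which scans a deterministic grid and returns the first
  configuration for which the control-occupancy regime (9.04 %) meets the
  wild-type physiological criteria — mean single-pulse latency < 1.00 ms and
  ≥ 90 % following of a 10-stimulus 100 Hz train — while 1 % occupancy
  (the gap-junction-null regime) is substantially degraded. The shipped
  defaults are the first entries of the default grid, so
  `gf_calibrate()` re-selects them; the self-consistency is tested.
* **Stimulus noise.** Zero-mean Gaussian noise with SD 1 (model units) added
  independently at every time sample of the injected current. The effective
  strength of "unit variance" relative to the pulse amplitude is not
  determined by the model description; it is treated as a free knob with the
  literal default. At the default `dt` this noise perturbs latency only
  mildly, so run-to-run variability of the model is far smaller than the
  biological variability across terminals.

## Numerical choices

* **Integration** is forward Euler, the method the source model prescribes.
  The default step is `dt = 0.01` ms. A 1 ms step is unstable here —
  $\tau_m$ bottoms out at 0.04 ms — so the package reads the published
  "10 ms" and "100 ms" figures as protocol durations (single-pulse and train
  protocols respectively), not step sizes, and ships `dt` as a configurable
  parameter with a convergence test: halving `dt` moves the noise-free
  latency by < 2 %.
* **Spike detection**: upward crossing of 0 mV with a 2 ms refractory
  window; unambiguous for full-height spikes and configurable in
  `gf_circuit()`.
* **Latency** is the compartment-3 peak time minus the compartment-0 peak
  time within the first-stimulus window (onset to one inter-stimulus
  interval). The "peak" is the global maximum on the time grid; on exact
  ties the earliest sample wins. If compartment 3 never spikes in the
  window, latency is `NA` (a transmission failure, encoded as an empty CSV
  field plus a `responded` flag).
* **Response frequency**: a stimulus counts as answered if at least one
  compartment-3 spike falls within one inter-stimulus interval after its
  onset, at most one response per onset; reported as a percentage of
  onsets. The default train protocol simulates one 10-stimulus train per
  run and repeats runs with different child seeds (the experimental
  protocol's repeated trains); whether responses are scored per train or
  pooled is not specified in the source description, and per-run scoring
  with across-run averaging was chosen.
* **Divergence** (non-finite state) aborts with the compartment index and
  simulation time, rather than returning garbage.
* **Seeding.** Every stochastic stage takes a seed; one master seed fans out
  as `(master + 104729·stream + 1299709·index) mod (2³¹−1)` so any child run
  can be reproduced in isolation. Seeded paths restore the caller's RNG
  state on exit.

## The 2D two-sample KS test

Genotypes are compared on paired measures — (latency, GJ%) and (following,
GJ%) — with the two-dimensional two-sample Kolmogorov–Smirnov test. For
origins placed at each data point, the four open-quadrant fractions of both
samples are compared; $D$ is the mean of the two maxima obtained with
origins running over each sample (the sample-point variant; the
all-grid-points variant is quadratically more expensive and the choice is
logged here). Points exactly on a dividing line are excluded from quadrant
counts: the tie rule must be fixed for the brute-force oracle equivalence
tested in the suite, and with continuous data ties are measure-zero.

Two p-value routes are provided:

* **Analytic**: $p = Q_{KS}(\lambda)$ with $\lambda = D\sqrt{n_{eff}}\,/\,
  (1 + \sqrt{1-\bar r^2}(0.25 - 0.75/\sqrt{n_{eff}}))$,
  $n_{eff} = n_1 n_2/(n_1+n_2)$, $\bar r$ the mean Pearson correlation of
  the two samples. Like all approximations of this family it is accurate in
  the tail (small $p$, the regime where decisions are made) and
  conservative-to-rough in the body of the distribution; the suite checks
  tail agreement with the permutation route.
* **Permutation**: label permutation of the pooled sample with the add-one
  estimator $(1 + \#\{D^{perm} \ge D^{obs}\})/(n_{perm}+1)$, seeded.

The analytic route is the default (standard practice for this test);
each comparison is reported unadjusted, mirroring the separate-independent-
tests design, with $\alpha = 0.05$.

## The synthetic data generator

`default_genotype_table()` carries twelve study groups with per-genotype
mean/SD/n of the three per-terminal measures. `generate_terminals()` draws
(latency, following, GJ%) from a correlated trivariate Gaussian, truncates
latency and GJ% at zero (rejection sampling) and clamps following frequency
into [0, 100] so that wild-type-like groups pile mass at 100 % — the
ceiling effect visible in real following-frequency data. The fraction of
altered draws is recorded as an attribute.

Declared assumptions, configurable per `genotype_spec()`:

* **Correlations.** Lower occupancy goes with longer latency and lower
  following; the magnitudes are not published. Defaults:
  $\rho_{lat,gj} = -0.5$, $\rho_{freq,gj} = +0.5$, and (needed to complete
  the matrix) $\rho_{lat,freq} = -0.5$, which matches the sign logic and
  keeps the correlation matrix positive definite. Infeasible user matrices
  are rejected.
* **Unpublished cells.** GJ% was never published for the full-length rescue
  and intracellular-domain rescue groups, nor physiology for the wild-type
  and ablation control groups; those entries are stand-ins chosen to match
  each group's described phenotype and are flagged `source = "assumed"` or
  `"mixed"` in the table. The gap-junction-null ablation group uses ~1 %
  occupancy, the published lower bound for that mutant.
* **Bilateral terminals** occur in LOF-background genotypes at roughly the
  described phenotype frequencies (≈ 0.45 for LOF backgrounds, ≈ 0.8 for
  the constructs with frequent bilateral terminals, 1.0 for ablation-induced
  bilaterals, 0 for controls). The phenotype class labels records but does
  not shift the generating distributions, consistent with the multivariate
  null result between wild-type-appearing and bilateral terminals.
* **No fly-level clustering.** Left/right terminals of one fly are drawn
  independently (each terminal is one statistical unit). Any real fly-level
  random effect is unknowable from summary statistics and omitted.

What passing tests show — and do not show. The generator reproduces
published summary moments and correlation signs under a Gaussian copula; it
does not reproduce raw-data features such as skewness, floor effects in
latency, fly-level pairing, or measurement error structure. Pipeline results
on synthetic data therefore validate the machinery and the qualitative
comparison structure, not the exact published p-values, which derive from
unreleased raw measurements.

## Problem sizes

The test suite and the acceptance script run at desk scale by design: 10
seeded runs per protocol for the physiological criteria, single-repetition
noise-free sweeps for monotonicity properties, 1,000 null replicates with
199 permutations each for the type-I-error calibration of the permutation
test, 10⁴ permutations for the analytic-vs-permutation tail comparison, and
10⁴ terminals for moment-recovery checks.

## Known limitations

* The four identical compartments are a functional abstraction, not a
  morphological reconstruction; bilateral-terminal geometries would need
  subcompartments with their own occupancy, which the structure supports in
  principle but does not implement.
* Calcium currents, adaptation and temperature effects are absent.
* The analytic KS tail approximation should not be trusted for large
  p-values; use the permutation route when the decision is not already in
  the tail.
* Model units for conductance/current are dimensionless; only voltages and
  times are physical. Quantitative conductance values therefore transfer to
  other models only through the calibration criteria, not unit-for-unit.
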