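# gfsynapse

Biophysical simulation and statistics for the *Drosophila* Giant Fiber (GF)
escape circuit. The GF makes a **mixed electrochemical synapse** onto the
tergotrochanteral (jump) motoneuron (TTMn): an acetylcholine-releasing
chemical component plus an electrical component built from shaking-B innexin
gap junctions. Mutations that deplete presynaptic gap junctions lengthen the
GF→TTMn response latency and degrade the circuit's ability to follow 100 Hz
stimulation. `gfsynapse` is for modelers and physiologists who want to ask,
quantitatively: *how much of the circuit's performance is explained by how
much gap junction the terminal carries?*

The package provides:

1. **A four-compartment Hodgkin–Huxley model** of the GF→TTMn pathway.
   Each compartment follows
   `C_m dV/dt = −(I_Na + I_K + I_L + I_syn) + I_stim`, with
   `I_Na = g_Na m³h (V − E_Na)`, `I_K = g_K n⁴ (V − E_K)`,
   `I_L = g_L (V − E_L)` and first-order gating
   `dx/dt = (x_∞(V) − x)/τ_x(V)` for `x = n, m, h`, where
   `x_∞(V) = 1/(1 + exp((V_½ − V)/k))` and the time constants are Gaussian
   bells of voltage. A stimulus (rectangular pulses plus per-sample Gaussian
   noise) enters compartment 0; compartments 0–1–2 are coupled axially; the
   2→3 link is the mixed synapse.
2. **The occupancy → conductance sigmoid.** The electrical coupling
   conductance is derived from the percentage `p` of terminal volume occupied
   by gap-junction label:
   `g_gap(p) = L_min + (L_max − L_min)/(1 + exp(−k(p − x₀)))`, with
   `g_gap = 0` exactly at `p = 0` and `g_gap = L_max` exactly for `p > 10 %`.
3. **A 2D two-sample Kolmogorov–Smirnov test** (quadrant statistic with
   origins at the sample points, analytic tail approximation and seeded
   permutation p-value) for comparing paired (latency, GJ%) or
   (following, GJ%) distributions between genotypes.
4. **A synthetic per-terminal data generator** parameterized by published
   per-genotype summary statistics (correlated trivariate Gaussian with
   truncation/clamping), so the whole comparison pipeline runs offline.

## Worked example

Simulate a *frazzled* loss-of-function-like terminal (5.31 % occupancy) and
compare occupancy levels:

```r
library(gfsynapse)

circ <- gf_circuit(occupancy = 5.31)
run_circuit(circ, single_pulse_spec(seed = 1))
#> GF circuit simulation: 10 ms at dt = 0.01 ms, 1 stimuli
#>   spikes per compartment: 1/1/1/1
#>   latency: 1.08 ms   response: 100%

genotype_sweep(c(9.04, 5.31, 1), n_reps = 3, seed = 1)
#>   p_pct latency_ms_mean latency_ms_sd response_pct_mean response_pct_sd ...
#> 1  9.04            0.89       0.00000               100               0
#> 2  5.31            1.08       0.00577               100               0
#> 3  1.00            2.39       0.00000                70               0
```

At control-level occupancy (9.04 %) the model is wild-type: 0.89 ms latency
(the wild-type criterion is < 1.00 ms) and 100 % following of a 100 Hz train
(criterion ≥ 90 %). At the LOF occupancy the latency lengthens to ~1.1 ms,
and with gap junctions nearly absent (1 %) transmission is slow (2.4 ms,
carried by the chemical component alone) and drops stimuli (70 % following).

Generate synthetic per-terminal data for all twelve study groups and run the
genotype comparison table (reference group: *frazzled* LOF):

```r
rec <- generate_all_terminals(seed = 1)
table1_comparisons(rec)[1:3, c("genotype", "n", "p_lat_gj", "sig_lat_gj")]
#>          genotype  n p_lat_gj sig_lat_gj
#> 1 control_sibling 16 3.83e-06       TRUE
#> 2    UAS_Frazzled 38 6.30e-02      FALSE
#> 3      UAS_FraICD 23 7.57e-08       TRUE
```

Each row tests the joint (latency, GJ%) distribution of one genotype against
the LOF reference with the 2D KS test; `sig_*` flags significance at
α = 0.05.

A thin command-line wrapper over the same pipeline ships at
`system.file("cli", "gf-pipeline.R", package = "gfsynapse")` with verbs
`simulate | sweep | generate | compare | calibrate`.

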