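#' Chemical synapse parameters
#'
#' The transmitter-gated component of the mixed GF-TTMn synapse. The gate `s`
#' (fraction of open postsynaptic channels) relaxes with rise and decay time
#' constants, and the current is \eqn{I_{chem} = g_{syn}\, s\, (V_{post} - V_{syn})}.
#'
#' @param g_syn maximum synaptic conductance (model units, >= 0); default 0.1.
#' @param v_syn synaptic reversal potential (mV); 0 mV, an excitatory synapse.
#' @param tau_rise,tau_decay activation / deactivation time constants (ms, > 0);
#'   defaults 0.1 and 3 ms.
#' @return An object of class `"chem_synapse_params"`.
#' @export
chem_synapse_params <- function(g_syn = 0.1, v_syn = 0, tau_rise = 0.1, tau_decay = 3) {
  stopifnot(g_syn >= 0, tau_rise > 0, tau_decay > 0)
  structure(list(g_syn = g_syn, v_syn = v_syn,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "chem_synapse_params")
}

#' Presynaptic drive of the chemical gate
#'
#' \eqn{(1 + \tanh(V_{pre}/4)) / 2}: a smooth 0-1 switch on the presynaptic
#' membrane potential that turns the gate on during a presynaptic spike.
#'
#' @param v_pre presynaptic membrane potential (mV); vectorized.
#' @return Drive in (0, 1).
#' @export
chem_gate_drive <- function(v_pre) {
  (1 + tanh(v_pre / 4)) / 2
}

#' Time derivative of the chemical gate
#'
#' \eqn{ds/dt = drive(V_{pre})\,(1 - s)/\tau_{rise} - s/\tau_{decay}}. Both
#' boundary derivatives point inward, so trajectories started in \[0, 1\]
#' stay there for any bounded presynaptic voltage.
#'
#' @param s gate value in \[0, 1\].
#' @param v_pre presynaptic membrane potential (mV).
#' @param params a [chem_synapse_params()].
#' @return Rate of change (per ms).
#' @export
chem_gate_derivative <- function(s, v_pre, params) {
  chem_gate_drive(v_pre) * (1 - s) / params$tau_rise - s / params$tau_decay
}

#' Chemical synaptic current
#'
#' @param s gate value in \[0, 1\].
#' @param v_post postsynaptic membrane potential (mV).
#' @param params a [chem_synapse_params()].
#' @return Current (model units; negative = depolarizing for `v_post < v_syn`).
#' @export
chem_current <- function(s, v_post, params) {
  params$g_syn * s * (v_post - params$v_syn)
}

#' Occupancy-to-conductance map parameters
#'
#' Parameters of the sigmoid that converts the percentage of presynaptic
#' terminal volume occupied by gap-junction protein into an electrical coupling
#' conductance (see [occupancy_to_conductance()]). Conductance bounds follow
#' the age-related gap-junction loss literature adopted by the circuit model;
#' the shipped values were set by [gf_calibrate()] so that control-level
#' occupancy (~9-10%) meets the wild-type latency and following criteria while
#' ~1% occupancy gives a weak response.
#'
#' @param l_min,l_max minimum / maximum coupling conductance (model units,
#'   `0 <= l_min <= l_max`).
#' @param k_sig sigmoid steepness (per % occupancy, > 0).
#' @param x0 sigmoid midpoint (% occupancy, in (0, p_sat)).
#' @param p_sat saturation threshold (%): occupancies strictly above it map to
#'   `l_max` exactly; default 10.
#' @return An object of class `"gap_map_params"`.
#' @export
gap_map_params <- function(l_min = 0.01, l_max = 0.6, k_sig = 0.9, x0 = 5, p_sat = 10) {
  stopifnot(l_min >= 0, l_max >= l_min, k_sig > 0, x0 > 0, x0 < p_sat)
  structure(list(l_min = l_min, l_max = l_max, k_sig = k_sig, x0 = x0, p_sat = p_sat),
            class = "gap_map_params")
}

#' Gap-junction occupancy to electrical coupling conductance
#'
#' Sigmoid map with two documented overrides: zero occupancy gives exactly zero
#' conductance (no gap junctions, no electrical coupling), and occupancy
#' strictly above the saturation threshold gives exactly `l_max`. In between,
#' \deqn{g_{gap}(p) = L_{min} + \frac{L_{max} - L_{min}}{1 + e^{-k (p - x_0)}}.}
#' At `p == p_sat` the sigmoid value is used (the override is a strict
#' inequality). Monotone nondecreasing on `[0, Inf)` and bounded by `[0, l_max]`.
#'
#' @param p percentage of terminal volume occupied (>= 0); vectorized.
#' @param params a [gap_map_params()].
#' @return Coupling conductance (model units).
#' @examples
#' occupancy_to_conductance(0)          # exact 0
#' occupancy_to_conductance(12)         # exact l_max
#' occupancy_to_conductance(5)          # midpoint: (l_min + l_max)/2
#' @export
occupancy_to_conductance <- function(p, params = gap_map_params()) {
  if (any(p < 0)) stop("occupancy p must be >= 0")
  g <- params$l_min +
    (params$l_max - params$l_min) / (1 + exp(-params$k_sig * (p - params$x0)))
  g[p > params$p_sat] <- params$l_max
  g[p == 0] <- 0
  g
}

#' Gap-junction (electrical) current
#'
#' Ohmic coupling with the gate fixed open: the current applied to the
#' postsynaptic compartment is \eqn{g_{gap} (V_{post} - V_{pre})} (positive
#' outward), and the presynaptic compartment receives its negative, so the pair
#' conserves charge. With `rectified = TRUE` the junction conducts only while
#' the presynaptic side is depolarized relative to the postsynaptic side
#' (the biological GF junction rectifies); the ohmic form is the default.
#'
#' @param v_pre,v_post membrane potentials (mV) of the coupled compartments.
#' @param g_gap coupling conductance (model units, >= 0).
#' @param rectified logical; conduct only when `v_pre > v_post`.
#' @return Current applied to the postsynaptic compartment (model units).
#' @export
gap_current <- function(v_pre, v_post, g_gap, rectified = FALSE) {
  stopifnot(all(g_gap >= 0))
  i <- g_gap * (v_post - v_pre)
  if (rectified) i <- i * (v_pre > v_post)
  i
}
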