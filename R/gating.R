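#' Voltage-dependent gating kinetics
#'
#' Describes one Hodgkin-Huxley gating variable by its Boltzmann steady-state
#' curve and a Gaussian-bell voltage-dependent time constant:
#' \deqn{x_\infty(V) = 1 / (1 + e^{(V_{1/2} - V)/k})}
#' \deqn{\tau_x(V) = \tau_{base} + \tau_{amp}\, e^{-((\tau_{center} - V)/\tau_{width})^2}}
#'
#' @param v_half half-activation voltage \eqn{V_{1/2}} (mV).
#' @param slope Boltzmann slope factor \eqn{k} (mV, signed; negative for
#'   inactivation gates).
#' @param tau_base baseline time constant (ms, > 0).
#' @param tau_amp amplitude of the Gaussian bell (ms, >= 0).
#' @param tau_center voltage at which the time constant peaks (mV).
#' @param tau_width width of the bell (mV, nonzero).
#' @return An object of class `"gating_kinetics"`.
#' @examples
#' nk <- gating_kinetics(-53, 15, 1.1, 4.7, -79, 50)
#' gating_steady_state(-53, nk)    # 0.5 at the half-activation voltage
#' gating_time_constant(-79, nk)   # peak: 1.1 + 4.7 ms
#' @export
gating_kinetics <- function(v_half, slope, tau_base, tau_amp, tau_center, tau_width) {
  stopifnot(is.numeric(v_half), is.numeric(slope), slope != 0,
            tau_base > 0, tau_amp >= 0, tau_width != 0)
  structure(list(v_half = v_half, slope = slope, tau_base = tau_base,
                 tau_amp = tau_amp, tau_center = tau_center, tau_width = tau_width),
            class = "gating_kinetics")
}

#' Default gating kinetics of the GF compartment model
#'
#' The three gating variables of the compartment model: delayed-rectifier
#' activation `n` (-53 mV, k = 15), sodium activation `m` (-40 mV, k = 15) and
#' sodium inactivation `h` (-62 mV, k = -7), with time constants
#' \eqn{\tau_n = 1.1 + 4.7 e^{-((-79-V)/50)^2}},
#' \eqn{\tau_m = 0.04 + 0.46 e^{-((-38-V)/30)^2}} and
#' \eqn{\tau_h = 1.2 + 7.4 e^{-((-67-V)/20)^2}} (all ms).
#'
#' @return Named list with elements `n`, `m`, `h`, each a [gating_kinetics()].
#' @export
default_gating <- function() {
  list(n = gating_kinetics(-53, 15, 1.1, 4.7, -79, 50),
       m = gating_kinetics(-40, 15, 0.04, 0.46, -38, 30),
       h = gating_kinetics(-62, -7, 1.2, 7.4, -67, 20))
}

#' Steady-state value of a gating variable
#'
#' @param v membrane potential (mV); vectorized.
#' @param kin a [gating_kinetics()] object.
#' @return Steady-state open fraction in (0, 1).
#' @export
gating_steady_state <- function(v, kin) {
  1 / (1 + exp((kin$v_half - v) / kin$slope))
}

#' Voltage-dependent time constant of a gating variable
#'
#' @inheritParams gating_steady_state
#' @return Time constant (ms), strictly positive; peaks at `tau_center`.
#' @export
gating_time_constant <- function(v, kin) {
  kin$tau_base + kin$tau_amp * exp(-((kin$tau_center - v) / kin$tau_width)^2)
}

#' First-order relaxation rate of a gating variable
#'
#' \eqn{dx/dt = (x_\infty(V) - x) / \tau_x(V)}.
#'
#' @param x current gate value in \[0, 1\].
#' @inheritParams gating_steady_state
#' @return Rate of change (per ms).
#' @export
gating_derivative <- function(x, v, kin) {
  (gating_steady_state(v, kin) - x) / gating_time_constant(v, kin)
}

#' Passive and active membrane parameters of one compartment
#'
#' Maximal conductances, capacitance and reversal potentials of a single
#' Hodgkin-Huxley compartment with currents
#' \eqn{I_{Na} = g_{Na} m^3 h (V - E_{Na})},
#' \eqn{I_K = g_K n^4 (V - E_K)} and \eqn{I_L = g_L (V - E_L)}.
#' Conductances and currents are in dimensionless model units; only voltages
#' (mV) and time (ms) carry physical units. The shipped maximal conductances
#' were set by circuit calibration ([gf_calibrate()]) so that the resting
#' potential lies near the leak reversal and a suprathreshold pulse elicits a
#' single spike.
#'
#' @param c_m membrane capacitance (model units, > 0).
#' @param g_na,g_k,g_leak maximal sodium / potassium / leak conductances (>= 0).
#' @param e_na,e_k,e_leak reversal potentials (mV); defaults 65, -74, -85.
#' @param gating named list of [gating_kinetics()] for `n`, `m`, `h`.
#' @return An object of class `"membrane_params"`.
#' @export
membrane_params <- function(c_m = 1, g_na = 120, g_k = 36, g_leak = 1,
                            e_na = 65, e_k = -74, e_leak = -85,
                            gating = default_gating()) {
  stopifnot(c_m > 0, g_na >= 0, g_k >= 0, g_leak >= 0,
            all(c("n", "m", "h") %in% names(gating)))
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak, gating = gating),
            class = "membrane_params")
}

#' Compartment state
#'
#' @param v membrane potential (mV).
#' @param n,m,h gating variables in \[0, 1\].
#' @return An object of class `"compartment_state"`.
#' @export
compartment_state <- function(v, n, m, h) {
  stopifnot(all(c(n, m, h) >= 0), all(c(n, m, h) <= 1))
  structure(list(v = v, n = n, m = m, h = h), class = "compartment_state")
}

#' Ionic currents of one compartment
#'
#' Each current vanishes at its reversal potential; the leak is linear in
#' `(v - e_leak)`; sodium uses `m^3 h` and potassium `n^4` gating.
#'
#' @param state a [compartment_state()] (or list with `v`, `n`, `m`, `h`).
#' @param params a [membrane_params()].
#' @return Named list `i_na`, `i_k`, `i_leak` (model units; positive outward).
#' @export
ionic_currents <- function(state, params) {
  list(i_na = params$g_na * state$m^3 * state$h * (state$v - params$e_na),
       i_k = params$g_k * state$n^4 * (state$v - params$e_k),
       i_leak = params$g_leak * (state$v - params$e_leak))
}

#' Membrane potential derivative
#'
#' \eqn{C_m\, dV/dt = -(I_{Na} + I_K + I_L + I_{syn}) + I_{stim}}.
#'
#' @inheritParams ionic_currents
#' @param i_syn total synaptic (and coupling) current, positive outward.
#' @param i_stim injected stimulus current, positive depolarizing.
#' @return Rate of change of V (mV/ms).
#' @export
membrane_derivative <- function(state, params, i_syn = 0, i_stim = 0) {
  ion <- ionic_currents(state, params)
  (-(ion$i_na + ion$i_k + ion$i_leak + i_syn) + i_stim) / params$c_m
}

#' Resting state of a compartment
#'
#' Solves for the most hyperpolarized zero of the steady-state current balance
#' (with all gates at their steady-state values) and returns the corresponding
#' fixed point. The Boltzmann activation curves admit multiple equilibria; the
#' hyperpolarized one is the physiological rest.
#'
#' @param params a [membrane_params()].
#' @param v_range search interval (mV) scanned for the lowest root.
#' @return A [compartment_state()] at rest.
#' @export
resting_state <- function(params, v_range = c(-95, -40)) {
  f <- function(v) {
    st <- list(v = v,
               n = gating_steady_state(v, params$gating$n),
               m = gating_steady_state(v, params$gating$m),
               h = gating_steady_state(v, params$gating$h))
    membrane_derivative(st, params)
  }
  vs <- seq(v_range[1], v_range[2], by = 0.1)
  fv <- vapply(vs, f, numeric(1))
  i <- which(diff(sign(fv)) != 0)
  if (length(i) == 0)
    stop("no resting equilibrium found in [", v_range[1], ", ", v_range[2], "] mV")
  v0 <- stats::uniroot(f, c(vs[i[1]], vs[i[1] + 1]), tol = 1e-10)$root
  compartment_state(v0,
                    n = gating_steady_state(v0, params$gating$n),
                    m = gating_steady_state(v0, params$gating$m),
                    h = gating_steady_state(v0, params$gating$h))
}
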