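#' Stimulus specification
#'
#' A train of rectangular current pulses plus i.i.d. zero-mean Gaussian noise
#' added at every time sample, injected into compartment 0. Two protocols are
#' used throughout: a single suprathreshold pulse over 10 ms (latency
#' protocol) and a 10-stimulus 100 Hz train over 100 ms (following-frequency
#' protocol); see [single_pulse_spec()] and [train_spec()].
#'
#' @param pulse_rate pulse repetition rate (Hz).
#' @param n_pulses number of pulses.
#' @param pulse_amplitude pulse current amplitude (model units).
#' @param pulse_width pulse width (ms).
#' @param noise_sd standard deviation of the per-sample Gaussian noise current
#'   (model units); default 1 (zero-mean, unit-variance).
#' @param duration total simulated time (ms); must cover all pulse onsets.
#' @param dt integration time step (ms, > 0); default 0.01.
#' @param seed integer seed for the noise, or `NULL` to use the current RNG
#'   state.
#' @param onset time of the first pulse (ms).
#' @return An object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(pulse_rate = 10, n_pulses = 1, pulse_amplitude = 80,
                          pulse_width = 0.5, noise_sd = 1, duration = 10,
                          dt = 0.01, seed = NULL, onset = 1) {
  stopifnot(dt > 0, pulse_rate > 0, n_pulses >= 0, pulse_width > 0,
            noise_sd >= 0, duration > 0)
  if (n_pulses > 0 &&
      onset + (n_pulses - 1) * 1000 / pulse_rate + pulse_width > duration)
    stop("duration too short for ", n_pulses, " pulses at ", pulse_rate, " Hz")
  structure(list(pulse_rate = pulse_rate, n_pulses = n_pulses,
                 pulse_amplitude = pulse_amplitude, pulse_width = pulse_width,
                 noise_sd = noise_sd, duration = duration, dt = dt,
                 seed = seed, onset = onset),
            class = "stimulus_spec")
}

#' @rdname stimulus_spec
#' @param ... overrides passed to [stimulus_spec()].
#' @export
single_pulse_spec <- function(...) {
  spec <- list(pulse_rate = 10, n_pulses = 1, duration = 10)
  override <- list(...)
  do.call(stimulus_spec, utils::modifyList(spec, override))
}

#' @rdname stimulus_spec
#' @export
train_spec <- function(...) {
  spec <- list(pulse_rate = 100, n_pulses = 10, duration = 100)
  override <- list(...)
  do.call(stimulus_spec, utils::modifyList(spec, override))
}

#' Realize a stimulus time series
#'
#' @param spec a [stimulus_spec()].
#' @return List of class `"gf_stimulus"` with `time` (ms grid), `current`
#'   (injected current per sample), `pulse` (the noise-free pulse component)
#'   and `onsets` (pulse onset times, ms). Deterministic given `spec$seed`.
#' @export
make_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  tt <- seq(0, spec$duration - spec$dt, by = spec$dt)
  pulse <- numeric(length(tt))
  onsets <- if (spec$n_pulses > 0)
    spec$onset + (seq_len(spec$n_pulses) - 1) * 1000 / spec$pulse_rate
  else numeric(0)
  for (o in onsets)
    pulse[tt >= o & tt < o + spec$pulse_width] <- spec$pulse_amplitude
  current <- pulse
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(spec$seed)
    }
    current <- current + stats::rnorm(length(tt), 0, spec$noise_sd)
  }
  structure(list(time = tt, current = current, pulse = pulse, onsets = onsets,
                 spec = spec),
            class = "gf_stimulus")
}

#' Four-compartment GF-TTMn circuit
#'
#' Compartments 0-2 form the Giant Fiber axon chain (symmetric axial coupling
#' between neighbors 0-1 and 1-2); compartment 3 is the postsynaptic motoneuron
#' compartment, connected to compartment 2 by the mixed electrochemical
#' synapse. The electrical coupling conductance is derived from the
#' gap-junction occupancy `p` through [occupancy_to_conductance()], and the
#' chemical component follows first-order transmitter-gate kinetics.
#'
#' @param membrane a single [membrane_params()] applied to all four
#'   compartments, or a list of four.
#' @param g_axial axial coupling conductance between adjacent non-synaptic
#'   compartments (model units, >= 0).
#' @param chem a [chem_synapse_params()]; set `g_syn = 0` to remove the
#'   chemical component.
#' @param gap_map a [gap_map_params()].
#' @param occupancy gap-junction occupancy `p` (% of terminal volume, >= 0).
#' @param rectified logical; rectified electrical coupling (off by default,
#'   matching the ohmic model form).
#' @param spike_threshold spike detection threshold (mV); upward crossings.
#' @param refractory spike detection refractory window (ms).
#' @return An object of class `"gf_circuit"`.
#' @examples
#' circ <- gf_circuit(occupancy = 9.04)
#' sim <- run_circuit(circ, single_pulse_spec(noise_sd = 0))
#' compute_latency(sim)
#' @export
gf_circuit <- function(membrane = membrane_params(), g_axial = 2,
                       chem = chem_synapse_params(), gap_map = gap_map_params(),
                       occupancy = 9.04, rectified = FALSE,
                       spike_threshold = 0, refractory = 2) {
  if (inherits(membrane, "membrane_params")) membrane <- rep(list(membrane), 4)
  stopifnot(length(membrane) == 4,
            all(vapply(membrane, inherits, logical(1), "membrane_params")),
            g_axial >= 0, occupancy >= 0,
            inherits(chem, "chem_synapse_params"),
            inherits(gap_map, "gap_map_params"))
  structure(list(membrane = membrane, g_axial = g_axial, chem = chem,
                 gap_map = gap_map, occupancy = occupancy,
                 rectified = rectified, spike_threshold = spike_threshold,
                 refractory = refractory),
            class = "gf_circuit")
}

#' @export
print.gf_circuit <- function(x, ...) {
  g <- occupancy_to_conductance(x$occupancy, x$gap_map)
  cat("Four-compartment GF-TTMn circuit\n")
  cat(sprintf("  gap-junction occupancy: %.2f%%  ->  g_gap = %.4g%s\n",
              x$occupancy, g, if (x$rectified) " (rectified)" else ""))
  cat(sprintf("  chemical synapse: g_syn = %.3g (tau_rise %.3g ms, tau_decay %.3g ms)\n",
              x$chem$g_syn, x$chem$tau_rise, x$chem$tau_decay))
  cat(sprintf("  axial coupling: %.3g;  membrane g_na/g_k/g_leak = %.3g/%.3g/%.3g\n",
              x$g_axial, x$membrane[[1]]$g_na, x$membrane[[1]]$g_k,
              x$membrane[[1]]$g_leak))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with a refractory window: a crossing within
#' `refractory` ms of the previous accepted spike is ignored.
#'
#' @param v voltage trace (mV).
#' @param time time grid (ms), same length as `v`.
#' @param threshold crossing threshold (mV).
#' @param refractory minimum inter-spike interval (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(v, time, threshold = 0, refractory = 2) {
  nv <- length(v)
  idx <- which(v[-1] >= threshold & v[-nv] < threshold) + 1
  out <- numeric(0)
  last <- -Inf
  for (i in idx) {
    if (time[i] - last >= refractory) {
      out <- c(out, time[i])
      last <- time[i]
    }
  }
  out
}

#' Simulate the four-compartment circuit
#'
#' Forward-Euler integration of the four membrane compartments and the
#' chemical gate. The stimulus is injected into compartment 0 only;
#' compartments 0-1 and 1-2 are coupled axially; compartment 3 receives the
#' chemical and electrical synaptic currents from compartment 2, and
#' compartment 2 receives the negative of the electrical current (charge
#' conservation). All compartments start at the resting fixed point with
#' gates at steady state, so latency measurements carry no onset transient.
#'
#' @param circuit a [gf_circuit()].
#' @param spec a [stimulus_spec()]; its `seed` fixes the stimulus noise.
#' @param stimulus optionally a pre-built [make_stimulus()] realization
#'   (overrides `spec`).
#' @return An object of class `"gf_sim"`: `time`, `v` (matrix, one column per
#'   compartment), `s` (chemical gate trace), `i_gap` (electrical current into
#'   compartment 3 per step), `spikes` (list of spike-time vectors), `onsets`,
#'   `latency` (ms, `NA` if compartment 3 never spiked in the first-stimulus
#'   window), `response_pct` and the generating `circuit`/`spec`.
#' @export
run_circuit <- function(circuit, spec = single_pulse_spec(), stimulus = NULL) {
  stopifnot(inherits(circuit, "gf_circuit"))
  if (is.null(stimulus)) stimulus <- make_stimulus(spec) else spec <- stimulus$spec
  tt <- stimulus$time
  istim <- stimulus$current
  dt <- spec$dt
  nst <- length(tt)

  mp <- circuit$membrane
  g_gap <- occupancy_to_conductance(circuit$occupancy, circuit$gap_map)
  gax <- circuit$g_axial
  chem <- circuit$chem

  # per-compartment parameter vectors (length 4) for a vectorized Euler step
  gna <- vapply(mp, `[[`, numeric(1), "g_na")
  gk <- vapply(mp, `[[`, numeric(1), "g_k")
  gl <- vapply(mp, `[[`, numeric(1), "g_leak")
  cm <- vapply(mp, `[[`, numeric(1), "c_m")
  ena <- vapply(mp, `[[`, numeric(1), "e_na")
  ek <- vapply(mp, `[[`, numeric(1), "e_k")
  el <- vapply(mp, `[[`, numeric(1), "e_leak")
  kin_n <- mp[[1]]$gating$n; kin_m <- mp[[1]]$gating$m; kin_h <- mp[[1]]$gating$h

  r0 <- resting_state(mp[[1]])
  v <- rep(r0$v, 4); n <- rep(r0$n, 4); m <- rep(r0$m, 4); h <- rep(r0$h, 4)
  if (length(unique(lapply(mp, unclass))) > 1) {
    for (j in 2:4) {
      rj <- resting_state(mp[[j]])
      v[j] <- rj$v; n[j] <- rj$n; m[j] <- rj$m; h[j] <- rj$h
    }
  }
  s <- 0

  V <- matrix(NA_real_, nst, 4)
  S <- numeric(nst)
  Igap <- numeric(nst)

  for (i in seq_len(nst)) {
    ina <- gna * m^3 * h * (v - ena)
    ik <- gk * n^4 * (v - ek)
    il <- gl * (v - el)
    isyn <- c(gax * (v[1] - v[2]),
              gax * (v[2] - v[1]) + gax * (v[2] - v[3]),
              gax * (v[3] - v[2]),
              0)
    igap <- gap_current(v[3], v[4], g_gap, circuit$rectified)
    ichem <- chem_current(s, v[4], chem)
    isyn[4] <- isyn[4] + ichem + igap
    isyn[3] <- isyn[3] - igap
    dv <- (-(ina + ik + il + isyn) + c(istim[i], 0, 0, 0)) / cm
    ds <- chem_gate_derivative(s, v[3], chem)
    v <- v + dt * dv
    n <- n + dt * (gating_steady_state(v, kin_n) - n) / gating_time_constant(v, kin_n)
    m <- m + dt * (gating_steady_state(v, kin_m) - m) / gating_time_constant(v, kin_m)
    h <- h + dt * (gating_steady_state(v, kin_h) - h) / gating_time_constant(v, kin_h)
    s <- s + dt * ds
    if (!all(is.finite(v))) {
      bad <- which(!is.finite(v))[1] - 1
      stop(sprintf("simulation diverged in compartment %d at t = %.3f ms",
                   bad, tt[i]))
    }
    V[i, ] <- v
    S[i] <- s
    Igap[i] <- igap
  }

  spikes <- lapply(1:4, function(j)
    detect_spikes(V[, j], tt, circuit$spike_threshold, circuit$refractory))

  res <- structure(list(time = tt, v = V, s = S, i_gap = Igap, spikes = spikes,
                        onsets = stimulus$onsets, circuit = circuit, spec = spec),
                   class = "gf_sim")
  res$latency <- compute_latency(res)
  res$response_pct <- compute_response_frequency(res)
  res
}

#' @export
print.gf_sim <- function(x, ...) {
  cat(sprintf("GF circuit simulation: %.0f ms at dt = %g ms, %d stimuli\n",
              max(x$time) + x$spec$dt, x$spec$dt, length(x$onsets)))
  cat(sprintf("  spikes per compartment: %s\n",
              paste(vapply(x$spikes, length, integer(1)), collapse = "/")))
  cat(sprintf("  latency: %s   response: %.0f%%\n",
              if (is.na(x$latency)) "failed (no compartment-3 spike)"
              else sprintf("%.2f ms", x$latency),
              x$response_pct))
  invisible(x)
}

#' @export
plot.gf_sim <- function(x, compartments = 1:4, ...) {
  cols <- grDevices::hcl.colors(4, "Dark 2")
  graphics::matplot(x$time, x$v[, compartments, drop = FALSE], type = "l",
                    lty = 1, col = cols[compartments],
                    xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::abline(v = x$onsets, col = "grey70", lty = 3)
  graphics::legend("topright", bty = "n", lty = 1, col = cols[compartments],
                   legend = paste0("comp ", compartments - 1))
  invisible(x)
}

#' GF-to-motoneuron response latency
#'
#' The time of the compartment-3 voltage peak minus the time of the
#' compartment-0 voltage peak within the first-stimulus window (from the first
#' onset to one inter-stimulus interval later, clipped to the trace). The peak
#' is the global maximum in the window; ties break to the earliest sample.
#' Returns `NA` if compartment 3 produced no spike in the window.
#'
#' @param result a `"gf_sim"` from [run_circuit()].
#' @return Latency in ms, or `NA_real_` on transmission failure.
#' @export
compute_latency <- function(result) {
  stopifnot(inherits(result, "gf_sim"))
  if (length(result$onsets) == 0) return(NA_real_)
  t0 <- result$onsets[1]
  t1 <- min(t0 + 1000 / result$spec$pulse_rate, max(result$time))
  win <- result$time >= t0 & result$time <= t1
  sp3 <- result$spikes[[4]]
  if (!any(sp3 > t0 & sp3 <= t1)) return(NA_real_)
  tpk <- function(j) {
    vw <- result$v[win, j]
    result$time[win][which.max(vw)]
  }
  tpk(4) - tpk(1)
}

#' Following (response) frequency of a stimulus train
#'
#' Percentage of stimulus onsets answered by at least one compartment-3 spike
#' within one inter-stimulus interval of the onset (at most one response
#' counted per onset).
#'
#' @param result a `"gf_sim"` from [run_circuit()].
#' @param onsets stimulus onset times (ms); defaults to the onsets of the run.
#' @return Response frequency in percent (0-100).
#' @export
compute_response_frequency <- function(result, onsets = result$onsets) {
  stopifnot(inherits(result, "gf_sim"))
  if (length(onsets) == 0) return(NA_real_)
  isi <- 1000 / result$spec$pulse_rate
  sp3 <- result$spikes[[4]]
  hits <- vapply(onsets, function(o) any(sp3 > o & sp3 <= o + isi), logical(1))
  100 * sum(hits) / length(onsets)
}

# RNG state helpers: preserve the caller's stream around locally seeded draws
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# documented fan-out from one master seed to per-stage child seeds
child_seed <- function(master, stream, index = 0) {
  (as.integer(master) + 104729L * as.integer(stream) +
     1299709L * as.integer(index)) %% 2147483647L
}
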