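test_that("steady-state curves hit 0.5 at the half-activation voltage and respect the slope sign", {
  g <- default_gating()
  expect_equal(gating_steady_state(-53, g$n), 0.5)
  expect_equal(gating_steady_state(-40, g$m), 0.5)
  expect_equal(gating_steady_state(-62, g$h), 0.5)
  # h inactivates with depolarization (negative slope)
  expect_lt(gating_steady_state(60, g$h), 1e-6)
  expect_gt(gating_steady_state(-120, g$h), 1 - 1e-3)
})

test_that("steady states stay in (0,1) and are monotone with the slope sign", {
  g <- default_gating()
  v <- seq(-150, 150, by = 0.5)
  for (kin in g) {
    x <- gating_steady_state(v, kin)
    expect_true(all(x > 0 & x < 1))
    if (kin$slope > 0) expect_true(all(diff(x) > 0)) else expect_true(all(diff(x) < 0))
  }
})

test_that("time constants peak at tau_center with the stated values", {
  g <- default_gating()
  expect_equal(gating_time_constant(-79, g$n), 5.8)
  expect_equal(gating_time_constant(-38, g$m), 0.5)
  expect_equal(gating_time_constant(-67, g$h), 8.6)
  v <- seq(-150, 150, by = 0.5)
  for (kin in g) {
    tau <- gating_time_constant(v, kin)
    expect_true(all(tau > 0))
    expect_equal(v[which.max(tau)], kin$tau_center)
  }
})

test_that("kinetics constructor rejects degenerate parameters", {
  expect_error(gating_kinetics(-53, 0, 1, 1, -79, 50))
  expect_error(gating_kinetics(-53, 15, 0, 1, -79, 50))
  expect_error(gating_kinetics(-53, 15, 1, 1, -79, 0))
})

test_that("ionic currents vanish at their reversal potentials and scale with gating", {
  p <- membrane_params()
  st <- compartment_state(v = 65, n = 0.3, m = 0.6, h = 0.4)
  expect_equal(ionic_currents(st, p)$i_na, 0)
  st$v <- -85
  expect_equal(ionic_currents(st, p)$i_leak, 0)
  st$v <- -74
  expect_equal(ionic_currents(st, p)$i_k, 0)
  # unit gating: i_k = g_k * (0 - e_k)
  st <- compartment_state(v = 0, n = 1, m = 1, h = 1)
  expect_equal(ionic_currents(st, p)$i_k, p$g_k * 74)
  # leak is linear in (v - e_leak)
  i1 <- ionic_currents(compartment_state(-75, 0, 0, 1), p)$i_leak
  i2 <- ionic_currents(compartment_state(-65, 0, 0, 1), p)$i_leak
  expect_equal(i2 / i1, 2)
})

test_that("membrane derivative balances stimulus, synaptic and ionic currents", {
  p <- membrane_params(g_na = 0, g_k = 0, g_leak = 0)
  st <- compartment_state(-70, 0.1, 0.1, 0.9)
  expect_equal(membrane_derivative(st, p, i_syn = 0, i_stim = p$c_m), 1)
  expect_equal(membrane_derivative(st, p, i_syn = 5, i_stim = 5), 0)
  # leak-only, above rest: hyperpolarizing drift
  p2 <- membrane_params(g_na = 0, g_k = 0, g_leak = 1)
  expect_lt(membrane_derivative(compartment_state(-60, 0, 0, 1), p2), 0)
})

test_that("gating relaxation matches the closed-form exponential at fixed voltage", {
  g <- default_gating()
  v <- -60
  for (kin in g) {
    xinf <- gating_steady_state(v, kin)
    tau <- gating_time_constant(v, kin)
    expect_equal(gating_derivative(xinf, v, kin), 0)     # fixed point
    expect_gt(gating_derivative(0, v, kin), 0)           # inward at boundary
    dt <- tau / 100                                      # well inside dt <= tau/20
    nstep <- ceiling(5 * tau / dt)
    x <- 0.9
    t <- 0
    for (i in seq_len(nstep)) {
      x <- x + dt * gating_derivative(x, v, kin)
      t <- t + dt
    }
    analytic <- xinf + (0.9 - xinf) * exp(-t / tau)
    expect_equal(x, analytic, tolerance = 1e-3)
  }
})

test_that("the resting state is a stable fixed point of the unstimulated compartment", {
  p <- membrane_params()
  r <- resting_state(p)
  expect_lt(r$v, -70)  # hyperpolarized branch, not a depolarized equilibrium
  expect_lt(abs(membrane_derivative(r, p)), 1e-8)
  # integrate 200 ms with no input: stays put
  circ <- gf_circuit()
  spec <- stimulus_spec(n_pulses = 0, noise_sd = 0, duration = 200, dt = 0.01)
  sim <- run_circuit(circ, spec)
  nst <- nrow(sim$v)
  drift <- abs(sim$v[nst, ] - sim$v[nst - 100, ]) / 1  # mV per ms
  expect_true(all(drift < 1e-6))
  expect_equal(unname(sim$v[nst, 1]), r$v, tolerance = 1e-4)
})

test_that("gating variables remain in [0,1] during an integrated spike", {
  sim <- run_circuit(gf_circuit(), quiet_single())
  expect_true(all(is.finite(sim$v)))
  expect_true(all(sim$s >= 0 & sim$s <= 1))
})
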