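test_that("stimulus schedule places exact pulses and reproduces under a seed", {
  spec <- train_spec(noise_sd = 0)
  st <- make_stimulus(spec)
  expect_length(st$onsets, 10)
  expect_equal(diff(st$onsets), rep(10, 9))
  # each pulse occupies width/dt samples at the pulse amplitude
  expect_equal(sum(st$current == spec$pulse_amplitude),
               10 * spec$pulse_width / spec$dt)
  s1 <- make_stimulus(train_spec(seed = 99))
  s2 <- make_stimulus(train_spec(seed = 99))
  expect_identical(s1$current, s2$current)
  s3 <- make_stimulus(train_spec(seed = 100))
  expect_false(identical(s1$current, s3$current))
})

test_that("stimulus noise is zero-mean at the law-of-large-numbers scale", {
  spec <- stimulus_spec(n_pulses = 1, noise_sd = 1, duration = 1000, dt = 0.01,
                        seed = 5)
  st <- make_stimulus(spec)
  noise <- st$current - st$pulse
  n <- length(noise)
  expect_gt(n, 1e5 - 1)
  expect_lt(abs(mean(noise)), 4 / sqrt(n))      # 4 SE
  expect_equal(sd(noise), 1, tolerance = 0.02)
})

test_that("stimulus spec rejects impossible durations", {
  expect_error(stimulus_spec(pulse_rate = 100, n_pulses = 10, duration = 50))
  expect_error(stimulus_spec(dt = 0))
})

test_that("a fully decoupled postsynaptic compartment never fires", {
  circ <- gf_circuit(chem = chem_synapse_params(g_syn = 0), occupancy = 0)
  sim <- run_circuit(circ, quiet_train())
  expect_length(sim$spikes[[4]], 0)
  expect_equal(sim$response_pct, 0)
  expect_true(is.na(sim$latency))
  # the GF chain itself still fires
  expect_length(sim$spikes[[1]], 10)
})

test_that("saturated coupling transmits a single suprathreshold pulse", {
  sim <- run_circuit(fixture_circuit(occupancy = 12), quiet_single())
  expect_length(sim$spikes[[4]], 1)
  expect_lt(sim$latency, 1.0)
  expect_equal(sim$response_pct, 100)
})

test_that("doubling the stimulus amplitude never loses compartment-0 spikes", {
  counts <- vapply(c(40, 80, 160), function(a) {
    sim <- run_circuit(gf_circuit(), quiet_train(pulse_amplitude = a))
    length(sim$spikes[[1]])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("latency shortens when the gap conductance is multiplied by 10", {
  gm <- gap_map_params()
  lat_of <- function(l) {
    gm$l_min <- l; gm$l_max <- l
    run_circuit(gf_circuit(gap_map = gm, occupancy = 5), quiet_single())$latency
  }
  expect_gt(lat_of(0.05), lat_of(0.5))
})

test_that("halving the integration step moves latency by less than 2 percent", {
  l1 <- run_circuit(gf_circuit(), quiet_single(dt = 0.01))$latency
  l2 <- run_circuit(gf_circuit(), quiet_single(dt = 0.005))$latency
  expect_lt(abs(l1 - l2) / l2, 0.02)
})

test_that("gap current bookkeeping conserves charge at every step", {
  sim <- run_circuit(gf_circuit(), quiet_single())
  # recompute the coupling current from the stored traces: current into
  # compartment 3 must equal the current out of compartment 2 (the stored
  # current at step i is the one used in the Euler update, i.e. computed
  # from the state after step i-1)
  g <- occupancy_to_conductance(sim$circuit$occupancy, sim$circuit$gap_map)
  nst <- nrow(sim$v)
  expect_equal(sim$i_gap[-1], g * (sim$v[-nst, 4] - sim$v[-nst, 3]),
               tolerance = 1e-6)
})

test_that("seeded runs are bit-reproducible", {
  a <- run_circuit(gf_circuit(), train_spec(seed = 7))
  b <- run_circuit(gf_circuit(), train_spec(seed = 7))
  expect_identical(a$v, b$v)
  expect_identical(a$latency, b$latency)
})

test_that("divergence aborts with a diagnostic naming compartment and time", {
  # a step far above the fastest gating time constant destabilizes Euler
  expect_error(run_circuit(gf_circuit(), quiet_single(dt = 0.5)),
               "diverged in compartment [0-3] at t")
})

test_that("response frequency counts at most one response per onset", {
  sim <- run_circuit(gf_circuit(occupancy = 12), quiet_train())
  expect_equal(sim$response_pct, 100)
  expect_equal(compute_response_frequency(sim, sim$onsets[1:5]), 100)
  # spikes after onsets {1,2,3,5,7} only -> 50% (synthetic spike list)
  fake <- sim
  fake$spikes[[4]] <- sim$onsets[c(1, 2, 3, 5, 7)] + 1.5
  expect_equal(compute_response_frequency(fake), 50)
})

test_that("latency is zero for identical compartment-0 and compartment-3 traces", {
  sim <- run_circuit(gf_circuit(occupancy = 12), quiet_single())
  fake <- sim
  fake$v[, 4] <- fake$v[, 1]
  fake$spikes[[4]] <- fake$spikes[[1]]
  expect_equal(compute_latency(fake), 0)
})
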