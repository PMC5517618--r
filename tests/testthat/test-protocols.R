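test_that("stimulus waveforms follow the protocol definitions", {
  const <- constant_protocol(0.83, onset = 20, duration = 1, window = c(0, 1))
  expect_identical(stimulus_current(10, const), 0)
  expect_identical(stimulus_current(20, const), 0.83)
  expect_identical(stimulus_current(500, const), 0.83)
  pulsed <- pulsed_protocol(45, amplitude = 60, tau_stim = 1, duration = 1,
                            window = c(0, 1))
  expect_identical(stimulus_current(45.5, pulsed), 60)
  expect_identical(stimulus_current(44.0, pulsed), 0)
  expect_identical(stimulus_current(0, pulsed), 60)
  expect_identical(stimulus_current(1.0, pulsed), 0)
})

test_that("protocol invariants are enforced", {
  expect_error(pulsed_protocol(bcl = 0.5, tau_stim = 1))
  expect_error(pulsed_protocol(100, amplitude = -1))
  expect_error(constant_protocol(0.5, duration = 10, window = c(5, 20)),
               "window")
})

test_that("traces are deterministic and structurally valid", {
  prot <- pulsed_protocol(100, duration = 1, window = c(0, 1))
  a <- run_simulation(wt_params, prot, initial = wt_rest)
  b <- run_simulation(wt_params, prot, initial = wt_rest)
  expect_identical(a$V, b$V)
  expect_identical(a$Cai, b$Cai)
  expect_true(all(diff(a$time) > 0))
  expect_length(a$V, length(a$time))
  expect_length(a$Cai, length(a$time))
})

test_that("pulse-edge restarts are robust to a 10x finer forced step", {
  prot <- pulsed_protocol(100, duration = 2, window = c(0, 2))
  coarse <- wt_trace_2s
  fine <- run_simulation(wt_params, prot, initial = wt_rest, dt_fine = 0.05,
                         rtol = 1e-6, atol_scale = 1)
  fine2 <- run_simulation(wt_params, prot, initial = wt_rest, dt_fine = 0.005)
  n0 <- length(detect_spikes(coarse))
  n1 <- length(detect_spikes(fine2))
  expect_identical(n0, n1)
})

test_that("halving the tolerance changes APD50 and peak Ca by < 1%", {
  prot <- pulsed_protocol(100, duration = 2, window = c(1, 2))
  a <- run_simulation(wt_params, prot, initial = wt_rest, rtol = 1e-6)
  b <- run_simulation(wt_params, prot, initial = wt_rest, rtol = 5e-7)
  fa <- extract_features(a); fb <- extract_features(b)
  expect_lt(abs(mean(fa$ap$apd50) - mean(fb$ap$apd50)) / mean(fa$ap$apd50),
            0.01)
  expect_lt(abs(max(a$Cai) - max(b$Cai)) / max(a$Cai), 0.01)
})

test_that("concentrations stay positive and occupancies bounded along trajectories", {
  tr <- run_simulation(wt_params,
                       constant_protocol(0.76, duration = 5, window = c(0, 5)),
                       initial = wt_rest,
                       keep = c("Cass", "CaJSR", "ONa", "OCaL", "PO1"))
  expect_true(all(tr$Cai > 0))
  expect_true(all(tr$CaNSR > 0))
  expect_true(all(tr$extra[, "Cass"] > 0))
  expect_true(all(tr$extra[, "CaJSR"] > 0))
  for (nm in c("ONa", "OCaL", "PO1")) {
    expect_true(all(tr$extra[, nm] >= -1e-8))
    expect_true(all(tr$extra[, nm] <= 1 + 1e-8))
  }
  # final state passes the full invariant audit (run_simulation enforces it)
  expect_silent(validate_state(tr$final_state, tol = 1e-6))
})

test_that("epsilon endpoints reproduce the genotype presets bit-identically in simulation", {
  prot <- pulsed_protocol(100, duration = 1, window = c(0, 1))
  wt_eps <- run_simulation(interpolate_parameters(0), prot, initial = wt_rest)
  wt_ref <- run_simulation(wt_params, prot, initial = wt_rest)
  expect_identical(wt_eps$V, wt_ref$V)
  expect_identical(wt_eps$Cai, wt_ref$Cai)
  tg_eps <- run_simulation(interpolate_parameters(1), prot, initial = tg_rest)
  tg_ref <- run_simulation(tg_params, prot, initial = tg_rest)
  expect_identical(tg_eps$V, tg_ref$V)
})
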