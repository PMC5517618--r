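test_that("all transition rates are non-negative across the physiological range", {
  full <- ina_scheme("full")
  for (V in seq(-100, 60, by = 5)) {
    r <- ina_rates(V, full)
    expect_true(all(is.finite(r$value)))
    expect_true(all(r$value >= 0))
  }
})

test_that("stripping removes exactly the I1/I2 states and their edges", {
  full <- ina_scheme("full")
  stripped <- strip_slow_inactivation(full)
  expect_identical(stripped$variant, "no_slow_inact")
  expect_length(stripped$states, 7)
  expect_false(any(c("I1Na", "I2Na") %in% stripped$states))
  slow_edges <- full$edges$from %in% c("I1Na", "I2Na") |
    full$edges$to %in% c("I1Na", "I2Na")
  expect_identical(nrow(full$edges) - nrow(stripped$edges),
                   sum(slow_edges))
  r <- ina_rates(-20, stripped)
  expect_false(any(r$from %in% c("I1Na", "I2Na")))
  expect_false(any(r$to %in% c("I1Na", "I2Na")))
  # no double stripping
  expect_error(strip_slow_inactivation(stripped), "already")
})

test_that("stripping a state reassigns the slow-inactivated mass to IF", {
  y <- wt_rest
  y[["I1Na"]] <- 0.2; y[["I2Na"]] <- 0.1
  res <- strip_slow_inactivation(ina_scheme("full"), state = y)
  expect_identical(res$state[["I1Na"]], 0)
  expect_identical(res$state[["I2Na"]], 0)
  expect_equal(res$state[["IFNa"]], y[["IFNa"]] + 0.3)
  # total Na-chain mass unchanged
  expect_equal(sum(res$state[na_occ_names[-1]]), sum(y[na_occ_names[-1]]) - 0.3 + 0.3)
})

test_that("occupancy derivatives conserve probability and deactivate from O", {
  for (variant in c("full", "no_slow_inact")) {
    sch <- ina_scheme(variant)
    n <- length(sch$states)
    set.seed(42)
    for (i in 1:5) {
      occ <- stats::runif(n); occ <- setNames(occ / sum(occ), sch$states)
      for (V in c(-100, -60, 0, 40)) {
        d <- ina_occupancy_derivatives(occ, V, sch)
        expect_equal(sum(d), 0, tolerance = 1e-12)
      }
    }
  }
  # all mass in O at -100 mV: open state must lose probability
  sch <- ina_scheme("full")
  occ <- setNames(numeric(9), sch$states); occ[["ONa"]] <- 1
  d <- ina_occupancy_derivatives(occ, -100, sch)
  expect_lt(d[["ONa"]], 0)
})

test_that("occupancy vectors are validated", {
  sch <- ina_scheme("full")
  occ <- setNames(rep(1 / 7, 7), ina_scheme("no_slow_inact")$states)
  expect_error(ina_occupancy_derivatives(occ, -50, sch), "9 states")
  occ2 <- setNames(rep(0.2, 9), sch$states)
  expect_error(ina_occupancy_derivatives(occ2, -50, sch), "sum to 1")
})

test_that("the open-state current follows the ohmic form", {
  p <- wt_params
  Nai <- wt_rest[["Nai"]]; Ki <- wt_rest[["Ki"]]
  expect_identical(ina_current(-20, 0, Nai, p, Ki), 0)
  RTF <- p$constants[["Rgas"]] * p$constants[["TK"]] / p$constants[["F"]]
  ENa <- RTF * log((0.9 * p$constants[["Nao"]] + 0.1 * p$constants[["Ko"]]) /
                     (0.9 * Nai + 0.1 * Ki))
  expect_equal(ina_current(ENa, 1, Nai, p, Ki), 0)
  expect_equal(ina_current(ENa - 10, 1, Nai, p, Ki),
               -10 * p$constants[["GNa"]])
})

test_that("the no-slow-inactivation variant keeps I1/I2 empty along trajectories", {
  res <- strip_slow_inactivation(ina_scheme("full"), state = wt_rest)
  tr <- run_simulation(wt_params,
                       pulsed_protocol(100, duration = 2, window = c(0, 2)),
                       scheme = "no_slow_inact", initial = res$state,
                       keep = c("I1Na", "I2Na"))
  expect_true(all(tr$extra[, "I1Na"] == 0))
  expect_true(all(tr$extra[, "I2Na"] == 0))
  # and the full scheme does populate I1 under the same pacing
  tr2 <- run_simulation(wt_params,
                        pulsed_protocol(100, duration = 2, window = c(0, 2)),
                        initial = wt_rest, keep = "I1Na")
  expect_gt(max(tr2$extra[, "I1Na"]), 0)
})

test_that("without slow inactivation the strong-stimulus depolarized state sits higher", {
  prot <- constant_protocol(0.9, duration = 20, window = c(15, 20))
  full <- run_simulation(wt_params, prot, initial = wt_rest, dt_fine = 1)
  res <- strip_slow_inactivation(ina_scheme("full"), state = wt_rest)
  stripped <- run_simulation(wt_params, prot, scheme = "no_slow_inact",
                             initial = res$state, dt_fine = 1)
  expect_gt(stripped$final_state[["V"]], full$final_state[["V"]] + 10)
  expect_gt(full$final_state[["V"]], -55)   # both are depolarized block states
})
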