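test_that("grids are validated", {
  expect_error(bifurcation_sweep("istim", numeric(0)), "empty")
  expect_error(bifurcation_sweep("istim", c(0.2, 0.1)), "increasing")
  expect_error(bifurcation_sweep("istim", c(0.5, 1.5)), "lie in")
  expect_error(bifurcation_sweep("bcl", c(10, 20)), "lie in")
})

test_that("a single-point sweep yields one labeled point and no transitions", {
  dg <- bifurcation_sweep(
    "istim", 0.2, base_params = wt_params,
    protocol_template = constant_protocol(0, duration = 2, window = c(1, 2)),
    dt_fine = 0.5)
  expect_length(dg$grid, 1)
  expect_identical(dg$regimes, "quiescent")
  expect_equal(nrow(dg$transitions), 0)
  df <- as.data.frame(dg)
  expect_true(all(c("control", "observable", "branch", "value", "regime")
                  %in% names(df)))
})

test_that("bisection localizes a synthetic step-function transition", {
  classify <- function(x) if (x > 0.3) "spiking" else "quiescent"
  th <- find_threshold("istim", c(0, 1), predicate = function(r) r == "spiking",
                       tol = 0.004, classify_fn = classify)
  expect_equal(as.numeric(th), 0.3, tolerance = 0.004)
  expect_lt(diff(attr(th, "bracket")), 0.004 + 1e-12)
  # endpoints must straddle the transition
  expect_error(
    find_threshold("istim", c(0.5, 1), predicate = function(r) r == "spiking",
                   classify_fn = classify),
    "straddle")
})

test_that("transition tables are assembled in grid order", {
  labels <- c("quiescent", "quiescent", "spiking", "bursting", "bursting",
              "depolarized-block")
  tr <- myoburst:::.transitions(seq(0.1, 0.6, 0.1), labels)
  expect_equal(nrow(tr), 3)
  expect_identical(tr$from, c("quiescent", "spiking", "bursting"))
  expect_identical(tr$to, c("spiking", "bursting", "depolarized-block"))
  expect_equal(tr$control, c(0.25, 0.35, 0.55))
})

test_that("identical AP and Ca transition sets give an empty split table", {
  dg <- list(grid = seq(0, 1, 0.1),
             transitions = data.frame(control = 0.5, from = "quiescent",
                                      to = "spiking",
                                      stringsAsFactors = FALSE),
             ca_transitions = data.frame(control = 0.5, from = "steady",
                                         to = "periodic",
                                         stringsAsFactors = FALSE))
  out <- ca_ap_threshold_split(dg)
  expect_equal(nrow(out$split), 0)
  dg$ca_transitions <- rbind(dg$ca_transitions,
                             data.frame(control = 0.8, from = "periodic",
                                        to = "irregular",
                                        stringsAsFactors = FALSE))
  out2 <- ca_ap_threshold_split(dg)
  expect_equal(nrow(out2$split), 1)
  expect_identical(out2$split$observable, "Ca")
  expect_equal(out2$split$control, 0.8)
})
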