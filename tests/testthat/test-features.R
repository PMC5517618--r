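test_that("spike detection matches the closed-form crossings of a square wave", {
  sq <- synthetic_square_trace()
  sp <- detect_spikes(sq, v_th = -40, reset_level = -50)
  expect_length(sp, length(sq$expected_spike_times))
  expect_equal(sp, sq$expected_spike_times, tolerance = 1e-9)
  isi <- interspike_intervals(sp, window = c(0, 1))
  expect_equal(isi$isi, sq$expected_isi, tolerance = 1e-9)
  expect_equal(isi$mean_isi, 100, tolerance = 1e-6)
})

test_that("a trace that never crosses threshold yields no spikes", {
  tt <- seq(0, 1000, 0.5)
  expect_length(detect_spikes(list(time = tt, V = rep(-70, length(tt)))), 0)
  expect_length(detect_spikes(list(time = tt, V = -70 + 5 * sin(tt / 50))), 0)
})

test_that("hysteresis counts a re-crossing shoulder once", {
  # AP with a shoulder that dips to -45 (above reset -50) and re-crosses -40
  tt <- seq(0, 60, 0.1)
  v <- rep(-80, length(tt))
  v[tt >= 10 & tt < 15] <- 10
  v[tt >= 15 & tt < 20] <- -45
  v[tt >= 20 & tt < 25] <- -20
  sp <- detect_spikes(list(time = tt, V = v))
  expect_length(sp, 1)
  # dipping below the reset level re-arms the detector
  v2 <- v
  v2[tt >= 15 & tt < 20] <- -55
  expect_length(detect_spikes(list(time = tt, V = v2)), 2)
})

test_that("interspike intervals flag undefined means", {
  r <- interspike_intervals(c(40100, 40200, 40300), window = c(40, 50))
  expect_equal(r$isi, c(100, 100))
  expect_equal(r$mean_isi, 100)
  r1 <- interspike_intervals(45000, window = c(40, 50))
  expect_length(r1$isi, 0)
  expect_true(is.na(r1$mean_isi))
  # bursting synthetic train: 4 spikes 20 ms apart, 500 ms gap, repeated
  train <- as.vector(outer((0:3) * 20, (0:9) * 560, "+")) + 40000
  r2 <- interspike_intervals(sort(train), window = c(40, 50))
  expect_setequal(round(unique(r2$isi)), c(20, 500))
  expect_equal(sum(r2$isi == 500), 9)
})

test_that("AP metrics reproduce piecewise-linear geometry", {
  tri <- synthetic_triangle_ap()  # rise -80 -> 20 in 1 ms, fall in 9 ms
  sp <- detect_spikes(tri)
  m <- ap_metrics(tri, sp)
  expect_equal(nrow(m), 1)
  expect_equal(m$amplitude, tri$expected_amplitude, tolerance = 1e-3)
  expect_equal(m$apd50, tri$expected_apd50, tolerance = 0.05)
  # truncated AP (window ends mid-repolarization) is omitted
  cut <- which(tri$time <= 101.5)
  m2 <- ap_metrics(list(time = tri$time[cut], V = tri$V[cut]),
                   detect_spikes(list(time = tri$time[cut], V = tri$V[cut])))
  expect_equal(nrow(m2), 0)
})

test_that("extrema branches resolve constants, alternans and sine waves", {
  tt <- seq(0, 10000, 1)
  cons <- extrema_branches(tt, rep(5, length(tt)), window = c(0, 10))
  expect_equal(cons$max_branches, 5)
  expect_equal(cons$min_branches, 5)
  # period-2 alternans: peaks alternating 10 and 20
  v <- 15 + 5 * sin(2 * pi * tt / 200) * rep(c(1, -1), length.out = length(tt))
  alt <- 5 * sin(2 * pi * tt / 100) +
    2.5 * sin(pi * tt / 100)  # period-200 modulation of a period-100 wave
  br <- extrema_branches(tt, alt, window = c(0, 10), tol = 0.5)
  expect_length(br$max_branches, 2)
  sine <- extrema_branches(tt, sin(2 * pi * tt / 500), window = c(0, 10),
                           tol = 0.01)
  expect_length(sine$max_branches, 1)
  expect_length(sine$min_branches, 1)
  expect_equal(sine$max_branches, 1, tolerance = 1e-4)
})

test_that("regime classification follows the stated rules on synthetic traces", {
  tt <- seq(40000, 50000, 0.5)
  flat <- function(level) {
    tr <- list(time = tt, V = rep(level, length(tt)),
               Cai = rep(0.1, length(tt)),
               protocol = list(window = c(40, 50)))
    extract_features(tr, window = c(40, 50))
  }
  expect_identical(flat(-80)$regime, "quiescent")
  expect_identical(flat(-45)$regime, "depolarized-block")

  mk <- function(spike_times, width = 2, amps = 100) {
    v <- rep(-80, length(tt))
    amps <- rep(amps, length.out = length(spike_times))
    for (i in seq_along(spike_times))
      v[tt >= spike_times[i] & tt < spike_times[i] + width] <-
        -80 + amps[i]
    tr <- list(time = tt, V = v, Cai = rep(0.1, length(tt)),
               protocol = list(window = c(40, 50)))
    extract_features(tr, window = c(40, 50))
  }
  tonic <- mk(seq(40100, 49900, by = 200))
  expect_identical(tonic$regime, "spiking")
  burst <- mk(as.vector(outer((0:3) * 30, seq(40100, 49000, by = 1000), "+")))
  expect_identical(burst$regime, "bursting")
  altern <- mk(seq(40100, 49900, by = 200), amps = c(100, 80))
  expect_identical(altern$regime, "alternans")
})

test_that("classification is invariant to time shift and 2x resampling", {
  tr <- run_simulation(
    wt_params, pulsed_protocol(100, duration = 3, window = c(1, 3)),
    initial = wt_rest)
  f0 <- extract_features(tr)
  shifted <- tr
  shifted$time <- tr$time + 5000
  f1 <- extract_features(shifted, window = c(6, 8))
  expect_identical(f0$regime, f1$regime)
  half <- seq(1, length(tr$time), by = 2)
  down <- tr
  down$time <- tr$time[half]; down$V <- tr$V[half]; down$Cai <- tr$Cai[half]
  f2 <- extract_features(down)
  expect_identical(f0$regime, f2$regime)
  expect_equal(f2$n_spikes, f0$n_spikes)
})

test_that("Ca transient statistics report amplitudes and diastolic levels", {
  tt <- seq(40000, 50000, 1)
  ca <- 0.1 + 0.2 * pmax(sin(2 * pi * tt / 500), 0)^4
  tr <- list(time = tt, V = rep(-80, length(tt)), Cai = ca,
             protocol = list(window = c(40, 50)))
  st <- ca_transient_stats(tr, window = c(40, 50))
  expect_equal(st$diastolic, 0.1, tolerance = 1e-3)
  expect_equal(mean(st$amplitudes), 0.2, tolerance = 1e-2)
  expect_identical(st$regime, "periodic")
  cons <- ca_transient_stats(list(time = tt, V = tt * 0, Cai = rep(0.2, length(tt)),
                                  protocol = list(window = c(40, 50))),
                             window = c(40, 50))
  expect_identical(cons$regime, "steady")
  expect_length(cons$max_branches, 1)
})
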