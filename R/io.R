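# Trace and diagram persistence (CSV + JSON sidecar) and reference fixtures.

#' Write / read a simulation trace
#'
#' Traces are stored as a CSV of `(time, V, Cai, CaNSR, ...)` at full double
#' precision plus a JSON sidecar (`<path>.json`) carrying the protocol, scheme,
#' solver settings and package version needed to regenerate the run.
#'
#' @param trace a `myocyte_trace`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = trace$time, V = trace$V, Cai = trace$Cai,
                   CaNSR = trace$CaNSR)
  if (!is.null(trace$extra)) df <- cbind(df, as.data.frame(trace$extra))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(protocol = unclass(trace$protocol), scheme = trace$scheme,
               genotype = trace$genotype, eps = trace$eps,
               solver = trace$solver,
               final_state = as.list(trace$final_state),
               version = as.character(utils::packageVersion("myoburst")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @return `read_trace()`: a `myocyte_trace` reconstructed from disk.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prot <- meta$protocol
  protocol <- if (prot$kind == "pulsed")
    pulsed_protocol(prot$bcl, prot$amplitude, prot$tau_stim, prot$onset,
                    prot$duration, unlist(prot$window))
  else
    constant_protocol(prot$amplitude, prot$onset, prot$duration,
                      unlist(prot$window))
  extra_cols <- setdiff(names(df), c("time", "V", "Cai", "CaNSR"))
  structure(list(time = df$time, V = df$V, Cai = df$Cai, CaNSR = df$CaNSR,
                 extra = if (length(extra_cols))
                   as.matrix(df[extra_cols]),
                 currents = NULL, protocol = protocol, scheme = meta$scheme,
                 genotype = meta$genotype, eps = meta$eps,
                 final_state = unlist(meta$final_state), solver = meta$solver,
                 drift = NA_real_),
            class = "myocyte_trace")
}

#' Write a bifurcation diagram as a tidy CSV
#'
#' One row per grid point x observable x branch (see
#' [as.data.frame.bifurcation_diagram()]), suitable for replotting orbit
#' diagrams; a JSON sidecar records the control, scheme and regime sequence.
#'
#' @param diagram a `bifurcation_diagram`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  utils::write.csv(as.data.frame(diagram), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(control = diagram$control, grid = diagram$grid,
         regimes = diagram$regimes, ca_regimes = diagram$ca_regimes,
         transitions = diagram$transitions, scheme = diagram$scheme,
         genotype = diagram$genotype,
         version = as.character(utils::packageVersion("myoburst"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic reference fixtures
#'
#' Generates the short reference runs used by the test suite: the WT resting
#' state, a 2-s WT paced run at BCL 100 ms, a 2-s WT constant-current run, and
#' a closed-form synthetic square-wave "trace" with a known spike count for
#' exercising the feature extractors. Everything is deterministic: regenerating
#' the set gives identical files.
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("myoburst-fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- make_parameters("wt")
  rest <- find_resting_state(wt)
  files <- character(0)

  p <- file.path(dir, "wt_rest.csv")
  utils::write.csv(data.frame(state = names(rest),
                              value = format(unname(rest), digits = 15)),
                   p, row.names = FALSE, quote = FALSE)
  files["wt_rest"] <- p

  tr <- run_simulation(wt, pulsed_protocol(100, duration = 2, window = c(0, 2)),
                       initial = rest)
  files["wt_paced_2s"] <- write_trace(tr, file.path(dir, "wt_paced_2s.csv"))

  trc <- run_simulation(wt, constant_protocol(0.75, duration = 2,
                                              window = c(0, 2)),
                        initial = rest)
  files["wt_constant_2s"] <- write_trace(trc,
                                         file.path(dir, "wt_constant_2s.csv"))

  sq <- synthetic_square_trace()
  p <- file.path(dir, "synthetic_square.csv")
  utils::write.csv(data.frame(time = sq$time, V = sq$V), p,
                   row.names = FALSE, quote = FALSE)
  files["synthetic_square"] <- p
  invisible(files)
}

#' Closed-form synthetic waveforms for feature-extractor oracles
#'
#' `synthetic_square_trace()` builds a square-wave voltage train
#' (`V = base + height` for `t mod period < width`), whose crossing times and
#' interspike intervals are known exactly by construction.
#' `synthetic_triangle_ap()` builds a piecewise-linear action potential (rise
#' over `t_rise`, fall over `t_fall`) whose amplitude and APD50 follow from
#' plane geometry.
#'
#' @param period,width,base,height square-wave parameters (ms, mV).
#' @param duration total length (ms); `dt` sample step (ms).
#' @return List with `time`, `V`, and the exact expected features.
#' @export
synthetic_square_trace <- function(period = 100, width = 2, base = -80,
                                   height = 100, duration = 1000, dt = 0.05) {
  tt <- seq(0, duration, by = dt)
  v <- base + height * as.numeric(tt %% period < width)
  # the waveform starts high, so upward crossings occur at k*period for
  # k >= 1; on the sample grid the linear interpolation of the jump between
  # the last low sample (k*period - dt) and the first high sample crosses a
  # threshold v_th at k*period - dt * (1 - (v_th - base)/height)
  k <- seq_len(floor(duration / period))
  cross <- function(v_th) k * period - dt * (1 - (v_th - base) / height)
  list(time = tt, V = v, period = period, dt = dt, base = base,
       height = height, expected_crossings = cross,
       expected_spike_times = cross(-40),
       expected_isi = rep(period, length(k) - 1))
}

#' @rdname synthetic_square_trace
#' @param t_start,v_base,v_peak,t_rise,t_fall triangle AP geometry (ms, mV).
#' @export
synthetic_triangle_ap <- function(t_start = 100, v_base = -80, v_peak = 20,
                                  t_rise = 1, t_fall = 9, duration = 300,
                                  dt = 0.01) {
  tt <- seq(0, duration, by = dt)
  v <- rep(v_base, length(tt))
  rise <- tt >= t_start & tt < t_start + t_rise
  fall <- tt >= t_start + t_rise & tt <= t_start + t_rise + t_fall
  v[rise] <- v_base + (v_peak - v_base) * (tt[rise] - t_start) / t_rise
  v[fall] <- v_peak - (v_peak - v_base) *
    (tt[fall] - t_start - t_rise) / t_fall
  amp <- v_peak - v_base
  # APD50 from the upstroke (max dV/dt = whole rising limb start) to the
  # half-repolarization point halfway down the falling limb
  apd50 <- t_rise + t_fall / 2
  list(time = tt, V = v, expected_amplitude = amp, expected_apd50 = apd50)
}
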