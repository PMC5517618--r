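# Stimulation protocols and trajectory integration.

#' Stimulation protocols
#'
#' `pulsed_protocol()` describes the standard pacing protocol: rectangular
#' current pulses of amplitude `amplitude` (default 60 pA/pF) and duration
#' `tau_stim` (default 1 ms) delivered at a basic cycle length `bcl`.
#' `constant_protocol()` describes steady-state stimulation: a current step of
#' `amplitude` pA/pF switched on at `onset` (default 20 ms) and held for the
#' rest of the run.
#'
#' @param amplitude stimulus current density (pA/pF, >= 0).
#' @param bcl basic cycle length (ms); must exceed `tau_stim`.
#' @param tau_stim pulse duration (ms).
#' @param onset time at which stimulation starts (ms).
#' @param duration total simulated time (s; default 50).
#' @param window analysis window (s, s) within the run; defaults follow the
#'   bifurcation-diagram conventions: 48-50 s for pulsed pacing, 40-50 s for
#'   constant stimulation.
#' @return An object of class `stimulus_protocol`.
#' @export
pulsed_protocol <- function(bcl, amplitude = 60, tau_stim = 1, onset = 0,
                            duration = 50, window = c(48, 50)) {
  stopifnot(amplitude >= 0, tau_stim > 0, bcl > tau_stim, onset >= 0)
  .check_window(window, duration)
  structure(list(kind = "pulsed", amplitude = amplitude, tau_stim = tau_stim,
                 bcl = bcl, onset = onset, duration = duration,
                 window = window),
            class = "stimulus_protocol")
}

#' @rdname pulsed_protocol
#' @export
constant_protocol <- function(amplitude, onset = 20, duration = 50,
                              window = c(40, 50)) {
  stopifnot(amplitude >= 0, onset >= 0)
  .check_window(window, duration)
  structure(list(kind = "constant", amplitude = amplitude, onset = onset,
                 duration = duration, window = window),
            class = "stimulus_protocol")
}

.check_window <- function(window, duration) {
  if (length(window) != 2 || window[1] < 0 || window[2] > duration ||
      window[1] >= window[2])
    stop("analysis window must be an increasing pair inside [0, duration] s")
  invisible(TRUE)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "pulsed")
    cat(sprintf("Pulsed stimulation: %g pA/pF x %g ms at BCL %g ms, %g s total\n",
                x$amplitude, x$tau_stim, x$bcl, x$duration))
  else
    cat(sprintf("Constant stimulation: %g pA/pF from t = %g ms, %g s total\n",
                x$amplitude, x$onset, x$duration))
  cat(sprintf("  analysis window: %g-%g s\n", x$window[1], x$window[2]))
  invisible(x)
}

#' Stimulus current at a time point
#'
#' @param t time (ms), scalar or vector.
#' @param protocol a [stimulus_protocol()] object.
#' @return Stimulus current density (pA/pF) at `t`.
#' @export
stimulus_current <- function(t, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"), all(t >= 0))
  if (protocol$kind == "constant")
    return(ifelse(t >= protocol$onset, protocol$amplitude, 0))
  phase <- (t - protocol$onset) %% protocol$bcl
  ifelse(t >= protocol$onset & phase < protocol$tau_stim, protocol$amplitude, 0)
}

# Piecewise-constant stimulus segments [start, end, istim] covering
# [0, duration]; the integrator is restarted at every edge.
.stim_segments <- function(protocol) {
  total <- protocol$duration * 1000
  if (protocol$kind == "constant") {
    edges <- unique(pmin(c(0, protocol$onset, total), total))
    levels <- ifelse(edges[-length(edges)] >= protocol$onset,
                     protocol$amplitude, 0)
  } else {
    starts <- seq(protocol$onset, total, by = protocol$bcl)
    edges <- sort(unique(pmin(c(0, starts, starts + protocol$tau_stim, total),
                              total)))
    mid <- edges[-length(edges)]
    levels <- stimulus_current(mid, protocol)
  }
  data.frame(start = edges[-length(edges)], end = edges[-1], istim = levels)
}

# Output grid: coarse before the analysis window, fine inside it.
.output_times <- function(protocol, dt_fine, dt_coarse) {
  total <- protocol$duration * 1000
  w0 <- protocol$window[1] * 1000
  w1 <- protocol$window[2] * 1000
  t <- c(seq(0, w0, by = dt_coarse), seq(w0, w1, by = dt_fine),
         if (w1 < total) seq(w1, total, by = dt_coarse), total)
  sort(unique(round(t, 6)))
}

.default_atol <- function(rtol) {
  typ <- c(V = 100, Cai = 1, Cass = 1, CaJSR = 2000, CaNSR = 2000,
           LTRPNCa = 70, HTRPNCa = 140,
           PO1 = 1, PO2 = 1, PC2 = 1, PRyR = 1,
           OCaL = 1, C2CaL = 1, C3CaL = 1, C4CaL = 1, I1CaL = 1, I2CaL = 1,
           I3CaL = 1,
           CNa2 = 1, CNa1 = 1, ONa = 1, IFNa = 1, I1Na = 1, I2Na = 1,
           ICNa2 = 1, ICNa3 = 1,
           Nai = 15000, Ki = 150000,
           atof = 1, itof = 1, atos = 1, itos = 1, nKs = 1, aur = 1, iur = 1,
           aKss = 1, iKss = 1, CK1 = 1, CK2 = 1, OK = 1, IK = 1)
  1e-2 * rtol * typ[.state_order]
}

.current_names <- c("INa", "ICaL", "IpCa", "INaCa", "ICab", "INab", "INaK",
                    "IKtof", "IKtos", "IK1", "IKs", "IKur", "IKss", "IKr",
                    "IClCa", "Istim", "Jup", "Jrel", "Jtr", "Jleak", "Jxfer",
                    "Jtrpn", "Itotal")

#' Integrate the myocyte model under a stimulation protocol
#'
#' Runs the whole-cell model with the stiff adaptive integrator (`lsoda`),
#' restarting at every stimulus edge so discontinuities are never stepped over.
#' Output is sampled coarsely outside the protocol's analysis window and at
#' `dt_fine` (default 0.05 ms, resolving the ~4.5 ms mouse action potential)
#' inside it.
#'
#' @param params a `myocyte_parameters` object.
#' @param protocol a [stimulus_protocol()] object.
#' @param scheme Na+ channel scheme variant: `"full"` (with slow inactivation)
#'   or `"no_slow_inact"`, or an `ina_scheme` object.
#' @param initial initial state: `"rest"` (default) computes the parameter
#'   set's resting state via [find_resting_state()], or a named state vector.
#' @param keep extra state variables to record alongside `V`, `Cai`, `CaNSR`.
#' @param record_currents if `TRUE`, record the current/flux decomposition at
#'   the output times.
#' @param dt_fine,dt_coarse output sampling steps (ms) inside/outside the
#'   analysis window.
#' @param rtol,atol_scale solver tolerances; `atol` is per-variable,
#'   `atol_scale` times a typical-magnitude scaling.
#' @return An object of class `myocyte_trace`: list with `time` (ms), `V`
#'   (mV), `Cai` (uM), `CaNSR` (uM), optional `extra` matrix and `currents`,
#'   the `protocol`, `final_state`, and solver metadata.
#' @export
run_simulation <- function(params, protocol, scheme = c("full", "no_slow_inact"),
                           initial = "rest", keep = character(),
                           record_currents = FALSE,
                           dt_fine = 0.05, dt_coarse = 1,
                           rtol = 1e-6, atol_scale = 1) {
  stopifnot(inherits(params, "myocyte_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (inherits(scheme, "ina_scheme")) scheme <- scheme$variant
  scheme <- match.arg(scheme)
  slow <- scheme == "full"
  if (identical(initial, "rest"))
    initial <- find_resting_state(params, slow_inact = slow)
  validate_state(initial)
  if (!slow) {
    if (initial[["I1Na"]] > 1e-10 || initial[["I2Na"]] > 1e-10)
      stop("no_slow_inact scheme requires zero I1Na/I2Na occupancy; ",
           "renormalize the initial state with strip_slow_inactivation()")
    initial[["I1Na"]] <- 0
    initial[["I2Na"]] <- 0
  }

  y <- initial[.state_order]
  atol <- .default_atol(rtol) * atol_scale
  times <- .output_times(protocol, dt_fine, dt_coarse)
  segs <- .stim_segments(protocol)
  keep <- setdiff(keep, c("V", "Cai", "CaNSR"))
  cols <- c("V", "Cai", "CaNSR", keep)

  out_list <- vector("list", nrow(segs))
  cur_list <- if (record_currents) vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    tt <- times[times >= segs$start[i] & times <= segs$end[i]]
    if (length(tt) == 0 || tt[1] > segs$start[i]) tt <- c(segs$start[i], tt)
    if (tt[length(tt)] < segs$end[i]) tt <- c(tt, segs$end[i])
    parms <- .parm_vector(params, istim = segs$istim[i], slow_inact = slow)
    sol <- deSolve::ode(y = y, times = tt, func = "myoburst_derivs",
                        parms = parms, dllname = "myoburst",
                        initfunc = "myoburst_initmod",
                        nout = length(.current_names),
                        outnames = .current_names,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure in segment %d at t ~ %.3f ms", i,
                   sol[nrow(sol), "time"]))
    y <- sol[nrow(sol), .state_order]
    out_list[[i]] <- sol[-nrow(sol), c("time", cols), drop = FALSE]
    if (record_currents)
      cur_list[[i]] <- sol[-nrow(sol), c("time", .current_names), drop = FALSE]
  }
  out <- do.call(rbind, out_list)
  out <- rbind(out, c(segs$end[nrow(segs)], y[cols]))
  out <- out[!duplicated(out[, "time"]), , drop = FALSE]
  out <- out[out[, "time"] %in% times, , drop = FALSE]

  # occupancy/positivity audit: explicit chain occupancies must not overrun
  # their implicit closing state by more than the solver can justify
  drift <- max(pmax(.chain_explicit_sums(y) - 1, 0))
  if (drift > 1e-6)
    stop("Markov occupancy sum drifted beyond 1 by ", format(drift))
  validate_state(y, tol = 1e-6)

  trace <- structure(list(
    time = unname(out[, "time"]),
    V = unname(out[, "V"]),
    Cai = unname(out[, "Cai"]),
    CaNSR = unname(out[, "CaNSR"]),
    extra = if (length(keep)) out[, keep, drop = FALSE],
    currents = if (record_currents) {
      cc <- do.call(rbind, cur_list)
      cc[!duplicated(cc[, "time"]) & cc[, "time"] %in% out[, "time"], ,
         drop = FALSE]
    },
    protocol = protocol,
    scheme = scheme,
    genotype = params$genotype_tag,
    eps = params$eps,
    final_state = y,
    solver = list(method = "lsoda", rtol = rtol, atol_scale = atol_scale,
                  dt_fine = dt_fine, dt_coarse = dt_coarse),
    drift = drift),
    class = "myocyte_trace")
  trace
}

.chain_explicit_sums <- function(state) {
  vapply(.markov_chains, function(m) sum(state[m]), numeric(1))
}

#' @export
print.myocyte_trace <- function(x, ...) {
  cat(sprintf("Myocyte trace: %s, %s scheme, %s stimulation (%g pA/pF)\n",
              x$genotype, x$scheme, x$protocol$kind, x$protocol$amplitude))
  cat(sprintf("  %d samples over %.3g s; V in [%.1f, %.1f] mV; Cai in [%.3g, %.3g] uM\n",
              length(x$time), max(x$time) / 1000, min(x$V), max(x$V),
              min(x$Cai), max(x$Cai)))
  invisible(x)
}

# Restrict a trace to its analysis window; returns indices.
.window_idx <- function(trace, window = NULL) {
  if (is.null(window)) window <- trace$protocol$window
  which(trace$time >= window[1] * 1000 & trace$time <= window[2] * 1000)
}
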