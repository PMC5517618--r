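# Feature extraction: spikes, interspike intervals, AP metrics, extrema
# branches, Ca2+ transient statistics, and regime classification.

#' Detect spikes as threshold crossings with hysteresis
#'
#' A spike is an upward crossing of `v_th`; after a spike, the potential must
#' fall below `reset_level` before another crossing counts, so plateau ripples
#' that re-touch the threshold are not double-counted. Crossing times are
#' refined by linear interpolation between samples.
#'
#' @param trace a `myocyte_trace`, or a list with numeric `time` (ms) and `V`.
#' @param v_th spike threshold (mV); the diagrams use -40 mV.
#' @param reset_level re-arming level (mV), strictly below `v_th`. The default
#'   -50 mV sits below the silent phases of bursting, which hover between -40
#'   and -50 mV.
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(trace, v_th = -40, reset_level = -50) {
  stopifnot(reset_level < v_th)
  tt <- trace$time; v <- trace$V
  stopifnot(length(tt) == length(v), !is.unsorted(tt))
  above <- v > v_th
  cross <- which(diff(above) == 1)  # v[i] <= v_th < v[i+1]
  if (!length(cross)) return(numeric(0))
  tc <- tt[cross] + (v_th - v[cross]) / (v[cross + 1] - v[cross]) *
    (tt[cross + 1] - tt[cross])
  # hysteresis: keep a crossing only if V dipped below reset_level since the
  # previous kept crossing
  keep <- logical(length(cross))
  last <- 0L
  for (k in seq_along(cross)) {
    # look only at samples strictly after the previous kept crossing
    seg <- if (last == 0L) seq_len(cross[k]) else ((cross[last] + 1):cross[k])
    if (any(v[seg] < reset_level)) {
      keep[k] <- TRUE
      last <- k
    }
  }
  tc[keep]
}

#' Interspike intervals within an analysis window
#'
#' @param spike_times sorted spike times (ms).
#' @param window analysis window in seconds `(start, end)`; an interval is
#'   included when its earlier spike lies in the window.
#' @return List with `isi` (ms), `mean_isi` (ms, `NA` when fewer than two
#'   spikes fall in the window) and `n_spikes`.
#' @export
interspike_intervals <- function(spike_times, window) {
  stopifnot(!is.unsorted(spike_times))
  isi_all <- diff(spike_times)
  in_win <- spike_times[-length(spike_times)] >= window[1] * 1000 &
    spike_times[-length(spike_times)] <= window[2] * 1000
  isi <- if (length(isi_all)) isi_all[in_win] else numeric(0)
  n <- sum(spike_times >= window[1] * 1000 & spike_times <= window[2] * 1000)
  list(isi = isi,
       mean_isi = if (length(isi)) mean(isi) else NA_real_,
       n_spikes = n)
}

#' Per-beat action potential amplitude and duration
#'
#' For each spike, the amplitude is the AP peak minus the preceding diastolic
#' minimum, and APD50 is measured from the upstroke (the point of maximal
#' dV/dt before the peak) until the potential first repolarizes below
#' `peak - 0.5 * amplitude`. APs truncated by the end of the trace are
#' omitted.
#'
#' @param trace a `myocyte_trace` (or list with `time`, `V`).
#' @param spike_times spike times from [detect_spikes()].
#' @return Data frame with one row per complete AP: `t_spike`, `t_peak`,
#'   `v_peak`, `v_diastolic`, `amplitude` (mV), `apd50` (ms).
#' @export
ap_metrics <- function(trace, spike_times) {
  tt <- trace$time; v <- trace$V
  if (!length(spike_times))
    return(data.frame(t_spike = numeric(0), t_peak = numeric(0),
                      v_peak = numeric(0), v_diastolic = numeric(0),
                      amplitude = numeric(0), apd50 = numeric(0)))
  bounds <- c(tt[1], spike_times, tt[length(tt)])
  out <- vector("list", length(spike_times))
  for (k in seq_along(spike_times)) {
    i0 <- findInterval(bounds[k], tt)          # previous spike (or start)
    i1 <- findInterval(spike_times[k], tt)     # this upstroke crossing
    i2 <- findInterval(bounds[k + 2], tt)      # next spike (or end)
    if (i1 <= i0 || i2 <= i1) next
    seg_peak <- i1:i2
    ipk <- seg_peak[which.max(v[seg_peak])]
    vpk <- v[ipk]
    vdia <- min(v[i0:i1])
    amp <- vpk - vdia
    # upstroke: max dV/dt on the rising limb before the peak
    rise <- max(i0, ipk - 400):ipk
    if (length(rise) < 2) next
    dv <- diff(v[rise]) / diff(tt[rise])
    iup <- rise[which.max(dv)]
    half <- vpk - 0.5 * amp
    post <- ipk:i2
    rep_idx <- post[which(v[post] < half)[1]]
    if (is.na(rep_idx)) next                   # truncated AP
    # refine the crossing linearly
    j <- rep_idx
    t50 <- if (j > ipk && v[j - 1] >= half)
      tt[j - 1] + (v[j - 1] - half) / (v[j - 1] - v[j]) * (tt[j] - tt[j - 1])
    else tt[j]
    out[[k]] <- data.frame(t_spike = spike_times[k], t_peak = tt[ipk],
                           v_peak = vpk, v_diastolic = vdia, amplitude = amp,
                           apd50 = t50 - tt[iup])
  }
  rows <- out[!vapply(out, is.null, logical(1))]
  if (!length(rows))
    return(ap_metrics(trace, numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Local-extrema branches of a sampled series
#'
#' Collects strict local maxima and minima inside the window and clusters each
#' set in one dimension: sorted values are split where consecutive values
#' differ by more than `tol` (absolute, or relative to the median magnitude
#' when `relative = TRUE`). The per-cluster means are the branch values that
#' bifurcation diagrams plot.
#'
#' @param time sample times (ms).
#' @param series sampled values.
#' @param window analysis window (s, s).
#' @param tol clustering tolerance (same units as `series`, or a fraction).
#' @param relative interpret `tol` as a fraction of the median magnitude.
#' @return List with `max_branches`, `min_branches` (cluster means, sorted),
#'   `maxima`, `minima` (raw extreme values), and counts per branch.
#' @export
extrema_branches <- function(time, series, window, tol = 0.5,
                             relative = FALSE) {
  i <- which(time >= window[1] * 1000 & time <= window[2] * 1000)
  x <- series[i]
  if (length(x) < 3)
    return(list(max_branches = numeric(0), min_branches = numeric(0),
                maxima = numeric(0), minima = numeric(0),
                max_counts = integer(0), min_counts = integer(0)))
  d <- diff(x)
  # collapse zero differences so plateaus yield single extrema
  sgn <- sign(d)
  sgn[sgn == 0] <- NA
  sgn <- .locf(sgn)
  turn <- diff(sgn)
  maxima <- x[which(turn == -2) + 1]
  minima <- x[which(turn == 2) + 1]
  # a side with no interior turning points (constant or monotone series)
  # degenerates to a single branch at the corresponding end value
  if (!length(maxima)) maxima <- max(x)
  if (!length(minima)) minima <- min(x)
  cl_max <- .cluster1d(maxima, tol, relative)
  cl_min <- .cluster1d(minima, tol, relative)
  list(max_branches = cl_max$centers, min_branches = cl_min$centers,
       maxima = maxima, minima = minima,
       max_counts = cl_max$counts, min_counts = cl_min$counts)
}

# last-observation-carried-forward for the sign vector (no zoo dependency)
.locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cumsum(ok)
  idx[idx == 0] <- 1
  x[ok][idx]
}

.cluster1d <- function(x, tol, relative = FALSE) {
  if (!length(x)) return(list(centers = numeric(0), counts = integer(0)))
  if (relative) tol <- tol * max(abs(stats::median(x)), 1e-12)
  xs <- sort(x)
  grp <- cumsum(c(1, diff(xs) > tol))
  centers <- as.numeric(tapply(xs, grp, mean))
  counts <- as.integer(table(grp))
  list(centers = centers, counts = counts)
}

#' Ca2+ transient statistics
#'
#' Extrema branches of the intracellular Ca2+ series (relative clustering
#' tolerance, default 2%) plus per-beat transient amplitudes (each local peak
#' minus the preceding diastolic minimum).
#'
#' @param trace a `myocyte_trace`.
#' @param window analysis window (s, s); defaults to the protocol's.
#' @param tol relative clustering tolerance for Ca branches.
#' @return List with the [extrema_branches()] fields plus `amplitudes`,
#'   `diastolic` (uM) and `regime`, the Ca-transient regime label
#'   (`"steady"`, `"periodic"`, `"alternans"` or `"irregular"`).
#' @export
ca_transient_stats <- function(trace, window = NULL, tol = 0.02) {
  if (is.null(window)) window <- trace$protocol$window
  br <- extrema_branches(trace$time, trace$Cai, window, tol = tol,
                         relative = TRUE)
  i <- which(trace$time >= window[1] * 1000 & trace$time <= window[2] * 1000)
  ca <- trace$Cai[i]; tt <- trace$time[i]
  d <- diff(ca)
  sgn <- .locf(replace(sign(d), sign(d) == 0, NA))
  turn <- diff(sgn)
  ipk <- which(turn == -2) + 1
  imn <- which(turn == 2) + 1
  amps <- vapply(ipk, function(j) {
    prev <- imn[imn < j]
    base <- if (length(prev)) ca[max(prev)] else ca[1]
    ca[j] - base
  }, numeric(1))
  span <- max(ca) - min(ca)
  level <- max(abs(ca))
  nb <- length(br$max_branches)
  sig <- br$max_counts >= 3  # branches supported by >= 3 beats
  nsig <- sum(sig)
  regime <-
    if (span < 0.02 * level) "steady"
    else if (nb == 1 || nsig <= 1) "periodic"
    else if (nsig == 2 && nb == 2) "alternans"
    else "irregular"
  c(br, list(amplitudes = amps, diastolic = min(ca), regime = regime))
}

#' Extract the full feature set of a trace
#'
#' Convenience wrapper: spike detection, interspike intervals, AP metrics,
#' voltage and Ca2+ extrema branches, and the regime classification.
#'
#' @param trace a `myocyte_trace`.
#' @param window analysis window (s, s); defaults to the protocol's.
#' @param v_th,reset_level spike detection thresholds (mV).
#' @param v_tol voltage branch clustering tolerance (mV).
#' @param ca_tol relative Ca branch clustering tolerance.
#' @return Object of class `myocyte_features`.
#' @export
extract_features <- function(trace, window = NULL, v_th = -40,
                             reset_level = -50, v_tol = 0.5, ca_tol = 0.02) {
  if (is.null(window)) window <- trace$protocol$window
  spikes <- detect_spikes(trace, v_th = v_th, reset_level = reset_level)
  spikes_w <- spikes[spikes >= window[1] * 1000 & spikes <= window[2] * 1000]
  isi <- interspike_intervals(spikes, window)
  ap <- ap_metrics(trace, spikes_w)
  vbr <- extrema_branches(trace$time, trace$V, window, tol = v_tol)
  ca <- ca_transient_stats(trace, window, tol = ca_tol)
  fs <- structure(list(
    window = window, spike_times = spikes_w, isi = isi$isi,
    mean_isi = isi$mean_isi, n_spikes = isi$n_spikes, ap = ap,
    v_branches = vbr, ca = ca,
    thresholds = list(v_th = v_th, reset_level = reset_level,
                      v_tol = v_tol, ca_tol = ca_tol)),
    class = "myocyte_features")
  fs$regime <- classify_regime(fs)
  fs
}

#' Classify the dynamical regime of a window of activity
#'
#' Rules, applied to a full analysis window:
#' \itemize{
#'   \item \emph{quiescent}: no spikes and the potential settles below -60 mV;
#'   \item \emph{depolarized-block}: no spikes, settling above -55 mV;
#'   \item \emph{bursting}: the interspike-interval distribution is bimodal
#'     with a gap factor of at least `gap_factor` (largest ISI cluster at
#'     least `gap_factor` times the median ISI) and at least 2 spikes between
#'     gaps;
#'   \item \emph{alternans}: exactly two interleaved AP-amplitude or ISI
#'     branches, each with at least `min_events` events;
#'   \item \emph{spiking}: spikes with a single ISI cluster and a single
#'     amplitude branch;
#'   \item \emph{irregular}: anything else (reported, never silently forced).
#' }
#'
#' @param features a `myocyte_features` object from [extract_features()].
#' @param gap_factor bimodality gap factor for bursting.
#' @param min_events minimum events per branch for alternans.
#' @return Character regime label.
#' @export
classify_regime <- function(features, gap_factor = 3, min_events = 5) {
  vbr <- features$v_branches
  n <- features$n_spikes
  if (n == 0) {
    vmax <- suppressWarnings(max(vbr$max_branches))
    vmin <- suppressWarnings(min(vbr$min_branches))
    if (!is.finite(vmax)) return("irregular")
    span <- vmax - vmin
    if (span < 2 && vmin < -60) return("quiescent")
    if (span < 2 && vmin > -55) return("depolarized-block")
    if (vmin < -60) return("quiescent")       # subthreshold oscillation
    if (vmin > -55) return("depolarized-block")
    return("irregular")
  }
  isi <- features$isi
  if (length(isi) >= 3) {
    med <- stats::median(isi)
    gaps <- isi >= gap_factor * med
    if (any(gaps) && med > 0) {
      # spikes between consecutive gaps
      runs <- rle(!gaps)
      spikes_per_burst <- runs$lengths[runs$values] + 1
      if (any(spikes_per_burst >= 2)) return("bursting")
    }
  }
  amp <- features$ap$amplitude
  acl <- .cluster1d(amp, tol = 0.02, relative = TRUE)
  icl <- .cluster1d(isi, tol = 0.05, relative = TRUE)
  interleaved <- function(x, centers, tol) {
    if (length(centers) != 2) return(FALSE)
    lab <- vapply(x, function(z) which.min(abs(z - centers)), integer(1))
    mean(diff(lab) != 0) > 0.8
  }
  if ((length(acl$centers) == 2 && all(acl$counts >= min_events) &&
       interleaved(amp, acl$centers)) ||
      (length(icl$centers) == 2 && all(icl$counts >= min_events) &&
       interleaved(isi, icl$centers)))
    return("alternans")
  if (length(acl$centers) <= 1 && length(icl$centers) <= 1) return("spiking")
  if (n <= 3) return("spiking")   # too few events to subdivide
  "irregular"
}

#' @export
print.myocyte_features <- function(x, ...) {
  cat(sprintf("Features over %g-%g s: regime '%s', %d spikes, mean ISI %s ms\n",
              x$window[1], x$window[2], x$regime, x$n_spikes,
              if (is.na(x$mean_isi)) "-" else sprintf("%.1f", x$mean_isi)))
  cat(sprintf("  V branches: %d max / %d min; Ca regime '%s' (%d branches)\n",
              length(x$v_branches$max_branches),
              length(x$v_branches$min_branches),
              x$ca$regime, length(x$ca$max_branches)))
  invisible(x)
}
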