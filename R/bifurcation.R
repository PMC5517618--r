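# Sweep engine over BCL, constant stimulus current, and the WT->TG
# interpolation parameter; threshold localization by bisection.

.point_setup <- function(control, value, base_params, protocol_template,
                         schedule = "linear", exp_param = NULL) {
  params <- base_params
  protocol <- protocol_template
  switch(control,
    istim = {
      protocol <- constant_protocol(value, onset = protocol_template$onset,
                                    duration = protocol_template$duration,
                                    window = protocol_template$window)
    },
    bcl = {
      protocol <- pulsed_protocol(value,
                                  amplitude = protocol_template$amplitude,
                                  tau_stim = protocol_template$tau_stim,
                                  onset = protocol_template$onset,
                                  duration = protocol_template$duration,
                                  window = protocol_template$window)
    },
    epsilon = {
      params <- interpolate_parameters(value, schedule = schedule,
                                       exp_param = exp_param)
    },
    stop("unknown control parameter: ", control))
  list(params = params, protocol = protocol)
}

.evaluate_point <- function(control, value, base_params, protocol_template,
                            scheme, schedule, exp_param, dt_fine, rtol, ...) {
  setup <- .point_setup(control, value, base_params, protocol_template,
                        schedule, exp_param)
  trace <- run_simulation(setup$params, setup$protocol, scheme = scheme,
                          initial = "rest", dt_fine = dt_fine, rtol = rtol,
                          ...)
  extract_features(trace)
}

#' Brute-force bifurcation sweep
#'
#' Runs one cold-start simulation per grid value of the control parameter
#' (`"istim"`: constant stimulus amplitude in pA/pF; `"bcl"`: pacing cycle
#' length in ms; `"epsilon"`: the WT-to-TG interpolation coordinate), extracts
#' features, and assembles an orbit diagram with a regime label per point and
#' the list of transitions where consecutive labels differ.
#'
#' @param control `"istim"`, `"bcl"` or `"epsilon"`.
#' @param grid strictly monotone numeric grid of control values.
#' @param base_params `myocyte_parameters`; for `"epsilon"` the WT/TG presets
#'   are interpolated internally and `base_params` is ignored.
#' @param protocol_template protocol whose non-control fields (amplitude,
#'   windows, duration) are reused at every point. For `"epsilon"` this is the
#'   constant-current protocol to apply at each value.
#' @param scheme Na+ scheme variant, as in [run_simulation()].
#' @param schedule,exp_param interpolation schedule for `"epsilon"` sweeps.
#' @param dt_fine,rtol solver/output settings forwarded to [run_simulation()].
#' @param ... further arguments to [run_simulation()].
#' @return Object of class `bifurcation_diagram`: list with `control`, `grid`,
#'   `features` (per point), `regimes`, `ca_regimes`, `transitions` and
#'   `failed` (solver-failure flags; failed points carry `NA` regimes).
#' @export
bifurcation_sweep <- function(control = c("istim", "bcl", "epsilon"), grid,
                              base_params = make_parameters("wt"),
                              protocol_template = constant_protocol(0),
                              scheme = "full", schedule = "linear",
                              exp_param = NULL, dt_fine = 0.1, rtol = 1e-6,
                              ...) {
  control <- match.arg(control)
  if (!length(grid)) stop("empty control grid")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  .check_grid_range(control, grid)
  feats <- vector("list", length(grid))
  failed <- logical(length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch(
      .evaluate_point(control, grid[i], base_params, protocol_template,
                      scheme, schedule, exp_param, dt_fine, rtol, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      warning(sprintf("sweep point %s = %g failed: %s", control, grid[i],
                      conditionMessage(res)))
    } else feats[[i]] <- res
  }
  regimes <- vapply(feats, function(f) if (is.null(f)) NA_character_ else
    f$regime, character(1))
  ca_regimes <- vapply(feats, function(f) if (is.null(f)) NA_character_ else
    f$ca$regime, character(1))
  structure(list(control = control, grid = grid, features = feats,
                 regimes = regimes, ca_regimes = ca_regimes,
                 transitions = .transitions(grid, regimes),
                 ca_transitions = .transitions(grid, ca_regimes),
                 failed = failed, scheme = scheme,
                 genotype = base_params$genotype_tag),
            class = "bifurcation_diagram")
}

.check_grid_range <- function(control, grid) {
  rng <- switch(control, istim = c(0, 1), bcl = c(30, 150), epsilon = c(0, 1))
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf("%s grid must lie in [%g, %g]", control, rng[1], rng[2]))
  invisible(TRUE)
}

.transitions <- function(grid, labels) {
  ok <- !is.na(labels)
  g <- grid[ok]; l <- labels[ok]
  if (length(l) < 2)
    return(data.frame(control = numeric(0), from = character(0),
                      to = character(0)))
  ch <- which(l[-1] != l[-length(l)])
  data.frame(control = (g[ch] + g[ch + 1]) / 2, from = l[ch], to = l[ch + 1],
             stringsAsFactors = FALSE)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over %s (%d points, %s, %s scheme)\n",
              x$control, length(x$grid), x$genotype, x$scheme))
  r <- rle(x$regimes)
  cat("  regimes:", paste(sprintf("%s x%d", r$values, r$lengths),
                          collapse = " | "), "\n")
  if (nrow(x$transitions)) {
    cat("  transitions:\n")
    for (i in seq_len(nrow(x$transitions)))
      cat(sprintf("    %s -> %s at %s = %g\n", x$transitions$from[i],
                  x$transitions$to[i], x$control, x$transitions$control[i]))
  }
  invisible(x)
}

#' Convert a diagram to a tidy per-branch table
#'
#' @param x a `bifurcation_diagram`.
#' @param ... unused.
#' @return Data frame with one row per grid point x observable x branch:
#'   columns `control`, `value`, `observable` (`Vmax`, `Vmin`, `Camax`,
#'   `Camin`, `ISI`), `branch`, `regime`.
#' @export
as.data.frame.bifurcation_diagram <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$grid)) {
    f <- x$features[[i]]
    if (is.null(f)) next
    add <- function(obs, vals) {
      if (!length(vals)) return(NULL)
      data.frame(control = x$grid[i], observable = obs,
                 branch = seq_along(vals), value = vals,
                 regime = x$regimes[i], stringsAsFactors = FALSE)
    }
    rows <- c(rows, list(
      add("Vmax", f$v_branches$max_branches),
      add("Vmin", f$v_branches$min_branches),
      add("Camax", f$ca$max_branches),
      add("Camin", f$ca$min_branches),
      add("ISI", if (is.na(f$mean_isi)) numeric(0) else f$mean_isi)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Locate a regime transition by bisection
#'
#' Bisects the control parameter between two values that classify to the
#' `from` and `to` regimes of a transition until the bracket is narrower than
#' `tol`; returns the midpoint. Classification at each probe uses a full
#' cold-start simulation.
#'
#' @param control,base_params,protocol_template,scheme,schedule,exp_param,...
#'   as in [bifurcation_sweep()].
#' @param bracket numeric length-2: control values bracketing the transition.
#' @param predicate function mapping a regime label (character) to `TRUE` when
#'   the point lies on the far (`to`) side of the transition. Supplying a
#'   predicate rather than a single target label keeps the bisection
#'   well-defined when intermediate regimes intervene.
#' @param tol bracket width at which to stop (default 0.005 for current, use
#'   0.01 for epsilon).
#' @param classify_fn optional function mapping a control value to a regime
#'   label, replacing the default simulate-and-classify evaluation (used for
#'   cheap classifiers and testing).
#' @return The transition control value (bracket midpoint), with attribute
#'   `bracket` and `evaluations` (a data frame of probed points and labels).
#' @export
find_threshold <- function(control, bracket, predicate, tol = 0.005,
                           base_params = make_parameters("wt"),
                           protocol_template = constant_protocol(0),
                           scheme = "full", schedule = "linear",
                           exp_param = NULL, classify_fn = NULL, ...) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  classify <- if (!is.null(classify_fn)) classify_fn else function(v) {
    f <- .evaluate_point(control, v, base_params, protocol_template, scheme,
                         schedule, exp_param, dt_fine = 0.1, rtol = 1e-6, ...)
    f$regime
  }
  evals <- data.frame(control = numeric(0), regime = character(0))
  note <- function(v, r) evals[nrow(evals) + 1, ] <<- list(v, r)
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- classify(lo); note(lo, rlo)
  rhi <- classify(hi); note(hi, rhi)
  if (predicate(rlo) || !predicate(rhi))
    stop(sprintf(
      "bracket endpoints do not straddle the transition: %g -> '%s', %g -> '%s'",
      lo, rlo, hi, rhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    rmid <- classify(mid); note(mid, rmid)
    if (predicate(rmid)) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), evaluations = evals)
}

#' Compare voltage- and Ca2+-based transition locations
#'
#' Given two diagrams on a shared grid (typically the same sweep read through
#' the AP regime labels and through the Ca-transient regime labels), tabulates
#' every transition of each observable and reports where they differ.
#'
#' @param diagram a `bifurcation_diagram`.
#' @return List with `ap` and `ca` transition tables and `split`, the rows
#'   where one observable changes regime and the other does not (within half a
#'   grid step).
#' @export
ca_ap_threshold_split <- function(diagram) {
  ap <- diagram$transitions
  ca <- diagram$ca_transitions
  if (!nrow(ap) && !nrow(ca))
    return(list(ap = ap, ca = ca, split = ap))
  step <- if (length(diagram$grid) > 1) stats::median(diff(diagram$grid)) else 0
  near <- function(x, ys) length(ys) && any(abs(x - ys) <= step / 2 + 1e-12)
  only <- function(tab, other, obs) {
    sub <- tab[!vapply(tab$control, near, logical(1), other$control), ,
               drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub$observable <- obs
    sub
  }
  split <- rbind(only(ap, ca, "AP"), only(ca, ap, "Ca"))
  if (is.null(split))
    split <- cbind(ap[0, , drop = FALSE], observable = character(0))
  rownames(split) <- NULL
  list(ap = ap, ca = ca, split = split)
}
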