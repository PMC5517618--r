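# The 9-state fast Na+ current Markov scheme and its variant without the slow
# inactivated states I1/I2.

#' Fast Na+ channel Markov scheme
#'
#' The full scheme has three closed states (CNa3-CNa1), one open state (ONa),
#' one fast inactivated state (IFNa), two closed-inactivated states
#' (ICNa2/ICNa3) and two slow inactivated states (I1Na/I2Na). The
#' `no_slow_inact` variant removes I1Na/I2Na together with every edge incident
#' to them; it is the scheme used to demonstrate that slow inactivation drives
#' bursting.
#'
#' @param variant `"full"` or `"no_slow_inact"`.
#' @return An object of class `ina_scheme`: list with `variant`, `states`,
#'   `edges` (data frame `from`, `to`, `rate`) and `GNa` (mS/uF).
#' @export
ina_scheme <- function(variant = c("full", "no_slow_inact")) {
  variant <- match.arg(variant)
  topo <- .load_presets()$ina_scheme
  edges <- as.data.frame(topo$edges, stringsAsFactors = FALSE)
  states <- topo$states_full
  if (variant == "no_slow_inact") {
    slow <- c("I1Na", "I2Na")
    edges <- edges[!(edges$from %in% slow | edges$to %in% slow), ]
    states <- topo$states_no_slow_inact
    rownames(edges) <- NULL
  }
  structure(list(variant = variant, states = states, edges = edges,
                 GNa = .load_presets()$wt$GNa),
            class = "ina_scheme")
}

#' @export
print.ina_scheme <- function(x, ...) {
  cat(sprintf("Fast Na+ current Markov scheme (%s): %d states, %d directed edges\n",
              x$variant, length(x$states), nrow(x$edges)))
  invisible(x)
}

#' Voltage-dependent transition rates of the Na+ channel scheme
#'
#' @param V membrane potential (mV), finite scalar.
#' @param scheme an [ina_scheme()] object.
#' @return Data frame `from`, `to`, `rate` (name), `value` (ms^-1), one row per
#'   directed edge of the scheme; edges absent from the variant are absent.
#' @export
ina_rates <- function(V, scheme = ina_scheme()) {
  stopifnot(inherits(scheme, "ina_scheme"))
  vals <- .ina_rate_values(V)
  out <- scheme$edges
  out$value <- unname(vals[out$rate])
  out
}

#' Master-equation derivatives of the Na+ channel occupancies
#'
#' @param occ named occupancy vector over `scheme$states`; must sum to 1.
#' @param V membrane potential (mV).
#' @param scheme an [ina_scheme()] object.
#' @return Named derivative vector over the scheme's states (sums to zero).
#' @export
ina_occupancy_derivatives <- function(occ, V, scheme = ina_scheme()) {
  stopifnot(inherits(scheme, "ina_scheme"))
  if (length(occ) != length(scheme$states) ||
      !setequal(names(occ), scheme$states))
    stop("occupancy vector must be named over the scheme's ",
         length(scheme$states), " states")
  if (abs(sum(occ) - 1) > 1e-6)
    stop("occupancies must sum to 1 (got ", format(sum(occ)), ")")
  rates <- ina_rates(V, scheme)
  d <- setNames(numeric(length(scheme$states)), scheme$states)
  flow <- rates$value * occ[rates$from]
  for (i in seq_len(nrow(rates))) {
    d[[rates$from[i]]] <- d[[rates$from[i]]] - flow[i]
    d[[rates$to[i]]] <- d[[rates$to[i]]] + flow[i]
  }
  d
}

#' Fast Na+ current from the open-state occupancy
#'
#' Ohmic form `GNa * O * (V - ENa)` with the Nernst-type reversal computed from
#' the instantaneous Na+ (with a small K+ admixture) gradient.
#'
#' @param V membrane potential (mV).
#' @param O_occupancy open-state occupancy in [0, 1].
#' @param Nai intracellular Na+ (uM).
#' @param params a `myocyte_parameters` object.
#' @param Ki intracellular K+ (uM), defaulting to the reference quiescent value.
#' @return Current density (pA/pF).
#' @export
ina_current <- function(V, O_occupancy, Nai, params,
                        Ki = initial_state()[["Ki"]]) {
  stopifnot(O_occupancy >= 0, O_occupancy <= 1)
  p <- params$constants
  RTF <- p[["Rgas"]] * p[["TK"]] / p[["F"]]
  ENa <- RTF * log((0.9 * p[["Nao"]] + 0.1 * p[["Ko"]]) /
                     (0.9 * Nai + 0.1 * Ki))
  unname(p[["GNa"]] * O_occupancy * (V - ENa))
}

#' Remove slow inactivation from the Na+ scheme
#'
#' Returns the variant without I1/I2. When a state vector is supplied, the
#' occupancy mass currently in I1/I2 is reassigned to the fast inactivated
#' state IF (their nearest neighbor), so total occupancy is preserved at the
#' point of switching; fresh simulations should instead start from the
#' variant's own resting state.
#'
#' @param scheme a full-variant [ina_scheme()].
#' @param state optional full model state to renormalize alongside.
#' @param reassign_to state receiving the I1/I2 mass (default `"IFNa"`).
#' @return The stripped scheme, or (if `state` given) a list with elements
#'   `scheme` and `state`.
#' @export
strip_slow_inactivation <- function(scheme = ina_scheme("full"), state = NULL,
                                    reassign_to = "IFNa") {
  stopifnot(inherits(scheme, "ina_scheme"))
  if (scheme$variant != "full")
    stop("scheme already has slow inactivation removed")
  stripped <- ina_scheme("no_slow_inact")
  stripped$GNa <- scheme$GNa
  if (is.null(state)) return(stripped)
  stopifnot(reassign_to %in% stripped$states)
  state[[reassign_to]] <- state[[reassign_to]] + state[["I1Na"]] + state[["I2Na"]]
  state[["I1Na"]] <- 0
  state[["I2Na"]] <- 0
  list(scheme = stripped, state = state)
}
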