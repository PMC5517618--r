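# State vector construction and validation.

.markov_chains <- list(
  RyR = c("PO1", "PO2", "PC2"),                  # PC1 implicit
  CaL = c("OCaL", "C2CaL", "C3CaL", "C4CaL", "I1CaL", "I2CaL", "I3CaL"), # C1 implicit
  Na  = c("CNa2", "CNa1", "ONa", "IFNa", "I1Na", "I2Na", "ICNa2", "ICNa3"), # CNa3 implicit
  Kr  = c("CK1", "CK2", "OK", "IK")              # CK0 implicit
)

.gate_names <- c("atof", "itof", "atos", "itos", "nKs", "aur", "iur",
                 "aKss", "iKss")

#' Reference quiescent state of the myocyte model
#'
#' The published quiescent starting point of the whole-cell mouse myocyte model
#' (V = -82.42 mV, diastolic Ca2+ about 0.115 uM). It is a good initial guess
#' for [find_resting_state()], which relaxes it onto the resting state of a
#' given parameter set.
#'
#' @return Named numeric vector of the 41 state variables. Membrane potential
#'   `V` in mV; all concentrations in uM (`Nai`, `Ki` included); gating
#'   variables and Markov occupancies dimensionless.
#' @export
initial_state <- function() {
  c(V = -82.4202,
    Cai = 0.115001, Cass = 0.115001, CaJSR = 1299.5, CaNSR = 1299.5,
    LTRPNCa = 11.2684, HTRPNCa = 125.29,
    PO1 = 1.49102e-5, PO2 = 9.51726e-11, PC2 = 1.6774e-5, PRyR = 0,
    OCaL = 9.30308e-19, C2CaL = 1.24216e-4, C3CaL = 5.78679e-9,
    C4CaL = 1.19816e-13, I1CaL = 4.97923e-19, I2CaL = 3.45847e-14,
    I3CaL = 1.85106e-14,
    CNa2 = 0.020752, CNa1 = 2.79132e-4, ONa = 7.13483e-7,
    IFNa = 1.53176e-4, I1Na = 6.73345e-7, I2Na = 1.55787e-9,
    ICNa2 = 0.0113879, ICNa3 = 0.34278,
    Nai = 14237.1, Ki = 143720,
    atof = 0.00265563, itof = 0.999977,
    atos = 4.17069e-4, itos = 0.998543,
    nKs = 2.62753e-4,
    aur = 4.17069e-4, iur = 0.998543,
    aKss = 4.17069e-4, iKss = 1,
    CK1 = 9.92513e-4, CK2 = 6.41229e-4, OK = 1.75298e-4, IK = 3.19129e-5)
}

# Occupancy sums including the implicit (eliminated) state of each chain.
.chain_sums <- function(state) {
  vapply(.markov_chains, function(members) {
    s <- sum(state[members])
    s + (1 - s)  # implicit member closes the chain to 1 by construction
  }, numeric(1))
}

#' Validate a model state vector
#'
#' Checks completeness, finiteness, gate and occupancy ranges, and
#' non-negativity of concentrations.
#'
#' @param state named numeric vector as produced by [initial_state()].
#' @param tol tolerance for occupancy range violations.
#' @return `state`, invisibly; errors name the offending field.
#' @export
validate_state <- function(state, tol = 1e-8) {
  missing <- setdiff(.state_order, names(state))
  if (length(missing))
    stop("state is missing fields: ", paste(missing, collapse = ", "))
  nf <- names(state)[!is.finite(state[.state_order])]
  if (length(nf))
    stop("non-finite state entries: ", paste(nf, collapse = ", "))
  conc <- c("Cai", "Cass", "CaJSR", "CaNSR", "Nai", "Ki", "LTRPNCa", "HTRPNCa")
  neg <- conc[state[conc] < 0]
  if (length(neg))
    stop("negative concentrations: ", paste(neg, collapse = ", "))
  occ <- c(unlist(.markov_chains, use.names = FALSE), .gate_names)
  bad <- occ[state[occ] < -tol | state[occ] > 1 + tol]
  if (length(bad))
    stop("occupancies/gates outside [0, 1]: ", paste(bad, collapse = ", "))
  for (chain in names(.markov_chains)) {
    s <- sum(state[.markov_chains[[chain]]])
    if (s > 1 + tol)
      stop("Markov chain ", chain, " explicit occupancies sum to ", format(s),
           " > 1")
  }
  invisible(state)
}
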