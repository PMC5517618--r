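# Reference R implementation of the model right-hand side.
#
# The compiled RHS in src/model.c is what the integrator runs; this pure-R
# mirror exposes the currents, fluxes and derivatives for inspection, feeds the
# user-facing compute_* operations, and lets the test suite cross-check the two
# transcriptions against each other on arbitrary states.

# Voltage-dependent transition rates of the fast Na+ channel Markov scheme.
.ina_rate_values <- function(V) {
  if (!is.finite(V)) stop("non-finite membrane potential V")
  a13 <- 3.802 / (0.1027 * exp(-(V + 2.5) / 12) + 0.25 * exp(-(V + 2.5) / 150))
  b13 <- 0.22 * exp(-(V - 7.5) / 20.3)
  a3 <- 7e-7 * exp(-(V + 7) / 7.7)
  b3 <- 0.0084 + 2e-5 * (V + 7)
  a2 <- 1 / (0.188495 * exp(-(V + 7) / 16.6) + 0.393956)
  c(alpha_Na11 = 3.802 / (0.1027 * exp(-(V + 2.5) / 17) + 0.20 * exp(-(V + 2.5) / 150)),
    alpha_Na12 = 3.802 / (0.1027 * exp(-(V + 2.5) / 15) + 0.23 * exp(-(V + 2.5) / 150)),
    alpha_Na13 = a13,
    beta_Na11 = 0.1917 * exp(-(V + 2.5) / 20.3),
    beta_Na12 = 0.20 * exp(-(V - 2.5) / 20.3),
    beta_Na13 = b13,
    alpha_Na3 = a3, beta_Na3 = b3,
    alpha_Na2 = a2, beta_Na2 = a13 * a2 * a3 / (b13 * b3),
    alpha_Na4 = a2 / 1000, beta_Na4 = a3,
    alpha_Na5 = a2 / 95000, beta_Na5 = a3 / 50)
}

.eval_model <- function(state, params, istim = 0, slow_inact = TRUE) {
  validate_state(state, tol = 1e-6)
  p <- as.list(params$constants)
  s <- as.list(state)
  RTF <- p$Rgas * p$TK / p$F
  VFRT <- s$V / RTF

  ENa <- RTF * log((0.9 * p$Nao + 0.1 * p$Ko) / (0.9 * s$Nai + 0.1 * s$Ki))
  EK <- RTF * log(p$Ko / s$Ki)
  EKr <- RTF * log((0.98 * p$Ko + 0.02 * p$Nao) / (0.98 * s$Ki + 0.02 * s$Nai))
  ECaN <- 0.5 * RTF * log(p$Cao / s$Cai)

  ## fast Na+ current
  r <- as.list(.ina_rate_values(s$V))
  if (!slow_inact)
    r[c("alpha_Na4", "beta_Na4", "alpha_Na5", "beta_Na5")] <- list(0, 0, 0, 0)
  CNa3 <- 1 - (s$CNa2 + s$CNa1 + s$ONa + s$IFNa + s$I1Na + s$I2Na +
                 s$ICNa2 + s$ICNa3)
  INa <- p$GNa * s$ONa * (s$V - ENa)
  dNa <- c(
    CNa2 = r$alpha_Na11 * CNa3 + r$beta_Na12 * s$CNa1 + r$alpha_Na3 * s$ICNa2 -
      (r$beta_Na11 + r$alpha_Na12 + r$beta_Na3) * s$CNa2,
    CNa1 = r$alpha_Na12 * s$CNa2 + r$beta_Na13 * s$ONa + r$alpha_Na3 * s$IFNa -
      (r$beta_Na12 + r$alpha_Na13 + r$beta_Na3) * s$CNa1,
    ONa = r$alpha_Na13 * s$CNa1 + r$beta_Na2 * s$IFNa -
      (r$beta_Na13 + r$alpha_Na2) * s$ONa,
    IFNa = r$alpha_Na2 * s$ONa + r$beta_Na3 * s$CNa1 + r$beta_Na4 * s$I1Na +
      r$alpha_Na12 * s$ICNa2 -
      (r$beta_Na2 + r$alpha_Na3 + r$alpha_Na4 + r$beta_Na12) * s$IFNa,
    I1Na = r$alpha_Na4 * s$IFNa + r$beta_Na5 * s$I2Na -
      (r$beta_Na4 + r$alpha_Na5) * s$I1Na,
    I2Na = r$alpha_Na5 * s$I1Na - r$beta_Na5 * s$I2Na,
    ICNa2 = r$alpha_Na11 * s$ICNa3 + r$beta_Na12 * s$IFNa + r$beta_Na3 * s$CNa2 -
      (r$beta_Na11 + r$alpha_Na12 + r$alpha_Na3) * s$ICNa2,
    ICNa3 = r$beta_Na11 * s$ICNa2 + r$beta_Na3 * CNa3 -
      (r$alpha_Na11 + r$alpha_Na3) * s$ICNa3)

  ## L-type Ca2+ current
  aL <- 0.4 * exp((s$V + 12) / 10) *
    (1 + 0.7 * exp(-(s$V + 40)^2 / 10) - 0.75 * exp(-(s$V + 20)^2 / 400)) /
    (1 + 0.12 * exp((s$V + 12) / 10))
  bL <- 0.05 * exp(-(s$V + 12) / 13)
  gL <- p$Kpc_max * s$Cass / (p$Kpc_half + s$Cass)
  Kpcf <- 13 * (1 - exp(-(s$V + 14.5)^2 / 100))
  C1L <- 1 - (s$OCaL + s$C2CaL + s$C3CaL + s$C4CaL + s$I1CaL + s$I2CaL + s$I3CaL)
  ICaL <- p$GCaL * s$OCaL * (s$V - p$ECaL)
  dCaLm <- c(
    OCaL = aL * s$C4CaL - 4 * bL * s$OCaL + p$Kpcb * s$I1CaL - gL * s$OCaL +
      0.001 * (aL * s$I2CaL - Kpcf * s$OCaL),
    C2CaL = 4 * aL * C1L + 2 * bL * s$C3CaL - (bL + 3 * aL) * s$C2CaL,
    C3CaL = 3 * aL * s$C2CaL + 3 * bL * s$C4CaL - (2 * bL + 2 * aL) * s$C3CaL,
    C4CaL = 2 * aL * s$C3CaL + 4 * bL * s$OCaL - (3 * bL + aL) * s$C4CaL +
      0.01 * (4 * p$Kpcb * bL * s$I1CaL - aL * gL * s$C4CaL) +
      0.002 * (4 * bL * s$I2CaL - Kpcf * s$C4CaL) +
      4 * bL * p$Kpcb * s$I3CaL - gL * Kpcf * s$C4CaL,
    I1CaL = gL * s$OCaL - p$Kpcb * s$I1CaL +
      0.001 * (Kpcf * s$I3CaL - aL * s$I1CaL) +
      0.01 * (aL * gL * s$C4CaL - 4 * p$Kpcb * bL * s$I1CaL),
    I2CaL = 0.001 * (Kpcf * s$OCaL - aL * s$I2CaL) + p$Kpcb * s$I3CaL -
      gL * s$I2CaL + 0.002 * (Kpcf * s$C4CaL - 4 * bL * s$I2CaL),
    I3CaL = 0.001 * (aL * s$I1CaL - Kpcf * s$I3CaL) + gL * s$I2CaL -
      p$Kpcb * s$I3CaL + gL * Kpcf * s$C4CaL - 4 * bL * p$Kpcb * s$I3CaL)

  ## remaining sarcolemmal currents
  IpCa <- p$IpCa_max * s$Cai^2 / (p$Km_pCa^2 + s$Cai^2)
  INaCa <- p$kNaCa / ((p$Km_Na^3 + p$Nao^3) * (p$Km_Ca + p$Cao) *
                        (1 + p$k_sat * exp((p$eta - 1) * VFRT))) *
    (exp(p$eta * VFRT) * s$Nai^3 * p$Cao -
       exp((p$eta - 1) * VFRT) * p$Nao^3 * s$Cai)
  ICab <- p$GCab * (s$V - ECaN)
  INab <- p$GNab * (s$V - ENa)
  sigma <- (exp(p$Nao / 67300) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * VFRT) + 0.0365 * sigma * exp(-VFRT))
  INaK <- p$INaK_max * fNaK * p$Ko / (p$Ko + p$Km_Ko) /
    (1 + (p$Km_Nai / s$Nai)^1.5)
  OClCa <- 0.2 / (1 + exp(-(s$V - 46.7) / 7.8))
  IClCa <- p$GClCa * OClCa * s$Cai / (s$Cai + p$Km_Cl) * (s$V - p$ECl)

  IKtof <- p$GKtof * s$atof^3 * s$itof * (s$V - EK)
  IKtos <- p$GKtos * s$atos * s$itos * (s$V - EK)
  IKur <- p$GKur * s$aur * s$iur * (s$V - EK)
  IKss <- p$GKss * s$aKss * s$iKss * (s$V - EK)
  IKs <- p$GKs * s$nKs^2 * (s$V - EK)
  IKr <- p$GKr * s$OK * (s$V - EKr)
  IK1 <- p$GK1 * (p$Ko / (p$Ko + p$K1_half))^p$nK1 * (s$V - EK) /
    (1 + exp(p$sK1 * (s$V - EK)))

  ## HH gates
  aa <- 0.18064 * exp(0.03577 * (s$V + 30))
  ba <- 0.3956 * exp(-0.06237 * (s$V + 30))
  ai <- 0.000152 * exp(-(s$V + 13.5) / 7) /
    (0.0067083 * exp(-(s$V + 33.5) / 7) + 1)
  bi <- 0.00095 * exp((s$V + 33.5) / 7) /
    (0.051335 * exp((s$V + 33.5) / 7) + 1)
  a_ss <- 1 / (1 + exp(-(s$V + 22.5) / 7.7))
  i_ss <- 1 / (1 + exp((s$V + 45.2) / 5.7))
  dv <- s$V + 26.5
  an <- if (abs(dv) < 1e-6) 0.00000481333 / 0.128 else
    0.00000481333 * dv / (1 - exp(-0.128 * dv))
  bn <- 0.0000953333 * exp(-0.038 * dv)
  dgates <- c(
    atof = aa * (1 - s$atof) - ba * s$atof,
    itof = ai * (1 - s$itof) - bi * s$itof,
    atos = (a_ss - s$atos) / (0.493 * exp(-0.0629 * s$V) + 2.058),
    itos = (i_ss - s$itos) / (270 + 1050 / (1 + exp((s$V + 45.2) / 5.7))),
    nKs = an * (1 - s$nKs) - bn * s$nKs,
    aur = (a_ss - s$aur) / (0.493 * exp(-0.0629 * s$V) + 2.058),
    iur = (i_ss - s$iur) / (1200 - 170 / (1 + exp((s$V + 45.2) / 5.7))),
    aKss = (a_ss - s$aKss) / (39.3 * exp(-0.0862 * s$V) + 13.17),
    iKss = 0)

  ## IKr Markov
  CK0 <- 1 - (s$CK1 + s$CK2 + s$OK + s$IK)
  aa0 <- 0.022348 * exp(0.01176 * s$V); ba0 <- 0.047002 * exp(-0.0631 * s$V)
  aa1 <- 0.013733 * exp(0.038198 * s$V); ba1 <- 0.0000689 * exp(-0.04178 * s$V)
  aikr <- 0.090821 * exp(0.023391 * (s$V + 5))
  bikr <- 0.006497 * exp(-0.03268 * (s$V + 5))
  dKr <- c(
    CK1 = aa0 * CK0 - ba0 * s$CK1 + p$kb * s$CK2 - p$kf * s$CK1,
    CK2 = p$kf * s$CK1 - p$kb * s$CK2 + ba1 * s$OK - aa1 * s$CK2,
    OK = aa1 * s$CK2 - ba1 * s$OK + bikr * s$IK - aikr * s$OK,
    IK = aikr * s$OK - bikr * s$IK)

  ## RyR and Ca2+ fluxes
  PC1 <- 1 - (s$PO1 + s$PO2 + s$PC2)
  dRyR <- c(
    PO1 = p$ka_plus * s$Cass^p$n_ryr * PC1 - p$ka_minus * s$PO1 -
      p$kb_plus * s$Cass^p$m_ryr * s$PO1 + p$kb_minus * s$PO2 -
      p$kc_plus * s$PO1 + p$kc_minus * s$PC2,
    PO2 = p$kb_plus * s$Cass^p$m_ryr * s$PO1 - p$kb_minus * s$PO2,
    PC2 = p$kc_plus * s$PO1 - p$kc_minus * s$PC2,
    PRyR = -0.04 * s$PRyR - 0.1 * (ICaL / p$ICaL_max) *
      exp(-(s$V - 5)^2 / 648))

  Jrel <- p$v1 * (s$PO1 + s$PO2) * (s$CaJSR - s$Cass) * s$PRyR
  Jtr <- (s$CaNSR - s$CaJSR) / p$tau_tr
  Jxfer <- (s$Cass - s$Cai) / p$tau_xfer
  Jleak <- p$v2 * (s$CaNSR - s$Cai)
  Jup <- p$v3 * s$Cai^2 / (p$Km_up^2 + s$Cai^2)
  dLT <- p$k_ltrpn_plus * s$Cai * (p$LTRPN_tot - s$LTRPNCa) -
    p$k_ltrpn_minus * s$LTRPNCa
  dHT <- p$k_htrpn_plus * s$Cai * (p$HTRPN_tot - s$HTRPNCa) -
    p$k_htrpn_minus * s$HTRPNCa
  Jtrpn <- dLT + dHT

  Bi <- 1 / (1 + p$CMDN_tot * p$Km_CMDN / (p$Km_CMDN + s$Cai)^2)
  Bss <- 1 / (1 + p$CMDN_tot * p$Km_CMDN / (p$Km_CMDN + s$Cass)^2)
  BJSR <- 1 / (1 + p$CSQN_tot * p$Km_CSQN / (p$Km_CSQN + s$CaJSR)^2)
  fcur <- p$Acap * p$Cm / (2 * p$Vmyo * p$F)
  fss <- p$Acap * p$Cm / (2 * p$Vss * p$F)
  fion <- p$Acap * p$Cm / (p$Vmyo * p$F)

  Iion <- INa + ICaL + IpCa + INaCa + ICab + INab + INaK + IKtof + IKtos +
    IK1 + IKs + IKur + IKss + IKr + IClCa

  deriv <- c(
    V = -(Iion - istim),
    Cai = Bi * (Jleak + Jxfer - Jup - Jtrpn - (ICab - 2 * INaCa + IpCa) * fcur),
    Cass = Bss * (Jrel * p$VJSR / p$Vss - Jxfer * p$Vmyo / p$Vss - ICaL * fss),
    CaJSR = BJSR * (Jtr - Jrel),
    CaNSR = (Jup - Jleak) * p$Vmyo / p$VNSR - Jtr * p$VJSR / p$VNSR,
    LTRPNCa = dLT, HTRPNCa = dHT,
    dRyR, dCaLm, dNa,
    Nai = -(INa + INab + 3 * INaCa + 3 * INaK) * fion,
    Ki = -(IKtof + IKtos + IK1 + IKs + IKss + IKur + IKr -
             2 * INaK - istim) * fion,
    dgates, dKr)

  list(
    currents = list(INa = INa, ICaL = ICaL, IpCa = IpCa, INaCa = INaCa,
                    IKtof = IKtof, IKtos = IKtos, IKr = IKr, IKur = IKur,
                    IKss = IKss, IK1 = IK1, IKs = IKs, INaK = INaK,
                    IClCa = IClCa, ICab = ICab, INab = INab, Istim = istim,
                    Itotal = Iion),
    fluxes = list(Jup = Jup, Jrel = Jrel, Jtr = Jtr, Jleak = Jleak,
                  Jxfer = Jxfer, Jtrpn = Jtrpn),
    reversal = list(ENa = ENa, EK = EK, EKr = EKr, ECaN = ECaN),
    deriv = deriv[.state_order])
}

#' Membrane current densities at a given state
#'
#' Evaluates all 15 ionic currents of the model plus the stimulus, with
#' reversal potentials from the Nernst relations on the instantaneous
#' concentrations. Outward current is positive.
#'
#' @param state named state vector (see [initial_state()]).
#' @param params a `myocyte_parameters` object.
#' @param istim stimulus current density (pA/pF, depolarizing positive).
#' @return Named list of current densities in pA/pF, plus `Itotal`, the summed
#'   ionic current entering the voltage balance.
#' @export
compute_currents <- function(state, params, istim = 0) {
  .eval_model(state, params, istim)$currents
}

#' Ca2+ fluxes at a given state
#'
#' SERCA uptake `Jup` (cytosol to network SR), RyR release `Jrel` (junctional
#' SR to subspace), inter-SR transfer `Jtr`, SR leak `Jleak`, subspace-to-cytosol
#' diffusion `Jxfer`, and net troponin binding `Jtrpn`; all in uM/ms in their
#' source-compartment convention.
#'
#' @inheritParams compute_currents
#' @return Named list of the six fluxes (uM/ms).
#' @export
compute_fluxes <- function(state, params) {
  .eval_model(state, params)$fluxes
}

#' Time derivative of the full model state
#'
#' Assembles the balance equations: `dV/dt = -(I_ion - I_stim)` under the
#' capacitance-normalized convention, concentration balances from the fluxes
#' and current-to-flux conversions, and the kinetic equations of every gate and
#' Markov occupancy. The stimulus carried across the membrane is booked to the
#' K+ balance so long constant-current runs conserve charge.
#'
#' @param t time (ms); used only to evaluate the protocol's stimulus.
#' @param state named state vector.
#' @param params a `myocyte_parameters` object.
#' @param protocol a [stimulus_protocol()] object, or `NULL` for `istim` below.
#' @param istim stimulus (pA/pF) used when no protocol is given.
#' @param slow_inact `FALSE` evaluates the Na+ scheme variant without the slow
#'   inactivated states I1/I2.
#' @return Named derivative vector (same layout as the state).
#' @export
model_rhs <- function(t, state, params, protocol = NULL, istim = 0,
                      slow_inact = TRUE) {
  if (!is.null(protocol)) istim <- stimulus_current(t, protocol)
  .eval_model(state, params, istim, slow_inact = slow_inact)$deriv
}
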