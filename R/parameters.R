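# Model constants, WT/TG presets, and the consolidated WT->TG interpolation.

# Parameter order shared with src/model.c (positions matter).
.parm_order <- c(
  "Acap", "Cm", "Vmyo", "VJSR", "VNSR", "Vss", "Ko", "Nao", "Cao",
  "F", "TK", "Rgas",
  "v1", "v2", "v3", "Km_up", "tau_tr", "tau_xfer",
  "ka_plus", "ka_minus", "kb_plus", "kb_minus", "kc_plus", "kc_minus",
  "n_ryr", "m_ryr",
  "LTRPN_tot", "HTRPN_tot", "k_htrpn_plus", "k_htrpn_minus",
  "k_ltrpn_plus", "k_ltrpn_minus",
  "CMDN_tot", "Km_CMDN", "CSQN_tot", "Km_CSQN",
  "GCaL", "ECaL", "Kpc_max", "Kpc_half", "Kpcb", "ICaL_max",
  "GNa", "GNab", "GCab",
  "kNaCa", "Km_Na", "Km_Ca", "k_sat", "eta",
  "IpCa_max", "Km_pCa",
  "INaK_max", "Km_Nai", "Km_Ko",
  "GKtof", "GKtos", "GKur", "GKss", "GKs", "GKr", "kf", "kb",
  "GK1", "K1_half", "nK1", "sK1",
  "GClCa", "Km_Cl", "ECl"
)

# State order shared with src/model.c (positions matter).
.state_order <- c(
  "V", "Cai", "Cass", "CaJSR", "CaNSR", "LTRPNCa", "HTRPNCa",
  "PO1", "PO2", "PC2", "PRyR",
  "OCaL", "C2CaL", "C3CaL", "C4CaL", "I1CaL", "I2CaL", "I3CaL",
  "CNa2", "CNa1", "ONa", "IFNa", "I1Na", "I2Na", "ICNa2", "ICNa3",
  "Nai", "Ki",
  "atof", "itof", "atos", "itos", "nKs", "aur", "iur", "aKss", "iKss",
  "CK1", "CK2", "OK", "IK"
)

.pkg_cache <- new.env(parent = emptyenv())

.load_presets <- function() {
  if (is.null(.pkg_cache$presets)) {
    path <- system.file("extdata", "parameters.json", package = "myoburst",
                        mustWork = TRUE)
    .pkg_cache$presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .pkg_cache$presets
}

.quantity_names <- c("Acap", "Cm", "Vmyo", "VJSR", "VNSR", "Vss", "Ko", "Nao",
                     "Cao", "v1", "v3", "Km_up", "LTRPN_tot", "HTRPN_tot",
                     "CMDN_tot", "CSQN_tot", "GCaL", "GNa", "GNab", "GCab",
                     "IpCa_max", "INaK_max", "GKtof", "GKtos", "GKur", "GKss",
                     "GKs", "GKr", "GK1", "GClCa")

.validate_constants <- function(constants) {
  missing <- setdiff(.parm_order, names(constants))
  if (length(missing))
    stop("parameter set is missing constants: ", paste(missing, collapse = ", "))
  bad <- .quantity_names[constants[.quantity_names] < 0]
  if (length(bad))
    stop("negative conductance/volume/pool size: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Model parameter presets for wild-type and TNF-alpha overexpressing myocytes
#'
#' Builds the complete constant set of the whole-cell mouse ventricular myocyte
#' model. The transgenic (TG, TNF-alpha overexpressing) preset differs from the
#' wild-type (WT) preset in exactly seven parameters: the maximal SR uptake rate
#' `v3`, the Na+/Ca2+ exchanger scaling `kNaCa`, the conductances `GKtof`,
#' `GKur` and `GK1`, and the inward-rectifier shape parameters `nK1` (power
#' index on the K_o saturation factor) and `sK1` (rectification slope).
#'
#' @param genotype `"wt"` or `"tg"`.
#' @return An object of class `myocyte_parameters`: a list with elements
#'   `genotype_tag`, `eps` (interpolation coordinate, 0 for WT, 1 for TG),
#'   `constants` (named numeric vector, units ms/mV/pA-per-pF/uM) and
#'   `flagged` (names of the seven WT/TG-differing entries).
#' @examples
#' wt <- make_parameters("wt")
#' tg <- make_parameters("tg")
#' names(which(wt$constants != tg$constants))
#' @export
make_parameters <- function(genotype = c("wt", "tg")) {
  if (!is.character(genotype) || length(genotype) != 1 ||
      !genotype %in% c("wt", "tg"))
    stop("unknown genotype tag: ", deparse(substitute(genotype)),
         " (must be \"wt\" or \"tg\")")
  presets <- .load_presets()
  constants <- unlist(presets$wt)[.parm_order]
  if (genotype == "tg") {
    tg <- unlist(presets$tg)
    constants[names(tg)] <- tg
  }
  .validate_constants(constants)
  structure(
    list(genotype_tag = genotype,
         eps = if (genotype == "wt") 0 else 1,
         constants = constants,
         flagged = presets$flagged),
    class = "myocyte_parameters")
}

#' Interpolate the seven WT/TG-differing parameters
#'
#' Consolidates the seven remodeled parameters into a single bifurcation
#' coordinate `eps`, with `eps = 0` the WT preset and `eps = 1` the TG preset.
#' The linear schedule moves every flagged parameter along
#' `p(eps) = p_WT + eps * (p_TG - p_WT)`. The exponential schedule accelerates
#' one named parameter along the monotone, endpoint-preserving curve
#' `p(eps) = p_WT + (p_TG - p_WT) * (1 - exp(-k * eps)) / (1 - exp(-k))`,
#' which moves toward the TG value faster than linearly at every interior
#' `eps`, while the remaining six move linearly.
#'
#' @param eps interpolation coordinate in `[0, 1]`.
#' @param schedule `"linear"` or `"exponential"`.
#' @param exp_param for the exponential schedule, which of the seven flagged
#'   parameters follows the exponential curve.
#' @param k curvature of the exponential schedule (dimensionless, default 5).
#' @return A `myocyte_parameters` object (see [make_parameters()]); at the
#'   endpoints the presets are returned bit-identically.
#' @examples
#' mid <- interpolate_parameters(0.5)
#' mid$constants["v3"]
#' @export
interpolate_parameters <- function(eps, schedule = c("linear", "exponential"),
                                   exp_param = NULL, k = 5) {
  schedule <- match.arg(schedule)
  if (!is.numeric(eps) || length(eps) != 1 || is.na(eps) || eps < 0 || eps > 1)
    stop("eps must be a single value in [0, 1], got ", format(eps))
  wt <- make_parameters("wt")
  tg <- make_parameters("tg")
  if (schedule == "exponential") {
    if (is.null(exp_param) || !exp_param %in% wt$flagged)
      stop("exponential schedule must name one of the seven flagged parameters: ",
           paste(wt$flagged, collapse = ", "))
  }
  if (eps == 0) return(wt)
  if (eps == 1) return(tg)
  constants <- wt$constants
  for (nm in wt$flagged) {
    w <- wt$constants[[nm]]; g <- tg$constants[[nm]]
    frac <- if (schedule == "exponential" && identical(nm, exp_param))
      -expm1(-k * eps) / -expm1(-k) else eps
    constants[[nm]] <- w + frac * (g - w)
  }
  .validate_constants(constants)
  structure(
    list(genotype_tag = "interpolated", eps = eps, constants = constants,
         flagged = wt$flagged),
    class = "myocyte_parameters")
}

#' @export
print.myocyte_parameters <- function(x, ...) {
  cat("Mouse ventricular myocyte model parameters\n")
  cat("  genotype:", x$genotype_tag,
      if (x$genotype_tag == "interpolated") sprintf("(eps = %.3f)", x$eps) else "",
      "\n")
  cat("  flagged WT/TG-differing parameters:\n")
  for (nm in x$flagged)
    cat(sprintf("    %-8s = %g\n", nm, x$constants[[nm]]))
  cat("  plus", length(x$constants) - length(x$flagged), "shared constants\n")
  invisible(x)
}

# Ordered numeric vector handed to the compiled RHS.
.parm_vector <- function(params, istim = 0, slow_inact = TRUE) {
  stopifnot(inherits(params, "myocyte_parameters"))
  c(params$constants[.parm_order], slow_inact = as.numeric(slow_inact),
    istim = istim)
}
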