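# Resting-state location by long unstimulated relaxation.

#' Resting state of the model cell
#'
#' Relaxes the model without stimulation until the trajectory stops moving:
#' repeated unstimulated integration in `chunk`-second blocks until the
#' membrane potential changes by less than `dv_tol` over a whole block and the
#' scaled right-hand side is small. The quiescent myocyte is strongly
#' attracting for both presets, so relaxation converges quickly; the residual
#' derivative of the slow Na+/K+ pools sets the attainable tolerance.
#'
#' @param params a `myocyte_parameters` object.
#' @param slow_inact `FALSE` rests the Na+ scheme variant without slow
#'   inactivation (I1/I2 occupancies stay identically zero).
#' @param t_relax initial relaxation time (s).
#' @param chunk refinement block length (s).
#' @param dv_tol convergence tolerance on the membrane-potential change per
#'   block (mV).
#' @param max_chunks iteration budget; exceeded -> error with the residual.
#' @param rtol solver relative tolerance.
#' @return Named state vector with attributes `residual` (max scaled
#'   |dy/dt|) and `dv_last` (V drift over the last block, mV).
#' @export
find_resting_state <- function(params, slow_inact = TRUE, t_relax = 100,
                               chunk = 50, dv_tol = 1e-3, max_chunks = 20,
                               rtol = 1e-8) {
  key <- paste(params$genotype_tag, format(params$eps, digits = 12),
               paste(format(params$constants[params$flagged], digits = 15),
                     collapse = "|"),
               slow_inact, t_relax, chunk, dv_tol, rtol, sep = "@")
  cached <- .pkg_cache$resting[[key]]
  if (!is.null(cached)) return(cached)

  y <- initial_state()
  if (!slow_inact) {
    y[["IFNa"]] <- y[["IFNa"]] + y[["I1Na"]] + y[["I2Na"]]
    y[["I1Na"]] <- 0
    y[["I2Na"]] <- 0
  }
  atol <- .default_atol(rtol)
  integrate_block <- function(y, t_ms) {
    parms <- .parm_vector(params, istim = 0, slow_inact = slow_inact)
    sol <- deSolve::ode(y = y, times = c(0, t_ms), func = "myoburst_derivs",
                        parms = parms, dllname = "myoburst",
                        initfunc = "myoburst_initmod", nout = 23,
                        outnames = .current_names, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 200000)
    if (attr(sol, "istate")[1] < 0) stop("solver failure during relaxation")
    sol[nrow(sol), .state_order]
  }
  y <- integrate_block(y, t_relax * 1000)
  dv <- Inf
  for (i in seq_len(max_chunks)) {
    y2 <- integrate_block(y, chunk * 1000)
    dv <- abs(y2[["V"]] - y[["V"]])
    y <- y2
    if (dv < dv_tol) break
  }
  if (!slow_inact) {
    # the integrator can leave numerical dust in the disconnected states
    y[["I1Na"]] <- 0
    y[["I2Na"]] <- 0
  }
  deriv <- model_rhs(0, y, params, istim = 0, slow_inact = slow_inact)
  residual <- max(abs(deriv) / pmax(abs(y[.state_order]), 1))
  if (dv >= dv_tol)
    stop(sprintf(
      "resting state did not converge: dV = %.3g mV per %g s block, scaled residual %.3g",
      dv, chunk, residual))
  attr(y, "residual") <- residual
  attr(y, "dv_last") <- dv
  if (is.null(.pkg_cache$resting)) .pkg_cache$resting <- list()
  .pkg_cache$resting[[key]] <- y
  y
}
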