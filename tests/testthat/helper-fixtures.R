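# Shared fixtures, computed once per test run (everything is deterministic).

wt_params <- make_parameters("wt")
tg_params <- make_parameters("tg")
wt_rest <- find_resting_state(wt_params)
tg_rest <- find_resting_state(tg_params, dv_tol = 5e-4, max_chunks = 20)

# a mildly excited but valid state, for generic RHS checks
perturbed_state <- function(shift = 0) {
  y <- wt_rest
  y[["V"]] <- y[["V"]] + 20 + shift
  y[["Cai"]] <- y[["Cai"]] * 2
  y[["Cass"]] <- y[["Cass"]] * 3
  y[["ONa"]] <- 0.05
  y[["CNa2"]] <- y[["CNa2"]] + 0.01
  y[["OCaL"]] <- 0.02
  y[["atof"]] <- 0.3
  y[["PO1"]] <- 0.1
  y
}

# short cached traces used by several files
wt_trace_2s <- run_simulation(
  wt_params, pulsed_protocol(100, duration = 2, window = c(0, 2)),
  initial = wt_rest)

na_occ_names <- c("CNa3", "CNa2", "CNa1", "ONa", "IFNa", "I1Na", "I2Na",
                  "ICNa2", "ICNa3")

na_occupancies_from_state <- function(state, scheme) {
  occ <- state[setdiff(na_occ_names, "CNa3")]
  occ["CNa3"] <- 1 - sum(occ)
  occ[scheme$states]
}
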