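# Myocyte electrophysiology surface: instantaneous currents, gate kinetics,
# SR release and uptake fluxes, pacing stimulus.

check_state <- function(state, n = 0L) {
  n_exp <- 26L + 3L * n
  if (length(state) != n_exp)
    stop("state must have ", n_exp, " entries (got ", length(state), ")",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- state_names(n)
  bad <- !is.finite(state)
  if (any(bad))
    stop("non-finite state entries: ", paste(names(state)[bad], collapse = ", "),
         call. = FALSE)
  gates <- state[c("m","h","j","xr1","xr2","xs","r","s","d","f","f2","fcass")]
  if (any(gates < -1e-9 | gates > 1 + 1e-9))
    stop("gating variables must lie in [0, 1]", call. = FALSE)
  occ <- state[c("ryr_r","ryr_o","ryr_i","ryr_ri")]
  if (any(occ < -1e-9) || abs(sum(occ) - 1) > 1e-6)
    stop("RyR occupancies must be non-negative and sum to 1", call. = FALSE)
  conc <- state[c("Na_i","K_i","Ca_i","Ca_ss","Ca_sr","CaTnC")]
  if (any(conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  state
}

#' Instantaneous myocyte membrane currents and Ca2+ fluxes
#'
#' Evaluates every sarcolemmal current (pA/pF) and SR/cytosol Ca2+
#' translocation flux (mM/ms) at the given state, plus their sarcolemmal sum
#' `i_myo_total`.  The L-type current scales linearly with the `x_ical`
#' multiplier in `params`.
#'
#' @param state named myocyte state vector (26 entries, see
#'   [initial_state()]).
#' @param params [myocyte_params()] list.
#' @return named list of currents and fluxes.
#' @export
ep_currents <- function(state, params = myocyte_params()) {
  state <- check_state(state)
  cpp_myo_currents(unname(state), params)
}

#' Hodgkin-Huxley gate derivatives
#'
#' Returns (gate_inf(V) - gate) / tau(V) for the 12 voltage (and subspace
#' Ca2+) dependent gates.
#'
#' @param state named myocyte state vector.
#' @return named numeric vector of gate rates (1/ms).
#' @export
gating_derivatives <- function(state) {
  state <- check_state(state)
  tab <- cpp_gate_tables(state[["V"]], state[["Ca_ss"]])
  g <- state[c("m","h","j","xr1","xr2","xs","r","s","d","f","f2","fcass")]
  stats::setNames((tab["inf", ] - as.numeric(g)) / tab["tau", ], colnames(tab))
}

#' Gate steady states and time constants
#'
#' @param V membrane potential (mV).
#' @param ca_ss subspace Ca2+ (mM), used by the `fcass` gate.
#' @return 2 x 12 matrix with rows `inf` and `tau`.
#' @export
gate_tables <- function(V, ca_ss = 0.0001) {
  if (!is.finite(V)) stop("V must be finite", call. = FALSE)
  cpp_gate_tables(V, ca_ss)
}

#' SR Ca2+ release through the four-state RyR channel
#'
#' Release flux I_rel (proportional to the open fraction and the SR-subspace
#' gradient) and the occupancy derivatives of the R/O/I/RI gating scheme
#' (which sum to zero).
#'
#' @param state named myocyte state vector; occupancies must sum to 1.
#' @param params [myocyte_params()].
#' @return list: `I_rel` (mM/ms), `d_occ` (length-4 derivative vector).
#' @export
ryr_release <- function(state, params = myocyte_params()) {
  state <- check_state(state)
  out <- cpp_ryr(unname(state), params)
  names(out$d_occ) <- c("ryr_r", "ryr_o", "ryr_i", "ryr_ri")
  out
}

#' SERCA uptake, SR leak and subspace-cytosol transfer fluxes
#'
#' I_up saturates in cytosolic Ca2+ and scales with the SERCA multiplier;
#' I_leak and I_xfer are linear in their gradients.
#'
#' @inheritParams ryr_release
#' @return list with `I_up`, `I_leak`, `I_xfer` (mM/ms).
#' @export
sr_cytosol_fluxes <- function(state, params = myocyte_params()) {
  state <- check_state(state)
  cpp_sr_fluxes(unname(state), params)
}

#' Pacing stimulus current
#'
#' Rectangular pulses of the configured amplitude and width repeating at the
#' pacing period.
#'
#' @param t time (ms), scalar or vector, >= 0.
#' @param protocol list with `frequency_hz`, `amplitude`, `duration`,
#'   `start` (as in the `pacing` field of [ensemble_config()]).
#' @return stimulus current (pA/pF) at each `t`.
#' @export
apply_stimulus <- function(t, protocol = list()) {
  p <- merge_known(list(frequency_hz = 1, amplitude = -52, duration = 1,
                        start = 0), protocol, "pacing")
  if (p$frequency_hz <= 0) stop("pacing frequency must be positive", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  period <- 1000 / p$frequency_hz
  ph <- (t - p$start) %% period
  ifelse(t >= p$start & ph < p$duration, p$amplitude, 0)
}
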