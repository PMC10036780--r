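# Fibroblast surface: MacCannell ionic currents, the length-dependent
# mechanosensitive current, its calibration lines, and the membrane ODE.

#' Fibroblast ionic membrane currents
#'
#' The four MacCannell currents — delayed-rectifier i_Kv, inward-rectifier
#' i_K1, Na+/K+ pump i_NaK and background Na+ leak i_bNa — in pA, and their
#' sum `i_cf`.  The mechanosensitive current is *not* included here; it is
#' added separately in the membrane equation when the mode couples mechanics.
#'
#' @param v_cf fibroblast membrane potential (mV).
#' @param r_kv,s_kv activation/inactivation gates of i_Kv in \[0, 1\].
#' @param fb [fibroblast_params()].
#' @return named list of currents (pA).
#' @export
fb_ionic_currents <- function(v_cf, r_kv, s_kv, fb = fibroblast_params()) {
  if (any(c(r_kv, s_kv) < 0 | c(r_kv, s_kv) > 1))
    stop("Kv gates must lie in [0, 1]", call. = FALSE)
  cpp_fb_currents(v_cf, r_kv, s_kv, fb)
}

#' Fibroblast Kv-gate steady states and time constants
#'
#' @param v_cf membrane potential (mV).
#' @return 2 x 2 matrix (rows `inf`, `tau`; columns `r_kv`, `s_kv`).
#' @export
fb_gate_tables <- function(v_cf) {
  if (!is.finite(v_cf)) stop("v_cf must be finite", call. = FALSE)
  cpp_fb_gate_tables(v_cf)
}

#' Mechanosensitive fibroblast current
#'
#' i_MS = g_max a(dl) (V_cf - V_rev(length)): a linear I-V whose slope
#' scales with the deformation factor a(dl) = 1 + a_slope dl (a(0) = 1) and
#' whose reversal potential is affine in the instantaneous fibroblast length
#' over the 80--90\% L_max working range.  Negative current depolarizes.
#'
#' @param dl deformation relative to the run's initial length (strain).
#' @param v_cf membrane potential (mV).
#' @param length_frac instantaneous fibroblast length as a fraction of
#'   L_max (defaults to the working-range upper endpoint).
#' @param fb [fibroblast_params()].
#' @return i_MS (pA).
#' @export
msc_current <- function(dl, v_cf, length_frac = NULL, fb = fibroblast_params()) {
  if (is.null(length_frac)) length_frac <- fb$length_hi
  cpp_msc_current(length_frac, dl, v_cf, fb)
}

#' Calibrated linear functions of the mechanosensitive current
#'
#' Returns the deformation factor a(dl) and reversal potential V_rev(length)
#' as R functions, together with the endpoint values.  V_rev is affine over
#' \[length_lo, length_hi\] with endpoint values {-38, -30} mV; which
#' endpoint carries the more negative value is set by `vrev_neg_at_long`.
#'
#' @param fb [fibroblast_params()].
#' @return list: `a` (function of dl), `v_rev` (function of length
#'   fraction), `v_rev_lo`, `v_rev_hi`, `length_lo`, `length_hi`.
#' @export
msc_calibration <- function(fb = fibroblast_params()) {
  if (fb$length_hi <= fb$length_lo)
    stop("degenerate length range: length_hi must exceed length_lo",
         call. = FALSE)
  if (fb$v_rev_lo >= fb$v_rev_hi)
    stop("v_rev_lo must be below v_rev_hi", call. = FALSE)
  list(
    a = function(dl) pmax(0, 1 + fb$a_slope * dl),
    v_rev = function(length_frac)
      vapply(length_frac, function(l) cpp_vrev(l, fb), numeric(1)),
    v_rev_lo = fb$v_rev_lo / fb$x_vrev,
    v_rev_hi = fb$v_rev_hi / fb$x_vrev,
    length_lo = fb$length_lo,
    length_hi = fb$length_hi)
}

#' Fibroblast membrane potential derivative
#'
#' dV_cf/dt = -(i_cf \[+ i_MS in model2\] + g_gap (V_cf - V_myo)) / C_mf.
#'
#' @param v_cf,r_kv,s_kv fibroblast state.
#' @param v_myo myocyte membrane potential (mV).
#' @param g_gap gap-junction conductance (nS), >= 0.
#' @param dl deformation relative to initial length (used in model2).
#' @param length_frac instantaneous length fraction (used in model2).
#' @param mode "model1" (no i_MS) or "model2".
#' @param fb [fibroblast_params()].
#' @return dV_cf/dt (mV/ms).
#' @export
fb_membrane_derivative <- function(v_cf, r_kv, s_kv, v_myo, g_gap,
                                   dl = 0, length_frac = NULL,
                                   mode = c("model2", "model1"),
                                   fb = fibroblast_params()) {
  mode <- match.arg(mode)
  if (g_gap < 0) stop("g_gap must be >= 0 nS", call. = FALSE)
  ic <- fb_ionic_currents(v_cf, r_kv, s_kv, fb)$i_cf
  ims <- if (mode == "model2") msc_current(dl, v_cf, length_frac, fb) else 0
  -(ic + ims + g_gap * (v_cf - v_myo)) / fb$C_mf
}
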