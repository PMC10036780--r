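# Packaged default parameter sets.
#
# Electrophysiology: ten Tusscher-Panfilov 2006 epicardial values (units mV,
# ms, mM, pA/pF), with the L-type conductance anchored at 5e-5 (F s)^-1 and
# the generalized cytosolic buffer split into a 70 uM troponin-C pool plus a
# residual instantaneous buffer so that total capacity (0.2 mM) is preserved.
# RyR gating: four-state scheme with luminal regulation; rate constants
# calibrated to give post-release refractoriness and SR-load alternans under
# Ca2+ overload (see the methods vignette).
# Mechanics and mechanosensitive-current constants are calibrated values; the
# calibration rationale is documented in the methods vignette.

#' Default myocyte electrophysiology parameters
#'
#' Returns the packaged parameter set for the ventricular myocyte
#' electrophysiology module: maximal conductances and permeabilities,
#' exchanger/pump constants, compartment volumes, buffering, SR flux rates,
#' the four-state RyR gating constants, Ca-TnC kinetic constants and the
#' stimulus protocol.  Conductance multipliers (`x_ical`, `x_ikr`, `x_iks`,
#' `x_serca`) default to 1.
#'
#' @param ... named overrides of individual entries.
#' @return named list of parameters.
#' @export
#' @examples
#' p <- myocyte_params(x_ical = 2)   # doubled L-type conductance
myocyte_params <- function(...) {
  p <- list(
    # maximal conductances (nS/pF except where noted)
    g_Na = 14.838, g_K1 = 5.405, g_to = 0.294, g_Kr = 0.153, g_Ks = 0.392,
    g_CaL = 5e-5,            # (F s)^-1, L-type permeability scale
    g_bNa = 0.00029, g_bCa = 0.000592, g_pK = 0.0146,
    g_pCa = 0.1238, K_pCa = 0.0005,
    P_NaK = 2.724, K_mK = 1.0, K_mNa = 40.0,
    k_NaCa = 1000.0, K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1,
    gamma_ncx = 0.35, alpha_ncx = 2.5, p_KNa = 0.03,
    # external concentrations (mM)
    K_o = 5.4, Na_o = 140.0, Ca_o = 2.0,
    # geometry
    V_c = 0.016404, V_sr = 0.001094, V_ss = 0.00005468,
    C_myo = 185.0,           # pF
    # buffering (residual cytosolic buffer after the TnC split)
    buf_c2 = 0.13, K_bufc = 0.001,
    buf_sr = 10.0, K_bufsr = 0.3, buf_ss = 0.4, K_bufss = 0.00025,
    # SR fluxes
    V_maxup = 0.006375, K_up = 0.00025,
    V_leak = 0.00036, V_xfer = 0.0038, V_rel = 0.102,
    # four-state RyR gating (calibrated)
    ryr_ko_ca = 4.8, ryr_ki_ca = 0.08, ryr_k_om = 0.06, ryr_k_im = 0.005,
    ryr_ec50_sr = 3.22, ryr_max_sr = 32.0, ryr_min_sr = 0.05, ryr_hill_sr = 30.0,
    # multipliers
    x_ical = 1.0, x_ikr = 1.0, x_iks = 1.0, x_serca = 1.0,
    # stimulus (rectangular pulses)
    stim_amplitude = -52.0, stim_duration = 1.0,
    stim_period = 1000.0, stim_start = 0.0,
    # Ca-troponin C pool (mM, per-ms rates; cooperative off-rate, calibrated)
    tnc_total = 0.07, tnc_a_on = 100.0, tnc_k_off0 = 0.3,
    tnc_k_a = 20.0, tnc_pi_min = 0.15, tnc_pi_q = 8.0
  )
  override_params(p, list(...), "myocyte_params")
}

#' Default mechanics parameters
#'
#' Rheology of the preparation: exponential stiffness pairs for the parallel
#' (PE), series (SE) and end-compliance (XSE) elastic elements and the
#' fibroblast elastic element (PEfb, sharing the PE pair), viscous
#' coefficients, contractile-element force-velocity constants, cross-bridge
#' kinetics, and the calibrated force normalization.  Strains are
#' dimensionless fractions of L_max relative to slack; forces are in units of
#' the uncoupled-myocyte peak twitch force at 90\% L_max.
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
mech_params <- function(...) {
  p <- list(
    alpha_pe = 30.0, beta_pe = 0.004,
    alpha_fb = 30.0, beta_fb = 0.004,    # identical to the PE pair by default
    alpha_se = 200.0, beta_se = 0.01,
    alpha_xse = 200.0, beta_xse = 0.01,
    nu_vs1 = 8.0, nu_vs2 = 4.0,          # normalized force per (strain/ms)
    f_ce_scale = 3.0,                    # CE force scale (calibrated)
    v_max = 0.002,                       # unloaded shortening velocity, strain/ms
    fv_curvature = 0.25,                 # Hill a/F0
    xb_k_att = 0.08, xb_k_det = 0.04,    # 1/ms
    xb_det_v = 2.0,                      # velocity sensitivity of detachment
    lambda_lo = 0.55, lambda_hi = 1.0,   # overlap ramp, sarcomere fraction of L_max
    xb_km_catnc = 0.05,                  # mM, half-activation of attachment
    base_frac = 0.80,                    # slack length as fraction of L_max
    f_norm = 0.801363,                   # calibrated peak-force normalization
    L_max_um = 2.23                      # sarcomere length at L_max, um
  )
  override_params(p, list(...), "mech_params")
}

#' Default fibroblast parameters
#'
#' MacCannell active-fibroblast membrane parameters (capacitance 6.3 pF,
#' delayed-rectifier, inward-rectifier, Na+/K+ pump and background Na+
#' currents) plus the calibrated mechanosensitive-current constants: zero
#' deformation conductance `g_max`, deformation factor slope `a_slope`, and
#' the reversal-potential endpoints (-38 mV / -30 mV) over the 80--90\% L_max
#' working range.  `vrev_neg_at_long = 1` assigns the most negative reversal
#' potential to the 90\% endpoint (the default orientation; flip with 0).
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
fibroblast_params <- function(...) {
  p <- list(
    C_mf = 6.3,                       # pF
    g_Kv = 0.25, g_K1f = 0.4822,      # nS/pF
    g_bNaf = 0.0095, i_NaK_max = 2.002,
    K_mKf = 1.0, K_mNaf = 11.0,
    K_if = 129.4349, Na_if = 8.5547,  # mM, held fixed
    g_max = 1.0,                      # nS at zero deformation (calibrated)
    a_slope = 5.0,                    # per unit strain
    v_rev_lo = -38.0, v_rev_hi = -30.0,
    length_lo = 0.80, length_hi = 0.90,
    vrev_neg_at_long = 1,
    x_gmax = 1.0, x_vrev = 1.0
  )
  override_params(p, list(...), "fibroblast_params")
}

# apply overrides, rejecting unknown names
override_params <- function(defaults, overrides, where) {
  if (length(overrides) == 0L) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop(where, ": overrides must be named", call. = FALSE)
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown))
    stop(where, ": unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- modifyList(defaults, overrides)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L || !is.finite(x),
                logical(1))
  if (any(bad))
    stop(where, ": non-finite or non-scalar value for: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  p
}
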