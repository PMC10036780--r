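# Mechanics surface: cooperative Ca-TnC kinetics, cross-bridge kinetics,
# element forces of the rheological scheme, and the per-step isometric force
# balance.

#' Ca-troponin C kinetics with cross-bridge cooperativity
#'
#' dCaTnC/dt = a_on * Ca_i * (A_tot - CaTnC) - k_off(N_xb, CaTnC) * CaTnC,
#' where the off-rate k_off = k_off0 * exp(-k_A CaTnC) * pi(N_xb) falls
#' strictly as the attached cross-bridge fraction rises (the cooperative
#' feedback that underlies Xb-induced spontaneous Ca2+ release).  When
#' `koff_frozen` is supplied the off-rate is held at that value, emulating
#' the cooperativity clamp.
#'
#' @param catnc Ca-TnC concentration (uM).
#' @param ca_i cytosolic free Ca2+ (mM).
#' @param n_xb attached cross-bridge fraction in \[0, 1\].
#' @param params [myocyte_params()] (the Ca-TnC constants live there, next
#'   to the rest of the Ca2+ handling).
#' @param koff_frozen optional frozen off-rate (1/ms); NULL for cooperative.
#' @return dCaTnC/dt in uM/ms.
#' @export
catnc_rate <- function(catnc, ca_i, n_xb, params = myocyte_params(),
                       koff_frozen = NULL) {
  a_mM <- catnc / 1000
  if (a_mM > params$tnc_total + 1e-12)
    stop("CaTnC exceeds the total troponin-C pool (",
         params$tnc_total * 1000, " uM)", call. = FALSE)
  1000 * cpp_catnc_rate(a_mM, ca_i, n_xb, params,
                        if (is.null(koff_frozen)) -1 else koff_frozen)
}

#' Cooperative Ca-TnC off-rate
#'
#' @inheritParams catnc_rate
#' @return off-rate (1/ms).
#' @export
catnc_koff <- function(catnc, n_xb, params = myocyte_params()) {
  cpp_catnc_koff(catnc / 1000, n_xb, params)
}

#' Cross-bridge attachment/detachment kinetics
#'
#' dN_xb/dt with attachment increasing in Ca-TnC and sarcomere length
#' (length-dependent activation) and detachment increasing with shortening
#' or lengthening speed; N_xb stays in \[0, 1\].
#'
#' @param n_xb attached fraction.
#' @param catnc Ca-TnC (uM).
#' @param l1 contractile-element strain (fraction of L_max above slack).
#' @param v1 contractile-element velocity (strain/ms; shortening negative).
#' @param mech [mech_params()].
#' @return dN_xb/dt (1/ms).
#' @export
xb_kinetics <- function(n_xb, catnc, l1, v1 = 0, mech = mech_params()) {
  if (n_xb < 0 || n_xb > 1) stop("n_xb must lie in [0, 1]", call. = FALSE)
  cpp_xb_rate(n_xb, catnc / 1000, l1, v1, mech)
}

#' Forces of every element of the rheological scheme
#'
#' Exponential elastic forces for PE, PEfb, SE and XSE, the contractile
#' force from the attached cross-bridge fraction with the force-velocity
#' factor, and the viscous forces.  With default coefficients F_PE(l) and
#' F_PEfb(l) coincide (shared coefficient pair).
#'
#' @param l1,l2 contractile and parallel-branch strains.
#' @param l3 series end-element (XSE) strain.
#' @param v1 CE velocity (strain/ms).
#' @param dl2 parallel-branch strain rate (strain/ms).
#' @param n_xb attached cross-bridge fraction.
#' @param n fibroblast count (for reporting only).
#' @param mech [mech_params()].
#' @return named list of forces (normalized units).
#' @export
element_forces <- function(l1, l2, l3 = 0, v1 = 0, dl2 = 0, n_xb = 0,
                           n = 0L, mech = mech_params()) {
  cpp_element_forces(l1, l2, l3, v1, dl2, n_xb, as.integer(n), mech)
}

#' Solve the isometric force balance for the internal velocities
#'
#' With the whole-preparation length fixed, finds the contractile-element
#' velocity v1 and parallel-branch rate dl2/dt such that
#' F_XSE = F_PE + n F_PEfb + F_CE + F_VS1 (+ F_VS2) holds, by bracketed
#' root-finding on the inner node velocity.  Each additional fibroblast adds
#' one F_PEfb term.
#'
#' @param l1,l2 current strains.
#' @param n_xb attached cross-bridge fraction.
#' @param L whole-preparation length (fraction of L_max).
#' @param n number of fibroblast elastic elements.
#' @param mech [mech_params()].
#' @return list with `v1`, `dl2`, every element force, the balance
#'   `residual` and solver diagnostics.
#' @export
solve_isometric_balance <- function(l1, l2, n_xb, L = 0.90, n = 0L,
                                    mech = mech_params()) {
  out <- cpp_mech_solve(l1, l2, n_xb, L, as.integer(n), mech)
  if (!isTRUE(out$ok))
    stop("no root in bracket for the force balance; residual at bracket ",
         "ends did not change sign", call. = FALSE)
  out
}
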