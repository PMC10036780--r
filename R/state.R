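# State vectors: myocyte electrical + mechanical block (26 entries) followed
# by (V_cf, r_kv, s_kv) triplets for each fibroblast.

MYO_STATE_NAMES <- c(
  "V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2", "fcass",
  "ryr_r", "ryr_o", "ryr_i", "ryr_ri",
  "Na_i", "K_i", "Ca_i", "Ca_ss", "Ca_sr", "CaTnC",
  "l1", "l2", "N_xb")

state_names <- function(n = 0L) {
  nm <- MYO_STATE_NAMES
  if (n > 0)
    nm <- c(nm, as.vector(vapply(seq_len(n), function(i)
      paste0(c("V_cf", "r_kv", "s_kv"), i), character(3))))
  nm
}

#' Resting mechanical configuration at a given preparation length
#'
#' Solves the passive balance F_XSE = F_PE + n F_PEfb (cross-bridges
#' detached, so the series element is slack and l1 = l2) for the parallel
#' branch strain l2 at fixed whole-preparation length.
#'
#' @param initial_length preparation length as a fraction of L_max.
#' @param n_elastic number of fibroblast elastic elements in parallel
#'   (0 unless mechanical coupling is active).
#' @param mech mechanics parameter list.
#' @return list with `l1`, `l2`, `l3` strains.
#' @export
passive_rest_lengths <- function(initial_length, n_elastic = 0L,
                                 mech = mech_params()) {
  L <- initial_length
  bal <- function(l2) {
    l3 <- L - mech$base_frac - l2
    cpp_fexp(mech$alpha_xse, mech$beta_xse, l3) -
      cpp_fexp(mech$alpha_pe, mech$beta_pe, l2) -
      n_elastic * cpp_fexp(mech$alpha_fb, mech$beta_fb, l2)
  }
  span <- L - mech$base_frac
  l2 <- uniroot(bal, lower = min(-0.2, span - 0.2), upper = max(0.2, span + 0.2),
                tol = 1e-12)$root
  list(l1 = l2, l2 = l2, l3 = L - mech$base_frac - l2)
}

#' Initial state vector for a simulation
#'
#' Myocyte electrical variables start from the published resting values of
#' the base ventricular model (or a packaged paced-steady-state snapshot when
#' available, see [steady_snapshot()]); the mechanical coordinates start at
#' the passive rest configuration for the requested length; fibroblasts start
#' at their uncoupled resting potential with gates at steady state.
#'
#' @param initial_length fraction of L_max (0.7, 1.0].
#' @param n fibroblast count.
#' @param mode one of "single", "model1", "model2".
#' @param mech,fb parameter lists.
#' @param use_snapshot start the myocyte from a packaged 1-Hz steady-state
#'   snapshot when one exists for this length (default TRUE).
#' @return named numeric state vector.
#' @export
initial_state <- function(initial_length = 0.90, n = 0L, mode = "single",
                          mech = mech_params(), fb = fibroblast_params(),
                          use_snapshot = TRUE) {
  snap <- if (use_snapshot) steady_snapshot(initial_length) else NULL
  if (!is.null(snap)) {
    myo <- snap
  } else {
    myo <- c(
      V = -85.23, m = 0.0017, h = 0.749, j = 0.749,
      xr1 = 0.0000207, xr2 = 0.475, xs = 0.0087,
      r = 2.35e-8, s = 1.0, d = 3.16e-5, f = 0.8, f2 = 0.995, fcass = 1.0,
      ryr_r = 0.99, ryr_o = 0.0, ryr_i = 0.0, ryr_ri = 0.01,
      Na_i = 7.67, K_i = 138.3, Ca_i = 0.00007, Ca_ss = 0.00007, Ca_sr = 1.3,
      CaTnC = 0.0002,
      l1 = 0, l2 = 0, N_xb = 0)
    rest <- passive_rest_lengths(initial_length,
                                 n_elastic = if (mode == "model2") n else 0L,
                                 mech = mech)
    myo[["l1"]] <- rest$l1
    myo[["l2"]] <- rest$l2
  }
  if (!is.null(snap) && mode == "model2" && n > 0) {
    # re-solve the passive rest for the extra parallel elements
    rest <- passive_rest_lengths(initial_length, n_elastic = n, mech = mech)
    myo[["l1"]] <- rest$l1
    myo[["l2"]] <- rest$l2
  }
  st <- myo
  if (n > 0) {
    vrest <- fb_resting_potential(fb)
    g <- cpp_fb_gate_tables(vrest)
    fbst <- rep(c(vrest, g["inf", "r_kv"], g["inf", "s_kv"]), n)
    st <- c(st, fbst)
  }
  names(st) <- state_names(n)
  st
}

#' Packaged paced steady-state myocyte snapshot
#'
#' Returns the stored single-myocyte 1-Hz steady-state vector for the given
#' initial length (80, 85 or 90\% L_max), or NULL when none is packaged.
#'
#' @param initial_length fraction of L_max.
#' @return named numeric vector of the 26 myocyte states, or NULL.
#' @export
steady_snapshot <- function(initial_length) {
  key <- sprintf("%02d", round(initial_length * 100))
  path <- system.file("extdata", paste0("steady_single_", key, ".json"),
                      package = "cardiofib")
  if (!nzchar(path)) return(NULL)
  v <- unlist(jsonlite::fromJSON(path))
  stats::setNames(as.numeric(v), names(v))
}

#' Uncoupled fibroblast resting potential
#'
#' Root of the total ionic current of the uncoupled fibroblast (no gap
#' junction, no mechanosensitive current), with the Kv gates at their
#' voltage steady state, located by bisection on \[-90, 0\] mV.
#'
#' @param fb fibroblast parameter list.
#' @return resting potential (mV).
#' @export
fb_resting_potential <- function(fb = fibroblast_params()) {
  f <- function(v) {
    g <- cpp_fb_gate_tables(v)
    cpp_fb_currents(v, g["inf", "r_kv"], g["inf", "s_kv"], fb)$i_cf
  }
  uniroot(f, lower = -90, upper = 0, tol = 1e-10)$root
}
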