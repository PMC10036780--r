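# Integration driver: assemble the coupled system from a configuration and
# produce a uniformly sampled trace.

mode_code <- function(mode) match(mode, MODES) - 1L

params_from_config <- function(config) {
  m <- config$multipliers
  pac <- config$pacing
  myo <- myocyte_params(
    x_ical = m$i_CaL, x_ikr = m$i_Kr, x_iks = m$i_Ks, x_serca = m$SERCA,
    stim_amplitude = pac$amplitude, stim_duration = pac$duration,
    stim_period = 1000 / pac$frequency_hz, stim_start = pac$start)
  fb <- fibroblast_params(x_gmax = m$g_max, x_vrev = m$V_rev)
  list(myo = myo, mech = mech_params(), fb = fb)
}

#' Simulate the coupled myocyte-fibroblast ensemble
#'
#' Integrates the full electromechanical system (myocyte membrane and Ca2+
#' dynamics, per-step isometric force balance, n fibroblast membranes) over
#' the configured duration and returns a trace sampled on a uniform grid.
#' The run is fully deterministic.
#'
#' @param config a [ensemble_config()] object.
#' @param init optional initial state vector (defaults to
#'   [initial_state()] for the configured length/mode).
#' @param t_start absolute time of the first sample (ms); stimulus phase and
#'   clamp times are absolute, so a continuation run keeps its alignment.
#' @param params optional partial override of the parameter sets: a list with
#'   any of `myo`, `mech`, `fb`, each a named list of entries to replace
#'   (applied after the config multipliers).
#' @return `cardiofib_trace`: a data.frame with one column per channel
#'   (time, potentials, Ca2+ signals, forces, strains, per-fibroblast
#'   channels), with the configuration, final state and solver statistics
#'   attached as attributes.
#' @export
#' @examples
#' cfg <- ensemble_config("single", duration = 2000)
#' tr <- simulate_ensemble(cfg)
#' max(tr$V_myo_mV)
simulate_ensemble <- function(config, init = NULL, t_start = 0,
                              params = list()) {
  stopifnot(inherits(config, "cardiofib_config"))
  if (is.null(init))
    init <- initial_state(config$initial_length, config$n, config$mode)
  n_exp <- 26L + 3L * config$n
  if (length(init) != n_exp)
    stop("state dimension mismatch: config (mode=", config$mode, ", n=",
         config$n, ") needs ", n_exp, " states, got ", length(init),
         call. = FALSE)
  bad <- !is.finite(init)
  if (any(bad))
    stop("non-finite initial state entries: ",
         paste(names(init)[bad], collapse = ", "), call. = FALSE)
  if (!is.null(config$pre_pace_s) && config$pre_pace_s > 0 && t_start == 0) {
    pre <- config
    pre$pre_pace_s <- 0
    pre$multipliers <- list(i_CaL = 1, i_Kr = 1, i_Ks = 1, SERCA = 1,
                            g_max = 1, V_rev = 1)
    pre$clamp <- NULL
    pre$duration <- config$pre_pace_s * 1000
    pre$record_currents <- FALSE
    init <- attr(simulate_ensemble(pre, init = init, params = params),
                 "final_state")
  }
  p <- params_from_config(config)
  for (blk in intersect(names(params), c("myo", "mech", "fb")))
    p[[blk]] <- modifyList(p[[blk]], params[[blk]])
  ccfg <- list(mode_code = mode_code(config$mode), n = config$n,
               g_gap = config$g_gap, initial_length = config$initial_length,
               duration = config$duration, output_dt = config$solver$output_dt,
               dt = config$solver$dt, t_start = t_start,
               clamp_time = if (is.null(config$clamp)) -1 else config$clamp$time_ms,
               record_currents = config$record_currents)
  res <- cpp_simulate(unname(init), ccfg, p$myo, p$mech, p$fb)
  if (isTRUE(res$mech_solver_failed))
    stop("force-balance solver failed at t = ", res$mech_fail_time,
         " ms; residual bracket could not be established", call. = FALSE)
  tr <- as.data.frame(res$trace)
  fin <- stats::setNames(as.numeric(res$final_state), state_names(config$n))
  structure(tr,
            config = config,
            final_state = fin,
            max_residual = res$max_residual,
            koff_frozen = res$koff_frozen,
            f_rest = res$f_rest,
            t_start = t_start,
            class = c("cardiofib_trace", "data.frame"))
}

#' @export
print.cardiofib_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<cardiofib_trace> ", nrow(x), " samples x ", ncol(x), " channels, ",
      "t = [", x$time_ms[1], ", ", x$time_ms[nrow(x)], "] ms",
      if (!is.null(cfg)) paste0(" (", cfg$mode, ", n=", cfg$n, ")"), "\n",
      sep = "")
  invisible(x)
}

# per-beat scalar metrics used by the steady-state monitor
beat_metrics <- function(trace, period, t0) {
  tt <- trace$time_ms
  lo <- t0
  hi <- t0 + period
  sel <- tt >= lo & tt < hi
  if (!any(sel)) return(NULL)
  v <- trace$V_myo_mV[sel]
  ca <- trace$Ca_i_mM[sel]
  f <- trace$F_active_norm[sel]
  rp_sel <- tt >= (hi - 15) & tt <= (hi - 5)
  ap <- detect_action_potentials(trace[sel, , drop = FALSE])
  apd <- if (nrow(ap)) ap$apd90[1] else NA_real_
  c(rp = if (any(rp_sel)) mean(trace$V_myo_mV[rp_sel]) else v[length(v)],
    ca_peak = max(ca), casr_peak = max(trace$Ca_sr_mM[sel]),
    f_peak = max(f), apd90 = apd)
}

#' Pace the ensemble to a periodic steady state
#'
#' Runs the configured pacing beat by beat until the relative beat-to-beat
#' change of resting potential, Ca2+ peak, force peak and APD90 drops below
#' `tol`, or flags period-2 alternans (metrics agreeing between beats k and
#' k+2 but not k and k+1), up to `max_beats`.
#'
#' @param config [ensemble_config()]; its `duration` is ignored.
#' @param tol relative beat-to-beat tolerance (default 0.001).
#' @param max_beats cap on the number of beats (default 100).
#' @param final_beats how many converged cycles to return in the trace.
#' @param init optional initial state.
#' @return list: `trace` (the final cycles), `beats_taken`, `converged`,
#'   `alternans`, `final_state`, `metrics` (per-beat matrix).
#' @export
run_to_steady_state <- function(config, tol = 0.001, max_beats = 100,
                                final_beats = 2, init = NULL) {
  stopifnot(inherits(config, "cardiofib_config"))
  period <- 1000 / config$pacing$frequency_hz
  one <- config
  one$duration <- period
  if (is.null(init))
    init <- initial_state(config$initial_length, config$n, config$mode)
  state <- init
  hist <- NULL
  converged <- FALSE
  alternans <- FALSE
  beats <- 0L
  last_traces <- list()
  for (b in seq_len(max_beats)) {
    t0 <- (b - 1) * period
    tr <- simulate_ensemble(one, init = state, t_start = t0)
    state <- attr(tr, "final_state")
    mb <- beat_metrics(tr, period, t0)
    hist <- rbind(hist, mb)
    beats <- b
    last_traces[[1 + (b - 1) %% (final_beats + 1)]] <- tr
    if (b >= 3) {
      rel <- function(a, bb) {
        d <- abs(a - bb)
        s <- pmax(abs(a), abs(bb), 1e-9)
        max(d / s, na.rm = TRUE)
      }
      d1 <- rel(hist[b, ], hist[b - 1, ])
      d2 <- rel(hist[b, ], hist[b - 2, ])
      if (d1 < tol) { converged <- TRUE; break }
      # period-2: beats k and k-2 agree (up to residual slow drift) while
      # consecutive beats differ by much more
      if (d1 >= 3 * tol && d2 < max(tol, d1 / 3)) {
        alternans <- TRUE; converged <- TRUE; break
      }
    }
  }
  keep <- max(1, beats - final_beats + 1):beats
  idx <- 1 + (keep - 1) %% (final_beats + 1)
  out <- do.call(rbind, lapply(last_traces[idx], as.data.frame))
  out <- out[!duplicated(out$time_ms), , drop = FALSE]
  structure(list(trace = structure(out, config = config,
                                   f_rest = attr(last_traces[[idx[length(idx)]]], "f_rest"),
                                   class = c("cardiofib_trace", "data.frame")),
                 beats_taken = beats, converged = converged,
                 alternans = alternans, final_state = state,
                 metrics = hist),
            class = "cardiofib_steady")
}
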