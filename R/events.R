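# Measurement and experiment layer: resting potentials, AP/APD detection,
# EAD and extrasystole classification, vulnerability diagrams, threshold
# scans, mechanosensitive I-V diagrams, cooperativity-clamp experiment.

trace_pacing <- function(trace, pacing = NULL) {
  if (!is.null(pacing)) return(merge_known(
    list(frequency_hz = 1, amplitude = -52, duration = 1, start = 0),
    pacing, "pacing"))
  cfg <- attr(trace, "config")
  if (is.null(cfg)) stop("no pacing protocol: pass `pacing` or use a trace ",
                         "produced by simulate_ensemble()", call. = FALSE)
  cfg$pacing
}

stimulus_onsets <- function(trace, pacing) {
  period <- 1000 / pacing$frequency_hz
  t0 <- trace$time_ms[1]
  t1 <- trace$time_ms[nrow(trace)]
  k <- seq(floor((t0 - pacing$start) / period), ceiling((t1 - pacing$start) / period))
  on <- pacing$start + k * period
  on[on >= t0 - period & on <= t1]
}

#' Per-beat resting potentials
#'
#' The resting potential of each beat is the membrane potential averaged
#' over the 10 ms window ending 5 ms before the stimulus onset.  Beats whose
#' window falls outside the trace are skipped with a warning.
#'
#' @param trace a `cardiofib_trace` (or data.frame with `time_ms`,
#'   `V_myo_mV` and optional `V_cf*_mV` columns).
#' @param pacing pacing protocol; defaults to the trace's configuration.
#' @return data.frame: `stim_ms`, `rp_myo_mV`, and one `rp_cf<i>_mV` column
#'   per fibroblast.
#' @export
measure_resting_potentials <- function(trace, pacing = NULL) {
  pacing <- trace_pacing(trace, pacing)
  ons <- stimulus_onsets(trace, pacing)
  tt <- trace$time_ms
  fbcols <- grep("^V_cf[0-9]+_mV$", names(trace), value = TRUE)
  rows <- lapply(ons, function(on) {
    sel <- tt >= on - 15 & tt <= on - 5
    if (!any(sel)) {
      warning("resting-potential window outside trace for stimulus at ",
              on, " ms; beat skipped", call. = FALSE)
      return(NULL)
    }
    out <- c(stim_ms = on, rp_myo_mV = mean(trace$V_myo_mV[sel]))
    if (length(fbcols))
      out <- c(out, stats::setNames(vapply(fbcols, function(cn)
        mean(trace[[cn]][sel]), numeric(1)),
        sub("^V_", "rp_", fbcols)))
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(stim_ms = numeric(0), rp_myo_mV = numeric(0)))
  as.data.frame(do.call(rbind, rows))
}

#' Detect action potentials and measure APD90
#'
#' An AP onset is an upward crossing of the onset threshold with
#' dV/dt above the slope threshold; APD90 runs from onset to 90\%
#' repolarization toward the pre-upstroke baseline.
#'
#' @param trace trace with `time_ms` and `V_myo_mV`.
#' @param thresholds list: `onset_mv` (-40), `dvdt` (10 mV/ms),
#'   `repol_frac` (0.9).
#' @return data.frame: `onset_ms`, `peak_ms`, `peak_mv`, `baseline_mv`,
#'   `apd90`.
#' @export
detect_action_potentials <- function(trace, thresholds = list()) {
  th <- merge_known(list(onset_mv = -40, dvdt = 10, repol_frac = 0.9),
                    thresholds, "thresholds")
  tt <- trace$time_ms
  v <- trace$V_myo_mV
  nt <- length(tt)
  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      peak_mv = numeric(0), baseline_mv = numeric(0),
                      apd90 = numeric(0))
  if (nt < 3) return(empty)
  dvdt <- c(diff(v) / diff(tt), 0)
  cross <- which(v[-nt] < th$onset_mv & v[-1] >= th$onset_mv &
                   dvdt[-nt] > th$dvdt)
  if (!length(cross)) return(empty)
  # collapse crossings closer than 5 ms (sampling artifacts on one upstroke)
  keep <- c(TRUE, diff(tt[cross]) > 5)
  cross <- cross[keep]
  out <- lapply(seq_along(cross), function(k) {
    i0 <- cross[k]
    i_end <- if (k < length(cross)) cross[k + 1] - 1 else nt
    seg <- i0:i_end
    ip <- seg[which.max(v[seg])]
    # baseline: most negative potential in the 50 ms before the upstroke
    pre <- which(tt >= tt[i0] - 50 & tt <= tt[i0])
    base <- if (length(pre)) min(v[pre]) else v[i0]
    lev <- v[ip] - th$repol_frac * (v[ip] - base)
    after <- seg[seg >= ip]
    j <- after[which(v[after] <= lev)[1]]
    apd <- if (length(j) && !is.na(j)) tt[j] - tt[i0] else NA_real_
    c(onset_ms = tt[i0], peak_ms = tt[ip], peak_mv = v[ip],
      baseline_mv = base, apd90 = apd)
  })
  as.data.frame(do.call(rbind, out))
}

#' Classify triggered activity in a paced trace
#'
#' Detects early afterdepolarizations (an upward deflection of at least
#' `ead_mv` after the AP peak and before the potential first falls below
#' `diastolic_mv`, whose peak does not qualify as a new AP onset) and
#' extrasystoles (an AP onset not attributable to any stimulus within
#' `attrib_ms`, confirmed by an extra force peak when a force channel is
#' present).  A run whose peak active force stays below `fail_frac` of the
#' uncoupled norm is classified as contractile failure.
#'
#' @param trace paced trace.
#' @param pacing pacing protocol; defaults to the trace's configuration.
#' @param thresholds list: `ead_mv` (5), `diastolic_mv` (-70), `attrib_ms`
#'   (10), `fail_frac` (0.05), `takeoff_max_mv` (-10; deflections taking off
#'   above this are the physiological spike-notch-dome, not EADs), plus the
#'   [detect_action_potentials()] thresholds.
#' @return `cardiofib_events` list: `rp` (per-beat resting potentials),
#'   `aps`, `eads`, `extrasystoles`, `outcome` in
#'   none/EAD/extrasystole/failure, `first_extrasystole_ms`.
#' @export
detect_triggered_activity <- function(trace, pacing = NULL, thresholds = list()) {
  th <- merge_known(list(ead_mv = 5, diastolic_mv = -70, attrib_ms = 10,
                         fail_frac = 0.05, takeoff_max_mv = -10,
                         onset_mv = -40, dvdt = 10,
                         repol_frac = 0.9), thresholds, "thresholds")
  pacing <- trace_pacing(trace, pacing)
  aps <- detect_action_potentials(trace, th[c("onset_mv", "dvdt", "repol_frac")])
  ons <- stimulus_onsets(trace, pacing)
  have_force <- "F_active_norm" %in% names(trace)
  if (!have_force)
    warning("no force channel in trace; extrasystole confirmation is ",
            "voltage-only", call. = FALSE)

  attributed <- if (nrow(aps)) vapply(aps$onset_ms, function(t0)
    any(t0 >= ons - th$attrib_ms & t0 <= ons + th$attrib_ms), logical(1))
  else logical(0)

  # extrasystoles: non-stimulus APs, force-confirmed where possible
  ex <- aps[!attributed, , drop = FALSE]
  if (nrow(ex) && have_force) {
    conf <- vapply(ex$onset_ms, function(t0) {
      sel <- trace$time_ms >= t0 & trace$time_ms <= t0 + 400
      f <- trace$F_active_norm[sel]
      length(f) > 2 && (max(f) - f[1]) > 0.01
    }, logical(1))
    ex <- ex[conf, , drop = FALSE]
  }

  # EADs: search each stimulus-attributed AP's repolarization
  tt <- trace$time_ms
  v <- trace$V_myo_mV
  eads <- list()
  ap_all <- aps$onset_ms
  for (k in seq_len(nrow(aps))) {
    if (!attributed[k]) next
    ipk <- which(tt == aps$peak_ms[k])
    iend <- length(tt)
    if (k < nrow(aps)) iend <- max(which(tt < aps$onset_ms[k + 1]))
    seg <- ipk:iend
    below <- seg[which(v[seg] < th$diastolic_mv)[1]]
    if (length(below) && !is.na(below)) seg <- seg[seg <= below]
    if (length(seg) < 5) next
    vv <- v[seg]
    # local minima followed by a rise >= ead_mv
    for (i in 2:(length(vv) - 1)) {
      if (vv[i] <= vv[i - 1] && vv[i] < vv[i + 1]) {
        rest <- vv[i:length(vv)]
        up_end <- which(diff(rest) < 0)[1]
        if (is.na(up_end)) up_end <- length(rest)
        amp <- max(rest[1:up_end]) - vv[i]
        t_min <- tt[seg[i]]
        t_pk <- tt[seg[i + which.max(rest[1:up_end]) - 1]]
        is_ap <- any(abs(ap_all - t_pk) < 5) || any(ap_all > t_min & ap_all < t_pk)
        if (amp >= th$ead_mv && !is_ap && vv[i] <= th$takeoff_max_mv)
          eads[[length(eads) + 1]] <- c(time_ms = t_min, takeoff_mv = vv[i],
                                        amplitude_mv = amp)
      }
    }
  }
  eads <- if (length(eads)) as.data.frame(do.call(rbind, eads))
  else data.frame(time_ms = numeric(0), takeoff_mv = numeric(0),
                  amplitude_mv = numeric(0))

  # contractile failure is judged on the settled end of the run (but always
  # over at least one full pacing cycle), not on the loading transient
  peak_force <- if (have_force) {
    tt_all <- trace$time_ms
    t_end <- tt_all[length(tt_all)]
    period <- 1000 / pacing$frequency_hz
    start <- min(t_end - 0.2 * (t_end - tt_all[1]), t_end - period - 100)
    max(trace$F_active_norm[tt_all >= max(start, tt_all[1])])
  } else NA_real_
  outcome <- if (nrow(ex)) "extrasystole"
  else if (nrow(eads)) "EAD"
  else if (have_force && is.finite(peak_force) && peak_force < th$fail_frac) "failure"
  else "none"

  structure(list(
    rp = measure_resting_potentials(trace, pacing),
    aps = aps,
    eads = eads,
    extrasystoles = data.frame(time_ms = ex$onset_ms),
    outcome = outcome,
    first_extrasystole_ms = if (nrow(ex)) min(ex$onset_ms) else NA_real_,
    peak_force = peak_force,
    thresholds = th), class = "cardiofib_events")
}

#' @export
print.cardiofib_events <- function(x, ...) {
  cat("<cardiofib_events> outcome:", x$outcome,
      "|", nrow(x$eads), "EAD(s),", nrow(x$extrasystoles), "extrasystole(s)\n")
  if (is.finite(x$first_extrasystole_ms))
    cat("  first extrasystole at", x$first_extrasystole_ms, "ms\n")
  invisible(x)
}

#' Vulnerability diagram over fibroblast count and junctional conductance
#'
#' Runs one full paced simulation per (n, g_gap) grid cell at the given
#' L-type multiplier and records the triggered-activity outcome of each.
#'
#' @param base_config configuration template (its `n`, `g_gap` and i_CaL
#'   multiplier are overridden per cell).
#' @param n_values,g_gap_values grid axes.
#' @param i_cal_multiplier L-type conductance multiplier for every cell.
#' @return `cardiofib_vulnerability`: list with `outcomes` (matrix n x
#'   g_gap), `first_extrasystole_ms` matrix, and the fixed settings.
#' @export
vulnerability_sweep <- function(base_config, n_values = 0:4,
                                g_gap_values = c(0.5, 1, 2, 3),
                                i_cal_multiplier = 2) {
  stopifnot(length(n_values) > 0, length(g_gap_values) > 0)
  out <- matrix(NA_character_, length(n_values), length(g_gap_values),
                dimnames = list(paste0("n", n_values),
                                paste0("g", g_gap_values)))
  tex <- matrix(NA_real_, length(n_values), length(g_gap_values),
                dimnames = dimnames(out))
  for (i in seq_along(n_values)) for (j in seq_along(g_gap_values)) {
    cfg <- base_config
    cfg$n <- as.integer(n_values[i])
    cfg$g_gap <- g_gap_values[j]
    if (cfg$n == 0 && cfg$mode == "single") cfg$mode <- "single"
    cfg$multipliers$i_CaL <- i_cal_multiplier
    res <- tryCatch({
      ev <- detect_triggered_activity(simulate_ensemble(cfg))
      list(out = ev$outcome, t = ev$first_extrasystole_ms)
    }, error = function(e) list(out = "failure", t = NA_real_))
    out[i, j] <- res$out
    tex[i, j] <- res$t
  }
  structure(list(outcomes = out, first_extrasystole_ms = tex,
                 n_values = n_values, g_gap_values = g_gap_values,
                 i_cal_multiplier = i_cal_multiplier,
                 initial_length = base_config$initial_length,
                 mode = base_config$mode),
            class = "cardiofib_vulnerability")
}

#' @export
print.cardiofib_vulnerability <- function(x, ...) {
  cat("<cardiofib_vulnerability> mode", x$mode, ", i_CaL x",
      x$i_cal_multiplier, ", L =", x$initial_length * 100, "% L_max\n")
  print(x$outcomes)
  invisible(x)
}

#' Threshold scan over the L-type conductance multiplier
#'
#' Finds, on an ascending multiplier grid, the smallest i_CaL multiplier at
#' which each triggered-activity class first appears, using monotone
#' bisection on the grid (each probe is one full paced run).
#'
#' @param base_config configuration template.
#' @param modifier named multipliers applied to every run (e.g.
#'   `list(SERCA = 0.5)` or `list(i_Kr = 0.5, i_Ks = 0.5)`).
#' @param grid ascending multiplier grid (default 1.0--3.5 step 0.1).
#' @return list: `any_triggered`, `EAD`, `extrasystole` — smallest grid
#'   multiplier exhibiting each (NA when none does, reported as above-grid),
#'   `runs` (outcomes of the probed multipliers), `modifier`.
#' @export
threshold_scan <- function(base_config, modifier = list(),
                           grid = seq(1.0, 3.5, by = 0.1)) {
  stopifnot(!is.unsorted(grid))
  cache <- new.env(parent = emptyenv())
  probe <- function(mult) {
    key <- sprintf("%.10g", mult)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- base_config
    cfg$multipliers <- modifyList(cfg$multipliers, modifier)
    cfg$multipliers$i_CaL <- cfg$multipliers$i_CaL * mult
    ev <- detect_triggered_activity(simulate_ensemble(cfg))
    cache[[key]] <- ev
    ev
  }
  bisect <- function(pred) {
    lo <- 1L
    hi <- length(grid)
    if (pred(probe(grid[lo]))) return(grid[lo])
    if (!pred(probe(grid[hi]))) return(NA_real_)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (pred(probe(grid[mid]))) hi <- mid else lo <- mid
    }
    grid[hi]
  }
  res <- list(
    any_triggered = bisect(function(e) e$outcome %in% c("EAD", "extrasystole")),
    EAD = bisect(function(e) nrow(e$eads) > 0),
    extrasystole = bisect(function(e) nrow(e$extrasystoles) > 0))
  runs <- sort(as.numeric(ls(cache)))
  res$runs <- data.frame(multiplier = runs,
                         outcome = vapply(sprintf("%.10g", runs), function(k)
                           cache[[k]]$outcome, character(1)))
  res$modifier <- modifier
  res$grid_step <- if (length(grid) > 1) grid[2] - grid[1] else NA_real_
  res
}

#' Mechanosensitive current I-V lines at given lengths
#'
#' For each length, the affine i_MS line (slope, reversal potential, sampled
#' values on the voltage grid) with the deformation referenced to
#' `ref_length`; also reports the sign-ambiguity band spanned by the
#' reversal potentials.
#'
#' @param lengths fibroblast lengths as fractions of L_max.
#' @param v_grid voltage grid (mV).
#' @param ref_length length the deformation is measured from (default: the
#'   working-range upper endpoint, where the paced runs start).
#' @param fb [fibroblast_params()].
#' @return list: `curves` data.frame (length, slope_nS, v_rev_mV),
#'   `lines` (list of data.frames V/i_MS), `band_mV` (range of V_rev).
#' @export
msc_iv_curves <- function(lengths = c(0.80, 0.90),
                          v_grid = seq(-100, 40, by = 1),
                          ref_length = NULL, fb = fibroblast_params()) {
  if (is.null(ref_length)) ref_length <- fb$length_hi
  cal <- msc_calibration(fb)
  rows <- lapply(lengths, function(L) {
    dl <- L - ref_length
    slope <- fb$x_gmax * fb$g_max * cal$a(dl)
    vr <- cal$v_rev(L)
    list(row = data.frame(length = L, slope_nS = slope, v_rev_mV = vr),
         line = data.frame(V_mV = v_grid, i_MS_pA = slope * (v_grid - vr)))
  })
  curves <- do.call(rbind, lapply(rows, `[[`, "row"))
  list(curves = curves,
       lines = stats::setNames(lapply(rows, `[[`, "line"),
                               paste0("L", lengths * 100)),
       band_mV = range(curves$v_rev_mV))
}

#' Cooperativity-clamp mechanism experiment
#'
#' Runs the configured simulation twice: unchanged, and with the Ca-TnC
#' off-rate frozen from `clamp_time` (absolute ms) at the value reached at
#' that moment.  Returns both traces, the triggered-activity reports for the
#' window from the last stimulus before the clamp to the next one, and the
#' instantaneous Ca-TnC dissociation-flux curves (k_off times CaTnC) for the
#' first `window_ms` after the clamp.
#'
#' @param base_config configuration; `duration` must exceed `clamp_time`.
#' @param clamp_time absolute time of the off-rate freeze (ms).
#' @param window_ms length of the reported dissociation-flux window.
#' @param init,t_start optional initial state and start time (for starting
#'   from a pre-rolled snapshot).
#' @return list: `baseline`, `clamped` (traces), `events_baseline`,
#'   `events_clamped` (reports for the clamp beat), `flux` (data.frame
#'   time_ms / flux_baseline / flux_clamped, uM/ms), `koff_frozen`.
#' @export
cooperativity_clamp_experiment <- function(base_config, clamp_time,
                                           window_ms = 30, init = NULL,
                                           t_start = 0) {
  if (clamp_time < t_start || clamp_time > t_start + base_config$duration)
    stop("clamp_time lies outside the simulated interval", call. = FALSE)
  base <- base_config
  base$clamp <- NULL
  clamped_cfg <- base_config
  clamped_cfg$clamp <- list(time_ms = clamp_time)
  tr0 <- simulate_ensemble(base, init = init, t_start = t_start)
  tr1 <- simulate_ensemble(clamped_cfg, init = init, t_start = t_start)
  pacing <- base$pacing
  period <- 1000 / pacing$frequency_hz
  beat_start <- pacing$start + floor((clamp_time - pacing$start) / period) * period
  # compare the clamp beat only: the freeze persists, so later beats diverge
  win <- function(tr) tr[tr$time_ms >= beat_start - 20 &
                           tr$time_ms < beat_start + period, , drop = FALSE]
  ev0 <- detect_triggered_activity(structure(win(tr0), config = base,
                                             class = class(tr0)))
  ev1 <- detect_triggered_activity(structure(win(tr1), config = clamped_cfg,
                                             class = class(tr1)))
  sel <- tr0$time_ms >= clamp_time & tr0$time_ms <= clamp_time + window_ms
  flux <- data.frame(
    time_ms = tr0$time_ms[sel],
    flux_baseline = tr0$catnc_koff_per_ms[sel] * tr0$CaTnC_uM[sel],
    flux_clamped = tr1$catnc_koff_per_ms[sel] * tr1$CaTnC_uM[sel])
  list(baseline = tr0, clamped = tr1,
       events_baseline = ev0, events_clamped = ev1,
       flux = flux, koff_frozen = attr(tr1, "koff_frozen"),
       clamp_time = clamp_time)
}
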