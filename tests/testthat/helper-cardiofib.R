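# Shared helpers: canonical parameter sets, a resting myocyte state, and a
# small memo cache so expensive paced runs are computed once per test run.

MYO <- myocyte_params()
MECH <- mech_params()
FB <- fibroblast_params()
RTF <- 8314.472 * 310 / 96485.3415

rest_state <- function() initial_state(0.90, 0, "single")

short_cfg <- function(mode = "single", n = 0L, g_gap = 0, duration = 2000, ...) {
  ensemble_config(mode, n = n, g_gap = g_gap, duration = duration, ...)
}

.memo <- new.env(parent = emptyenv())
memo_run <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

# resting potential after `beats` of pacing (mean over the pre-stimulus window
# of the last beat)
settled_rp <- function(mode, n, g_gap, initial_length = 0.90, beats = 12) {
  cfg <- ensemble_config(mode, n = n, g_gap = g_gap,
                         initial_length = initial_length,
                         duration = beats * 1000)
  tr <- simulate_ensemble(cfg)
  rp <- suppressWarnings(measure_resting_potentials(tr))
  list(myo = rp$rp_myo_mV[nrow(rp)],
       cf = if (n > 0) rp[nrow(rp), 3] else NA_real_)
}
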