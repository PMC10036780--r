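# Ensemble run configuration: construction, validation, (de)serialization.

MODES <- c("single", "model1", "model2")

#' Build a validated ensemble configuration
#'
#' Fully specifies a run of the coupled myocyte-fibroblast model: mode,
#' ensemble composition, per-junction conductance, initial length, pacing,
#' duration, conductance multipliers, optional cooperativity clamp, and
#' solver settings.
#'
#' @param mode "single" (isolated myocyte), "model1" (electrotonic coupling
#'   only) or "model2" (electrotonic + mechanical coupling with the
#'   mechanosensitive fibroblast current).
#' @param n fibroblast count (0--10); must be 0 for mode "single".
#' @param g_gap gap-junction conductance per fibroblast (nS).
#' @param initial_length preparation length, fraction of L_max, in (0.7, 1].
#' @param pacing list: `frequency_hz`, `amplitude` (pA/pF), `duration` (ms),
#'   `start` (ms).
#' @param duration run length (ms).
#' @param multipliers list of dimensionless multipliers: `i_CaL`, `i_Kr`,
#'   `i_Ks`, `SERCA`, `g_max`, `V_rev`.
#' @param clamp NULL, or list(`time_ms`) freezing the Ca-TnC off-rate at the
#'   value reached at that absolute time.
#' @param solver list: `dt` integration step (ms), `output_dt` trace sampling
#'   interval (ms).
#' @param record_currents include per-current channels in the trace.
#' @param pre_pace_s seconds of pacing at baseline multipliers (all 1) run
#'   before the recorded protocol, letting the coupled ensemble settle to its
#'   own beat-to-beat state; the trace and all event times start at the end
#'   of pre-pacing (t = 0).
#' @return object of class `cardiofib_config` (a named list).
#' @export
#' @examples
#' cfg <- ensemble_config("model2", n = 4, g_gap = 3.0, duration = 5000)
ensemble_config <- function(mode = "single", n = 0L, g_gap = 0,
                            initial_length = 0.90,
                            pacing = list(), duration = 200000,
                            multipliers = list(), clamp = NULL,
                            solver = list(), record_currents = FALSE,
                            pre_pace_s = 0) {
  mode <- match.arg(mode, MODES)
  pac_def <- list(frequency_hz = 1, amplitude = -52, duration = 1, start = 0)
  mul_def <- list(i_CaL = 1, i_Kr = 1, i_Ks = 1, SERCA = 1, g_max = 1, V_rev = 1)
  sol_def <- list(dt = 0.02, output_dt = 1)
  pacing <- merge_known(pac_def, pacing, "pacing")
  multipliers <- merge_known(mul_def, multipliers, "multipliers")
  solver <- merge_known(sol_def, solver, "solver")

  n <- as.integer(n)
  if (is.na(n) || n < 0 || n > 10)
    stop("n must be an integer in 0..10 (got ", n, ")", call. = FALSE)
  if (mode == "single" && n != 0)
    stop("mode 'single' requires n = 0 (got n = ", n, ")", call. = FALSE)
  if (!is.numeric(g_gap) || g_gap < 0)
    stop("g_gap must be >= 0 nS", call. = FALSE)
  if (initial_length <= 0.7 || initial_length > 1.0)
    stop("initial_length must lie in (0.7, 1.0] as a fraction of L_max",
         call. = FALSE)
  if (pacing$frequency_hz <= 0)
    stop("pacing frequency must be positive (valid range > 0 Hz)", call. = FALSE)
  if (duration <= 0) stop("duration must be positive (ms)", call. = FALSE)
  for (nm in names(multipliers))
    if (multipliers[[nm]] < 0)
      stop("multiplier ", nm, " must be >= 0", call. = FALSE)
  if (!is.null(clamp)) {
    if (!is.list(clamp) || is.null(clamp$time_ms) || clamp$time_ms < 0 ||
        clamp$time_ms > duration)
      stop("clamp must be list(time_ms) with 0 <= time_ms <= duration",
           call. = FALSE)
  }
  if (solver$dt <= 0 || solver$output_dt < solver$dt)
    stop("solver: need dt > 0 and output_dt >= dt", call. = FALSE)
  if (pre_pace_s < 0) stop("pre_pace_s must be >= 0", call. = FALSE)

  cfg <- list(mode = mode, n = n, g_gap = g_gap,
              initial_length = initial_length, pacing = pacing,
              duration = duration, multipliers = multipliers, clamp = clamp,
              solver = solver, record_currents = isTRUE(record_currents),
              pre_pace_s = pre_pace_s,
              schema_version = "cardiofib-config-1")
  class(cfg) <- "cardiofib_config"
  cfg
}

merge_known <- function(defaults, given, where) {
  if (length(given) == 0L) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  modifyList(defaults, given)
}

#' @export
print.cardiofib_config <- function(x, ...) {
  cat("<cardiofib_config> mode=", x$mode, " n=", x$n, " g_gap=", x$g_gap,
      " nS, L=", x$initial_length * 100, "% L_max, ",
      x$pacing$frequency_hz, " Hz, ", x$duration / 1000, " s\n", sep = "")
  mult <- x$multipliers[unlist(x$multipliers) != 1]
  if (length(mult))
    cat("  multipliers:", paste(names(mult), unlist(mult), sep = "=",
                                collapse = ", "), "\n")
  if (!is.null(x$clamp))
    cat("  cooperativity clamp at", x$clamp$time_ms, "ms\n")
  invisible(x)
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (1 Hz pacing, 90\% L_max, 200 s).
#'
#' @param path JSON file path.
#' @return `cardiofib_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$schema_version <- NULL
  known <- c("mode", "n", "g_gap", "initial_length", "pacing", "duration",
             "multipliers", "clamp", "solver", "record_currents", "pre_pace_s")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$clamp)) args$clamp <- as.list(args$clamp)
  for (f in c("pacing", "multipliers", "solver"))
    if (!is.null(args[[f]])) args[[f]] <- as.list(args[[f]])
  do.call(ensemble_config, args)
}

#' Write a run configuration to JSON
#'
#' @param config `cardiofib_config`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cardiofib_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
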