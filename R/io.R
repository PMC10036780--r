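# Output serialization, run manifests, and synthetic classifier fixtures.

#' Run manifest
#'
#' Summarizes a run for provenance: a hash of the configuration, the
#' parameter-set version, solver settings, wall time and outcome summary.
#'
#' @param config `cardiofib_config`.
#' @param events optional `cardiofib_events`.
#' @param wall_time_s elapsed seconds (optional).
#' @return named list.
#' @export
run_manifest <- function(config, events = NULL, wall_time_s = NA_real_) {
  stopifnot(inherits(config, "cardiofib_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  list(config_hash = hash,
       schema_version = config$schema_version,
       parameter_version = "cardiofib-params-1",
       solver = config$solver,
       wall_time_s = wall_time_s,
       outcome = if (!is.null(events)) events$outcome else NA_character_,
       first_extrasystole_ms = if (!is.null(events))
         events$first_extrasystole_ms else NA_real_)
}

#' Write trace, event report and manifest to a directory
#'
#' The trace goes to `trace.csv` (header names carry units), the report to
#' `report.json` and the manifest to `manifest.json`.  Reports round-trip
#' bit-exactly through [read_outputs()]; traces round-trip to full double
#' precision.
#'
#' @param trace `cardiofib_trace`.
#' @param report `cardiofib_events` (or any list).
#' @param manifest output of [run_manifest()].
#' @param out_dir directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_outputs <- function(trace, report, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  f_trace <- file.path(out_dir, "trace.csv")
  f_rep <- file.path(out_dir, "report.json")
  f_man <- file.path(out_dir, "manifest.json")
  df <- as.data.frame(trace)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   f_trace, row.names = FALSE, quote = FALSE)
  rep <- report
  if (inherits(rep, "cardiofib_events")) rep <- unclass(rep)
  jsonlite::write_json(rep, f_rep, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(trace = f_trace, report = f_rep, manifest = f_man))
}

#' Read back files written by [write_outputs()]
#'
#' @param out_dir directory written by [write_outputs()].
#' @return list with `trace` (data.frame), `report`, `manifest`.
#' @export
read_outputs <- function(out_dir) {
  list(trace = utils::read.csv(file.path(out_dir, "trace.csv"),
                               check.names = FALSE),
       report = jsonlite::fromJSON(file.path(out_dir, "report.json"),
                                   simplifyVector = TRUE),
       manifest = jsonlite::fromJSON(file.path(out_dir, "manifest.json"),
                                     simplifyVector = TRUE))
}

#' Synthetic traces for exercising the event classifier
#'
#' Deterministic stylized traces built without running the ODE system:
#' `flat` (quiescent membrane), `plain-AP` (three paced beats),
#' `EAD-template` (one beat carries a sub-threshold late hump) and
#' `extrasystole-template` (one full ectopic AP with an extra force peak).
#' Pacing metadata is attached so the classifier can attribute beats.
#'
#' @param kind one of "flat", "plain-AP", "EAD-template",
#'   "extrasystole-template".
#' @return a `cardiofib_trace`-like data.frame (1 ms sampling, 3 beats).
#' @export
make_fixtures <- function(kind = c("plain-AP", "EAD-template",
                                   "extrasystole-template", "flat")) {
  kind <- match.arg(kind)
  tt <- seq(0, 2999, by = 1)
  v <- rep(-86, length(tt))
  f <- rep(0, length(tt))

  ap_shape <- function(trel) {
    # 0..2 ms upstroke, plateau decay, repolarized by ~320 ms
    ifelse(trel < 0, 0,
    ifelse(trel < 2, trel / 2 * 116,
    ifelse(trel < 250, 116 - (trel - 2) / 248 * 50,
    ifelse(trel < 320, 66 - (trel - 250) / 70 * 66, 0))))
  }
  force_shape <- function(trel)
    ifelse(trel < 0 | trel >= 400, 0,
           ifelse(trel < 150, trel / 150, 1 - (trel - 150) / 250))

  if (kind != "flat") {
    for (on in c(0, 1000, 2000)) {
      v <- pmax(v, -86 + ap_shape(tt - on))
      f <- pmax(f, force_shape(tt - on))
    }
  }
  if (kind == "EAD-template") {
    # beat 2 (onset 1000 ms) carries a late hump: repolarization pauses at
    # -58 mV and rises 11 mV at ~0.6 mV/ms (far below the AP-onset slope)
    # before resuming; the deflection sits above the -70 mV diastolic bound
    seg <- tt >= 1280 & tt < 1380
    t_rel <- tt[seg] - 1280
    v[seg] <- ifelse(t_rel < 20, -48 - t_rel / 20 * 10,          # down to -58
              ifelse(t_rel < 40, -58 + (t_rel - 20) / 20 * 11,   # hump +11 mV
                     -47 - (t_rel - 40) / 60 * 39))              # resume to -86
  }
  if (kind == "extrasystole-template") {
    # full ectopic AP (and force peak) 500 ms after beat 2's stimulus
    v <- pmax(v, -86 + ap_shape(tt - 1500))
    f <- pmax(f, 0.8 * force_shape(tt - 1500))
  }
  cfg <- ensemble_config("single", duration = 3000)
  structure(data.frame(time_ms = tt, V_myo_mV = v, F_active_norm = f),
            config = cfg, class = c("cardiofib_trace", "data.frame"))
}
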