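# Numerical integration of cell models under a protocol.

#' Integrate a cell model under a protocol
#'
#' Runs the model's ordinary differential equations for the full protocol
#' duration with an adaptive embedded Runge-Kutta scheme (Dormand-Prince
#' 5(4), relative tolerance 1e-6, absolute tolerance 1e-8 by default) and
#' returns voltage and intracellular Ca2+ resampled on a uniform grid.
#' Stimulus on/off edges are integration breakpoints, so the rectangular
#' stimulus is represented exactly.  Integration is deterministic for
#' fixed inputs and tolerances.  A step-size collapse is reported by
#' flagging the trace as failed rather than raising an error, so
#' population runs continue.
#'
#' @param model A `cell_model`.
#' @param protocol A `protocol_spec`.
#' @param record_from Start of the recorded window in ms (default 0 =
#'   record everything).  Population runs record only the tail they need.
#' @param dt_out Output sampling interval in ms (default 0.5).
#' @param rtol,atol Integration tolerances.
#' @param stim_amp Stimulus amplitude in uA/uF (default 33, about 1.5x
#'   the diastolic threshold of the adult fixture at baseline).
#' @param stim_dur Stimulus duration in ms.
#' @return An `ap_trace`: list with `time` (ms), `V` (mV), `Cai` (mM),
#'   `failed` flag, final `state`, and `meta` (model/protocol ids, mode,
#'   frequency, duration, stimulus settings, units).
#' @export
integrate_model <- function(model, protocol, record_from = 0, dt_out = 0.5,
                            rtol = 1e-6, atol = 1e-8,
                            stim_amp = 33, stim_dur = 2) {
  stopifnot(inherits(model, "cell_model"), inherits(protocol, "protocol_spec"))
  if (protocol$mode == "spontaneous" && !model$capabilities[["spontaneous"]]) {
    stop("model '", model$id, "' has no spontaneous capability; ",
         "cannot run protocol '", protocol$id, "'")
  }
  m <- model
  if (!is.na(protocol$Nao)) m <- set_extracellular(m, Nao = protocol$Nao)
  if (!is.na(protocol$Cao)) m <- set_extracellular(m, Cao = protocol$Cao)
  if (!is.na(protocol$Ko)) m <- set_extracellular(m, Ko = protocol$Ko)

  dur_ms <- protocol$duration * 1000
  if (record_from < 0) record_from <- max(0, dur_ms + record_from)
  paced <- protocol$mode == "paced"
  amp <- if (paced) stim_amp else 0
  period <- if (paced) 1000 / protocol$frequency else 0

  res <- cc_integrate(unname(m$params), unname(m$state0), dur_ms,
                      amp, stim_dur, period, 0,
                      record_from, dt_out, rtol, atol)
  structure(
    list(time = res$time, V = res$V, Cai = res$Cai,
         failed = isTRUE(res$failed),
         state = stats::setNames(res$state, .state_names),
         meta = list(model_id = model$id, protocol_id = protocol$id,
                     transport = m$params[transport_pathways()],
                     mode = protocol$mode, frequency = protocol$frequency,
                     duration_ms = dur_ms, stim_amp = amp,
                     stim_dur = stim_dur, record_from = record_from,
                     dt_out = dt_out, n_steps = res$n_steps,
                     units = list(time = "ms", V = "mV", Cai = "mM"))),
    class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace> ", x$meta$model_id, " / ", x$meta$protocol_id,
      if (x$failed) "  [FAILED]", "\n", sep = "")
  cat("  ", length(x$time), " samples over ", x$meta$duration_ms, " ms (",
      x$meta$dt_out, " ms sampling, recorded from ",
      round(x$meta$record_from), " ms)\n", sep = "")
  if (!x$failed) {
    cat("  V range [", round(min(x$V), 1), ", ", round(max(x$V), 1),
        "] mV; Cai range [", signif(min(x$Cai), 3), ", ",
        signif(max(x$Cai), 3), "] mM\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.ap_trace <- function(x, ...) {
  data.frame(time_ms = x$time, V_mV = x$V, Cai = x$Cai)
}

#' Write a trace to CSV
#'
#' Columns `time_ms`, `V_mV`, `Cai`; metadata (model id, protocol id,
#' units) goes to a JSON sidecar `<path>.json`.
#'
#' @param trace An `ap_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- trace$meta[c("model_id", "protocol_id", "transport", "mode",
                       "duration_ms", "dt_out", "units")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Evaluate the model right-hand side
#'
#' Exposes the state derivatives of a `cell_model` at a given time and
#' state, mainly for cross-checking the packaged integrator against a
#' general-purpose ODE solver.
#'
#' @param model A `cell_model`.
#' @param t Time (ms).
#' @param state Named or unnamed state vector (length 9).
#' @param istim Stimulus current (uA/uF, positive = outward convention of
#'   the membrane equation; the packaged stimulus is inward).
#' @return Named derivative vector.
#' @export
model_rhs <- function(model, t, state, istim = 0) {
  stopifnot(inherits(model, "cell_model"))
  d <- cc_rhs(t, unname(state), unname(model$params), istim)
  stats::setNames(d, .state_names)
}
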