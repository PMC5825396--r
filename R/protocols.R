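# Simulated experimental protocols: pacing / spontaneous activity with
# optional extracellular ion overrides, and final-beat segmentation.

#' Define a simulation protocol
#'
#' @param mode `"paced"` (rectangular stimulus current) or `"spontaneous"`
#'   (no stimulus; requires a spontaneously active model).
#' @param frequency Pacing frequency in Hz (paced mode only).
#' @param duration Simulated time in seconds (default 120 s, enough to
#'   reach steady state).
#' @param Nao,Cao,Ko Extracellular concentration overrides in mM; `NA`
#'   keeps the model's baseline.
#' @param id Identifier string used as feature-column metadata; defaults
#'   to a canonical name built from the settings.
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(mode = c("paced", "spontaneous"), frequency = NULL,
                          duration = 120, Nao = NA, Cao = NA, Ko = NA,
                          id = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (mode == "paced") {
    if (is.null(frequency) || !is.finite(frequency) || frequency <= 0) {
      stop("paced protocols need frequency > 0 (Hz)")
    }
  } else {
    frequency <- NA_real_
  }
  for (nm in c("Nao", "Cao", "Ko")) {
    v <- get(nm)
    if (!is.na(v) && v <= 0) stop(nm, " override must be positive")
  }
  if (is.null(id)) {
    id <- if (mode == "spontaneous") "spont" else
      paste0("pace", format(frequency, trim = TRUE))
    if (!is.na(Cao)) id <- paste0(id, "_Cao", Cao)
    if (!is.na(Nao)) id <- paste0(id, "_Nao", Nao)
    if (!is.na(Ko)) id <- paste0(id, "_Ko", Ko)
  }
  structure(list(mode = mode, frequency = frequency, duration = duration,
                 Nao = Nao, Cao = Cao, Ko = Ko, id = id),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol> ", x$id, ": ", x$mode, sep = "")
  if (x$mode == "paced") cat(" @ ", x$frequency, " Hz", sep = "")
  cat(", ", x$duration, " s", sep = "")
  ov <- c(Nao = x$Nao, Cao = x$Cao, Ko = x$Ko)
  ov <- ov[!is.na(ov)]
  if (length(ov)) {
    cat(", overrides: ", paste(names(ov), ov, sep = "=", collapse = " "),
        " mM", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' The standard protocol set
#'
#' The ten simulated experimental conditions: the cell-kind baseline
#' (1 Hz pacing for adult-like cells, spontaneous activity for iPSC-like
#' cells), 0.5 / 1 / 2 Hz pacing, and raised/lowered extracellular Ca2+
#' (3.0 / 0.9 mM vs 1.8), Na+ (300 / 70 mM vs 151) and K+ (10 / 3 mM vs
#' 5.4).  For iPSC-like cells the ion-override protocols run in
#' spontaneous mode; for adult-like cells they are paced at 1 Hz, and the
#' 1 Hz entry is the baseline itself (9 protocols instead of 10).
#'
#' @param cell_kind `"adult"`-like (paced baseline) or `"ipsc"`-like
#'   (spontaneous baseline).
#' @param duration Protocol duration in seconds (default 120).
#' @return Named list of `protocol_spec`s keyed by stable identifiers
#'   (`spont`, `pace0.5`, `pace1`, `pace2`, `CaHigh`, `CaLow`, `NaHigh`,
#'   `NaLow`, `KHigh`, `KLow`).
#' @export
standard_protocols <- function(cell_kind = c("adult", "ipsc"), duration = 120) {
  cell_kind <- match.arg(cell_kind)
  ion_mode <- if (cell_kind == "ipsc") "spontaneous" else "paced"
  ion <- function(id, Nao = NA, Cao = NA, Ko = NA) {
    protocol_spec(ion_mode, frequency = if (ion_mode == "paced") 1 else NULL,
                  duration = duration, Nao = Nao, Cao = Cao, Ko = Ko, id = id)
  }
  out <- list()
  if (cell_kind == "ipsc") {
    out$spont <- protocol_spec("spontaneous", duration = duration, id = "spont")
  }
  out[["pace0.5"]] <- protocol_spec("paced", 0.5, duration, id = "pace0.5")
  out[["pace1"]] <- protocol_spec("paced", 1, duration, id = "pace1")
  out[["pace2"]] <- protocol_spec("paced", 2, duration, id = "pace2")
  out$CaHigh <- ion("CaHigh", Cao = 3.0)
  out$CaLow <- ion("CaLow", Cao = 0.9)
  out$NaHigh <- ion("NaHigh", Nao = 300)
  out$NaLow <- ion("NaLow", Nao = 70)
  out$KHigh <- ion("KHigh", Ko = 10)
  out$KLow <- ion("KLow", Ko = 3)
  out
}

#' Run a protocol on a model and segment the final beat
#'
#' @param model A `cell_model`.
#' @param protocol A `protocol_spec`.
#' @param ... Passed to [integrate_model()] (tolerances, stimulus
#'   settings, recording window).
#' @return List with elements `trace` (an `ap_trace`) and `beat` (a
#'   `beat_segment`, or `NULL` when no beat was detected).
#' @export
run_protocol <- function(model, protocol, ...) {
  trace <- integrate_model(model, protocol, ...)
  beat <- if (trace$failed) NULL else segment_last_beat(trace)
  list(trace = trace, beat = beat)
}

# numerical dV/dt on the recorded grid
.dvdt <- function(time, v) {
  n <- length(v)
  if (n < 3) return(rep(0, n))
  c(diff(v[1:2]) / diff(time[1:2]),
    (v[3:n] - v[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)]),
    (v[n] - v[n - 1]) / (time[n] - time[n - 1]))
}

#' Detect upstrokes in a voltage trace
#'
#' An upstroke is a rise of dV/dt above a threshold equal to a fraction
#' of the trace's maximum dV/dt (default 10%), with a refractory window
#' (default 100 ms) so one AP is counted once.  Traces with total voltage
#' excursion below `min_amplitude` report no upstrokes.
#'
#' @param time,v Time (ms) and voltage (mV) vectors.
#' @param frac Threshold fraction of max dV/dt.
#' @param refractory Minimum spacing between detected upstrokes (ms).
#' @param min_amplitude Minimum peak-to-trough excursion (mV).
#' @return Times (ms) of maximum dV/dt for each detected upstroke.
#' @export
detect_upstrokes <- function(time, v, frac = 0.1, refractory = 100,
                             min_amplitude = 30) {
  ok <- is.finite(v)
  time <- time[ok]; v <- v[ok]
  if (length(v) < 5 || diff(range(v)) < min_amplitude) return(numeric(0))
  dv <- .dvdt(time, v)
  thr <- frac * max(dv)
  if (thr <= 0) return(numeric(0))
  above <- dv >= thr
  starts <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(starts)) return(numeric(0))
  ups <- numeric(0)
  last <- -Inf
  for (s in starts) {
    if (time[s] - last < refractory) next
    # locate the dV/dt maximum within this suprathreshold run
    e <- s
    while (e < length(above) && above[e + 1]) e <- e + 1
    i_max <- s + which.max(dv[s:e]) - 1
    ups <- c(ups, time[i_max])
    last <- time[i_max]
  }
  ups
}

new_beat_segment <- function(time, v, cai, t_up, cl, mode, protocol_id) {
  structure(list(time = time, V = v, Cai = cai, t_up = t_up, cl = cl,
                 mode = mode, protocol_id = protocol_id),
            class = "beat_segment")
}

#' Extract the final beat from a trace
#'
#' For paced traces the segment starts at the last stimulus and spans one
#' cycle length.  For spontaneous traces the segment is bounded by the
#' last two detected upstrokes (see [detect_upstrokes()]), i.e. the last
#' complete beat.  The upstroke time is the time of maximum dV/dt.
#'
#' @param trace An `ap_trace` from [integrate_model()].
#' @param n_back Count backwards: 1 = final beat (default), 2 = the beat
#'   before it (used for steady-state diagnostics).
#' @return A `beat_segment`, or `NULL` if no beat is present.
#' @export
segment_last_beat <- function(trace, n_back = 1) {
  stopifnot(inherits(trace, "ap_trace"))
  if (isTRUE(trace$failed)) return(NULL)
  meta <- trace$meta
  time <- trace$time; v <- trace$V; cai <- trace$Cai
  if (identical(meta$mode, "paced")) {
    cl <- 1000 / meta$frequency
    dur <- meta$duration_ms
    n_stim <- floor((dur - 1e-6) / cl) + 1
    k <- n_stim - n_back + 1
    if (k < 1) return(NULL)
    t0 <- (k - 1) * cl
    t1 <- min(t0 + cl, dur)
    sel <- time >= t0 - 1e-9 & time <= t1 + 1e-9
    if (sum(sel) < 5) return(NULL)
    ts <- time[sel]; vs <- v[sel]; cs <- cai[sel]
    if (!all(is.finite(vs)) || diff(range(vs)) < 30) return(NULL)
    dv <- .dvdt(ts, vs)
    t_up <- ts[which.max(dv)]
    new_beat_segment(ts, vs, cs, t_up, cl, "paced", meta$protocol_id)
  } else {
    ups <- detect_upstrokes(time, v)
    if (length(ups) < n_back + 1) return(NULL)
    u0 <- ups[length(ups) - n_back]
    u1 <- ups[length(ups) - n_back + 1]
    sel <- time >= u0 - 1e-9 & time <= u1 + 1e-9
    if (sum(sel) < 5) return(NULL)
    new_beat_segment(time[sel], v[sel], cai[sel], u0, u1 - u0,
                     "spontaneous", meta$protocol_id)
  }
}

#' @export
print.beat_segment <- function(x, ...) {
  cat("<beat_segment> ", x$protocol_id, " (", x$mode, "), cycle length ",
      round(x$cl, 1), " ms, upstroke at t=", round(x$t_up, 1), " ms\n",
      sep = "")
  invisible(x)
}

#' Steady-state pacing diagnostic
#'
#' Compares APD90 of the final two beats of a trace.  A cell is
#' considered at steady state when they differ by less than `tol`
#' (relative, default 1%).
#'
#' @param trace An `ap_trace`.
#' @param tol Relative tolerance.
#' @return List with `apd90_last`, `apd90_prev`, `rel_diff`, `steady`.
#' @export
steady_state_check <- function(trace, tol = 0.01) {
  b1 <- segment_last_beat(trace, n_back = 1)
  b2 <- segment_last_beat(trace, n_back = 2)
  if (is.null(b1) || is.null(b2)) {
    return(list(apd90_last = NA_real_, apd90_prev = NA_real_,
                rel_diff = NA_real_, steady = NA))
  }
  a1 <- extract_features(b1)[["APD90"]]
  a2 <- extract_features(b2)[["APD90"]]
  rd <- abs(a1 - a2) / a2
  list(apd90_last = a1, apd90_prev = a2, rel_diff = rd,
       steady = is.finite(rd) && rd < tol)
}
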