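# AP and Ca2+-transient biomarkers of a segmented beat.

.ap_features <- c("APDm60", "APD90", "APD50", "Vpeak", "Vrest")
.cat_features <- c("CaTA", "Ca_rest", "Ca_peak", "CaD50", "CaDecayTime",
                   "CaD90")

#' Feature names for a protocol mode
#'
#' Paced protocols contribute 11 AP/CaT features; spontaneous protocols
#' additionally contribute the beating rate (12 features).
#'
#' @param mode `"paced"` or `"spontaneous"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(mode = c("paced", "spontaneous")) {
  mode <- match.arg(mode)
  out <- c(.ap_features, .cat_features)
  if (mode == "spontaneous") out <- c(out, "rate")
  out
}

# first time, after index `from`, at which y crosses below `level`
# (linear interpolation between samples); NA when it never does
.cross_below <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- from:(n - 1L)
  hit <- which(y[idx] >= level & y[idx + 1L] < level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1L]]
  t[i] + (y[i] - level) / (y[i] - y[i + 1L]) * (t[i + 1L] - t[i])
}

# first time y crosses above `level`
.cross_above <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- from:(n - 1L)
  hit <- which(y[idx] <= level & y[idx + 1L] > level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1L]]
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

# total time y > level, by linear interpolation at the boundary crossings
.time_above <- function(t, y, level) {
  n <- length(y)
  if (n < 2) return(0)
  above <- y > level
  total <- 0
  i <- 1L
  while (i < n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      t_start <- if (i == 1L) t[1L] else {
        t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
      }
      t_end <- if (j == n) t[n] else {
        t[j] + (y[j] - level) / (y[j] - y[j + 1L]) * (t[j + 1L] - t[j])
      }
      total <- total + (t_end - t_start)
      i <- j + 1L
    } else i <- i + 1L
  }
  total
}

#' Extract AP and CaT biomarkers from a beat
#'
#' Computes the 11 standard features (plus beating `rate` for
#' spontaneous beats):
#' * `APD90` / `APD50`: time from the upstroke until voltage has
#'   repolarised by 90% / 50% of the peak-to-rest amplitude, i.e. crosses
#'   `Vpeak - q * (Vpeak - Vrest)`, with linear interpolation at the
#'   crossing.
#' * `APDm60`: total time the membrane spends above -60 mV within the
#'   beat.
#' * `Vpeak`, `Vrest`: peak voltage and resting/maximum-diastolic
#'   voltage (the voltage at stimulus onset for paced beats, the minimum
#'   diastolic voltage for spontaneous beats).
#' * `Ca_rest`, `Ca_peak`, `CaTA`: diastolic and peak [Ca2+] and their
#'   difference.
#' * `CaD50` / `CaD90`: duration from the Ca2+ upstroke (10% rise time)
#'   until [Ca2+] has returned 50% / 90% of the way back to the
#'   within-beat baseline.
#' * `CaDecayTime`: time from the Ca2+ peak until the elevation above
#'   `Ca_rest` has fallen by a factor of e.
#'
#' Features whose defining threshold is never crossed (e.g. APD90 when
#' the cell fails to repolarise) are `NA`.
#'
#' @param beat A `beat_segment`, or `NULL`.
#' @param mode Override the segment's mode (rarely needed).
#' @return Named numeric vector (all `NA` for `NULL` input).
#' @export
extract_features <- function(beat, mode = NULL) {
  if (is.null(mode)) mode <- if (is.null(beat)) "paced" else beat$mode
  nms <- feature_names(mode)
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (is.null(beat)) return(out)
  stopifnot(inherits(beat, "beat_segment"))
  t <- beat$time - beat$time[1L]
  v <- beat$V
  ca <- beat$Cai
  ok <- is.finite(v) & is.finite(ca)
  t <- t[ok]; v <- v[ok]; ca <- ca[ok]
  if (length(t) < 5) return(out)
  t_up <- beat$t_up - beat$time[1L]

  vpeak <- max(v)
  i_peak <- which.max(v)
  vrest <- if (mode == "paced") v[1L] else min(v)
  out["Vpeak"] <- vpeak
  out["Vrest"] <- vrest
  amp <- vpeak - vrest
  if (amp >= 30) {
    for (q in c(0.9, 0.5)) {
      lvl <- vpeak - q * amp
      tc <- .cross_below(t, v, lvl, from = i_peak)
      out[paste0("APD", q * 100)] <- if (is.na(tc)) NA_real_ else tc - t_up
    }
    out["APDm60"] <- .time_above(t, v, -60)
  }

  ca_rest <- min(ca)
  ca_peak <- max(ca)
  i_cpeak <- which.max(ca)
  cata <- ca_peak - ca_rest
  out["Ca_rest"] <- ca_rest
  out["Ca_peak"] <- ca_peak
  out["CaTA"] <- cata
  if (cata > 0) {
    t_rise <- .cross_above(t, ca, ca_rest + 0.1 * cata)
    if (is.na(t_rise)) t_rise <- t[1L]  # beat starts at/above the 10% level
    c50 <- .cross_below(t, ca, ca_rest + 0.5 * cata, from = i_cpeak)
    c90 <- .cross_below(t, ca, ca_rest + 0.1 * cata, from = i_cpeak)
    out["CaD50"] <- if (is.na(c50)) NA_real_ else c50 - t_rise
    out["CaD90"] <- if (is.na(c90)) NA_real_ else c90 - t_rise
    cdec <- .cross_below(t, ca, ca_rest + cata / exp(1), from = i_cpeak)
    out["CaDecayTime"] <- if (is.na(cdec)) NA_real_ else cdec - t[i_cpeak]
  }
  if (mode == "spontaneous") out["rate"] <- 1000 / beat$cl
  out
}

#' Detect abnormal beat dynamics
#'
#' Pure function of the segment; flags are a subset of
#' `c("no_beat", "repolarization_failure", "afterdepolarization")`:
#' * `no_beat` - peak-to-rest amplitude below `min_amplitude` (30 mV).
#' * `repolarization_failure` - the voltage never returns below
#'   `repol_level` (-60 mV) after the upstroke within the beat.
#' * `afterdepolarization` - after 50% repolarisation but before 90%
#'   repolarisation, a local voltage minimum is followed by a
#'   depolarising excursion of at least `ead_mV` (2 mV).
#'
#' An empty character vector means the beat is normal.  A `NULL` beat
#' (segmentation found no beat) is flagged `no_beat`.
#'
#' @param beat A `beat_segment` or `NULL`.
#' @param repol_level,ead_mV,min_amplitude Detector thresholds.
#' @return Character vector of flags (possibly empty).
#' @export
detect_abnormal <- function(beat, repol_level = -60, ead_mV = 2,
                            min_amplitude = 30) {
  if (is.null(beat)) return("no_beat")
  stopifnot(inherits(beat, "beat_segment"))
  v <- beat$V
  t <- beat$time
  ok <- is.finite(v)
  v <- v[ok]; t <- t[ok]
  if (length(v) < 5) return("no_beat")
  vpeak <- max(v)
  i_peak <- which.max(v)
  vrest <- if (beat$mode == "paced") v[1L] else min(v)
  amp <- vpeak - vrest
  if (amp < min_amplitude) return("no_beat")

  flags <- character(0)
  if (!any(v[i_peak:length(v)] < repol_level)) {
    flags <- c(flags, "repolarization_failure")
  }

  # EAD window: between 50% and 90% repolarisation after the peak
  t0 <- t - t[1L]
  l50 <- vpeak - 0.5 * amp
  l90 <- vpeak - 0.9 * amp
  tc50 <- .cross_below(t0, v, l50, from = i_peak)
  tc90 <- .cross_below(t0, v, l90, from = i_peak)
  if (!is.na(tc50)) {
    hi <- if (is.na(tc90)) max(t0) else tc90
    sel <- which(t0 >= tc50 & t0 <= hi)
    if (length(sel) > 3) {
      w <- v[sel]
      run_min <- cummin(w)
      if (max(w - run_min) >= ead_mV) {
        flags <- c(flags, "afterdepolarization")
      }
    }
  }
  flags
}

#' Assemble a feature matrix from per-protocol feature blocks
#'
#' Binds per-protocol feature matrices (cells x features) into one
#' cells x (protocol, feature) matrix with column names
#' `"<protocol>.<feature>"`.  Spontaneous-mode protocols contribute 12
#' columns (including `rate`), paced protocols 11.  Cell indexing must be
#' consistent across blocks; missing values stay explicit as `NA`.
#'
#' @param blocks Named list of numeric matrices, one per protocol, with
#'   feature names as column names.
#' @return Numeric matrix with attribute `protocol` (column-wise protocol
#'   id) and `feature` (column-wise feature name).
#' @export
feature_table <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) > 0, !is.null(names(blocks)))
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1L) stop("all protocol blocks must have the same row count")
  cols <- unlist(lapply(names(blocks), function(p) {
    paste(p, colnames(blocks[[p]]), sep = ".")
  }))
  if (anyDuplicated(cols)) {
    stop("duplicated (protocol, feature) column(s): ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  out <- do.call(cbind, unname(blocks))
  colnames(out) <- cols
  attr(out, "protocol") <- rep(names(blocks),
                               vapply(blocks, ncol, integer(1)))
  attr(out, "feature") <- unlist(lapply(blocks, colnames), use.names = FALSE)
  out
}
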