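# Shared test fixtures: analytic beats and a small cached population study.

# triangular AP: instant rise vrest -> vpeak at t = t0, linear fall back to
# vrest over `fall_ms`; sampled at `dt` ms
# the rise sits exactly on the first sample so threshold crossings on the
# rising edge carry no interpolation error (resting voltage = diastolic
# minimum in spontaneous mode)
triangular_beat <- function(vrest = -80, vpeak = 40, fall_ms = 400,
                            t0 = 0, dt = 1, pad_ms = 100,
                            ca = NULL, mode = "spontaneous") {
  time <- seq(0, t0 + fall_ms + pad_ms, by = dt)
  v <- ifelse(time < t0, vrest,
              ifelse(time <= t0 + fall_ms,
                     vpeak - (vpeak - vrest) * (time - t0) / fall_ms, vrest))
  if (is.null(ca)) ca <- rep(1e-4, length(time))
  crosscell:::new_beat_segment(time, v, ca, t_up = t0,
                               cl = max(time), mode = mode,
                               protocol_id = "synthetic")
}

# exponential Ca transient: ca(t) = base + amp * exp(-t / tau); peak at t = 0
exponential_cat_beat <- function(base = 0.1, amp = 0.5, tau = 200,
                                 dur = 3000, dt = 1) {
  time <- seq(0, dur, by = dt)
  ca <- base + amp * exp(-time / tau)
  # voltage: a plain triangular AP so AP features stay defined
  v <- ifelse(time <= 300, 40 - 120 * time / 300, -80)
  crosscell:::new_beat_segment(time, v, ca, t_up = 0, cl = dur,
                               mode = "paced", protocol_id = "synthetic")
}

# random positive feature blocks shaped like simulator output
synthetic_blocks <- function(ids, n = 20, seed = 1) {
  set.seed(seed)
  out <- list()
  for (id in ids) {
    mode <- if (grepl("spont|Ca|Na|K", id)) "spontaneous" else "paced"
    nms <- feature_names(mode)
    m <- matrix(rlnorm(n * length(nms)), n, length(nms),
                dimnames = list(NULL, nms))
    m[, "Vpeak"] <- rnorm(n, 40, 3)
    m[, "Vrest"] <- rnorm(n, -80, 3)
    out[[id]] <- m
  }
  out
}

# one small population study shared between test files (computed once)
.study_cache <- new.env(parent = emptyenv())
cached_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  sf <- draw_scale_factors(population_config(40, seed = 101))
  mi <- fixture_model("ipsc")
  ma <- fixture_model("adult")
  src <- simulate_population(
    mi, standard_protocols("ipsc", duration = 20)[c("spont", "pace2",
                                                    "CaHigh", "NaHigh")],
    scale_factors = sf, record_tail_ms = 4000)
  tgt <- simulate_population(
    ma, standard_protocols("adult", duration = 20)["pace1"],
    scale_factors = sf, record_tail_ms = 4000, steady_check = TRUE)
  .study_cache$study <- list(sf = sf, source = src, target = tgt)
  .study_cache$study
}
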