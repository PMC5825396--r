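# Fixture models and numerical integration.

test_that("both fixtures expose the same 13 transport pathways", {
  ms <- make_fixture_models()
  keys <- transport_pathways()
  expect_true(all(keys %in% names(ms$adult$params)))
  expect_true(all(keys %in% names(ms$ipsc$params)))
  expect_true(ms$adult$capabilities[["paced"]])
  expect_false(ms$adult$capabilities[["spontaneous"]])
  expect_true(ms$ipsc$capabilities[["spontaneous"]])
})

test_that("adult fixture has an adult-like resting potential and APD90", {
  m <- fixture_model("adult")
  tr <- integrate_model(m, protocol_spec("paced", 1, duration = 20),
                        record_from = -4000)
  f <- extract_features(segment_last_beat(tr))
  expect_lt(abs(f[["Vrest"]] - -85), 4)
  expect_gt(f[["APD90"]], 200)
  expect_lt(f[["APD90"]], 350)
  expect_length(detect_abnormal(segment_last_beat(tr)), 0)
})

test_that("spontaneous fixture self-oscillates in the contract range", {
  m <- fixture_model("ipsc")
  tr <- integrate_model(m, protocol_spec("spontaneous", duration = 10))
  ups <- detect_upstrokes(tr$time, tr$V)
  expect_gte(length(ups), 3)
  f <- extract_features(segment_last_beat(tr))
  expect_gt(f[["rate"]], 0.5)
  expect_lt(f[["rate"]], 1.5)
  # maximum diastolic potential less negative than the adult's rest
  expect_gt(f[["Vrest"]], -85)
})

test_that("APD90 is monotone non-increasing in the GKr multiplier", {
  m <- fixture_model("adult")
  p <- protocol_spec("paced", 1, duration = 12)
  apd <- vapply(c(0.5, 0.75, 1, 1.25, 1.5), function(s) {
    tr <- integrate_model(apply_scaling(m, c(GKr = s)), p)
    extract_features(segment_last_beat(tr))[["APD90"]]
  }, numeric(1))
  expect_true(all(diff(apd) <= 0))
  expect_gt(apd[1], apd[3])  # 50% block clearly prolongs the AP
})

test_that("reducing GCaL reduces the Ca transient amplitude", {
  m <- fixture_model("adult")
  p <- protocol_spec("paced", 1, duration = 12)
  cata <- vapply(c(0.5, 1, 1.5), function(s) {
    tr <- integrate_model(apply_scaling(m, c(GCaL = s)), p)
    extract_features(segment_last_beat(tr))[["CaTA"]]
  }, numeric(1))
  expect_true(all(diff(cata) > 0))
})

test_that("integration is deterministic and spans the full protocol", {
  m <- fixture_model("adult")
  p <- protocol_spec("paced", 1, duration = 10)
  tr1 <- integrate_model(m, p)
  tr2 <- integrate_model(m, p)
  expect_identical(tr1$V, tr2$V)   # max |dV| = 0
  expect_identical(tr1$Cai, tr2$Cai)
  expect_equal(max(tr1$time), 10000)
  expect_equal(min(tr1$time), 0)
})

test_that("a 120 s, 1 Hz protocol contains 120 beats", {
  m <- fixture_model("adult")
  tr <- integrate_model(m, protocol_spec("paced", 1, duration = 120),
                        dt_out = 1)
  ups <- detect_upstrokes(tr$time, tr$V, refractory = 500)
  expect_equal(length(ups), 120)
})

test_that("zero stimulus leaves the non-spontaneous fixture at rest", {
  m <- fixture_model("adult")
  tr <- integrate_model(m, protocol_spec("paced", 1, duration = 10),
                        stim_amp = 0)
  expect_length(detect_upstrokes(tr$time, tr$V), 0)
  expect_lt(diff(range(tr$V)), 10)
  expect_lt(max(tr$V), -75)
})

test_that("spontaneous protocols demand spontaneous capability", {
  m <- fixture_model("adult")
  expect_error(integrate_model(m, protocol_spec("spontaneous", duration = 5)),
               "spontaneous")
})

test_that("step-size collapse is flagged, not thrown", {
  m <- apply_scaling(fixture_model("adult"), c(GNa = 1e8, GCaL = 1e8))
  expect_no_error(tr <- integrate_model(m, protocol_spec("paced", 1,
                                                         duration = 1)))
  expect_true(tr$failed)
  expect_null(segment_last_beat(tr))
})

test_that("the packaged integrator matches an independent stiff solver", {
  skip_if_not_installed("deSolve")
  m <- fixture_model("adult")
  # drive deSolve's lsoda over the same equations, beat by beat, with the
  # stimulus as piecewise-constant segments
  rhs_desolve <- function(t, y, parms) {
    list(unname(model_rhs(m, t, y, istim = parms$istim)))
  }
  y <- unname(m$state0)
  out <- NULL
  for (seg in list(c(0, 2, -33), c(2, 1000, 0), c(1000, 1002, -33),
                   c(1002, 2000, 0))) {
    times <- seq(seg[1], seg[2], by = 0.5)
    sol <- deSolve::lsoda(y, times, rhs_desolve,
                          parms = list(istim = seg[3]),
                          rtol = 1e-8, atol = 1e-10)
    y <- as.numeric(sol[nrow(sol), -1])
    out <- rbind(out, sol[-1, ])
  }
  tr <- integrate_model(m, protocol_spec("paced", 1, duration = 2),
                        dt_out = 0.5)
  v_ref <- out[match(tr$time[-1], out[, 1]), 2]
  expect_lt(max(abs(tr$V[-1] - v_ref)), 0.5)  # mV, across two full beats
})
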