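# Log-normal populations, pairing, and abnormality accounting.

test_that("scale factors follow the configured log-normal distribution", {
  # ~1e6 draws: the 2.5th/97.5th percentiles sit near 60% and 167%
  tab <- draw_scale_factors(population_config(80000, seed = 3))
  v <- as.numeric(tab)
  q <- quantile(v, c(0.025, 0.975))
  expect_equal(unname(q[1]), exp(-1.96 * 0.2624), tolerance = 0.01)
  expect_equal(unname(q[2]), exp(1.96 * 0.2624), tolerance = 0.01)
  expect_equal(unname(q[1]), 0.60, tolerance = 0.02)
  expect_equal(unname(q[2]), 1.67, tolerance = 0.02)

  # median near 1 (log-mean zero); 3 SE band
  se_med <- sqrt(pi / 2) * 0.2624 / sqrt(length(v))
  expect_lt(abs(median(log(v))), 3 * se_med)

  # empirical log-SD within 1% of sigma
  expect_equal(sd(log(v)), 0.2624, tolerance = 0.01)
})

test_that("scale-factor tables are reproducible and well-formed", {
  t1 <- draw_scale_factors(population_config(50, seed = 9))
  t2 <- draw_scale_factors(population_config(50, seed = 9))
  t3 <- draw_scale_factors(population_config(50, seed = 10))
  expect_identical(t1, t2)
  expect_false(identical(t1[, 1], t3[, 1]))
  expect_identical(colnames(t1), transport_pathways())
  expect_true(all(t1 > 0))
  expect_equal(dim(t1), c(50, 13))
})

test_that("paired populations share rows and respect permutations", {
  tab <- draw_scale_factors(population_config(6, seed = 2))
  ms <- make_fixture_models()
  pops <- build_paired_populations(ms$adult, ms$ipsc, tab)
  expect_identical(pops$A$scale_factors, pops$B$scale_factors)
  expect_equal(nrow(pops$A$scale_factors), 6)

  # cell i uses row i: scaled parameters match a manual application
  i <- 4
  mi <- apply_scaling(ms$adult, tab[i, ])
  expect_equal(mi$params[transport_pathways()],
               ms$adult$params[transport_pathways()] * tab[i, ])

  # permuting rows permutes both populations identically
  perm <- c(3, 1, 2, 6, 5, 4)
  pops_p <- build_paired_populations(ms$adult, ms$ipsc, tab[perm, ])
  expect_identical(pops_p$A$scale_factors, pops_p$B$scale_factors)
  expect_identical(pops_p$A$scale_factors, tab[perm, ])

  # a unit row leaves both models at baseline
  unit <- matrix(1, 1, 13, dimnames = list(NULL, transport_pathways()))
  pops_u <- build_paired_populations(ms$adult, ms$ipsc, unit)
  m_u <- apply_scaling(pops_u$A$model, pops_u$A$scale_factors[1, ])
  expect_identical(m_u$params, ms$adult$params)

  bad <- tab; colnames(bad)[1] <- "oops"
  expect_error(build_paired_populations(ms$adult, ms$ipsc, bad), "canonical")
})

test_that("abnormality detectors fire on constructed traces", {
  # repolarization failure: V never returns below -60 mV after upstroke
  t <- seq(0, 900, by = 1)
  v_fail <- ifelse(t < 10, -80, -30 + 5 * exp(-t / 300))
  b_fail <- crosscell:::new_beat_segment(t, v_fail, rep(1e-4, length(t)),
                                         10, 900, "paced", "x")
  expect_true("repolarization_failure" %in% detect_abnormal(b_fail))

  # EAD: a depolarising deflection during late repolarisation; here the
  # falling phase reverses by `rise` mV between 450 and 500 ms
  ead_trace <- function(rise) {
    v <- rep(-80, length(t))
    up <- t >= 10
    v[up] <- 40 - 0.15 * (t[up] - 10)
    seg <- t >= 450 & t < 500
    v[seg] <- v[t == 450] + rise * (t[seg] - 450) / 50
    late <- t >= 500
    v[late] <- v[t == 450] + rise - 0.15 * (t[late] - 500)
    crosscell:::new_beat_segment(t, v, rep(1e-4, length(t)), 10, 900,
                                 "paced", "x")
  }
  expect_true("afterdepolarization" %in% detect_abnormal(ead_trace(5)))

  # sub-threshold (1 mV) bump is not an EAD
  expect_length(detect_abnormal(ead_trace(1)), 0)

  # detectors are pure: same input, same flags
  expect_identical(detect_abnormal(ead_trace(5)), detect_abnormal(ead_trace(5)))
})

test_that("the >25% rule drops conditions strictly above threshold", {
  flag <- function(n_bad, n) {
    c(rep(list("afterdepolarization"), n_bad),
      rep(list(character(0)), n - n_bad))
  }
  expect_true(condition_abnormal_fraction(flag(26, 100))$drop)
  expect_false(condition_abnormal_fraction(flag(25, 100))$drop)  # not "more than"
  expect_false(condition_abnormal_fraction(flag(0, 100))$drop)
  expect_equal(condition_abnormal_fraction(flag(26, 100))$fraction, 0.26)
  expect_error(condition_abnormal_fraction(list()), "empty")
})

test_that("population simulation flags cells and applies the rule", {
  study <- cached_study()
  ab <- study$source$abnormal
  expect_identical(ab$protocol, names(study$source$features))
  expect_true(all(ab$fraction >= 0 & ab$fraction <= 1))
  expect_identical(study$source$retained, ab$protocol[!ab$drop])
  # features of flagged cells may be NA; unflagged rows are complete for
  # retained conditions in this small healthy population
  expect_true(all(dim(study$source$features[[1]]) == c(40, 12)))
})
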