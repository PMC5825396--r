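# Pore-block pharmacology and the hypothetical drug library.

test_that("block_fraction implements IC50/(IC50+[C])", {
  expect_equal(block_fraction(1, 0), 1)            # no drug
  expect_equal(block_fraction(2, 2), 0.5)          # 50% at [C] = IC50
  # secondary target with IC50 = e x primary, at [C] = primary IC50:
  # remaining e/(e+1) = 0.7311 (26.9% block)
  expect_equal(block_fraction(exp(1), 1), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  expect_equal(block_fraction(exp(1), 1), 0.7311, tolerance = 1e-4)
  expect_error(block_fraction(1, -1), "concentration")
  expect_error(block_fraction(0, 1), "IC50")

  # strictly decreasing in concentration
  cc <- seq(0, 10, by = 0.5)
  expect_true(all(diff(block_fraction(1, cc)) < 0))
})

test_that("drug specs validate and convert to scalings", {
  d <- drug("ikr-blocker", c(GKr = 2))
  expect_equal(d$conc, 2)                   # defaults to lowest IC50
  s <- drug_scaling(d)
  expect_equal(s[["GKr"]], 0.5)
  expect_true(all(s[setdiff(names(s), "GKr")] == 1))

  d2 <- drug("two-target", c(GKr = 1, GCaL = exp(1)))
  s2 <- drug_scaling(d2)
  expect_equal(s2[["GKr"]], 0.5)
  expect_equal(s2[["GCaL"]], 0.7311, tolerance = 1e-4)

  # zero concentration is the identity scaling
  expect_equal(drug_scaling(drug("nil", c(GKr = 1), conc = 0)),
               transport_scaling())

  expect_error(drug("bad", c(GXX = 1)), "GXX")
  expect_error(drug("dup", c(GKr = 1, GKr = 2)), "duplicate")
  expect_error(drug("many", setNames(1:6, transport_pathways()[1:6])),
               "at most 5")
})

test_that("the hypothetical library enumerates ordered pathway pairs", {
  lib <- hypothetical_drug_library()
  expect_length(lib, 90)                    # 10 pathways -> 90 drugs
  expect_length(hypothetical_drug_library(c("GKr", "GCaL", "GNa")), 6)

  for (d in lib[c(1, 25, 90)]) {
    expect_equal(unname(d$targets[2] / d$targets[1]), exp(1))
    sc <- drug_scaling(d)
    expect_equal(unname(sc[names(d$targets)[1]]), 0.5)  # primary 50% block
    expect_equal(unname(sc[names(d$targets)[2]]), exp(1) / (exp(1) + 1))
  }
  # all ordered pairs distinct
  expect_false(anyDuplicated(vapply(lib, `[[`, "", "name")) > 0)
})

test_that("drug catalogs load from CSV with row-level validation", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "name,pathway_1,ic50_1,pathway_2,ic50_2,pathway_3,ic50_3,pathway_4,ic50_4,pathway_5,ic50_5",
    "fivehit,GKr,1,GCaL,2,GNa,3,GKs,4,Gto,5",
    "selective,GK1,0.7,,,,,,,,"), path)
  drugs <- load_drug_catalog(path)
  expect_length(drugs, 2)
  expect_length(drugs[[1]]$targets, 5)
  expect_equal(drugs[[1]]$conc, 1)          # min IC50 across targets
  expect_equal(drug_scaling(drugs[[2]])[["GK1"]], 0.5)

  writeLines(c("name,pathway_1,ic50_1,pathway_2,ic50_2",
               "dup,GKr,1,GKr,2"), path)
  expect_error(load_drug_catalog(path), "row 1")
})

test_that("a null drug produces zero changes and zero prediction error", {
  sf <- draw_scale_factors(population_config(4, seed = 3))
  mi <- fixture_model("ipsc"); ma <- fixture_model("adult")
  spro <- standard_protocols("ipsc", duration = 8)[c("spont", "pace2")]
  tpro <- standard_protocols("adult", duration = 8)[["pace1"]]
  src <- simulate_population(mi, spro, scale_factors = sf,
                             record_tail_ms = 3000)
  tgt <- simulate_population(ma, list(pace1 = tpro), scale_factors = sf,
                             record_tail_ms = 3000)
  fit <- fit_crosscell(feature_table(src$features),
                       feature_table(tgt$features), ncomp = 2, k_folds = 2,
                       seed = 1)
  null_drug <- drug("nothing", c(GKr = 1), conc = 0)
  panel <- simulate_drug_panel(mi, ma, fit, list(null_drug), sf, spro, tpro,
                               record_tail_ms = 3000)
  expect_equal(panel$src_mean, c(0, 0), tolerance = 1e-8)
  expect_equal(panel$pred_mean, c(0, 0), tolerance = 1e-8)
  expect_equal(panel$tgt_mean, c(0, 0), tolerance = 1e-8)
})

test_that("predicted APD90 change is monotone in IKr block", {
  study <- cached_study()
  fit <- fit_crosscell(retained_features(study$source),
                       feature_table(study$target$features),
                       seed = 1)
  mi <- fixture_model("ipsc"); ma <- fixture_model("adult")
  spro <- standard_protocols("ipsc", duration = 15)[study$source$retained]
  tpro <- standard_protocols("adult", duration = 15)[["pace1"]]
  sf <- study$sf[1:10, ]
  # 15% / 35% / 50% / 55% block as a concentration sweep [C]/IC50 = f/(1-f)
  drugs <- lapply(c(0.15, 0.35, 0.5, 0.55), function(f) {
    drug(sprintf("ikr%d", round(100 * f)), c(GKr = 1), conc = f / (1 - f))
  })
  panel <- simulate_drug_panel(mi, ma, fit, drugs, sf, spro, tpro,
                               record_tail_ms = 4000)
  apd <- panel$pred_mean[panel$metric == "pace1.APD90"]
  expect_true(all(diff(apd) > 0))
  tgt <- panel$tgt_mean[panel$metric == "pace1.APD90"]
  expect_true(all(diff(tgt) > 0))

  # at 50% block, the translated mean dAPD90 lands within one population
  # SD of the directly simulated target response
  i50 <- which(panel$metric == "pace1.APD90" & panel$drug == "ikr50")
  expect_lt(abs(panel$pred_mean[i50] - panel$tgt_mean[i50]),
            panel$tgt_sd[i50])
})
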