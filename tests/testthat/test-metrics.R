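test_that("M4/M5 citrate split reads off oxidative and reductive entry", {
  pure_ox <- mid(c(0, 0, 0, 0, 1, 0, 0), corrected = TRUE)
  s <- citrate_ox_red(pure_ox)
  expect_equal(s$oxidative_fraction, 1)
  expect_equal(s$reductive_fraction, 0)
  expect_identical(s$ox_over_red, Inf)

  mixed <- mid(c(0.4, 0, 0, 0, 0.2, 0.4, 0), corrected = TRUE)
  s <- citrate_ox_red(mixed)
  expect_equal(s$oxidative_fraction, 0.2)
  expect_equal(s$reductive_fraction, 0.4)
  expect_equal(s$ox_over_red, 0.5)

  expect_error(citrate_ox_red(mid(c(0.5, 0.5))), "6 backbone carbons")
})

test_that("higher reductive flux share flips the citrate split", {
  gln <- tracer_experiment("glutamine", "U")
  cfg <- simulation_preset("control", tracer = gln, seed = 1, f_red = 0.7)
  cit <- propagate_labels(cfg)$mids$citrate
  s <- citrate_ox_red(mid(cit, corrected = TRUE))
  expect_gt(s$reductive_fraction, s$oxidative_fraction)
})

test_that("pool ratios divide normalized ion currents", {
  expect_equal(pool_ratio(2.0, 1.0), 2.0)
  expect_equal(pool_ratio(3.7, 3.7), 1.0)
  expect_error(pool_ratio(1, 0), "zero")
})

test_that("substrate contribution normalizes mean enrichment by feed enrichment", {
  full <- mid(c(0, 0, 0, 1), corrected = TRUE)
  expect_equal(as.numeric(substrate_contribution(full, 1)), 1)
  none <- mid(c(1, 0, 0, 0), corrected = TRUE)
  expect_equal(as.numeric(substrate_contribution(none, 1)), 0)
  # raw mean enrichment rides along for the alternative convention
  half <- mid(c(0.5, 0, 0, 0.5), corrected = TRUE)
  sc <- substrate_contribution(half, 7 / 12)
  expect_equal(attr(sc, "mean_enrichment"), 0.5)
  expect_equal(as.numeric(sc), 0.5 / (7 / 12))
  expect_error(substrate_contribution(half, 0), "tracer_enrichment")
})

test_that("the 1:1 glucose cocktail's achievable enrichment is 7/12", {
  expect_equal(tracer_enrichment(glucose_mix_1to1()), 7 / 12)
  expect_equal(tracer_enrichment(tracer_experiment("glutamine", "U")), 1)
})

test_that("substrate contribution brackets the known glucose share of alpha-ketoglutarate", {
  # under pure U-13C6 glucose all glucose-derived carbons are labeled, so
  # mean enrichment IS the glucose carbon share of alpha-KG. With 60% of
  # the pool from unlabeled glutamine and 40% from citrate, the share is
  # sandwiched between the acetyl-only floor 0.4 * 2/5 = 0.16 (recycled
  # oxaloacetate carbons unlabeled) and the all-citrate ceiling 0.4.
  cfg <- simulation_config(tracer = tracer_experiment("glucose", "U"),
                           tracer_purity = 1,
                           f_ppp = 0, pyr_media_share = 0, f_red = 0,
                           akg_gln_share = 0.6, acetyl_acetate_share = 0,
                           seed = 1)
  akg <- propagate_labels(cfg)$mids$akg
  sc <- substrate_contribution(mid(akg, corrected = TRUE), 1)
  expect_gt(as.numeric(sc), 0.16)
  expect_lt(as.numeric(sc), 0.40)
})

test_that("M1 pyruvate index reads the cocktail-specific glycolysis signal", {
  expect_equal(m1_glycolysis_index(mid(c(1, 0, 0, 0), corrected = TRUE)), 0)
  expect_equal(
    m1_glycolysis_index(mid(c(0.4, 0.2, 0, 0.4), corrected = TRUE)), 0.2)
  expect_error(
    m1_glycolysis_index(mid(c(0.4, 0.2, 0, 0.4), corrected = TRUE),
                        tracer = tracer_experiment("glucose", "U")),
    "index undefined")
})

test_that("oxidative PPP routing strictly lowers the M1 pyruvate index", {
  idx <- vapply(c(0, 0.15, 0.3), function(fp) {
    cfg <- simulation_config(tracer = glucose_mix_1to1(), f_ppp = fp,
                             pyr_media_share = 0, tracer_purity = 1,
                             seed = 1)
    pyr <- propagate_labels(cfg)$mids$pyruvate
    m1_glycolysis_index(mid(pyr, corrected = TRUE))
  }, numeric(1))
  expect_equal(idx[1], 0.25)  # half the 1-13C1 half labels one triose arm
  expect_true(all(diff(idx) < 0))
})

test_that("metrics are invariant to rescaling raw intensities", {
  raw <- c(40, 0, 0, 0, 20, 40, 0)
  a <- citrate_ox_red(normalize_mid(raw, corrected = TRUE))
  b <- citrate_ox_red(normalize_mid(raw * 37.5, corrected = TRUE))
  expect_equal(a$ox_over_red, b$ox_over_red)
})
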