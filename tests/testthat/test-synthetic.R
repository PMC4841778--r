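test_that("an unlabeled feed produces purely unlabeled steady-state MIDs", {
  cfg <- simulation_config(tracer = tracer_experiment("none", "none"),
                           seed = 1)
  pr <- propagate_labels(cfg)
  for (m in pr$mids) expect_equal(m[1], 1)
})

test_that("limiting atom-map cases give pure M4 / M5 citrate", {
  gln <- tracer_experiment("glutamine", "U")
  # all citrate via reductive carboxylation of fully labeled alpha-KG
  red <- propagate_labels(simulation_config(
    tracer = gln, f_red = 1, akg_gln_share = 1, tracer_purity = 1,
    seed = 1))
  expect_equal(red$mids$citrate, c(0, 0, 0, 0, 0, 1, 0), tolerance = 1e-9)
  # oxidative turn with unlabeled acetyl-CoA: M4 citrate, M4 fumarate
  ox <- propagate_labels(simulation_config(
    tracer = gln, f_red = 0, akg_gln_share = 1, pyr_media_share = 1,
    acetyl_acetate_share = 0, tracer_purity = 1, seed = 1))
  expect_equal(ox$mids$citrate, c(0, 0, 0, 0, 1, 0, 0), tolerance = 1e-9)
  expect_equal(ox$mids$fumarate[5], 1, tolerance = 1e-9)
})

test_that("the 1:1 glucose cocktail labels one quarter of pyruvate at M1", {
  cfg <- simulation_config(tracer = glucose_mix_1to1(), f_ppp = 0,
                           pyr_media_share = 0, tracer_purity = 1,
                           seed = 1)
  pyr <- propagate_labels(cfg)$mids$pyruvate
  expect_equal(pyr, c(0.25, 0.25, 0, 0.5), tolerance = 1e-9)
})

test_that("label distributions sum to one at every network node", {
  cfg <- simulation_preset("cde", tracer = tracer_experiment("glutamine", "U"),
                           seed = 3)
  pr <- propagate_labels(cfg)
  for (m in pr$mids) expect_equal(sum(m), 1, tolerance = 1e-9)
  expect_equal(sum(pr$palmitate), 1, tolerance = 1e-9)
  expect_equal(sum(pr$lipogenic_acetyl), 1, tolerance = 1e-9)
})

test_that("carbon maps conserve label between reactants, products, and CO2", {
  set.seed(8)
  maps <- list(
    list(n_src = 6L, map = c(3L, 2L, 1L)),   # glycolysis DHAP arm
    list(n_src = 3L, map = c(2L, 3L)),       # PDH (loses C1)
    list(n_src = 6L, map = 2:6),             # citrate -> alpha-KG
    list(n_src = 5L, map = 2:5)              # alpha-KG -> succinate
  )
  for (mp in maps) {
    d <- stats::rgamma(2^mp$n_src, 1); d <- d / sum(d)
    marg <- exoflux:::iso_position_marginals(d, mp$n_src)
    prod <- exoflux:::apply_carbon_map(d, mp$n_src, mp$map)
    marg_prod <- exoflux:::iso_position_marginals(prod, length(mp$map))
    retained <- sum(marg[mp$map])
    lost <- sum(marg[setdiff(seq_len(mp$n_src), mp$map)])
    expect_equal(sum(marg_prod), retained, tolerance = 1e-12)
    expect_equal(sum(marg), retained + lost, tolerance = 1e-12)
  }
})

test_that("succinate scrambling is symmetric and mass-preserving", {
  d <- stats::rgamma(16, 1); d <- d / sum(d)
  s <- exoflux:::iso_scramble(d, 4L)
  expect_equal(sum(s), 1)
  expect_equal(exoflux:::iso_to_mid(s, 4L), exoflux:::iso_to_mid(d, 4L))
  marg <- exoflux:::iso_position_marginals(s, 4L)
  expect_equal(marg, rev(marg))
})

test_that("exosome transfer honours its limiting cases", {
  # zero supply: cell pools unlabeled (before noise)
  cfg0 <- simulation_preset("control", seed = 5, noise_sd = 0,
                            cargo_supply_fraction = c(leucine = 0,
                                                      lysine = 0))
  tr0 <- simulate_exosome_transfer(cfg0)
  for (m in tr0$truth$mids) expect_equal(m$cell[1], 1)

  # full supply of a fully labeled cargo, no turnover: cell matches tracer
  cfg1 <- simulation_config(seed = 5, noise_sd = 0, tracer_purity = 1,
                            exosome_label_fraction = 0.999,
                            cargo_supply_fraction = c(lysine = 1))
  tr1 <- simulate_exosome_transfer(cfg1)
  expect_gt(tr1$truth$mids$lysine$cell[7], 0.99)  # M+6 lysine
})

test_that("simulated output is byte-identical under a fixed seed", {
  cfg <- simulation_preset("cde", seed = 17)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_mid_table(simulate_mids(cfg)$table, f1)
  write_mid_table(simulate_mids(cfg)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
  t1 <- simulate_exosome_transfer(cfg)
  t2 <- simulate_exosome_transfer(cfg)
  expect_identical(t1$cell_table, t2$cell_table)
})

test_that("configuration validation guards shares, seeds, and labeling fraction", {
  expect_error(simulation_config(), "seed is mandatory")
  expect_error(simulation_config(glucose_share_of_acetyl = 0.8,
                                 glutamine_share = 0.3, seed = 1),
               "sum to <= 1")
  expect_error(simulation_config(exosome_label_fraction = 1, seed = 1),
               "sub-replication")
  expect_error(simulation_config(f_red = 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("non-convergence raises a diagnostic error", {
  cfg <- simulation_preset("control", seed = 1)
  expect_error(propagate_labels(cfg, tol = 0, max_iter = 3L),
               "did not converge")
})
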