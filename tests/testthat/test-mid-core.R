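test_that("raw intensities normalize proportionally and reject empty spectra", {
  expect_equal(normalize_mid(c(2, 1, 1))$fractions, c(0.5, 0.25, 0.25))
  expect_equal(normalize_mid(c(5, 0, 0))$fractions, c(1, 0, 0))
  expect_error(normalize_mid(c(0, 0, 0)), "empty spectrum")
  expect_error(normalize_mid(c(1, -1, 0)), "non-negative")
  expect_error(mid(c(0.5, 0.4), n_carbons = 2), "length")
  expect_error(mid(c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("mean enrichment evaluates the per-carbon labeling average", {
  expect_equal(mean_enrichment(mid(c(1, 0, 0))), 0)
  expect_equal(mean_enrichment(mid(c(0, 0, 1))), 1)
  expect_equal(mean_enrichment(mid(c(0.5, 0.25, 0.25))), 0.375)
})

test_that("mean enrichment is linear in the MID and bounded in [0, 1]", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    a <- random_mid(n); b <- random_mid(n)
    w <- runif(1)
    mixed <- mid(w * a$fractions + (1 - w) * b$fractions, n_carbons = n)
    expect_equal(mean_enrichment(mixed),
                 w * mean_enrichment(a) + (1 - w) * mean_enrichment(b))
    expect_gte(mean_enrichment(a), 0)
    expect_lte(mean_enrichment(a), 1)
  }
})

test_that("MID convolution enumerates condensation outcomes", {
  expect_equal(convolve_mids(mid(c(1, 0)), mid(c(1, 0)))$fractions,
               c(1, 0, 0))
  expect_equal(convolve_mids(mid(c(0, 1)), mid(c(0, 1)))$fractions,
               c(0, 0, 1))
  expect_equal(convolve_mids(mid(c(0.5, 0.5)), mid(c(0.5, 0.5)))$fractions,
               c(0.25, 0.5, 0.25))
})

test_that("MID convolution is commutative, associative, and normalized", {
  set.seed(7)
  for (rep in 1:10) {
    a <- random_mid(sample(1:4, 1))
    b <- random_mid(sample(1:4, 1))
    c3 <- random_mid(sample(1:4, 1))
    expect_equal(convolve_mids(a, b)$fractions,
                 convolve_mids(b, a)$fractions)
    expect_equal(convolve_mids(convolve_mids(a, b), c3)$fractions,
                 convolve_mids(a, convolve_mids(b, c3))$fractions)
    expect_equal(sum(convolve_mids(a, b)$fractions), 1)
  }
})

test_that("correction matrix matches direct binomial evaluation", {
  # trivial: nothing to correct -> identity
  M <- build_correction_matrix(fragment_formula(c(C = 2), 2),
                               backbone_natural = FALSE)
  expect_equal(M, diag(3))

  # 2-carbon backbone plus one non-backbone carbon at 13C abundance 0.011
  ab <- iupac_isotopes(); ab$C <- c(0.989, 0.011)
  M <- build_correction_matrix(fragment_formula(c(C = 3), 2), ab,
                               backbone_natural = FALSE)
  expect_equal(M[1, 1], 0.989)
  expect_equal(M[2, 1], 0.011)
  expect_equal(M[3, 1], 0)
  # every column is shifted by the same one-carbon distribution
  expect_equal(M[2, 2], 0.989)
  expect_equal(M[3, 2], 0.011)
})

test_that("column sums stay <= 1 for a large Si-containing fragment", {
  frag <- fragment_formula("C20H39O7Si3", 6)  # TBDMS-citrate-like
  M <- build_correction_matrix(frag)
  expect_true(all(M >= 0))
  expect_true(all(colSums(M) <= 1 + 1e-12))
  # heavy Si isotopes push real mass off the window: strict loss
  expect_lt(sum(M[, 1]), 1)
})

test_that("unsupported elements are rejected", {
  expect_error(fragment_formula(c(C = 2, P = 1), 2), "unsupported element")
  expect_error(fragment_formula("C2Br1", 2), "unsupported element")
})

test_that("correction inverts forward natural-abundance convolution", {
  # identity matrix leaves the MID untouched
  x <- mid(c(0.2, 0.3, 0.5))
  expect_equal(correct_natural_abundance(x, diag(3))$fractions, x$fractions)

  # pure unlabeled compound: raw equals the matrix's column 0
  frag <- fragment_formula("C9H15NO2Si", 3)
  M <- build_correction_matrix(frag)
  raw <- normalize_mid(M[, 1])
  rec <- correct_natural_abundance(raw, M)
  expect_equal(rec$fractions, c(1, 0, 0, 0), tolerance = 1e-10)

  # round trip over random MIDs and fragments
  set.seed(11)
  for (rep in 1:50) {
    frag <- random_fragment()
    n <- frag$n_backbone_carbons
    M <- build_correction_matrix(frag)
    x <- random_mid(n)$fractions
    raw <- as.numeric(M %*% x)
    rec <- correct_natural_abundance(normalize_mid(raw), M)
    expect_lt(max(abs(rec$fractions - x)), 1e-10)
  }
})

test_that("correcting an unlabeled compound's theoretical spectrum gives M0 >= 0.999", {
  set.seed(3)
  for (rep in 1:10) {
    frag <- random_fragment()
    M <- build_correction_matrix(frag)
    raw <- normalize_mid(M[, 1])  # theoretical unlabeled spectrum
    rec <- correct_natural_abundance(raw, M)
    expect_gte(rec$fractions[1], 0.999)
  }
})

test_that("correction enforces dimensions and correction state", {
  expect_error(correct_natural_abundance(mid(c(0.5, 0.5)), diag(3)),
               "dimensions")
  done <- mid(c(0.5, 0.5), corrected = TRUE)
  expect_error(correct_natural_abundance(done, diag(2)), "already")
})
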