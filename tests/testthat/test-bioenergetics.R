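make_series <- function(levels = c(100, 30, 250, 10), ecar = 30,
                        protein = 1, n = 5, dt = 6) {
  ocr <- rep(levels, each = n)
  times <- dt * (seq_along(ocr) - 1)
  inj <- dt * n * (1:3) - dt / 2
  list(series = flux_time_series(times, ocr, rep(ecar, length(ocr)),
                                 protein_ug = protein),
       schedule = injection_schedule(inj, c("oligomycin", "FCCP",
                                            "rotenone/antimycin")))
}

test_that("piecewise-constant stress test yields the textbook arithmetic", {
  fx <- make_series(levels = c(100, 30, 250, 10))
  m <- derive_bioenergetics(fx$series, fx$schedule)
  expect_equal(m$basal_ocr, 90)       # 100 - 10
  expect_equal(m$basal_ocr_raw, 100)
  expect_equal(m$maximal_ocr, 240)    # 250 - 10
  expect_equal(m$reserve_ocr, 150)
  expect_equal(m$nonmito_ocr, 10)
  expect_equal(m$basal_ecar, 30)
})

test_that("FCCP plateau at baseline gives zero reserve", {
  fx <- make_series(levels = c(100, 30, 100, 10))
  m <- derive_bioenergetics(fx$series, fx$schedule)
  expect_equal(m$reserve_ocr, 0)
})

test_that("reserve is exactly maximal minus basal and rates are floored at zero", {
  set.seed(4)
  for (rep in 1:5) {
    lv <- sort(runif(3, 5, 300))  # nonmito < basal < maximal
    fx <- make_series(levels = c(lv[2], lv[1], lv[3], lv[1]))
    m <- derive_bioenergetics(fx$series, fx$schedule)
    expect_equal(m$reserve_ocr, m$maximal_ocr - m$basal_ocr)
    expect_true(all(unlist(m) >= 0))
  }
  # an FCCP response below the ETC-block floor triggers the zero floor
  fx <- make_series(levels = c(100, 30, 5, 10))
  expect_warning(m <- derive_bioenergetics(fx$series, fx$schedule),
                 "floored")
  expect_equal(m$maximal_ocr, 0)
})

test_that("missing segments disable only the dependent metrics", {
  fx <- make_series()
  no_fccp <- injection_schedule(fx$schedule$time_min[c(1, 3)],
                                c("oligomycin", "rotenone"))
  m <- derive_bioenergetics(fx$series, no_fccp)
  expect_true(is.na(m$maximal_ocr))
  expect_true(is.na(m$reserve_ocr))
  expect_false(is.na(m$basal_ocr))
  expect_false(is.na(m$nonmito_ocr))
})

test_that("metrics are invariant to time shifts and protein rescaling", {
  fx <- make_series(protein = 1)
  m1 <- derive_bioenergetics(fx$series, fx$schedule)
  shifted <- flux_time_series(fx$series$time_min + 37, fx$series$ocr,
                              fx$series$ecar, protein_ug = 1)
  sched2 <- injection_schedule(fx$schedule$time_min + 37,
                               fx$schedule$compound)
  m2 <- derive_bioenergetics(shifted, sched2)
  expect_equal(m1, m2)
  # doubling both signal and protein mass leaves per-ug rates unchanged
  doubled <- flux_time_series(fx$series$time_min, fx$series$ocr * 2,
                              fx$series$ecar * 2, protein_ug = 2)
  m3 <- derive_bioenergetics(doubled, fx$schedule)
  expect_equal(m1, m3)
})

test_that("noisy simulated series recover the configured rates within 2 sd/sqrt(n)", {
  sd <- 3; n_draws <- 50
  est <- replicate(n_draws, {
    fx <- simulate_flux_series(100, 250, 10, noise_sd = sd,
                               seed = sample.int(1e6, 1))
    derive_bioenergetics(fx$series, fx$schedule)$basal_ocr
  })
  se <- sd / sqrt(3)  # window of 3 measurements
  expect_lt(abs(mean(est) - 90), 2 * se / sqrt(n_draws) * 3)
})

test_that("flux CSV and schedule YAML round-trip through the readers", {
  fx <- make_series()
  df <- data.frame(well = "A1", condition = "control",
                   time_min = fx$series$time_min, ocr = fx$series$ocr,
                   ecar = fx$series$ecar, protein_ug = 1)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  wells <- read_flux_csv(csv)
  expect_length(wells, 1)
  m <- derive_bioenergetics(wells[["A1"]], fx$schedule)
  expect_equal(m$basal_ocr, 90)

  yml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    list(time = 27, compound = "oligomycin", concentration = "2 ug/ml"),
    list(time = 57, compound = "FCCP", concentration = "2.5 uM"),
    list(time = 87, compound = "rotenone", concentration = "2 uM"))), yml)
  sched <- read_injection_schedule(yml)
  expect_equal(sched$compound, c("oligomycin", "fccp", "etc_block"))
  m2 <- derive_bioenergetics(fx$series, sched)
  expect_equal(m2$maximal_ocr, 240)
})

test_that("series validation rejects malformed input", {
  expect_error(flux_time_series(c(0, 0, 6), c(1, 2, 3), protein_ug = 1),
               "strictly increasing")
  expect_error(flux_time_series(c(0, 6), c(1, 2), protein_ug = 0),
               "positive")
  expect_error(injection_schedule(c(10, 5), c("oligomycin", "fccp")),
               "strictly increasing")
  expect_error(injection_schedule(5, "glucose"), "unknown injection")
  expect_error(simulate_flux_series(100, 90, 10), "maximal >= basal")
})
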