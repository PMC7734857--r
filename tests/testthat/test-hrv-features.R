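test_that("time-domain statistics match hand computations", {
  const <- make_epoch(rep(1000, 100))
  td <- time_domain(const)
  expect_equal(unname(td[c("RR", "HR", "SDNN", "RMSSD", "CVRR")]),
               c(1000, 60, 0, 0, 0))

  alt <- make_epoch(c(1000, 1010, 1000, 1010))
  expect_equal(unname(time_domain(alt)["RMSSD"]), 10)

  expect_error(time_domain(make_epoch(1000)), "too short")
})

test_that("mean heart rate is consistent with the mean RR at low variability", {
  set.seed(2)
  e <- make_epoch(1040.7 + stats::rnorm(1800, 0, 15))
  hr <- time_domain(e)[["HR"]]
  expect_lt(abs(hr - 60000 / 1040.7), 0.5)
  # the alternative definition is exactly 60000 / mean(RR)
  hr2 <- time_domain(e, hr_method = "mean_rr")[["HR"]]
  expect_equal(hr2, 60000 / mean(e$intervals))
})

test_that("time-domain measures are scale-equivariant", {
  set.seed(3)
  e <- make_epoch(stats::runif(500, 800, 1000))
  for (c_mult in c(0.5, 1.3)) {
    a <- time_domain(e)
    b <- time_domain(make_epoch(e$intervals * c_mult))
    expect_equal(b[["SDNN"]], c_mult * a[["SDNN"]])
    expect_equal(b[["RMSSD"]], c_mult * a[["RMSSD"]])
    expect_equal(b[["CVRR"]], a[["CVRR"]])
    pa <- poincare_features(e)
    pb <- poincare_features(make_epoch(e$intervals * c_mult))
    expect_equal(unname(pb), unname(c_mult * pa))
  }
})

test_that("tachogram resampling reproduces analytic RR signals", {
  const <- make_epoch(rep(1000, 300))
  tg <- resample_rr(const)
  expect_true(all(abs(tg$rr - 1000) < 1e-6))
  expect_gte(length(tg$rr), 240)

  # beats generated from a 0.1 Hz sinusoidal RR modulation are recovered
  f <- function(t) 1000 + 50 * sin(2 * pi * 0.1 * t)
  rr <- beats_from_rate(f, 300)
  tg <- resample_rr(make_epoch(rr))
  amp <- (max(tg$rr) - min(tg$rr)) / 2
  expect_lt(abs(amp - 50) / 50, 0.05)

  expect_error(resample_rr(make_epoch(c(1000, 1000, 1000))), "unusable")
  # 4 beats but spanning under a minute
  expect_error(resample_rr(make_epoch(rep(500, 4))), "unusable")
})

test_that("single tones are localized to the correct frequency band", {
  for (f0 in c(0.02, 0.1, 0.25)) {
    tg <- make_tachogram(function(t) {
      900 + 40 * sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 0.7 * t)
    })
    sf <- spectral_features(tg)
    band <- if (f0 < 0.04) "VLF" else if (f0 < 0.15) "LF" else "HF"
    expect_lt(abs(sf[[paste0(band, "_Hz")]] - f0), 4 / 1024 + 1e-9)
    expect_gt(sf[[paste0(band, "_perc")]], 90)
  }
})

test_that("equal-power tones give unit LF/HF ratio and nu sums to 100", {
  tg <- make_tachogram(function(t) {
    1000 + 30 * sin(2 * pi * 0.1 * t) + 30 * sin(2 * pi * 0.25 * t + 1)
  })
  sf <- spectral_features(tg)
  expect_lt(abs(sf[["LF_HF"]] - 1), 0.1)
  expect_equal(sf[["LF_nu"]] + sf[["HF_nu"]], 100, tolerance = 1e-9)
  expect_true(sf[["LF_Hz"]] >= 0.04 && sf[["LF_Hz"]] < 0.15)
  expect_true(sf[["HF_Hz"]] >= 0.15 && sf[["HF_Hz"]] <= 0.4)
})

test_that("total spectral power satisfies Parseval against the tachogram", {
  set.seed(4)
  for (i in 1:20) {
    sd_i <- stats::runif(1, 5, 40)
    x <- stats::rnorm(7201, 0, sd_i)
    tg <- list(t = seq(0, 1800, by = 0.25), rr = 1000 + x, fs = 4)
    sf <- spectral_features(tg)
    expect_lt(abs(sf[["Total_ms_sq"]] - stats::var(x)) / stats::var(x), 0.15)
  }
})

test_that("Poincare dispersions obey their algebraic identities", {
  expect_equal(unname(poincare_features(make_epoch(rep(900, 50)))), c(0, 0))
  expect_error(poincare_features(make_epoch(c(900, 910))), "too short")

  # hand case: alternating series, SD1 from successive differences
  e <- make_epoch(c(1000, 1010, 1000, 1010, 1000))
  sdsd <- stats::sd(diff(e$intervals))
  pc <- poincare_features(e)
  expect_equal(pc[["SD1"]], sqrt(0.5) * sdsd)
  # SD1 equals the dispersion perpendicular to the identity line of the
  # lag-1 return map (rotated-axes definition)
  x1 <- e$intervals[-5]; x2 <- e$intervals[-1]
  expect_equal(pc[["SD1"]], stats::sd((x2 - x1) / sqrt(2)))
  # here 2*SDNN^2 < SDSD^2/2: the SD2 radicand clamps at zero
  expect_equal(pc[["SD2"]], 0)

  # identity SD1^2 + SD2^2 = 2 SDNN^2 whenever no clamping occurs
  set.seed(5)
  for (i in 1:10) {
    e <- make_epoch(stats::rnorm(200, 900, 30))
    pc <- poincare_features(e)
    expect_equal(pc[["SD1"]]^2 + pc[["SD2"]]^2,
                 2 * stats::sd(e$intervals)^2, tolerance = 1e-6)
  }

  # white noise: SD1 and SD2 both near the marginal SD
  set.seed(6)
  e <- make_epoch(stats::rnorm(2000, 1000, 30))
  pc <- poincare_features(e)
  expect_lt(abs(pc[["SD1"]] - 30) / 30, 0.1)
  expect_lt(abs(pc[["SD2"]] - 30) / 30, 0.1)
})

test_that("feature tables have one row per complete epoch with NA policy", {
  p <- rr_gen_params(broadband_sd = 10, slow_trend_amp = 0)
  s <- gen_rr_series(p, duration_hours = 20.5, seed = 31)
  tab <- compute_feature_table(s)
  expect_equal(nrow(tab), 41)
  expect_equal(tab$time_point, 1:41)
  expect_true(all(hrv_feature_names() %in% names(tab)))
  expect_false(anyNA(tab[, hrv_feature_names()]))

  expect_error(
    compute_feature_table(rr_series(rep(1000, 29 * 60))),
    "shorter than one epoch"
  )

  # an epoch with only two huge intervals: time-domain computable, but
  # Poincare and spectral columns go missing while the row is retained
  set.seed(8)
  chunk <- function() {
    x <- stats::rnorm(1800, 1000, 20)
    x * (1800e3 / sum(x))  # exactly 30 minutes
  }
  rr <- c(chunk(), 900e3, 900e3, chunk())
  tab2 <- compute_feature_table(rr_series(rr))
  expect_equal(nrow(tab2), 3)
  expect_false(anyNA(tab2[c(1, 3), hrv_feature_names()]))
  expect_false(is.na(tab2$SDNN[2]))
  expect_true(is.na(tab2$SD1[2]))
  expect_true(is.na(tab2$Total_ms_sq[2]))
})

test_that("normalized units always sum to 100 when defined", {
  set.seed(7)
  for (i in 1:5) {
    tg <- make_tachogram(function(t) {
      900 + stats::rnorm(length(t), 0, 20) +
        stats::runif(1, 5, 40) * sin(2 * pi * 0.1 * t)
    })
    sf <- spectral_features(tg)
    expect_equal(sf[["LF_nu"]] + sf[["HF_nu"]], 100, tolerance = 1e-6)
  }
})
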