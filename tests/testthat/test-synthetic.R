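test_that("the RR generator is deterministic and respects its invariants", {
  p <- rr_gen_params()
  s1 <- gen_rr_series(p, duration_hours = 1, seed = 5)
  s2 <- gen_rr_series(p, duration_hours = 1, seed = 5)
  expect_identical(s1$intervals, s2$intervals)
  expect_false(identical(
    s1$intervals, gen_rr_series(p, duration_hours = 1, seed = 6)$intervals
  ))

  # silence: no oscillations, no noise -> a constant series
  quiet <- rr_gen_params(lf_amp = 0, hf_amp = 0, broadband_sd = 0,
                         slow_trend_amp = 0)
  sq <- gen_rr_series(quiet, duration_hours = 1, seed = 1)
  expect_equal(stats::sd(sq$intervals), 0)
  expect_equal(mean(sq$intervals), 900)

  # records reach the requested duration (complete final epoch included)
  expect_gte(rr_duration(s1), 3600)
  expect_length(segment_epochs(gen_rr_series(p, 24, seed = 2)), 48)

  expect_error(rr_gen_params(mean_rr = 100), "mean_rr")
  expect_error(rr_gen_params(lf_amp = -1), "non-negative")
  expect_error(gen_rr_series(p, duration_hours = 0.2), "at least one epoch")
})

test_that("generated mean RR tracks the configured mean", {
  set.seed(61)
  for (mrr in c(700, 900, 1100)) {
    s <- gen_rr_series(rr_gen_params(mean_rr = mrr), duration_hours = 2)
    expect_lt(abs(mean(s$intervals) - mrr) / mrr, 0.02)
  }
})

test_that("spectral content of generated series responds to its knobs", {
  set.seed(62)
  hf_lo <- hf_hi <- sdnn_lo <- sdnn_hi <- numeric(20)
  for (i in 1:20) {
    base <- rr_gen_params(hf_amp = 15, broadband_sd = 10,
                          slow_trend_amp = 0)
    dbl <- rr_gen_params(hf_amp = 30, broadband_sd = 10,
                         slow_trend_amp = 0)
    noisy <- rr_gen_params(hf_amp = 15, broadband_sd = 30,
                           slow_trend_amp = 0)
    f_base <- compute_feature_table(gen_rr_series(base, 1))
    f_dbl <- compute_feature_table(gen_rr_series(dbl, 1))
    f_noisy <- compute_feature_table(gen_rr_series(noisy, 1))
    hf_lo[i] <- mean(f_base$HF_ms_sq); hf_hi[i] <- mean(f_dbl$HF_ms_sq)
    sdnn_lo[i] <- mean(f_base$SDNN); sdnn_hi[i] <- mean(f_noisy$SDNN)
  }
  # doubling the HF amplitude raises HF band power essentially always
  expect_gte(mean(hf_hi > hf_lo), 0.95)
  expect_gt(mean(hf_hi) / mean(hf_lo), 2)
  # tripling broadband noise raises SDNN
  expect_gte(mean(sdnn_hi > sdnn_lo), 0.95)
})

test_that("HF-dominant dynamics give LF/HF below one in every epoch", {
  p <- rr_gen_params(lf_amp = 4, hf_amp = 60, broadband_sd = 5,
                     slow_trend_amp = 0)
  ft <- compute_feature_table(gen_rr_series(p, 2, seed = 63))
  expect_true(all(ft$LF_HF < 1))
})

test_that("cohort generation matches its configured structure exactly", {
  cfg <- cohort_config(seed = 77)
  co <- gen_cohort(cfg, compute_features = FALSE)
  truth <- attr(co, "truth")
  labels <- cohort_labels(co)
  expect_length(labels, 26)
  expect_equal(sum(labels == 0), 21)
  expect_equal(sum(labels == 1), 5)
  # exactly two truncated non-survivors, truncation range respected
  short <- truth$record_hours < cfg$record_hours
  expect_equal(sum(short), 2)
  expect_true(all(truth$outcome[short] == "non_survivor"))
  expect_true(all(truth$record_hours[short] >= 6 &
                    truth$record_hours[short] <= 12))
  # non-survivor effect multipliers recorded in the ground truth
  expect_true(all(truth$variability_decay[truth$outcome == "survivor"] == 1))
  expect_true(all(truth$variability_decay[truth$outcome == "non_survivor"] ==
                    cohort_effects()$decay))

  # determinism
  co2 <- gen_cohort(cfg, compute_features = FALSE)
  expect_identical(attr(co2, "truth"), truth)

  # null effects remove every group difference from the parameter draws
  nul <- gen_cohort(cohort_config(seed = 77, effects = null_effects()),
                    compute_features = FALSE)
  tn <- attr(nul, "truth")
  expect_true(all(tn$variability_decay == 1))
})

test_that("full feature tables are attached when requested", {
  cfg <- cohort_config(n_survivors = 2, n_non_survivors = 1,
                       n_truncated_non_survivors = 0,
                       record_hours = 5, seed = 42)
  co <- gen_cohort(cfg)
  p <- co$patients[[1]]
  expect_equal(nrow(p$features), 10)     # 5 h -> 10 epochs
  expect_equal(nrow(p$distf), 3)         # 10 - 8 + 1 windows
  expect_true(all(paste0("Dist", hrv_feature_names()) %in% names(p$distf)))
})
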