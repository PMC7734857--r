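# Shared fixtures: analytic beat generators and hand-built toy cohorts.
# Everything here is constructed in code at test time; no stored data.

# Emit beats from an analytic instantaneous RR function rr_fun(t) [ms],
# integrating beat-by-beat: the oracle path for resampling/spectral tests.
beats_from_rate <- function(rr_fun, duration_s) {
  t <- 0
  rr <- numeric(0)
  while (t < duration_s) {
    r <- rr_fun(t)
    rr <- c(rr, r)
    t <- t + r / 1000
  }
  rr
}

make_epoch <- function(intervals) {
  list(index = 0L, start_s = 0, end_s = sum(intervals) / 1000,
       intervals = intervals)
}

# Uniform tachogram built directly from an analytic function of time (s).
make_tachogram <- function(f, duration_s = 1800, fs = 4) {
  t <- seq(0, duration_s, by = 1 / fs)
  list(t = t, rr = f(t), fs = fs)
}

# A minimal cohort with fabricated feature tables: one plain feature `f1`,
# distance features `Distf1` (informative when `signal` > 0) and `Distf2`
# (pure noise), plus an uninformative constant `Distflat` and severity
# scores. Fast: no RR generation involved.
toy_cohort <- function(n_survivors = 12, n_non_survivors = 5,
                       n_time_points = 12, signal = 0,
                       score_shift = 0, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("S%02d", seq_len(n_survivors)),
           sprintf("N%02d", seq_len(n_non_survivors)))
  outcomes <- rep(c("survivor", "non_survivor"),
                  c(n_survivors, n_non_survivors))
  patients <- Map(function(id, outc) {
    is_ns <- outc == "non_survivor"
    base <- stats::rnorm(1, 50, 10) + if (is_ns) signal else 0
    tp <- seq_len(n_time_points)
    features <- data.frame(patient_id = id, time_point = tp,
                           f1 = base + stats::rnorm(n_time_points, 0, 2))
    distf <- data.frame(
      patient_id = id, time_point = tp,
      window_start = tp, window_end = tp + 7L,
      Distf1 = abs(base) * sqrt(8) + stats::rnorm(n_time_points, 0, 2),
      Distf2 = stats::rnorm(n_time_points, 100, 10),
      Distflat = 7
    )
    list(patient_id = id, outcome = outc,
         scores = c(APACHE_II = stats::rnorm(1, 15, 5) +
                      if (is_ns) score_shift else 0),
         features = features, distf = distf)
  }, ids, outcomes)
  hrv_cohort(patients)
}
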