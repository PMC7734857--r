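#' Default HRV frequency band limits (Hz)
#'
#' Very-low, low and high frequency bands of the short-term HRV standard:
#' VLF [0, 0.04), LF [0.04, 0.15), HF [0.15, 0.4]. The ultra-low band is
#' not computed (it is not resolvable from 30-minute epochs).
#'
#' @return Named list of 2-vectors `vlf`, `lf`, `hf`.
#' @export
hrv_bands <- function() {
  list(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

#' Resample an epoch's RR tachogram onto a uniform grid
#'
#' Spectral estimation needs uniformly sampled data, but beats arrive at
#' irregular times. The RR value of each interval is placed at its beat
#' onset time and RR(t) is interpolated with a cubic spline, evaluated on a
#' uniform grid at `fs` over the epoch's beat-time range.
#'
#' @param epoch One element of [segment_epochs()] output.
#' @param fs Sampling frequency in Hz (default 4, the usual tachogram rate;
#'   Nyquist 2 Hz comfortably covers the 0.4 Hz upper HF edge).
#' @return List with `t` (s, relative to first beat of the epoch), `rr`
#'   (ms) and `fs`.
#' @export
resample_rr <- function(epoch, fs = 4) {
  rr <- epoch$intervals
  n <- length(rr)
  if (n < 4L) stop("epoch unusable for spectral analysis: fewer than 4 beats")
  onsets <- cumsum(c(0, rr[-n])) / 1000
  span <- onsets[n] - onsets[1]
  if (span < 60) stop("epoch unusable for spectral analysis: span under 60 s")
  f <- stats::splinefun(onsets, rr, method = "fmm")
  grid <- seq(onsets[1], onsets[n], by = 1 / fs)
  list(t = grid, rr = f(grid), fs = fs)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the (already detrended) series is cut into
#' Hann-windowed segments of `nperseg` samples with 50% overlap and the
#' one-sided periodograms are averaged. The PSD is normalised as a density
#' (ms^2/Hz): its integral over frequency equals the series variance up to
#' windowing loss.
#'
#' @param x Numeric series (uniformly sampled, zero-mean/detrended).
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length in samples; shortened to `length(x)` when
#'   the series is shorter.
#' @return List with `freq` (Hz) and `psd` (power density).
#' @export
welch_psd <- function(x, fs, nperseg = 1024) {
  n <- length(x)
  if (n < 8L) stop("series too short for spectral estimation")
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))
  wss <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * wss)
    p <- sp[seq_len(nfreq)]
    # fold the negative frequencies into the one-sided density
    if (nperseg %% 2 == 0) {
      p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    } else {
      p[2:nfreq] <- 2 * p[2:nfreq]
    }
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = acc / length(starts))
}

band_mask <- function(freq, band, closed_right = FALSE) {
  if (closed_right) freq >= band[1] & freq <= band[2]
  else freq >= band[1] & freq < band[2]
}

#' Frequency-domain HRV parameters from a resampled tachogram
#'
#' The tachogram is linearly detrended and its PSD estimated by Welch's
#' method (256-s Hann segments at 4 Hz, 50% overlap, by default). Band
#' powers are the integral of the PSD over the VLF, LF and HF bands;
#' relative powers are percentages of the total spectral power (the
#' integral over the full 0--Nyquist range, i.e. the tachogram variance);
#' normalized units divide LF and HF by the in-band total minus VLF, so
#' LF_nu + HF_nu = 100; peak frequencies are the PSD argmax within each
#' band (the zero-frequency bin is excluded from peak search).
#'
#' @param tachogram Output of [resample_rr()].
#' @param bands Band limits, see [hrv_bands()].
#' @param nperseg Welch segment length in samples (default 1024 = 256 s at
#'   4 Hz).
#' @param detrend `"linear"` (default) removes a least-squares line before
#'   the PSD; `"mean"` removes only the mean.
#' @return Named numeric vector with elements `VLF_Hz`, `LF_Hz`, `HF_Hz`,
#'   `VLF_ms_sq`, `LF_ms_sq`, `HF_ms_sq`, `VLF_perc`, `LF_perc`, `HF_perc`,
#'   `LF_nu`, `HF_nu`, `Total_ms_sq`, `LF_HF`. `LF_HF` is `NA` when the HF
#'   power is zero.
#' @export
spectral_features <- function(tachogram, bands = hrv_bands(), nperseg = 1024,
                              detrend = c("linear", "mean")) {
  detrend <- match.arg(detrend)
  x <- tachogram$rr
  if (detrend == "linear") {
    tt <- tachogram$t - mean(tachogram$t)
    x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  } else {
    x <- x - mean(x)
  }
  sp <- welch_psd(x, fs = tachogram$fs, nperseg = nperseg)
  df <- sp$freq[2] - sp$freq[1]
  total <- sum(sp$psd) * df

  power_in <- function(mask) sum(sp$psd[mask]) * df
  peak_in <- function(mask) {
    mask <- mask & sp$freq > 0
    if (!any(mask)) return(NA_real_)
    f <- sp$freq[mask]
    f[which.max(sp$psd[mask])]
  }

  m_vlf <- band_mask(sp$freq, bands$vlf)
  m_lf <- band_mask(sp$freq, bands$lf)
  m_hf <- band_mask(sp$freq, bands$hf, closed_right = TRUE)
  vlf <- power_in(m_vlf); lf <- power_in(m_lf); hf <- power_in(m_hf)
  # nu denominator: in-band total minus VLF
  denom <- lf + hf
  c(
    VLF_Hz = peak_in(m_vlf), LF_Hz = peak_in(m_lf), HF_Hz = peak_in(m_hf),
    VLF_ms_sq = vlf, LF_ms_sq = lf, HF_ms_sq = hf,
    VLF_perc = if (total > 0) 100 * vlf / total else NA_real_,
    LF_perc = if (total > 0) 100 * lf / total else NA_real_,
    HF_perc = if (total > 0) 100 * hf / total else NA_real_,
    LF_nu = if (denom > 0) 100 * lf / denom else NA_real_,
    HF_nu = if (denom > 0) 100 * hf / denom else NA_real_,
    Total_ms_sq = total,
    LF_HF = if (hf > 0) lf / hf else NA_real_
  )
}
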