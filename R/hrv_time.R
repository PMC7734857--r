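#' Time-domain HRV parameters for one epoch
#'
#' Computes the classical beat-to-beat statistics: mean RR, mean heart rate,
#' SDNN, RMSSD and the coefficient of variation CVRR = SDNN / mean RR.
#' SDNN uses the sample (n - 1) standard deviation, the convention of the
#' Task Force standard and of Kubios.
#'
#' @param epoch One element of [segment_epochs()] output, or any list with
#'   an `intervals` field in ms.
#' @param hr_method `"instantaneous"` (default): HR is the mean of the
#'   per-beat rates 60000 / RR_k, matching the "mean HR" of common HRV
#'   software; `"mean_rr"`: HR = 60000 / mean(RR).
#' @return Named numeric vector with elements `HR` (bpm), `RR` (ms),
#'   `SDNN` (ms), `RMSSD` (ms), `CVRR` (dimensionless).
#' @examples
#' e <- list(intervals = c(1000, 1010, 1000, 1010))
#' time_domain(e)["RMSSD"]  # 10 ms
#' @export
time_domain <- function(epoch, hr_method = c("instantaneous", "mean_rr")) {
  hr_method <- match.arg(hr_method)
  rr <- epoch$intervals
  if (length(rr) < 2L) stop("epoch too short")
  mrr <- mean(rr)
  sdnn <- stats::sd(rr)
  hr <- if (hr_method == "instantaneous") mean(60000 / rr) else 60000 / mrr
  c(
    HR = hr,
    RR = mrr,
    SDNN = sdnn,
    RMSSD = sqrt(mean(diff(rr)^2)),
    CVRR = sdnn / mrr
  )
}

#' Poincare plot dispersion (SD1, SD2) for one epoch
#'
#' SD1 and SD2 are the standard deviations of the lag-1 return map of the RR
#' series perpendicular to and along the identity line. They are computed
#' through the algebraic identities SD1^2 = SDSD^2 / 2 and
#' SD2^2 = 2 SDNN^2 - SDSD^2 / 2, where SDSD is the standard deviation of
#' successive differences; the SD2 radicand is clamped at zero. By
#' construction SD1^2 + SD2^2 = 2 SDNN^2.
#'
#' @param epoch A list with an `intervals` field (ms), at least 3 intervals.
#' @return Named numeric vector with `SD1` and `SD2` in ms.
#' @export
poincare_features <- function(epoch) {
  rr <- epoch$intervals
  if (length(rr) < 3L) stop("epoch too short for Poincare analysis")
  sdsd2 <- stats::var(diff(rr))
  sdnn2 <- stats::var(rr)
  c(
    SD1 = sqrt(0.5 * sdsd2),
    SD2 = sqrt(max(0, 2 * sdnn2 - 0.5 * sdsd2))
  )
}
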