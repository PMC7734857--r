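#' Canonical HRV parameter names
#'
#' The 20 per-epoch HRV parameters, in canonical column order: time domain
#' (HR, RR, SDNN, RMSSD, CVRR), frequency domain (peak frequencies,
#' absolute/relative/normalized band powers, total power, LF/HF ratio) and
#' the Poincare dispersions SD1, SD2.
#'
#' @return Character vector of length 20.
#' @export
hrv_feature_names <- function() {
  c("HR", "RR", "SDNN", "RMSSD", "CVRR",
    "VLF_Hz", "LF_Hz", "HF_Hz",
    "VLF_ms_sq", "LF_ms_sq", "HF_ms_sq",
    "VLF_perc", "LF_perc", "HF_perc",
    "LF_nu", "HF_nu", "Total_ms_sq", "LF_HF", "SD1", "SD2")
}

#' Per-epoch HRV feature table for one patient
#'
#' Segments the record into consecutive 30-minute epochs and computes all
#' 20 HRV parameters for each. Epochs that are too short or sparse for a
#' given analysis produce missing values in the affected columns; rows are
#' never dropped, so time points stay aligned with wall-clock time.
#'
#' @param series An [rr_series()].
#' @param epoch_minutes Epoch length in minutes (default 30).
#' @param fs Tachogram resampling rate in Hz for spectral analysis.
#' @param hr_method Passed to [time_domain()].
#' @param bands Band limits for [spectral_features()].
#' @param artifact_filter If `TRUE`, apply [filter_artifacts()] first
#'   (default `FALSE`).
#' @return A data frame with columns `patient_id`, `time_point` (1-based,
#'   consecutive) and the 20 [hrv_feature_names()] columns; one row per
#'   complete epoch.
#' @export
compute_feature_table <- function(series, epoch_minutes = 30, fs = 4,
                                  hr_method = "instantaneous",
                                  bands = hrv_bands(),
                                  artifact_filter = FALSE) {
  stopifnot(inherits(series, "rr_series"))
  if (artifact_filter) series <- filter_artifacts(series)
  epochs <- segment_epochs(series, epoch_minutes = epoch_minutes)
  if (length(epochs) == 0L) {
    stop("record shorter than one epoch: no complete ",
         epoch_minutes, "-minute epoch")
  }
  feats <- hrv_feature_names()
  rows <- lapply(epochs, function(e) {
    out <- stats::setNames(rep(NA_real_, length(feats)), feats)
    td <- tryCatch(time_domain(e, hr_method = hr_method),
                   error = function(err) NULL)
    if (!is.null(td)) out[names(td)] <- td
    pc <- tryCatch(poincare_features(e), error = function(err) NULL)
    if (!is.null(pc)) out[names(pc)] <- pc
    sf <- tryCatch(spectral_features(resample_rr(e, fs = fs), bands = bands),
                   error = function(err) NULL)
    if (!is.null(sf)) out[names(sf)] <- sf
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(
    data.frame(patient_id = series$patient_id,
               time_point = seq_along(epochs)),
    tab
  )
}

#' Write / read a feature table as CSV
#'
#' @param table Data frame from [compute_feature_table()] (or several
#'   patients' tables row-bound).
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
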