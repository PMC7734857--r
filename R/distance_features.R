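#' Euclidean distance feature of one window
#'
#' The distance feature of a window of n consecutive values of one HRV
#' parameter is the Euclidean distance between that vector and the origin
#' (a baseline vector of n zeros), i.e. the Euclidean norm
#' sqrt(F1^2 + F2^2 + ... + Fn^2). It summarises the magnitude of the
#' parameter's trajectory over the window; values are used raw, without
#' standardisation, so the feature keeps each parameter's native scale.
#'
#' @param values Numeric vector; all values must be finite.
#' @return Non-negative scalar.
#' @examples
#' dist_feature(c(3, 4))  # 5
#' @export
dist_feature <- function(values) {
  if (length(values) == 0L) stop("incomplete window: empty")
  if (anyNA(values) || any(!is.finite(values))) stop("incomplete window")
  sqrt(sum(values^2))
}

#' Sliding-window distance features over a per-epoch feature table
#'
#' For each time point t with a complete following window, computes the
#' distance feature of rows t .. t + n - 1 (inclusive) of every selected
#' HRV parameter. A 48-epoch record with the default window of 8 yields 41
#' rows. Windows containing missing values yield a missing distance
#' feature; the row is retained so time-point indices stay aligned.
#'
#' @param table Feature table from [compute_feature_table()] for a single
#'   patient (or pass a multi-patient table through
#'   [sliding_dist_cohort()]).
#' @param n_window Number of consecutive time points per window (>= 2;
#'   default 8, chosen so that even heavily truncated records of a few
#'   hours still contribute windows).
#' @param feature_names Which parameters to window (default all 20).
#' @return Data frame with `patient_id`, `time_point`, `window_start`,
#'   `window_end` and one `Dist<name>` column per selected parameter.
#' @examples
#' tab <- data.frame(patient_id = "p", time_point = 1:8, HR = rep(60, 8))
#' sliding_dist(tab, n_window = 8, feature_names = "HR")$DistHR  # 60*sqrt(8)
#' @export
sliding_dist <- function(table, n_window = 8,
                         feature_names = hrv_feature_names()) {
  if (n_window < 2) stop("n_window must be >= 2")
  if (length(unique(table$patient_id)) > 1L) {
    stop("sliding_dist expects a single patient; see sliding_dist_cohort()")
  }
  missing_cols <- setdiff(feature_names, names(table))
  if (length(missing_cols) > 0L) {
    stop("unknown feature columns: ", paste(missing_cols, collapse = ", "))
  }
  n_t <- nrow(table)
  if (n_t < n_window) stop("record shorter than window")
  table <- table[order(table$time_point), , drop = FALSE]
  n_out <- n_t - n_window + 1L
  out <- data.frame(
    patient_id = table$patient_id[seq_len(n_out)],
    time_point = table$time_point[seq_len(n_out)],
    window_start = table$time_point[seq_len(n_out)],
    window_end = table$time_point[seq_len(n_out)] + n_window - 1L
  )
  for (f in feature_names) {
    m <- stats::embed(table[[f]], n_window)  # rows: windows (reversed order)
    out[[paste0("Dist", f)]] <- sqrt(rowSums(m^2))
  }
  out
}

#' @rdname sliding_dist
#' @param tables A multi-patient feature table (rows for several
#'   `patient_id`s) or a list of single-patient tables.
#' @export
sliding_dist_cohort <- function(tables, n_window = 8,
                                feature_names = hrv_feature_names()) {
  if (is.data.frame(tables)) {
    tables <- split(tables, tables$patient_id)
  }
  do.call(rbind, c(lapply(tables, sliding_dist, n_window = n_window,
                          feature_names = feature_names),
                   make.row.names = FALSE))
}
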