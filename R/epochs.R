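#' Segment an RR series into consecutive fixed-length epochs
#'
#' Cuts the record into consecutive `epoch_minutes` epochs with half-open
#' time spans `[k * L, (k + 1) * L)`. An interval is assigned to the epoch
#' containing its beat onset time. Only complete epochs are returned: a
#' trailing partial epoch (the record ends before the epoch's right edge) is
#' dropped.
#'
#' @param series An [rr_series()].
#' @param epoch_minutes Epoch length in minutes (default 30, the standard
#'   short-term HRV analysis window).
#' @return A list of epochs, each a list with `index` (0-based), `start_s`,
#'   `end_s` and `intervals` (ms). May be empty if the record is shorter
#'   than one epoch.
#' @examples
#' s <- rr_series(rep(1000, 3600))  # one hour at 60 bpm
#' length(segment_epochs(s))        # 2 epochs
#' @export
segment_epochs <- function(series, epoch_minutes = 30) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series$intervals) == 0L) stop("no beats")
  if (epoch_minutes <= 0) stop("epoch_minutes must be positive")
  epoch_s <- epoch_minutes * 60
  total_s <- rr_duration(series)
  # small tolerance so a record of exactly k epochs yields k, not k - 1
  n_complete <- floor(total_s / epoch_s + 1e-9)
  if (n_complete == 0L) return(list())
  idx <- floor(series$offsets / epoch_s)
  keep <- idx < n_complete
  split_idx <- split(which(keep), idx[keep])
  lapply(seq_len(n_complete) - 1L, function(k) {
    beats <- split_idx[[as.character(k)]]
    list(
      index = k,
      start_s = k * epoch_s,
      end_s = (k + 1) * epoch_s,
      intervals = if (is.null(beats)) numeric(0) else series$intervals[beats]
    )
  })
}
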