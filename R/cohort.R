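#' Assemble a cohort dataset
#'
#' A cohort bundles, per patient: the outcome label, the numeric severity
#' scores, the per-epoch HRV feature table and the sliding-window distance
#' feature table. It is the unit the cross-validation scheme splits (by
#' patient, never by row).
#'
#' @param patients A list; each element a list with fields `patient_id`,
#'   `outcome` (`"survivor"` or `"non_survivor"`), `scores` (named numeric
#'   vector, e.g. `APACHE_II`, `APACHE_III`, `SAPS`), `features`
#'   (per-epoch feature table) and `distf` (distance feature table).
#' @return An object of class `hrv_cohort`.
#' @export
hrv_cohort <- function(patients) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id in cohort")
  for (p in patients) {
    if (!p$outcome %in% c("survivor", "non_survivor")) {
      stop("outcome must be 'survivor' or 'non_survivor' (patient ",
           p$patient_id, ")")
    }
    if (is.null(p$distf) || nrow(p$distf) < 1L) {
      stop("patient ", p$patient_id, " has no distance-feature rows")
    }
  }
  structure(list(patients = stats::setNames(patients, ids)),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<hrv_cohort> %d patients (%d survivors, %d non-survivors)\n",
              length(lab), sum(lab == 0), sum(lab == 1)))
  invisible(x)
}

#' Outcome labels of a cohort
#'
#' @param cohort An [hrv_cohort()].
#' @return Named integer vector, 1 = non-survivor (the positive class),
#'   0 = survivor.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients,
         function(p) as.integer(p$outcome == "non_survivor"),
         integer(1))
}

#' Time points with a complete distance-feature window, per patient
#'
#' A time point is usable for model building when the patient's distance
#' feature row at that index exists and contains no missing values (i.e.
#' the following window of epochs was complete and spectrally analysable).
#'
#' @param cohort An [hrv_cohort()].
#' @param feature_names Restrict the completeness check to these distance
#'   columns (default: all `Dist*` columns present).
#' @return Named list of integer time-point vectors.
#' @export
valid_time_points <- function(cohort, feature_names = NULL) {
  lapply(cohort$patients, function(p) {
    d <- p$distf
    cols <- grep("^Dist", names(d), value = TRUE)
    if (!is.null(feature_names)) cols <- intersect(cols, feature_names)
    ok <- stats::complete.cases(d[, cols, drop = FALSE])
    sort(d$time_point[ok])
  })
}

#' Build the design matrix for a feature set
#'
#' Assembles one row per (patient, selected time point). Plain HRV
#' parameter names are taken from the per-epoch table at the time point;
#' names prefixed `Dist` from the distance table at the same time-point
#' index; severity score names (`APACHE_II`, `APACHE_III`, `SAPS`, or any
#' name present in a patient's `scores`) are constant across a patient's
#' rows.
#'
#' @param cohort An [hrv_cohort()].
#' @param feature_set Character vector of feature names.
#' @param time_points Named list (by patient_id) of time-point vectors; a
#'   patient absent from the list contributes no rows.
#' @return List with `x` (numeric matrix, one column per feature), `y`
#'   (integer labels, 1 = non-survivor), `patient_id` (character, one per
#'   row).
#' @export
build_design_matrix <- function(cohort, feature_set, time_points) {
  if (length(feature_set) == 0L) stop("empty feature set")
  rows <- list(); ys <- list(); pids <- list()
  for (pid in names(time_points)) {
    p <- cohort$patients[[pid]]
    if (is.null(p)) stop("unknown patient_id: ", pid)
    tps <- time_points[[pid]]
    if (length(tps) == 0L) next
    m <- matrix(NA_real_, length(tps), length(feature_set),
                dimnames = list(NULL, feature_set))
    for (f in feature_set) {
      if (f %in% names(p$scores)) {
        m[, f] <- p$scores[[f]]
      } else if (startsWith(f, "Dist")) {
        idx <- match(tps, p$distf$time_point)
        if (anyNA(idx)) {
          stop("patient ", pid, ": time point beyond available windows")
        }
        if (!f %in% names(p$distf)) {
          stop("unknown feature '", f, "'; valid names are the severity ",
               "scores, the 20 HRV parameters, or Dist<parameter>")
        }
        m[, f] <- p$distf[[f]][idx]
      } else if (f %in% names(p$features)) {
        idx <- match(tps, p$features$time_point)
        if (anyNA(idx)) {
          stop("patient ", pid, ": time point beyond record length")
        }
        m[, f] <- p$features[[f]][idx]
      } else {
        stop("unknown feature '", f, "'; valid names are the severity ",
             "scores, the 20 HRV parameters, or Dist<parameter>")
      }
    }
    if (anyNA(m)) stop("patient ", pid, ": missing values at requested ",
                       "time points")
    rows[[pid]] <- m
    ys[[pid]] <- rep(as.integer(p$outcome == "non_survivor"), length(tps))
    pids[[pid]] <- rep(pid, length(tps))
  }
  list(
    x = do.call(rbind, rows),
    y = unlist(ys, use.names = FALSE),
    patient_id = unlist(pids, use.names = FALSE)
  )
}
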