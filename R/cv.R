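#' Repeated patient-grouped cross-validation scheme
#'
#' Describes the evaluation protocol: repeated five-fold cross-validation
#' where each test fold holds one non-survivor plus 20% of the survivors,
#' and each test patient contributes a fixed number of randomly chosen
#' time points (rows). Splits are by patient: no patient contributes rows
#' to both sides of a fold.
#'
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Number of repeats (default 5).
#' @param time_points_per_patient Test rows sampled per test patient
#'   (default 5), drawn without replacement from the patient's time points
#'   with a complete following window.
#' @param survivor_test_fraction Fraction of survivors per test fold
#'   (default 0.2; the count is rounded down, so 21 survivors give 4 per
#'   fold and one survivor is train-only within a repeat).
#' @param seed RNG seed; identical seeds give identical folds.
#' @param include_test_rows_in_train If `TRUE`, the unselected time points
#'   of test patients are kept in the training data (a literal reading of
#'   "the rest of the dataset"); default `FALSE`, the leakage-safe
#'   patient-grouped split.
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 5, n_repeats = 5,
                      time_points_per_patient = 5,
                      survivor_test_fraction = 0.2,
                      seed = 1,
                      include_test_rows_in_train = FALSE) {
  stopifnot(n_folds >= 2, n_repeats >= 1, time_points_per_patient >= 1,
            survivor_test_fraction > 0, survivor_test_fraction < 1)
  structure(
    list(n_folds = n_folds, n_repeats = n_repeats,
         time_points_per_patient = time_points_per_patient,
         survivor_test_fraction = survivor_test_fraction,
         seed = seed,
         include_test_rows_in_train = include_test_rows_in_train),
    class = "cv_scheme"
  )
}

#' Build the fold assignments for a cohort
#'
#' Per repeat: non-survivors are randomly permuted and dealt one per fold
#' (round-robin if their count differs from the fold count); survivors are
#' permuted and the first `floor(fraction * n) * n_folds` dealt evenly to
#' folds. For every test patient, `time_points_per_patient` time points are
#' drawn without replacement from the patient's valid time points (those
#' with a complete distance-feature window); a patient with fewer valid
#' points contributes them all, with a warning. Training rows are all valid
#' time points of the non-test patients.
#'
#' The same fold object must be reused across every model being compared,
#' so that differences in the report reflect the feature sets and not the
#' splits.
#'
#' @param cohort An [hrv_cohort()].
#' @param scheme A [cv_scheme()].
#' @return Object of class `cv_folds`: a list with one element per repeat,
#'   each a list of folds; a fold has `test_patients`, `train_patients`,
#'   `test_time_points` and `train_time_points` (named lists of time-point
#'   vectors).
#' @export
make_folds <- function(cohort, scheme = cv_scheme()) {
  stopifnot(inherits(cohort, "hrv_cohort"), inherits(scheme, "cv_scheme"))
  labels <- cohort_labels(cohort)
  surv <- names(labels)[labels == 0L]
  nonsurv <- names(labels)[labels == 1L]
  if (length(nonsurv) == 0L) stop("cohort has no non-survivors")
  if (length(surv) == 0L) stop("cohort has no survivors")
  valid <- valid_time_points(cohort)

  n_folds <- scheme$n_folds
  k_surv <- max(1L, floor(scheme$survivor_test_fraction * length(surv)))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(scheme$seed)

  repeats <- lapply(seq_len(scheme$n_repeats), function(r) {
    ns_perm <- sample(nonsurv)
    s_perm <- sample(surv)
    lapply(seq_len(n_folds), function(f) {
      ns_test <- ns_perm[((f - 1L) %% length(ns_perm)) + 1L]
      s_test <- s_perm[seq.int((f - 1L) * k_surv + 1L, f * k_surv)]
      s_test <- s_test[!is.na(s_test)]
      test_patients <- c(ns_test, s_test)
      train_patients <- setdiff(names(labels), test_patients)
      test_tps <- lapply(stats::setNames(test_patients, test_patients),
                         function(pid) {
        avail <- valid[[pid]]
        k <- scheme$time_points_per_patient
        if (length(avail) < k) {
          warning("patient ", pid, " has only ", length(avail),
                  " valid time points (requested ", k, ")")
          k <- length(avail)
        }
        sort(sample(avail, k))
      })
      train_tps <- valid[train_patients]
      if (scheme$include_test_rows_in_train) {
        extra <- lapply(stats::setNames(test_patients, test_patients),
                        function(pid) setdiff(valid[[pid]], test_tps[[pid]]))
        train_tps <- c(train_tps, extra[vapply(extra, length, 1L) > 0])
      }
      list(test_patients = test_patients,
           train_patients = train_patients,
           test_time_points = test_tps,
           train_time_points = train_tps)
    })
  })
  structure(repeats, class = "cv_folds", scheme = scheme)
}

#' Flatten a cv_folds object into a plain list of folds
#'
#' @param folds A `cv_folds` object from [make_folds()], or already a flat
#'   list of folds.
#' @return List of folds with `repeat`/`fold` indices attached.
#' @export
flatten_folds <- function(folds) {
  if (!inherits(folds, "cv_folds")) return(folds)
  out <- list()
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      fold <- folds[[r]][[f]]
      fold$repeat_idx <- r
      fold$fold_idx <- f
      out[[length(out) + 1L]] <- fold
    }
  }
  out
}
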