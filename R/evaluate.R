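#' Evaluate one feature set under the cross-validation scheme
#'
#' For every (repeat, fold) cell: fits the logistic model on the fold's
#' training rows and computes AUC, sensitivity and specificity (cutoff
#' 0.5) on both the training rows and the sampled test rows. Aggregates
#' are the mean over cells and a 95% confidence interval. The default
#' interval (`ci_method = "cluster"`) computes the standard error over
#' per-cluster means, clustering cells on the identity of the fold's
#' test non-survivor(s), with a t quantile: folds testing the same
#' non-survivor are strongly dependent (only a handful of positive
#' patients exist), and the naive per-cell SE is anti-conservative by
#' roughly the square root of the cluster multiplicity. The
#' `"normal"` method (mean +/- 1.96 * SE over all cells) is retained
#' for comparison. Cells with single-class training data are recorded
#' as missing and excluded from the aggregate n.
#'
#' @param feature_set Character vector of feature names.
#' @param cohort An [hrv_cohort()].
#' @param folds Folds from [make_folds()]; reuse the same object across
#'   every feature set being compared.
#' @param lambda Ridge penalty for the logistic fits.
#' @param cutoff Classification cutoff (default 0.5).
#' @return Object of class `hrv_eval`: `feature_set`, `cells` (one row per
#'   repeat x fold with the six metrics), `summary` (mean, lower, upper,
#'   n per metric).
#' @export
evaluate_feature_set <- function(feature_set, cohort, folds,
                                 lambda = 1e-4, cutoff = 0.5,
                                 ci_method = c("cluster", "normal")) {
  ci_method <- match.arg(ci_method)
  if (length(feature_set) == 0L) stop("empty feature set")
  flat <- flatten_folds(folds)
  labels <- cohort_labels(cohort)
  metrics <- c("train_auc", "train_sens", "train_spec",
               "test_auc", "test_sens", "test_spec")
  cells <- data.frame(
    repeat_idx = vapply(flat, function(f) f$repeat_idx %||% NA_integer_,
                        integer(1)),
    fold_idx = vapply(flat, function(f) f$fold_idx %||% NA_integer_,
                      integer(1)),
    cluster = vapply(flat, function(f) {
      ns <- f$test_patients[labels[f$test_patients] == 1L]
      paste(sort(ns), collapse = "+")
    }, character(1))
  )
  for (m in metrics) cells[[m]] <- NA_real_
  for (i in seq_along(flat)) {
    fold <- flat[[i]]
    train <- build_design_matrix(cohort, feature_set,
                                 fold$train_time_points)
    if (length(unique(train$y)) < 2L) next
    model <- fit_logistic(train$x, train$y, lambda = lambda)
    test <- build_design_matrix(cohort, feature_set, fold$test_time_points)
    p_tr <- predict_prob(model, train$x)
    p_te <- predict_prob(model, test$x)
    ss_tr <- sens_spec(train$y, p_tr, cutoff)
    ss_te <- sens_spec(test$y, p_te, cutoff)
    cells$train_auc[i] <- auc(train$y, p_tr)
    cells$train_sens[i] <- ss_tr[["sensitivity"]]
    cells$train_spec[i] <- ss_tr[["specificity"]]
    cells$test_auc[i] <- if (length(unique(test$y)) > 1L) {
      auc(test$y, p_te)
    } else NA_real_
    cells$test_sens[i] <- ss_te[["sensitivity"]]
    cells$test_spec[i] <- ss_te[["specificity"]]
  }
  summary <- do.call(rbind, lapply(metrics, function(m) {
    ok <- !is.na(cells[[m]])
    v <- cells[[m]][ok]
    n <- length(v)
    if (ci_method == "cluster" && n > 1L) {
      cm <- tapply(v, cells$cluster[ok], mean)
      k <- length(cm)
      half <- if (k > 1L) {
        stats::qt(0.975, k - 1L) * stats::sd(cm) / sqrt(k)
      } else 0
    } else {
      half <- if (n > 1L) 1.96 * stats::sd(v) / sqrt(n) else 0
    }
    data.frame(metric = m, mean = mean(v),
               lower = mean(v) - half, upper = mean(v) + half,
               n = n)
  }))
  structure(
    list(feature_set = feature_set, cells = cells, summary = summary),
    class = "hrv_eval"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hrv_eval <- function(x, ...) {
  cat("<hrv_eval>", paste(x$feature_set, collapse = " + "), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %.3f [%.3f, %.3f]  (n = %d)\n",
                s$metric[i], s$mean[i], s$lower[i], s$upper[i], s$n[i]))
  }
  invisible(x)
}

#' Compare several feature sets on shared folds
#'
#' Runs [evaluate_feature_set()] for each named set against the same fold
#' assignments and returns a report table with one row per set: train and
#' test AUC, sensitivity and specificity, each with its 95% CI.
#'
#' @param feature_sets Named list of character vectors.
#' @param cohort An [hrv_cohort()].
#' @param folds Folds from [make_folds()].
#' @param lambda,cutoff,ci_method Passed through to
#'   [evaluate_feature_set()].
#' @return Data frame of class `hrv_report` with numeric columns
#'   `<metric>`, `<metric>_lo`, `<metric>_hi` for the six metrics, plus
#'   `set` and `features`. The per-set `hrv_eval` objects are attached as
#'   the `evals` attribute.
#' @export
compare_models <- function(feature_sets, cohort, folds,
                           lambda = 1e-4, cutoff = 0.5,
                           ci_method = c("cluster", "normal")) {
  if (length(feature_sets) == 0L) stop("no feature sets to compare")
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- paste0("set_", seq_along(feature_sets))
  }
  evals <- lapply(feature_sets, evaluate_feature_set, cohort = cohort,
                  folds = folds, lambda = lambda, cutoff = cutoff,
                  ci_method = ci_method)
  rows <- lapply(names(evals), function(nm) {
    s <- evals[[nm]]$summary
    out <- data.frame(set = nm,
                      features = paste(evals[[nm]]$feature_set,
                                       collapse = " + "))
    for (i in seq_len(nrow(s))) {
      out[[s$metric[i]]] <- s$mean[i]
      out[[paste0(s$metric[i], "_lo")]] <- s$lower[i]
      out[[paste0(s$metric[i], "_hi")]] <- s$upper[i]
    }
    out
  })
  report <- do.call(rbind, rows)
  attr(report, "evals") <- evals
  class(report) <- c("hrv_report", class(report))
  report
}

#' Format a comparison report as Markdown or CSV
#'
#' @param report Output of [compare_models()].
#' @param path Optional file path; `.md` gives a Markdown table, anything
#'   else CSV.
#' @return Character vector of Markdown lines (invisibly if written).
#' @export
format_report <- function(report, path = NULL) {
  fmt <- function(m, lo, hi) sprintf("%.2f [%.2f, %.2f]", m, lo, hi)
  tab <- data.frame(
    Set = report$set,
    Features = report$features,
    `Train AUC` = fmt(report$train_auc, report$train_auc_lo,
                      report$train_auc_hi),
    `Train Sens` = fmt(report$train_sens, report$train_sens_lo,
                       report$train_sens_hi),
    `Train Spec` = fmt(report$train_spec, report$train_spec_lo,
                       report$train_spec_hi),
    `Test AUC` = fmt(report$test_auc, report$test_auc_lo,
                     report$test_auc_hi),
    `Test Sens` = fmt(report$test_sens, report$test_sens_lo,
                      report$test_sens_hi),
    `Test Spec` = fmt(report$test_spec, report$test_spec_lo,
                      report$test_spec_hi),
    check.names = FALSE
  )
  if (!is.null(path) && !grepl("\\.md$", path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(character(0)))
  }
  header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  lines <- c(header, sep, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
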