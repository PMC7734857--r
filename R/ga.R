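#' Genetic-algorithm configuration for feature selection
#'
#' Standard small-GA defaults for a binary feature-mask chromosome:
#' tournament selection, uniform crossover, per-bit mutation at 1/L, and
#' elitism. The search is repeated `n_runs` times from distinct seeds and
#' the final feature set is aggregated from the per-run best chromosomes.
#'
#' @param population_size Even number of chromosomes per generation.
#' @param n_generations Generations per run (0 = evaluate the random
#'   initial population only).
#' @param crossover_rate Probability a mated pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` (default) means
#'   1 / chromosome length.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism_count Top chromosomes copied unchanged each generation.
#' @param n_runs Independent GA restarts aggregated into the final set.
#' @param selection_threshold A feature enters the final set when its
#'   selection frequency over runs exceeds this (default 0.5).
#' @param parsimony Tiny per-selected-feature penalty subtracted from the
#'   fitness during selection (default 1e-4). Youden's J on small test
#'   folds is coarsely quantised, so many subsets can tie at the optimum;
#'   the penalty breaks such ties towards smaller feature sets without
#'   ever trading a real fitness difference (J changes in steps orders of
#'   magnitude larger). Set to 0 to disable.
#' @param seed Base RNG seed; run r uses `seed + r`.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, n_generations = 100,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      tournament_size = 3, elitism_count = 2,
                      n_runs = 100, selection_threshold = 0.5,
                      parsimony = 1e-4, seed = 1) {
  if (population_size %% 2 != 0) stop("population_size must be even")
  stopifnot(n_generations >= 0, n_runs >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            tournament_size >= 1, elitism_count >= 0, parsimony >= 0)
  structure(
    list(population_size = population_size, n_generations = n_generations,
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         tournament_size = tournament_size, elitism_count = elitism_count,
         n_runs = n_runs, selection_threshold = selection_threshold,
         parsimony = parsimony, seed = seed),
    class = "ga_config"
  )
}

#' Cross-validated Youden fitness of a feature set
#'
#' For each fold: fit the logistic model on the training rows, predict the
#' test rows, classify at probability 0.5 and compute Youden's
#' J = sensitivity + specificity - 1. The fitness is the mean J over folds.
#' A chromosome selecting no features scores -1 (the worst possible J).
#' Folds whose training data is single-class are skipped and recorded in
#' the `n_degenerate` attribute.
#'
#' @param feature_set Character vector of feature names (possibly empty).
#' @param cohort An [hrv_cohort()].
#' @param folds A `cv_folds` object or flat fold list (see [make_folds()]).
#' @param lambda Ridge penalty for [fit_logistic()].
#' @param cutoff Classification cutoff (default 0.5).
#' @return Scalar fitness in [-1, 1].
#' @export
youden_fitness <- function(feature_set, cohort, folds, lambda = 1e-4,
                           cutoff = 0.5) {
  if (length(feature_set) == 0L) return(-1)
  folds <- flatten_folds(folds)
  js <- numeric(0)
  n_degenerate <- 0L
  for (fold in folds) {
    train <- build_design_matrix(cohort, feature_set,
                                 fold$train_time_points)
    if (length(unique(train$y)) < 2L) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    model <- fit_logistic(train$x, train$y, lambda = lambda)
    test <- build_design_matrix(cohort, feature_set, fold$test_time_points)
    js <- c(js, youden_j(test$y, predict_prob(model, test$x),
                         cutoff = cutoff))
  }
  if (length(js) == 0L) return(-1)
  structure(mean(js), n_degenerate = n_degenerate)
}

# Assemble per-fold train/test design matrices over the full candidate set
# once, so each chromosome evaluation only selects columns.
precompute_fold_data <- function(cohort, candidates, folds) {
  lapply(flatten_folds(folds), function(fold) {
    list(
      train = build_design_matrix(cohort, candidates,
                                  fold$train_time_points),
      test = build_design_matrix(cohort, candidates, fold$test_time_points)
    )
  })
}

# Mean per-fold Youden J of a feature subset on precomputed fold data;
# must agree exactly with youden_fitness() on the same folds.
fold_youden <- function(fold_data, feature_set, lambda = 1e-4,
                        cutoff = 0.5) {
  if (length(feature_set) == 0L) return(-1)
  js <- numeric(0)
  for (fd in fold_data) {
    if (length(unique(fd$train$y)) < 2L) next
    model <- fit_logistic(fd$train$x[, feature_set, drop = FALSE],
                          fd$train$y, lambda = lambda)
    p <- predict_prob(model, fd$test$x[, feature_set, drop = FALSE])
    js <- c(js, youden_j(fd$test$y, p, cutoff = cutoff))
  }
  if (length(js) == 0L) return(-1)
  mean(js)
}

#' Genetic-algorithm feature selection with Youden-index fitness
#'
#' Searches binary feature masks over `candidates` with a generational GA
#' (tournament selection, uniform crossover, bit mutation, elitism),
#' scoring each mask by its cross-validated Youden index
#' ([youden_fitness()]) on a fixed set of folds shared by every evaluation.
#' The search is restarted `n_runs` times from different seeds; each run's
#' best chromosome is recorded, and a feature enters the final set when it
#' appears in more than `selection_threshold` of the per-run winners (ties
#' at the threshold are broken towards features whose containing runs have
#' the higher mean fitness). If no feature clears the threshold the single
#' most frequently selected feature is returned.
#'
#' @param cohort An [hrv_cohort()]; may be `NULL` when a custom `fitness`
#'   function is supplied.
#' @param candidates Character vector of candidate feature names.
#' @param folds Folds from [make_folds()]; one repeat of five folds is the
#'   usual fitness protocol. May be `NULL` with a custom `fitness`.
#' @param config A [ga_config()].
#' @param lambda Ridge penalty passed through to the logistic fits.
#' @param fitness Optional custom fitness: a function taking a character
#'   vector of selected feature names and returning a scalar. The default
#'   is the cross-validated Youden index ([youden_fitness()]), evaluated
#'   against per-fold design matrices that are assembled once and reused
#'   for every chromosome.
#' @return Object of class `ga_selection`: `runs` (per-run best chromosome,
#'   fitness, generation-by-generation best), `selection_frequency`
#'   (named, in [0, 1]), `final_feature_set`, `candidates`, `config`.
#' @export
ga_select <- function(cohort, candidates, folds, config = ga_config(),
                      lambda = 1e-4, fitness = NULL) {
  stopifnot(length(candidates) >= 1L)
  L <- length(candidates)
  p_mut <- if (is.null(config$mutation_rate)) 1 / L else config$mutation_rate
  if (is.null(fitness)) {
    fold_data <- precompute_fold_data(cohort, candidates, folds)
    fitness <- function(feature_set) {
      fold_youden(fold_data, feature_set, lambda = lambda)
    }
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- paste(chrom, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- as.numeric(fitness(candidates[chrom == 1L])) -
      config$parsimony * sum(chrom)
    cache[[key]] <- fit
    fit
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))

  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(config$seed + r)
    P <- config$population_size
    pop <- matrix(sample(0:1, P * L, replace = TRUE), nrow = P)
    fit_vec <- apply(pop, 1, evaluate)
    best_trace <- numeric(config$n_generations)
    g <- 0L
    while (g < config$n_generations) {
      g <- g + 1L
      ord <- order(fit_vec, decreasing = TRUE)
      elite <- pop[ord[seq_len(min(config$elitism_count, P))], ,
                   drop = FALSE]
      n_off <- P - nrow(elite)
      offspring <- matrix(0L, n_off, L)
      i <- 1L
      while (i <= n_off) {
        pick <- function() {
          contenders <- sample.int(P, config$tournament_size, replace = TRUE)
          pop[contenders[which.max(fit_vec[contenders])], ]
        }
        a <- pick(); b <- pick()
        if (stats::runif(1) < config$crossover_rate) {
          mask <- stats::runif(L) < 0.5
          tmp <- a[mask]; a[mask] <- b[mask]; b[mask] <- tmp
        }
        a <- ifelse(stats::runif(L) < p_mut, 1L - a, a)
        offspring[i, ] <- a
        i <- i + 1L
        if (i <= n_off) {
          b <- ifelse(stats::runif(L) < p_mut, 1L - b, b)
          offspring[i, ] <- b
          i <- i + 1L
        }
      }
      pop <- rbind(elite, offspring)
      fit_vec <- apply(pop, 1, evaluate)
      best_trace[g] <- max(fit_vec)
    }
    best_idx <- which.max(fit_vec)
    runs[[r]] <- list(
      best_chromosome = pop[best_idx, ],
      # report the raw Youden fitness, without the parsimony tie-breaker
      best_fitness = fit_vec[best_idx] +
        config$parsimony * sum(pop[best_idx, ]),
      best_trace = best_trace,
      seed = config$seed + r
    )
  }

  best_mat <- do.call(rbind, lapply(runs, `[[`, "best_chromosome"))
  freq <- stats::setNames(colMeans(best_mat), candidates)
  run_fit <- vapply(runs, `[[`, numeric(1), "best_fitness")
  mean_fit_with <- vapply(seq_len(L), function(j) {
    has <- best_mat[, j] == 1L
    if (any(has)) mean(run_fit[has]) else -Inf
  }, numeric(1))

  thr <- config$selection_threshold
  final <- candidates[freq > thr]
  if (length(final) == 0L) {
    # fall back to the most frequent feature, ties broken by mean fitness
    top <- max(freq)
    tied <- which(freq == top)
    final <- candidates[tied[which.max(mean_fit_with[tied])]]
  }
  structure(
    list(runs = runs, selection_frequency = freq,
         final_feature_set = final, candidates = candidates,
         config = config),
    class = "ga_selection"
  )
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("<ga_selection> %d runs over %d candidates\n",
              length(x$runs), length(x$candidates)))
  cat("final set:", paste(x$final_feature_set, collapse = ", "), "\n")
  cat("selection frequencies:\n")
  print(round(sort(x$selection_frequency, decreasing = TRUE), 3))
  invisible(x)
}
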