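#' Ridge-stabilised logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a small quadratic penalty 0.5 * lambda * sum(beta^2) on the slope
#' coefficients (the intercept is unpenalised). The penalty exists to keep
#' the fit finite on separable folds — with a handful of positive-class
#' patients per fold, perfect separation is routine — and at the default
#' lambda = 1e-4 it does not measurably move well-conditioned fits.
#'
#' @param x Numeric matrix (rows = observations) or data frame of numeric
#'   columns; column names become the model's feature names.
#' @param y Binary labels (0/1, or logical), 1 = positive class.
#' @param lambda Ridge penalty (default 1e-4).
#' @param standardize If `TRUE`, columns are z-scored with the training
#'   statistics before fitting (coefficients are reported on the original
#'   scale). Default `FALSE`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   penalised deviance.
#' @return Object of class `hrv_logit` with `intercept`, `coefficients`
#'   (named), `feature_names`, `lambda`, `converged`.
#' @export
fit_logistic <- function(x, y, lambda = 1e-4, standardize = FALSE,
                         maxit = 25, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (length(y) != nrow(x)) stop("x and y size mismatch")
  if (length(unique(y)) < 2L) stop("degenerate fold: single-class training data")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }

  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))) +
      lambda * sum(beta[-1]^2)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  # back-transform to the original feature scale
  slopes <- beta[-1] / scl
  intercept <- beta[1] - sum(beta[-1] * ctr / scl)
  structure(
    list(
      intercept = unname(intercept),
      coefficients = stats::setNames(unname(slopes), colnames(x)),
      feature_names = colnames(x),
      lambda = lambda,
      converged = converged
    ),
    class = "hrv_logit"
  )
}

#' @export
print.hrv_logit <- function(x, ...) {
  cat("<hrv_logit> ridge-stabilised logistic model\n")
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Predicted death probabilities from a fitted logistic model
#'
#' @param model An `hrv_logit` from [fit_logistic()].
#' @param x Matrix or data frame whose columns cover the model's
#'   `feature_names` (matched by name when names are present; extra
#'   columns are ignored, reordering is handled).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "hrv_logit"))
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing_cols <- setdiff(model$feature_names, colnames(x))
    if (length(missing_cols) > 0L) {
      stop("columns missing from newdata: ",
           paste(missing_cols, collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$feature_names)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(model$feature_names))
  }
  eta <- model$intercept + drop(x %*% model$coefficients)
  stats::plogis(eta)
}
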