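#' Standardize a feature matrix
#'
#' Centers every column and scales non-constant columns to population
#' standard deviation 1 (denominator `n`, not `n - 1`), the convention that
#' makes an l1 penalty comparable across summaries measured on different
#' scales. Constant columns are centered and assigned scale 1; the penalty
#' then holds their slopes at exactly zero.
#'
#' @param features Numeric matrix, all entries finite.
#' @return A list with `x` (standardized matrix), `center`, `scale`.
#' @examples
#' standardize(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
standardize <- function(features) {
  features <- as.matrix(features)
  assert_finite_matrix(features)
  n <- nrow(features)
  center <- colMeans(features)
  xc <- sweep(features, 2, center)
  scale <- sqrt(colSums(xc^2) / n)
  scale[scale == 0] <- 1
  list(x = sweep(xc, 2, scale, "/"), center = center, scale = scale)
}

#' Build a labelled two-class design for ratio estimation
#'
#' Stacks summary vectors from the conditional class (label 1) and the
#' marginal class (label 0) and precomputes the internal standardization.
#'
#' @param features Numeric matrix (rows = simulated datasets, columns =
#'   summary statistics).
#' @param labels Binary vector: 1 for the conditional class, 0 for the
#'   marginal class; both classes must be present.
#' @return An object of class `labelled_design`.
#' @export
labelled_design <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  assert_finite_matrix(features)
  if (nrow(features) != length(labels) || nrow(features) < 2) {
    abort("need one label per feature row and at least two rows",
          class = "lfire_data_error")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) != 2L) {
    abort("labels must contain both classes coded 0/1",
          class = "lfire_data_error")
  }
  std <- standardize(features)
  structure(
    list(features = features, labels = labels,
         x = std$x, center = std$center, scale = std$scale),
    class = "labelled_design"
  )
}

#' @export
print.labelled_design <- function(x, ...) {
  cat(sprintf("<labelled_design> %d x %d, %d positive / %d negative\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# Coefficients are reported on the original feature scale; the standardized
# representation travels along as an attribute for warm starts and KKT checks.
new_coefficients <- function(b0_std, beta_std, center, scale, names,
                             lambda = NA_real_, converged = TRUE) {
  slopes <- beta_std / scale
  intercept <- b0_std - sum(beta_std * center / scale)
  structure(
    list(intercept = intercept,
         slopes = stats::setNames(slopes, names)),
    std = list(intercept = b0_std, slopes = beta_std),
    lambda = lambda, converged = converged,
    class = "ratio_coefficients"
  )
}

#' @export
print.ratio_coefficients <- function(x, ...) {
  nz <- sum(x$slopes != 0)
  cat(sprintf("<ratio_coefficients> intercept %.4g, %d/%d nonzero slopes\n",
              x$intercept, nz, length(x$slopes)))
  invisible(x)
}

# Map original-scale coefficients to the standardized scale of a design.
coef_to_std <- function(coefficients, design) {
  beta_std <- as.numeric(coefficients$slopes) * design$scale
  b0_std <- coefficients$intercept +
    sum(as.numeric(coefficients$slopes) * design$center)
  list(intercept = b0_std, slopes = beta_std)
}

#' Penalised logistic objective
#'
#' Evaluates `(1/n) * sum_i log(1 + exp(-s_i eta_i)) + lambda * sum_j |beta_j|`
#' where `eta_i = beta0 + beta' x_i` on the design's standardized feature
#' scale, `s_i = +/-1` encodes the label, and the intercept is excluded from
#' the penalty. Evaluation is overflow-safe.
#'
#' @param coefficients List with `intercept` and `slopes` on the standardized
#'   scale (as stored in the `std` attribute of fitted coefficients).
#' @param design A [labelled_design()].
#' @param lambda Nonnegative penalty level.
#' @return The objective value (scalar).
#' @export
penalized_objective <- function(coefficients, design, lambda) {
  stopifnot(lambda >= 0)
  eta <- coefficients$intercept +
    drop(design$x %*% as.numeric(coefficients$slopes))
  s <- 2 * design$labels - 1
  mean(log1pexp(-s * eta)) + lambda * sum(abs(coefficients$slopes))
}

#' Smallest penalty with an all-zero solution
#'
#' The entry point of the regularisation path: the smallest `lambda` at which
#' the null model (all slopes zero, intercept at the log class odds) is
#' stationary, `max_j |(1/n) sum_i x_ij (y_i - ybar)|` on standardized
#' features. Any `lambda` at or above this value yields exactly zero slopes.
#'
#' @param design A [labelled_design()].
#' @return A nonnegative scalar.
#' @export
lambda_max <- function(design) {
  ybar <- mean(design$labels)
  max(abs(drop(crossprod(design$x, design$labels - ybar))) / nrow(design$x))
}

#' Fit l1-penalised logistic regression at one penalty level
#'
#' Cyclic coordinate descent with soft-threshold updates on an iteratively
#' reweighted quadratic approximation of the logistic loss, warm-startable.
#' Fitted probabilities are clamped to `[1e-5, 1 - 1e-5]` when forming the
#' working weights. Slopes are reported on the original feature scale.
#'
#' @param design A [labelled_design()].
#' @param lambda Nonnegative penalty.
#' @param warm_start Optional coefficients (original scale) to start from.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep (standardized scale). Default `1e-7`.
#' @param max_iter Maximum number of coordinate sweeps. Default `1e5`. On
#'   non-convergence a warning is issued and the best iterate returned.
#' @return A `ratio_coefficients` object with attributes `lambda`,
#'   `converged`, and `std` (the standardized-scale representation).
#' @export
fit_at_lambda <- function(design, lambda, warm_start = NULL,
                          tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(design, "labelled_design"), lambda >= 0)
  d <- ncol(design$x)
  if (is.null(warm_start)) {
    b0 <- 0; beta <- numeric(d)
  } else {
    ws <- coef_to_std(warm_start, design)
    b0 <- ws$intercept; beta <- ws$slopes
  }
  fit <- .cd_logistic_path(design$x, design$labels, lambda,
                           tol, max_iter, 1e-5, b0, beta)
  if (!fit$converged[1]) {
    warning("coordinate descent did not converge within max_iter; ",
            "returning the best iterate", call. = FALSE)
  }
  new_coefficients(fit$b0[1], fit$beta[, 1], design$center, design$scale,
                   colnames(design$features), lambda = lambda,
                   converged = fit$converged[1])
}

default_lambda_ratio <- function(n, d) if (n > d) 1e-4 else 1e-2

# Warm-started fits along a fixed decreasing lambda sequence.
fit_path_at <- function(design, lambdas, tol = 1e-7, max_iter = 1e5) {
  fit <- .cd_logistic_path(design$x, design$labels, lambdas, tol, max_iter,
                           1e-5, 0, numeric(ncol(design$x)))
  coefficients <- purrr::map(seq_along(lambdas), function(k) {
    new_coefficients(fit$b0[k], fit$beta[, k], design$center, design$scale,
                     colnames(design$features), lambda = lambdas[k],
                     converged = fit$converged[k])
  })
  structure(
    list(lambdas = lambdas,
         coefficients = coefficients,
         nonzero_counts = vapply(seq_along(lambdas),
                                 function(k) sum(fit$beta[, k] != 0), 0L),
         converged = fit$converged),
    class = "regularization_path"
  )
}

#' Fit a warm-started regularisation path
#'
#' Fits at `n_lambda` penalties log-spaced from [lambda_max()] down to
#' `lambda_max * lambda_ratio`, each solution warm-starting the next. The
#' first entry is the fully sparse null model.
#'
#' @param design A [labelled_design()].
#' @param n_lambda Path length, `>= 2` (default 100).
#' @param lambda_ratio Ratio of the smallest to the largest penalty; defaults
#'   to `1e-4` when `n > d` and `1e-2` otherwise.
#' @param tol,max_iter Solver controls, see [fit_at_lambda()].
#' @return An object of class `regularization_path` with elements `lambdas`
#'   (strictly decreasing), `coefficients` (one `ratio_coefficients` per
#'   penalty), `nonzero_counts` and `converged`.
#' @export
fit_path <- function(design, n_lambda = 100, lambda_ratio = NULL,
                     tol = 1e-7, max_iter = 1e5) {
  stopifnot(n_lambda >= 2)
  lmax <- lambda_max(design)
  if (lmax <= 0) {
    abort("features carry no signal at all (lambda_max is 0); no path exists",
          class = "lfire_data_error")
  }
  lambda_ratio <- lambda_ratio %||%
    default_lambda_ratio(nrow(design$x), ncol(design$x))
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_ratio),
                     length.out = n_lambda))
  fit_path_at(design, lambdas, tol = tol, max_iter = max_iter)
}

#' @export
print.regularization_path <- function(x, ...) {
  cat(sprintf("<regularization_path> %d penalties in [%.3g, %.3g], %d-%d nonzero\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              min(x$nonzero_counts), max(x$nonzero_counts)))
  invisible(x)
}

#' Tidy a regularisation path
#'
#' @param x A `regularization_path`.
#' @param ... Unused.
#' @return A tibble with one row per (penalty, coefficient) pair: `lambda`,
#'   `term`, `estimate` (original scale), `nonzero`.
#' @export
tidy.regularization_path <- function(x, ...) {
  purrr::map_dfr(seq_along(x$lambdas), function(k) {
    cf <- x$coefficients[[k]]
    tibble::tibble(
      lambda = x$lambdas[k],
      term = c("(Intercept)", names(cf$slopes)),
      estimate = c(cf$intercept, unname(cf$slopes)),
      nonzero = x$nonzero_counts[k]
    )
  })
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < n_folds) {
      abort("each class needs at least n_folds members for stratified CV",
            class = "lfire_data_error")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                  length(idx))
  }
  fold
}

#' Cross-validated penalty selection
#'
#' Stratified k-fold cross-validation over a fitted path's penalty sequence:
#' each fold's training rows are re-standardized and refitted along the full
#' sequence, the held-out binomial deviance (twice the average negative
#' log-likelihood) is averaged per penalty, and the penalty minimising the
#' mean deviance is chosen. Ties are broken toward the largest (sparsest)
#' penalty.
#'
#' @param design A [labelled_design()].
#' @param path A [fit_path()] result; its `lambdas` are reused per fold.
#' @param n_folds Number of folds, `>= 2` (default 10); each class must have
#'   at least `n_folds` members.
#' @param seed Optional integer seed for the fold assignment.
#' @param cores Fold fits run with `parallel::mclapply` when `cores > 1`;
#'   results are identical to the serial run.
#' @param tol,max_iter Solver controls.
#' @return An object of class `cv_selection`: `n_folds`, `lambdas`,
#'   `mean_deviance`, `se_deviance`, `chosen_lambda`, `chosen_index`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(design, path, n_folds = 10, seed = NULL,
                           cores = 1L, tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(design, "labelled_design"),
            inherits(path, "regularization_path"), n_folds >= 2)
  set_seed_if(seed)
  fold <- stratified_folds(design$labels, n_folds)
  lambdas <- path$lambdas

  one_fold <- function(f) {
    train <- fold != f
    d_train <- labelled_design(design$features[train, , drop = FALSE],
                               design$labels[train])
    p_train <- fit_path_at(d_train, lambdas, tol = tol, max_iter = max_iter)
    x_test <- design$features[!train, , drop = FALSE]
    s_test <- 2 * design$labels[!train] - 1
    vapply(p_train$coefficients, function(cf) {
      eta <- cf$intercept + drop(x_test %*% as.numeric(cf$slopes))
      2 * mean(log1pexp(-s_test * eta))
    }, numeric(1))
  }

  dev_by_fold <- if (cores > 1L) {
    parallel::mclapply(seq_len(n_folds), one_fold, mc.cores = cores)
  } else {
    lapply(seq_len(n_folds), one_fold)
  }
  dev <- do.call(rbind, dev_by_fold)
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2, stats::sd) / sqrt(n_folds)
  # lambdas are decreasing, so the first minimiser is the sparsest
  chosen <- which(mean_dev <= min(mean_dev) + 1e-12)[1]
  structure(
    list(n_folds = n_folds, lambdas = lambdas,
         mean_deviance = mean_dev, se_deviance = se_dev,
         chosen_lambda = lambdas[chosen], chosen_index = chosen,
         fold_assignment = fold),
    class = "cv_selection"
  )
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection> %d-fold, chosen lambda %.4g (deviance %.4g)\n",
              x$n_folds, x$chosen_lambda, x$mean_deviance[x$chosen_index]))
  invisible(x)
}
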