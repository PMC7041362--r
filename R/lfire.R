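#' Solver and execution options for LFIRE
#'
#' @param n_lambda Regularisation path length (default 100).
#' @param lambda_ratio Smallest-to-largest penalty ratio; `NULL` picks
#'   `1e-4` when `n > d`, else `1e-2`.
#' @param n_folds Cross-validation folds (default 10).
#' @param tol Coordinate-descent tolerance on the maximum coefficient change
#'   (default `1e-7`).
#' @param max_iter Maximum coordinate sweeps per fit (default `1e5`).
#' @param parallel What to parallelise when `cores > 1`: cross-validation
#'   folds (`"cv"`, the default), grid rows (`"grid"`), or nothing
#'   (`"none"`). Results are identical across modes for a given seed.
#' @param cores Number of worker processes (default 1).
#' @param marginal Optional precomputed marginal [summary set][generate_marginal_set()]
#'   to reuse instead of simulating a fresh one.
#' @return A list of class `lfire_options`.
#' @export
lfire_options <- function(n_lambda = 100, lambda_ratio = NULL, n_folds = 10,
                          tol = 1e-7, max_iter = 1e5,
                          parallel = c("cv", "grid", "none"), cores = 1L,
                          marginal = NULL) {
  structure(
    list(n_lambda = n_lambda, lambda_ratio = lambda_ratio,
         n_folds = n_folds, tol = tol, max_iter = max_iter,
         parallel = match.arg(parallel), cores = as.integer(cores),
         marginal = marginal),
    class = "lfire_options"
  )
}

new_summary_set <- function(summaries, origin, theta = NULL, params = NULL) {
  structure(
    list(summaries = summaries, origin = origin, theta = theta,
         params = params),
    class = "summary_set"
  )
}

#' @export
print.summary_set <- function(x, ...) {
  cat(sprintf("<summary_set> %s, %d x %d\n", x$origin,
              nrow(x$summaries), ncol(x$summaries)))
  invisible(x)
}

#' Coerce a summary set to a tibble
#' @param x A `summary_set`.
#' @param ... Unused.
#' @return A tibble of summary vectors, one simulated dataset per row.
#' @export
as_tibble.summary_set <- function(x, ...) {
  tibble::as_tibble(x$summaries)
}

simulate_summaries <- function(model, thetas) {
  thetas <- as.matrix(thetas)
  if (!is.null(model$simulate_batch) && !is.null(model$summarize_batch)) {
    s <- model$summarize_batch(model$simulate_batch(thetas))
  } else {
    s <- t(apply(thetas, 1, function(th) model$summarize(model$simulate(th))))
  }
  if (ncol(s) != n_summaries(model)) {
    abort("summary dimension does not match the model declaration",
          class = "lfire_data_error")
  }
  if (!all(is.finite(s))) {
    bad <- which(!apply(is.finite(s), 1, all))[1]
    abort(sprintf("non-finite summaries at parameter draw (%s)",
                  paste(signif(thetas[bad, ], 4), collapse = ", ")),
          class = "lfire_data_error")
  }
  colnames(s) <- model$summary_names
  s
}

#' Simulate the marginal (prior predictive) summary set
#'
#' Draws `N` parameter vectors from the prior, pushes each through the
#' simulator and summary map, and returns the resulting summary matrix. This
#' set approximates the marginal data distribution and is shared across all
#' grid rows during inference.
#'
#' @param model A [generative_model()].
#' @param N Set size, `>= 2`.
#' @param seed Optional integer seed.
#' @return A `summary_set` with origin `"marginal"`; `params` holds the prior
#'   draws used.
#' @export
generate_marginal_set <- function(model, N, seed = NULL) {
  stopifnot(inherits(model, "generative_model"), N >= 2)
  set_seed_if(seed)
  thetas <- as.matrix(sample_prior(model$priors, N))
  new_summary_set(simulate_summaries(model, thetas), "marginal",
                  params = thetas)
}

#' Simulate a conditional summary set at fixed parameters
#'
#' @param model A [generative_model()].
#' @param theta Parameter vector inside the prior support.
#' @param N Set size, `>= 2`.
#' @param seed Optional integer seed.
#' @return A `summary_set` with origin `"conditional"` and the generating
#'   `theta` attached.
#' @export
generate_conditional_set <- function(model, theta, N, seed = NULL) {
  stopifnot(inherits(model, "generative_model"), N >= 2)
  theta <- as.numeric(theta)
  if (!prior_in_support(model$priors, theta)) {
    abort("theta lies outside the prior support", class = "lfire_domain_error")
  }
  set_seed_if(seed)
  thetas <- matrix(theta, N, length(theta), byrow = TRUE)
  new_summary_set(simulate_summaries(model, thetas), "conditional",
                  theta = theta)
}

#' Estimate the log-ratio model at one parameter value
#'
#' Labels the conditional summaries 1 and the marginal summaries 0, fits the
#' l1-penalised logistic regularisation path, selects the penalty by
#' cross-validation, and returns the coefficients at the chosen penalty. The
#' fitted linear predictor `beta0 + beta' psi(x)` estimates the log-ratio
#' between the likelihood and the marginal likelihood at `theta`.
#'
#' @param theta Parameter vector the conditional set was simulated at.
#' @param conditional,marginal `summary_set`s of equal dimension.
#' @param options An [lfire_options()] list.
#' @param seed Optional integer seed for the CV fold assignment.
#' @return A `ratio_coefficients` object with the selected penalty in the
#'   `lambda` attribute and the CV object in the `cv` attribute.
#' @export
fit_ratio_at <- function(theta, conditional, marginal,
                         options = lfire_options(), seed = NULL) {
  stopifnot(ncol(conditional$summaries) == ncol(marginal$summaries))
  design <- labelled_design(
    rbind(conditional$summaries, marginal$summaries),
    c(rep(1L, nrow(conditional$summaries)), rep(0L, nrow(marginal$summaries)))
  )
  path <- fit_path(design, n_lambda = options$n_lambda,
                   lambda_ratio = options$lambda_ratio,
                   tol = options$tol, max_iter = options$max_iter)
  cv_cores <- if (options$parallel == "cv") options$cores else 1L
  cv <- cross_validate(design, path, n_folds = options$n_folds, seed = seed,
                       cores = cv_cores, tol = options$tol,
                       max_iter = options$max_iter)
  cf <- path$coefficients[[cv$chosen_index]]
  attr(cf, "cv") <- cv
  cf
}

#' Unnormalised posterior value at one grid point
#'
#' The ratio-estimation posterior approximation
#' `p(theta) * exp(beta0 + sum_i beta_i psi_i(x))`, evaluated at the observed
#' summaries with the coefficients fitted at `theta`. Returns exactly 0 when
#' `theta` falls outside the prior support.
#'
#' @param theta Parameter vector.
#' @param coefficients Fitted `ratio_coefficients` (original feature scale).
#' @param observed Observed summary vector, same length as the slopes.
#' @param priors A [prior_spec()].
#' @return A nonnegative scalar.
#' @examples
#' pr <- prior_spec(c("t1", "t2"), "uniform", c(-1, 0), c(1, 1))
#' cf <- list(intercept = 0, slopes = numeric(17))
#' evaluate_unnormalized_posterior(c(0, 0.5), cf, numeric(17), pr)  # 0.5
#' @export
evaluate_unnormalized_posterior <- function(theta, coefficients, observed,
                                            priors) {
  if (is.null(observed)) {
    abort("observed summaries are missing", class = "lfire_usage_error")
  }
  if (length(observed) != length(coefficients$slopes)) {
    abort("observed summary dimension does not match the slopes",
          class = "lfire_usage_error")
  }
  lp <- prior_log_density(priors, theta)
  if (!is.finite(lp)) return(0)
  eta <- coefficients$intercept +
    sum(as.numeric(coefficients$slopes) * as.numeric(observed))
  exp(lp + eta)
}

#' Normalise nonnegative grid values into probability weights
#'
#' Computed in log space with max-subtraction so very large or small
#' unnormalised values cannot overflow.
#'
#' @param unnormalized Nonnegative vector with at least one positive entry.
#' @return Weights proportional to the input, summing to 1.
#' @examples
#' normalize_over_grid(c(2, 6))  # 0.25 0.75
#' @export
normalize_over_grid <- function(unnormalized) {
  if (any(unnormalized < 0) || !all(is.finite(unnormalized))) {
    abort("unnormalized values must be finite and nonnegative",
          class = "lfire_data_error")
  }
  normalize_log_weights(log(unnormalized))
}

normalize_log_weights <- function(log_values) {
  m <- max(log_values)
  if (!is.finite(m)) {
    abort("all unnormalized posterior values are zero; nothing to normalise",
          class = "lfire_degeneracy_error")
  }
  w <- exp(log_values - m)
  w / sum(w)
}

coerce_grid <- function(grid, priors) {
  grid <- tibble::as_tibble(as.data.frame(grid))
  if (ncol(grid) != nrow(priors)) {
    abort("grid column count must equal the number of parameters",
          class = "lfire_config_error")
  }
  if (!is.null(names(grid)) && all(priors$name %in% names(grid))) {
    grid <- grid[, priors$name]
  } else {
    names(grid) <- priors$name
  }
  stopifnot(nrow(grid) >= 1)
  grid
}

#' Run likelihood-free inference by ratio estimation over a parameter grid
#'
#' For each candidate parameter combination (grid row), simulates a
#' conditional summary set of size `batch_size`, fits a cross-validated
#' l1-penalised logistic regression discriminating it from one shared
#' marginal set of the same size, evaluates the fitted log-ratio at the
#' observed summaries, multiplies by the prior density and normalises over
#' the grid. The l1 penalty performs automatic summary-statistic selection,
#' making the posterior robust to irrelevant summaries.
#'
#' All randomness derives from `seed` through fixed per-row sub-streams, so
#' serial and parallel execution give identical results.
#'
#' @param model A [generative_model()] with observed summaries attached (see
#'   [make_observed()]).
#' @param grid Candidate parameter combinations: a tibble/matrix with one
#'   column per parameter (see [build_grid()]).
#' @param batch_size Simulated dataset size per class, `>= 2`.
#' @param options An [lfire_options()] list.
#' @param seed Integer master seed (default 1).
#' @return An object of class `lfire_result`; see [posterior_summaries()],
#'   [tidy.lfire_result()], [render_summary()], [plot_marginals()].
#' @examples
#' \donttest{
#' m <- make_observed(arch_model(), c(0.3, 0.7), seed = 7)
#' g <- build_grid(t1 = c(-1, 1, 10), t2 = c(0, 1, 10))
#' res <- run_inference(m, g, batch_size = 150, seed = 7)
#' posterior_summaries(res)
#' }
#' @export
run_inference <- function(model, grid, batch_size,
                          options = lfire_options(), seed = 1L) {
  stopifnot(inherits(model, "generative_model"), batch_size >= 2)
  if (is.null(model$observed_summaries)) {
    abort("model has no observed summaries; call make_observed() first",
          class = "lfire_usage_error")
  }
  grid <- coerce_grid(grid, model$priors)
  m <- nrow(grid)
  observed <- model$observed_summaries

  marginal <- options$marginal %||%
    generate_marginal_set(model, batch_size, seed = derive_seed(seed, 0))
  if (ncol(marginal$summaries) != n_summaries(model)) {
    abort("precomputed marginal set dimension does not match the model",
          class = "lfire_usage_error")
  }

  fit_row <- function(i) {
    theta <- as.numeric(grid[i, ])
    tryCatch({
      cond <- generate_conditional_set(model, theta, batch_size,
                                       seed = derive_seed(seed, i))
      cf <- fit_ratio_at(theta, cond, marginal, options,
                         seed = derive_seed(seed, m + i))
      list(coef = c(cf$intercept, unname(cf$slopes)),
           log_ratio = cf$intercept +
             sum(as.numeric(cf$slopes) * observed),
           lambda = attr(cf, "lambda"),
           converged = isTRUE(attr(cf, "converged")))
    }, error = function(e) {
      abort(sprintf("inference failed at grid row %d (theta = %s): %s",
                    i, paste(signif(theta, 4), collapse = ", "),
                    conditionMessage(e)),
            class = "lfire_row_error")
    })
  }

  rows <- if (options$parallel == "grid" && options$cores > 1L) {
    parallel::mclapply(seq_len(m), fit_row, mc.cores = options$cores)
  } else {
    lapply(seq_len(m), fit_row)
  }

  log_ratio <- vapply(rows, `[[`, numeric(1), "log_ratio")
  log_prior <- vapply(seq_len(m), function(i) {
    prior_log_density(model$priors, as.numeric(grid[i, ]))
  }, numeric(1))
  log_unnorm <- log_prior + log_ratio
  posterior <- normalize_log_weights(log_unnorm)

  coefficients <- do.call(rbind, lapply(rows, `[[`, "coef"))
  colnames(coefficients) <- c("(Intercept)", model$summary_names)

  map_index <- which.max(posterior)  # ties: lowest row index
  posterior_means <- vapply(grid, function(col) sum(col * posterior),
                            numeric(1))

  structure(
    list(grid = grid,
         log_ratio = log_ratio,
         log_unnormalized = log_unnorm,
         unnormalized = exp(log_unnorm),
         posterior = posterior,
         coefficients = coefficients,
         chosen_lambda = vapply(rows, `[[`, numeric(1), "lambda"),
         converged = vapply(rows, `[[`, logical(1), "converged"),
         n_simulations = as.numeric(m) * batch_size,
         map_index = map_index,
         posterior_means = posterior_means,
         observed_summaries = observed,
         priors = model$priors,
         batch_size = batch_size,
         options = options,
         seed = seed),
    class = "lfire_result"
  )
}

#' Point summaries of an inference result
#'
#' @param result An [run_inference()] result.
#' @return A list with `map` (the grid row maximising the normalised
#'   posterior; ties broken toward the lowest row index) and `mean` (the
#'   posterior-weighted average of each parameter over the grid), both named
#'   numeric vectors.
#' @export
posterior_summaries <- function(result) {
  stopifnot(inherits(result, "lfire_result"))
  list(
    map = unlist(result$grid[result$map_index, ]),
    mean = result$posterior_means
  )
}

#' Marginal posterior over one parameter
#'
#' Sums the normalised grid posterior over the other parameters' axes.
#' Requires the grid to be a Cartesian product of per-parameter axes.
#'
#' @param result An [run_inference()] result.
#' @param parameter Parameter name or index.
#' @return A tibble with `value` (the parameter's axis) and `weight`
#'   (marginal probability, summing to 1).
#' @export
marginal_densities <- function(result, parameter) {
  stopifnot(inherits(result, "lfire_result"))
  grid <- result$grid
  if (is.numeric(parameter)) parameter <- names(grid)[parameter]
  if (!parameter %in% names(grid)) {
    abort("unknown parameter", class = "lfire_usage_error")
  }
  axes <- purrr::map(grid, ~ sort(unique(.x)))
  key <- do.call(paste, c(grid, sep = "\r"))
  if (prod(lengths(axes)) != nrow(grid) || anyDuplicated(key)) {
    abort("grid is not a Cartesian product of per-parameter axes",
          class = "lfire_layout_error")
  }
  w <- tapply(result$posterior, factor(grid[[parameter]],
                                       levels = axes[[parameter]]), sum)
  tibble::tibble(value = axes[[parameter]], weight = as.numeric(w))
}

#' @export
print.lfire_result <- function(x, ...) {
  cat(render_summary(x), "\n", sep = "")
  invisible(x)
}

#' Tidy an inference result
#'
#' @param x An `lfire_result`.
#' @param what `"posterior"` (default) returns one row per grid point with
#'   the log-ratio and the unnormalised and normalised posterior;
#'   `"coefficients"` returns the fitted intercept and slopes per grid point.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lfire_result <- function(x, what = c("posterior", "coefficients"), ...) {
  what <- match.arg(what)
  if (what == "posterior") {
    dplyr::bind_cols(
      x$grid,
      tibble::tibble(log_ratio = x$log_ratio,
                     unnormalized = x$unnormalized,
                     posterior = x$posterior)
    )
  } else {
    dplyr::bind_cols(x$grid, tibble::as_tibble(x$coefficients))
  }
}

#' One-row summary of an inference result
#'
#' @param x An `lfire_result`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, batch size, simulation count, MAP
#'   and posterior-mean coordinates per parameter, and the fraction of grid
#'   fits that converged.
#' @export
glance.lfire_result <- function(x, ...) {
  ps <- posterior_summaries(x)
  out <- tibble::tibble(
    grid_rows = nrow(x$grid),
    batch_size = x$batch_size,
    n_simulations = x$n_simulations,
    converged = mean(x$converged),
    seed = x$seed
  )
  for (p in names(x$grid)) {
    out[[paste0("map_", p)]] <- unname(ps$map[p])
    out[[paste0("mean_", p)]] <- unname(ps$mean[p])
  }
  out
}
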