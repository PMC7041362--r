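#' Define a generative model for likelihood-free inference
#'
#' A generative model bundles the three ingredients ratio-estimation
#' inference needs: a prior over parameters, a stochastic simulator, and a
#' summary map reducing a raw dataset to a fixed-dimension numeric vector.
#' Observed data enter through [make_observed()].
#'
#' Simulators and summary maps consume the R random number stream; seeding is
#' handled by the callers ([generate_marginal_set()], [run_inference()], ...)
#' so one integer seed reproduces a whole analysis.
#'
#' @param priors A [prior_spec()].
#' @param simulate `function(theta)` returning one raw dataset simulated at
#'   the parameter vector `theta`.
#' @param summarize `function(x)` mapping a raw dataset to a numeric summary
#'   vector of fixed length `length(summary_names)`.
#' @param summary_names Character vector naming the summary coordinates;
#'   fixes the summary dimension `d`.
#' @param simulate_batch Optional `function(theta_matrix)` returning a matrix
#'   with one simulated dataset per row of `theta_matrix` (a vectorised fast
#'   path; must be distributionally identical to `simulate`).
#' @param summarize_batch Optional `function(x_matrix)` summarising each row
#'   of a batch of raw datasets into a row of summaries.
#'
#' @return An object of class `generative_model`.
#' @seealso [arch_model()] for the built-in ARCH(1) demonstration model.
#' @export
generative_model <- function(priors, simulate, summarize, summary_names,
                             simulate_batch = NULL, summarize_batch = NULL) {
  priors <- validate_prior_spec(priors)
  stopifnot(is.function(simulate), is.function(summarize),
            is.character(summary_names), length(summary_names) >= 1)
  structure(
    list(
      priors = priors,
      simulate = simulate,
      summarize = summarize,
      summary_names = summary_names,
      simulate_batch = simulate_batch,
      summarize_batch = summarize_batch,
      observed_data = NULL,
      observed_summaries = NULL
    ),
    class = "generative_model"
  )
}

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model>\n")
  cat("  parameters:", paste(x$priors$name, collapse = ", "), "\n")
  cat("  summaries: ", length(x$summary_names), "\n")
  cat("  observed:  ", if (is.null(x$observed_summaries)) "absent" else "set",
      "\n")
  invisible(x)
}

n_summaries <- function(model) length(model$summary_names)

#' Append white-noise summary statistics to a model
#'
#' Adds `k` summary coordinates that are independent standard-normal draws,
#' regenerated fresh on every summarise call and independent of the raw data.
#' Such summaries carry no information about the parameters; they exercise
#' the automatic summary selection of the l1 penalty, which should drive
#' their coefficients to zero and leave the posterior essentially unchanged.
#'
#' @param model A [generative_model()].
#' @param k Number of white-noise summaries to append, `k >= 0`.
#' @return The model with summary dimension `d + k`. If observed data are
#'   already attached, the observed summaries are recomputed under the
#'   augmented map (the observed noise coordinates are fresh draws).
#' @examples
#' m <- augment_noise_summaries(arch_model(), 17)
#' length(m$summary_names)  # 34
#' @export
augment_noise_summaries <- function(model, k) {
  stopifnot(inherits(model, "generative_model"), k >= 0)
  k <- as.integer(k)
  if (k == 0L) return(model)
  base_summarize <- model$summarize
  base_batch <- model$summarize_batch
  noise_names <- paste0("noise", seq_len(k))

  model$summarize <- function(x) {
    c(base_summarize(x), stats::setNames(rnorm(k), noise_names))
  }
  if (!is.null(base_batch)) {
    model$summarize_batch <- function(xm) {
      s <- base_batch(xm)
      noise <- matrix(rnorm(nrow(s) * k), nrow(s), k,
                      dimnames = list(NULL, noise_names))
      cbind(s, noise)
    }
  }
  model$summary_names <- c(model$summary_names, noise_names)
  if (!is.null(model$observed_data)) {
    model$observed_summaries <- model$summarize(model$observed_data)
  } else {
    model$observed_summaries <- NULL
  }
  model
}

#' Attach synthetic observed data to a model
#'
#' Simulates one dataset at `theta_true`, stores it as the observed dataset,
#' and sets the model's observed summaries to its summary vector. Inference
#' then targets the posterior over parameters given this dataset.
#'
#' @param model A [generative_model()].
#' @param theta_true Parameter vector inside the prior support.
#' @param seed Optional integer seed making the observation reproducible.
#' @return The model with `observed_data` and `observed_summaries` set.
#' @examples
#' m <- make_observed(arch_model(), c(0.3, 0.7), seed = 1)
#' m$observed_summaries
#' @export
make_observed <- function(model, theta_true, seed = NULL) {
  stopifnot(inherits(model, "generative_model"))
  theta_true <- as.numeric(theta_true)
  if (!prior_in_support(model$priors, theta_true)) {
    abort("theta_true lies outside the prior support",
          class = "lfire_domain_error")
  }
  set_seed_if(seed)
  x <- model$simulate(theta_true)
  model$observed_data <- x
  psi <- model$summarize(x)
  if (length(psi) != n_summaries(model) || !all(is.finite(psi))) {
    abort("summarize(simulate(theta_true)) must be finite with the declared dimension",
          class = "lfire_data_error")
  }
  model$observed_summaries <- stats::setNames(as.numeric(psi),
                                              model$summary_names)
  model
}
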