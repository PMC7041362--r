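#' Specify independent box priors for the model parameters
#'
#' A prior specification is a tibble with one row per parameter. Only
#' independent bounded families are supported; currently `"uniform"`. The row
#' order fixes the parameter order used by [sample_prior()], [build_grid()]
#' and every inference result.
#'
#' @param name Character vector of unique parameter labels.
#' @param family Distribution family per parameter; only `"uniform"`.
#' @param lower,upper Numeric bounds, `lower < upper` elementwise.
#'
#' @return A tibble of class `prior_spec` with columns
#'   `name`, `family`, `lower`, `upper`.
#' @examples
#' prior_spec(c("t1", "t2"), "uniform", lower = c(-1, 0), upper = c(1, 1))
#' @export
prior_spec <- function(name, family = "uniform", lower, upper) {
  spec <- tibble::tibble(
    name = as.character(name),
    family = rep_len(as.character(family), length(name)),
    lower = as.numeric(lower),
    upper = as.numeric(upper)
  )
  validate_prior_spec(spec)
}

validate_prior_spec <- function(spec) {
  if (!all(c("name", "family", "lower", "upper") %in% names(spec))) {
    abort("prior spec needs columns name, family, lower, upper",
          class = "lfire_config_error")
  }
  if (anyDuplicated(spec$name)) {
    abort("parameter names must be unique", class = "lfire_config_error")
  }
  unknown <- setdiff(unique(spec$family), "uniform")
  if (length(unknown)) {
    abort(paste0("unknown prior family: ", paste(unknown, collapse = ", ")),
          class = "lfire_config_error")
  }
  if (!all(spec$lower < spec$upper)) {
    abort("every prior must satisfy lower < upper",
          class = "lfire_config_error")
  }
  class(spec) <- c("prior_spec", class(tibble::tibble()))
  spec
}

#' Draw independent samples from the prior
#'
#' @param priors A [prior_spec()].
#' @param n Number of draws, `n >= 1`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   consumed.
#'
#' @return A tibble with `n` rows and one column per parameter, in prior
#'   order.
#' @examples
#' pr <- prior_spec(c("t1", "t2"), "uniform", c(-1, 0), c(1, 1))
#' sample_prior(pr, 5, seed = 1)
#' @export
sample_prior <- function(priors, n, seed = NULL) {
  priors <- validate_prior_spec(priors)
  stopifnot(n >= 1)
  set_seed_if(seed)
  draws <- purrr::pmap(priors, function(name, family, lower, upper) {
    runif(n, lower, upper)
  })
  names(draws) <- priors$name
  tibble::as_tibble(draws)
}

# Log prior density at one parameter vector; -Inf outside the support box.
prior_log_density <- function(priors, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != nrow(priors)) {
    abort("theta length does not match the prior dimension",
          class = "lfire_usage_error")
  }
  if (any(theta < priors$lower | theta > priors$upper)) return(-Inf)
  -sum(log(priors$upper - priors$lower))
}

prior_in_support <- function(priors, theta) {
  is.finite(prior_log_density(priors, theta))
}
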