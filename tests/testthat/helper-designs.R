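# Small labelled designs for solver tests. Non-separable by construction
# (moderate signal, overlapping classes) so unpenalised fits exist.
random_design <- function(n = 60, d = 3, seed = 1, signal = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", seq_len(d))))
  beta <- signal * stats::rnorm(d) / sqrt(d)
  y <- stats::rbinom(n, 1, stats::plogis(0.2 + drop(x %*% beta)))
  # guarantee both classes
  if (all(y == y[1])) y[1] <- 1L - y[1]
  labelled_design(x, y)
}

# Independent term-by-term evaluation of the penalised objective (loops, no
# vectorisation) for cross-checking penalized_objective().
naive_objective <- function(intercept, slopes, x_std, labels, lambda) {
  total <- 0
  for (i in seq_len(nrow(x_std))) {
    eta <- intercept
    for (j in seq_len(ncol(x_std))) eta <- eta + slopes[j] * x_std[i, j]
    s <- if (labels[i] == 1) 1 else -1
    total <- total + log(1 + exp(-s * eta))
  }
  unname(total / nrow(x_std) + lambda * sum(abs(slopes)))
}

# KKT residual of a fit on the standardized scale: max violation of the
# subgradient conditions of the l1-penalised logistic objective.
kkt_residual <- function(fit, design, lambda) {
  std <- attr(fit, "std")
  eta <- std$intercept + drop(design$x %*% std$slopes)
  p <- stats::plogis(eta)
  g <- drop(crossprod(design$x, p - design$labels)) / nrow(design$x)
  g0 <- mean(p - design$labels)
  viol <- abs(g0)
  for (j in seq_along(std$slopes)) {
    viol <- max(viol, if (std$slopes[j] != 0) {
      abs(g[j] + sign(std$slopes[j]) * lambda)
    } else {
      max(0, abs(g[j]) - lambda)
    })
  }
  viol
}

# Minimal hand-built inference result, for functions that are pure in the
# posterior table (summaries, rendering, marginals).
fake_result <- function(grid, posterior, n_simulations = 0) {
  grid <- tibble::as_tibble(grid)
  structure(
    list(grid = grid,
         posterior = posterior,
         unnormalized = posterior,
         log_ratio = rep(0, nrow(grid)),
         map_index = which.max(posterior),
         posterior_means = vapply(grid, function(col) sum(col * posterior),
                                  numeric(1)),
         n_simulations = n_simulations,
         batch_size = NA_integer_,
         seed = NA_integer_),
    class = "lfire_result"
  )
}
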