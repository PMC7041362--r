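test_that("summary sets have the declared shape and are seed-reproducible", {
  m <- arch_model(T = 30)
  marg <- generate_marginal_set(m, 100, seed = 5)
  expect_s3_class(marg, "summary_set")
  expect_equal(dim(marg$summaries), c(100, 17))
  expect_identical(marg$origin, "marginal")
  expect_true(all(is.finite(marg$summaries)))
  marg2 <- generate_marginal_set(m, 100, seed = 5)
  expect_identical(marg$summaries, marg2$summaries)

  cond <- generate_conditional_set(m, c(0.3, 0.7), 50, seed = 6)
  expect_equal(dim(cond$summaries), c(50, 17))
  expect_identical(cond$theta, c(0.3, 0.7))
  expect_identical(cond$summaries,
                   generate_conditional_set(m, c(0.3, 0.7), 50, seed = 6)$summaries)
  expect_error(generate_conditional_set(m, c(0.3, 1.7), 50),
               class = "lfire_domain_error")
  # as_tibble exposes named summary columns
  tb <- tibble::as_tibble(cond)
  expect_named(tb, m$summary_names)
})

test_that("conditional variance summary grows with the heteroscedasticity parameter", {
  m <- arch_model(T = 100)
  lo <- generate_conditional_set(m, c(0.3, 0.1), 2000, seed = 41)
  hi <- generate_conditional_set(m, c(0.3, 0.9), 2000, seed = 42)
  expect_gt(mean(hi$summaries[, "variance"]), mean(lo$summaries[, "variance"]))
})

test_that("ratio fits recover which summaries separate the classes", {
  set.seed(71)
  hits <- 0
  for (r in 1:50) {
    d <- 5
    base <- matrix(rnorm(200 * d), 200, d,
                   dimnames = list(NULL, paste0("s", 1:d)))
    shift <- matrix(rnorm(200 * d), 200, d,
                    dimnames = list(NULL, paste0("s", 1:d)))
    shift[, 2] <- shift[, 2] + 1.5  # only summary 2 carries signal
    cond <- lfire:::new_summary_set(shift, "conditional", theta = 0)
    marg <- lfire:::new_summary_set(base, "marginal")
    cf <- fit_ratio_at(0, cond, marg, lfire_options(n_lambda = 40), seed = r)
    expect_length(cf$slopes, d)
    if (cf$slopes[2] > 0) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% of replicates
})

test_that("ratio fits on identically distributed sets stay near the null model", {
  m <- arch_model(T = 50)
  frac <- vapply(1:5, function(r) {
    a <- generate_marginal_set(m, 150, seed = 100 + r)
    b <- generate_marginal_set(m, 150, seed = 200 + r)
    cf <- fit_ratio_at(NULL, a, b, lfire_options(), seed = r)
    mean(cf$slopes != 0)
  }, numeric(1))
  expect_lt(mean(frac), 0.25)
})

test_that("unnormalised posterior follows prior x exponentiated log-ratio", {
  pr <- prior_spec(c("t1", "t2"), "uniform", c(-1, 0), c(1, 1))
  zero <- list(intercept = 0, slopes = numeric(17))
  obs <- rnorm(17)
  # zero coefficients: exp(0) = 1, leaving the prior density 1/(2*1) = 0.5
  expect_equal(evaluate_unnormalized_posterior(c(0, 0.5), zero, obs, pr), 0.5)
  # direct arithmetic: 0.5 * exp(1 + 0.5*2)
  one <- list(intercept = 1, slopes = 0.5)
  pr1 <- prior_spec("t", "uniform", 0, 2)
  expect_equal(evaluate_unnormalized_posterior(1, one, 2, pr1), 0.5 * exp(2))
  # outside the prior box the posterior is exactly zero
  expect_equal(evaluate_unnormalized_posterior(c(1.5, 0.5), zero, obs, pr), 0)
  expect_equal(evaluate_unnormalized_posterior(c(0, -0.1), zero, obs, pr), 0)
  expect_error(evaluate_unnormalized_posterior(c(0, 0.5), zero, NULL, pr),
               class = "lfire_usage_error")
})

test_that("grid normalisation is exact and overflow-safe", {
  expect_equal(normalize_over_grid(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalize_over_grid(c(2, 6)), c(0.25, 0.75))
  set.seed(13)
  u <- runif(50)
  expect_equal(normalize_over_grid(u), u / sum(u), tolerance = 1e-12)
  # values that would overflow exp() are handled in log space
  w <- lfire:::normalize_log_weights(c(1000, 1000 + log(3)))
  expect_equal(w, c(0.25, 0.75), tolerance = 1e-12)
  expect_error(normalize_over_grid(c(0, 0)), class = "lfire_degeneracy_error")
})

test_that("posterior summaries handle symmetric and degenerate weights", {
  g <- build_grid(t1 = c(-1, 1, 5), t2 = c(0, 1, 5))
  uni <- fake_result(g, rep(1 / 25, 25))
  ps <- posterior_summaries(uni)
  expect_equal(unname(ps$mean), c(0, 0.5))
  point <- fake_result(g, c(rep(0, 6), 1, rep(0, 18)))
  ps2 <- posterior_summaries(point)
  expect_equal(ps2$map, ps2$mean)
  expect_equal(unname(ps2$map), as.numeric(g[7, ]))
  # ties resolve to the lowest row index
  tied <- fake_result(g, c(0.5, rep(0, 23), 0.5))
  expect_equal(tied$map_index, 1L)
})

test_that("marginals sum the grid posterior and recover product factors", {
  g <- build_grid(t1 = c(-1, 1, 4), t2 = c(0, 1, 6))
  uni <- fake_result(g, rep(1 / 24, 24))
  m1 <- marginal_densities(uni, "t1")
  expect_equal(m1$weight, rep(0.25, 4))
  expect_equal(sum(marginal_densities(uni, 2)$weight), 1)
  # posterior built as an outer product factorises back exactly
  set.seed(3)
  wa <- normalize_over_grid(runif(4)); wb <- normalize_over_grid(runif(6))
  joint <- as.numeric(t(outer(wa, wb)))  # grid rows: t1 slowest
  joint <- fake_result(g, joint)
  expect_equal(marginal_densities(joint, "t1")$weight, wa, tolerance = 1e-12)
  expect_equal(marginal_densities(joint, "t2")$weight, wb, tolerance = 1e-12)
  # non-product grids are refused
  bad <- fake_result(tibble::tibble(t1 = c(0, 0, 1), t2 = c(0, 1, 0)),
                     rep(1 / 3, 3))
  expect_error(marginal_densities(bad, "t1"), class = "lfire_layout_error")
})

test_that("inference runs are deterministic, accountable, and parallel-safe", {
  m <- make_observed(arch_model(T = 30), c(0.3, 0.7), seed = 19)
  g <- build_grid(t1 = c(-1, 1, 2), t2 = c(0, 1, 2))
  opts <- lfire_options(n_lambda = 30, n_folds = 5)
  res <- run_inference(m, g, batch_size = 60, options = opts, seed = 4)
  expect_s3_class(res, "lfire_result")
  expect_equal(res$n_simulations, 4 * 60)
  expect_equal(sum(res$posterior), 1, tolerance = 1e-12)
  expect_true(all(res$unnormalized >= 0))
  expect_equal(res$map_index, which.max(res$posterior))
  expect_equal(dim(res$coefficients), c(4, 18))
  # identical rerun under the same seed
  res2 <- run_inference(m, g, batch_size = 60, options = opts, seed = 4)
  expect_identical(res$posterior, res2$posterior)
  expect_identical(res$coefficients, res2$coefficients)
  # parallel over grid rows is bitwise identical to serial
  res3 <- run_inference(m, g, batch_size = 60,
                        options = lfire_options(n_lambda = 30, n_folds = 5,
                                                parallel = "grid", cores = 2),
                        seed = 4)
  expect_identical(res$posterior, res3$posterior)
  expect_identical(res$coefficients, res3$coefficients)
  # a reused precomputed marginal set changes nothing
  marg <- generate_marginal_set(m, 60, seed = lfire:::derive_seed(4, 0))
  opts_pre <- lfire_options(n_lambda = 30, n_folds = 5, marginal = marg)
  res4 <- run_inference(m, g, batch_size = 60, options = opts_pre, seed = 4)
  expect_identical(res$posterior, res4$posterior)
  # single-cell grid normalises to 1
  res1 <- run_inference(m, build_grid(t1 = c(-1, 1, 1), t2 = c(0, 1, 1)),
                        batch_size = 60, options = opts, seed = 4)
  expect_equal(res1$posterior, 1)
  expect_error(run_inference(arch_model(T = 30), g, 60),
               class = "lfire_usage_error")
})

test_that("tidy and glance expose the result as tables", {
  m <- make_observed(arch_model(T = 30), c(0.3, 0.7), seed = 19)
  g <- build_grid(t1 = c(-1, 1, 2), t2 = c(0, 1, 2))
  res <- run_inference(m, g, batch_size = 60,
                       options = lfire_options(n_lambda = 20, n_folds = 5),
                       seed = 4)
  td <- tidy(res)
  expect_named(td, c("t1", "t2", "log_ratio", "unnormalized", "posterior"))
  expect_equal(nrow(td), 4)
  tc <- tidy(res, "coefficients")
  expect_equal(ncol(tc), 2 + 18)
  gl <- glance(res)
  expect_equal(gl$n_simulations, 240)
  expect_named(gl, c("grid_rows", "batch_size", "n_simulations", "converged",
                     "seed", "map_t1", "mean_t1", "map_t2", "mean_t2"))
})

test_that("grid posterior tracks the exact-likelihood posterior of the ARCH model", {
  # ARCH(1) admits direct likelihood evaluation given the series: the
  # innovations are determined by theta1 (e_t = y_t - theta1*y_{t-1}), and
  # the unobserved e0 only enters the variance of the first innovation, so
  # it integrates out by quadrature. This gives an independent oracle for
  # the whole ratio-estimation pipeline.
  exact_loglik <- function(y, t1, t2) {
    T <- length(y)
    e <- c(y[1], y[-1] - t1 * y[-T])
    v <- 0.2 + t2 * e[-T]^2
    z <- seq(-5, 5, length.out = 41)
    wq <- dnorm(z); wq <- wq / sum(wq)
    sum(dnorm(e[-1], 0, sqrt(v), log = TRUE)) +
      log(sum(wq * dnorm(e[1], 0, sqrt(0.2 + t2 * z^2))))
  }
  model <- make_observed(arch_model(T = 100), c(0.3, 0.7), seed = 14)
  grid <- build_grid(t1 = c(-1, 1, 8), t2 = c(0, 1, 8))
  ll <- mapply(function(a, b) exact_loglik(model$observed_data, a, b),
               grid$t1, grid$t2)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  exact_mean <- c(sum(grid$t1 * w), sum(grid$t2 * w))

  res <- run_inference(model, grid, batch_size = 1000, seed = 14)
  ps <- posterior_summaries(res)
  expect_lt(abs(ps$mean["t1"] - exact_mean[1]), 0.15)
  expect_lt(abs(ps$mean["t2"] - exact_mean[2]), 0.15)
  # the estimated posterior puts most mass where the exact posterior does
  top <- order(w, decreasing = TRUE)[1:16]  # top quarter of grid cells
  expect_gt(sum(res$posterior[top]), 0.5)
})
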