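#' Simulate an ARCH(1) time series
#'
#' Lag-one autoregression with conditional heteroscedasticity:
#' \deqn{y_t = \theta_1 y_{t-1} + e_t, \qquad
#'       e_t = \xi_t \sqrt{0.2 + \theta_2 e_{t-1}^2},}
#' with \eqn{y_0 = 0} and \eqn{e_0, \xi_t} independent standard normal. The
#' innovation variance depends on the previous innovation, so `theta2`
#' controls volatility clustering while `theta1` controls serial correlation.
#'
#' @param theta1 Autoregression coefficient.
#' @param theta2 Heteroscedasticity coefficient, must be `>= 0` so the
#'   radicand `0.2 + theta2 * e^2` stays nonnegative.
#' @param T Series length, `>= 1`.
#' @param e0 Optional initial innovation; drawn standard normal when `NULL`.
#' @param xi Optional vector of `T` innovations; drawn standard normal when
#'   `NULL`. Supplying `e0` and `xi` makes the recurrence a pure function,
#'   which is how the simulator is unit-tested.
#'
#' @return Numeric vector `y[1..T]` (the fixed `y0 = 0` is excluded).
#' @examples
#' y <- simulate_arch(0.3, 0.7, T = 100, e0 = 0, xi = rep(0, 100))
#' all(y == 0)
#' @export
simulate_arch <- function(theta1, theta2, T, e0 = NULL, xi = NULL) {
  stopifnot(T >= 1)
  if (theta2 < 0) {
    abort("theta2 must be nonnegative", class = "lfire_domain_error")
  }
  if (is.null(e0)) e0 <- rnorm(1)
  if (is.null(xi)) xi <- rnorm(T)
  if (length(xi) != T) {
    abort("xi must have length T", class = "lfire_domain_error")
  }
  y <- numeric(T)
  e_prev <- e0
  y_prev <- 0
  for (t in seq_len(T)) {
    e_t <- xi[t] * sqrt(0.2 + theta2 * e_prev^2)
    y[t] <- theta1 * y_prev + e_t
    e_prev <- e_t
    y_prev <- y[t]
  }
  y
}

# Vectorised batch simulator: one ARCH(1) series per row of theta (n x 2).
# The recurrence is sequential in t but vectorises over series.
simulate_arch_batch <- function(theta, T) {
  theta <- matrix(as.numeric(theta), ncol = 2)
  if (any(theta[, 2] < 0)) {
    abort("theta2 must be nonnegative", class = "lfire_domain_error")
  }
  n <- nrow(theta)
  y <- matrix(0, n, T)
  e_prev <- rnorm(n)
  y_prev <- numeric(n)
  for (t in seq_len(T)) {
    e_t <- rnorm(n) * sqrt(0.2 + theta[, 2] * e_prev^2)
    y[, t] <- theta[, 1] * y_prev + e_t
    e_prev <- e_t
    y_prev <- y[, t]
  }
  y
}

#' Sample autocorrelation at a given lag
#'
#' Mean-subtracted autocorrelation with the plug-in (biased) denominator
#' \eqn{\sum_t (y_t - \bar y)^2} over the full series, the convention that
#' keeps the estimate in `[-1, 1]`. A constant (zero-variance) series returns
#' 0 by convention, avoiding 0/0.
#'
#' @param series Numeric vector.
#' @param lag Nonnegative integer `< length(series)`.
#' @return The autocorrelation estimate in `[-1, 1]`.
#' @examples
#' autocorrelation(sin(1:50), 1)
#' autocorrelation(rep(2, 10), 1)  # 0 by convention
#' @export
autocorrelation <- function(series, lag) {
  T <- length(series)
  if (lag < 0 || lag >= T) {
    abort("lag must satisfy 0 <= lag < length(series)",
          class = "lfire_domain_error")
  }
  m <- mean(series)
  xc <- series - m
  den <- sum(xc^2)
  if (den == 0) return(0)
  sum(xc[seq_len(T - lag)] * xc[seq_len(T - lag) + lag]) / den
}

arch_summary_names <- local({
  pairs <- utils::combn(5, 2)
  c("mean", "variance", paste0("ac", 1:5),
    paste0("ac", pairs[1, ], "_ac", pairs[2, ]))
})

#' Summary statistics for an ARCH(1) series
#'
#' The 17 summaries used for ratio estimation: series mean, sample variance,
#' autocorrelations at lags 1-5, and the 10 pairwise products
#' `ac(i) * ac(j)` over distinct lags `i < j`. Products of autocorrelations
#' supply the classifier with interactions it could not form from a linear
#' combination of the autocorrelations alone.
#'
#' @param series Numeric vector of length `>= 6` (lags 1-5 must be defined).
#' @return Named numeric vector of length 17.
#' @examples
#' arch_summaries(simulate_arch(0.3, 0.7, 100, e0 = 1, xi = rep(0.5, 100)))
#' @export
arch_summaries <- function(series) {
  if (length(series) < 6) {
    abort("series must have length >= 6", class = "lfire_domain_error")
  }
  ac <- vapply(1:5, function(k) autocorrelation(series, k), numeric(1))
  pairs <- utils::combn(5, 2)
  stats::setNames(
    c(mean(series), var(series), ac, ac[pairs[1, ]] * ac[pairs[2, ]]),
    arch_summary_names
  )
}

# Row-wise summaries for a batch of series (n x T matrix), identical in value
# to apply(y, 1, arch_summaries) but vectorised.
arch_summaries_batch <- function(y) {
  T <- ncol(y)
  if (T < 6) abort("series must have length >= 6", class = "lfire_domain_error")
  m <- rowMeans(y)
  xc <- y - m
  den <- rowSums(xc^2)
  ac <- vapply(1:5, function(k) {
    num <- rowSums(xc[, seq_len(T - k), drop = FALSE] *
                     xc[, seq_len(T - k) + k, drop = FALSE])
    ifelse(den == 0, 0, num / den)
  }, numeric(nrow(y)))
  ac <- matrix(ac, nrow = nrow(y))
  pairs <- utils::combn(5, 2)
  out <- cbind(m, den / (T - 1),
               ac, ac[, pairs[1, ], drop = FALSE] * ac[, pairs[2, ], drop = FALSE])
  colnames(out) <- arch_summary_names
  out
}

#' The built-in ARCH(1) demonstration model
#'
#' A ready-made [generative_model()]: priors `t1 ~ Uniform(-1, 1)` and
#' `t2 ~ Uniform(0, 1)`, the [simulate_arch()] simulator with series length
#' `T`, and the 17 [arch_summaries()]. With `noise = k`, `k` white-noise
#' summaries are appended via [augment_noise_summaries()].
#'
#' @param T Series length (default 100).
#' @param noise Number of irrelevant white-noise summaries to append
#'   (default 0; the robustness experiment uses 17).
#' @return A `generative_model` without observed data; attach an observation
#'   with [make_observed()].
#' @examples
#' m <- arch_model()
#' m <- make_observed(m, c(0.3, 0.7), seed = 42)
#' @export
arch_model <- function(T = 100, noise = 0) {
  priors <- prior_spec(c("t1", "t2"), "uniform",
                       lower = c(-1, 0), upper = c(1, 1))
  m <- generative_model(
    priors = priors,
    simulate = function(theta) simulate_arch(theta[1], theta[2], T),
    summarize = arch_summaries,
    summary_names = arch_summary_names,
    simulate_batch = function(theta) simulate_arch_batch(theta, T),
    summarize_batch = arch_summaries_batch
  )
  augment_noise_summaries(m, noise)
}
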