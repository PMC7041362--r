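# lfire

Likelihood-free inference by ratio estimation for simulator-based models in
R.

## The problem this package solves

Many scientific models — epidemic processes, population-genetic histories,
volatility models — are easy to *simulate* but have no tractable likelihood
$p(x \mid \theta)$, so the Bayesian posterior

$$p(\theta \mid x) = \frac{p(\theta)\,p(x \mid \theta)}{p(x)}$$

cannot be evaluated directly. This package estimates the likelihood-to-
marginal-likelihood ratio by classification: at each candidate parameter
value $\theta$, an $\ell_1$-penalised logistic regression is fit to
discriminate summary statistics $\psi(x)$ of data simulated *at* $\theta$
from summaries of data simulated from the prior predictive. The fitted
linear model

$$h(x) = \beta_0 + \textstyle\sum_i \beta_i\,\psi_i(x)$$

estimates the log-ratio $\log p(x \mid \theta) / p(x)$, and the posterior
over a grid of candidate values is

$$\hat p(\theta \mid x) \propto p(\theta)\,
\exp\!\big(\hat\beta(\theta)^\top \psi(x_{\text{obs}})\big).$$

The lasso penalty zeroes the coefficients of uninformative summaries, so
summary-statistic selection is automatic and the posterior is robust to
irrelevant summaries. The solver — cyclic coordinate descent over a
warm-started 100-step regularisation path with stratified 10-fold
cross-validation choosing the penalty — is implemented in compiled code and
verified in the test suite against independent solvers.

The package is for statisticians and modellers who can write a simulator
(a prior sampler, a data generator, a summary map) and want a posterior
without deriving a likelihood. An ARCH(1) time-series model ships as a
complete, fully synthetic example.

## Worked example

The built-in demonstration model is an ARCH(1) process
$y^{(t)} = \theta_1 y^{(t-1)} + e^{(t)}$ with
$e^{(t)} = \xi^{(t)}\sqrt{0.2 + \theta_2 (e^{(t-1)})^2}$, uniform priors
$\theta_1 \sim U(-1,1)$, $\theta_2 \sim U(0,1)$, and 17 summaries (mean,
variance, autocorrelations at lags 1–5 and their pairwise products). The
observed series is simulated at $(\theta_1, \theta_2) = (0.3, 0.7)$ with
$T = 100$:

```r
library(lfire)

model <- arch_model(T = 100)                       # priors + simulator + summaries
model <- make_observed(model, c(0.3, 0.7), seed = 5)

grid <- build_grid(t1 = c(-1, 1, 15), t2 = c(0, 1, 15))
result <- run_inference(model, grid, batch_size = 1000, seed = 3)
result
```

```
Method: LFIRE
Number of simulations:225000
MAP estimates: t1:0.429, t2:0.5
Posterior means: t1:0.387, t2:0.682
```

The four lines report the method, the total number of conditional
simulations (grid rows × batch size), the grid cell with the highest
normalised posterior weight, and the posterior-weighted mean of each
parameter — both close to the generating values (0.3, 0.7) here. A series
of 100 observations carries limited information, so posterior means vary
substantially from one simulated observed series to the next; the posterior
quantifies exactly that uncertainty. Results are ordinary tibbles
underneath:

```r
tidy(result)                    # per grid point: log-ratio, posterior weight
tidy(result, "coefficients")    # which summaries each grid point selected
glance(result)                  # one-row run summary
marginal_densities(result, "t1")
plot_marginals(result)          # ggplot; plot_pairs(result) for the joint
```

Appending irrelevant white-noise summaries (`arch_model(noise = 17)`)
leaves the posterior essentially unchanged — the penalty discards them; the
test suite checks this property across matched-seed replicates.

A YAML-configured command-line interface wraps the same functions:

```sh
Rscript inst/cli/lfire.R run --grid 15x15 --batch-size 1000 \
  --seed 7 --out-dir results/
Rscript inst/cli/lfire.R summarize --out-dir results/
```

## Package layout

* `R/arch-model.R`, `R/generative-model.R` — the model abstraction
  (`prior_spec`, `generative_model`, `make_observed`,
  `augment_noise_summaries`) and the ARCH(1) model.
* `R/penalized-logistic.R`, `src/coord_descent.cpp` — the lasso logistic
  solver: `standardize`, `lambda_max`, `fit_at_lambda`, `fit_path`,
  `cross_validate`.
* `R/lfire.R` — `run_inference` and the posterior calculus
  (`evaluate_unnormalized_posterior`, `normalize_over_grid`,
  `posterior_summaries`, `marginal_densities`).
* `R/grid.R`, `R/report.R`, `R/config.R`, `inst/cli/lfire.R` — grids,
  summaries/plots/serialisation, YAML configs, CLI.
* `vignettes/lfire-methods.Rmd` — the model, solver internals, numerical
  choices, and limitations.
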