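fmt3 <- function(x) {
  vapply(x, function(v) {
    format(signif(v, 3), trim = TRUE, scientific = FALSE,
           drop0trailing = TRUE)
  }, character(1))
}

fmt_pairs <- function(values) {
  paste0(names(values), ":", fmt3(values), collapse = ", ")
}

#' Render the four-line textual summary of an inference run
#'
#' A pure function of the result: method name, total conditional simulation
#' count, MAP estimates and posterior means per parameter (3 significant
#' figures, trailing zeros trimmed).
#'
#' @param result An [run_inference()] result.
#' @return A single character string of four newline-separated lines.
#' @export
render_summary <- function(result) {
  stopifnot(inherits(result, "lfire_result"))
  ps <- posterior_summaries(result)
  paste(
    "Method: LFIRE",
    paste0("Number of simulations:",
           format(result$n_simulations, scientific = FALSE, trim = TRUE)),
    paste0("MAP estimates: ", fmt_pairs(ps$map)),
    paste0("Posterior means: ", fmt_pairs(ps$mean)),
    sep = "\n"
  )
}

marginals_data <- function(result) {
  purrr::map_dfr(names(result$grid), function(p) {
    dplyr::mutate(marginal_densities(result, p), parameter = p,
                  .before = 1)
  })
}

#' Plot marginal posterior densities
#'
#' One panel per parameter showing the marginal posterior weights over that
#' parameter's grid axis. Requires a Cartesian-product grid.
#'
#' @param result An [run_inference()] result.
#' @param file Optional path; when given the figure is also written there
#'   with [ggplot2::ggsave()].
#' @return A ggplot object.
#' @export
plot_marginals <- function(result, file = NULL) {
  df <- marginals_data(result)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "marginal posterior weight")
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 3.5)
  p
}

#' Plot pairwise and marginal posterior densities
#'
#' A panel matrix: marginal posteriors on the diagonal and pairwise joint
#' posterior heatmaps off-diagonal, assembled with patchwork. Requires a
#' Cartesian-product grid.
#'
#' @inheritParams plot_marginals
#' @return A patchwork object (prints as one figure).
#' @export
plot_pairs <- function(result, file = NULL) {
  pars <- names(result$grid)
  joint <- tidy(result)
  panels <- purrr::map(seq_along(pars), function(i) {
    purrr::map(seq_along(pars), function(j) {
      if (i == j) {
        ggplot2::ggplot(marginal_densities(result, pars[i]),
                        ggplot2::aes(x = .data$value, y = .data$weight)) +
          ggplot2::geom_line() +
          ggplot2::labs(x = pars[i], y = "weight")
      } else {
        ggplot2::ggplot(joint,
                        ggplot2::aes(x = .data[[pars[j]]],
                                     y = .data[[pars[i]]],
                                     fill = .data$posterior)) +
          ggplot2::geom_tile() +
          ggplot2::guides(fill = "none")
      }
    })
  })
  p <- patchwork::wrap_plots(purrr::flatten(panels), ncol = length(pars))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 7)
  p
}

#' @rdname plot_marginals
#' @param object An `lfire_result`.
#' @param ... Unused.
#' @export
autoplot.lfire_result <- function(object, ...) plot_marginals(object)

#' Write inference results to disk
#'
#' Three plain-text artifacts: `posterior.csv` (grid columns plus
#' unnormalised and normalised posterior), `coefficients.csv` (fitted
#' intercept and slopes per grid row), and `result.json` (MAP, posterior
#' means, simulation count, batch size, seed and solver options).
#'
#' @param result An [run_inference()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "lfire_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    posterior = file.path(dir, "posterior.csv"),
    coefficients = file.path(dir, "coefficients.csv"),
    json = file.path(dir, "result.json")
  )
  utils::write.csv(tidy(result), paths["posterior"], row.names = FALSE)
  utils::write.csv(tidy(result, "coefficients"), paths["coefficients"],
                   row.names = FALSE)
  ps <- posterior_summaries(result)
  jsonlite::write_json(
    list(method = "LFIRE",
         n_simulations = result$n_simulations,
         map_estimates = as.list(ps$map),
         posterior_means = as.list(ps$mean),
         batch_size = result$batch_size,
         seed = result$seed,
         options = result$options[c("n_lambda", "n_folds", "tol",
                                    "max_iter", "parallel", "cores")]),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Reload a written result for summarising and plotting
#'
#' Rebuilds a lightweight `lfire_result` from the files written by
#' [write_result()]; enough for [render_summary()], [marginal_densities()]
#' and the plotting functions, but without the model or summary sets.
#'
#' @param dir Directory previously passed to [write_result()].
#' @return An `lfire_result`.
#' @export
read_result <- function(dir) {
  post <- tibble::as_tibble(utils::read.csv(file.path(dir, "posterior.csv")))
  meta <- jsonlite::read_json(file.path(dir, "result.json"),
                              simplifyVector = TRUE)
  pars <- setdiff(names(post), c("log_ratio", "unnormalized", "posterior"))
  structure(
    list(grid = post[, pars],
         log_ratio = post$log_ratio,
         log_unnormalized = log(post$unnormalized),
         unnormalized = post$unnormalized,
         posterior = post$posterior,
         n_simulations = meta$n_simulations,
         map_index = which.max(post$posterior),
         posterior_means = unlist(meta$posterior_means),
         batch_size = meta$batch_size,
         seed = meta$seed),
    class = "lfire_result"
  )
}
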