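#' Build a Cartesian evaluation grid from per-parameter axes
#'
#' Each axis is `c(low, high, count)`: `count` equally spaced values from
#' `low` to `high` inclusive. Rows are ordered row-major with the first
#' parameter varying slowest, so `build_grid(t1 = c(0, 1, 2), t2 = c(0, 1, 2))`
#' yields rows (0,0), (0,1), (1,0), (1,1).
#'
#' @param ... Named axes, one per parameter, each `c(low, high, count)` with
#'   `low < high` and `count >= 1`. A `count` of 1 places the single point at
#'   `low`.
#' @return A tibble with `prod(counts)` rows, one column per parameter.
#' @examples
#' build_grid(t1 = c(-1, 1, 100), t2 = c(0, 1, 100))  # 10000 x 2
#' @export
build_grid <- function(...) {
  axes <- list(...)
  if (length(axes) == 0 || is.null(names(axes)) || any(names(axes) == "")) {
    abort("supply named axes, e.g. build_grid(t1 = c(-1, 1, 100))",
          class = "lfire_config_error")
  }
  values <- purrr::imap(axes, function(ax, nm) {
    if (length(ax) != 3 || ax[1] >= ax[2] || ax[3] < 1) {
      abort(sprintf("axis '%s' must be c(low, high, count) with low < high, count >= 1",
                    nm),
            class = "lfire_config_error")
    }
    if (ax[3] == 1) ax[1] else seq(ax[1], ax[2], length.out = ax[3])
  })
  # expand.grid varies the first factor fastest; feed axes reversed so the
  # first parameter varies slowest, then restore column order
  grid <- do.call(expand.grid, c(rev(values), KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(grid[, rev(seq_along(values)), drop = FALSE])
}
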