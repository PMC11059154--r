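#' @export
print.slo_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<slo_fit> %s SLOA%s | N = %d, iters = %d, dim = %d\n",
    if (cfg$mode == "fractional") "fractional-order" else "classic",
    if (cfg$mode == "fractional") sprintf(" (sigma = %g, M = %d)",
                                          cfg$sigma, cfg$memory_depth) else "",
    cfg$pop_size, cfg$max_iter, cfg$dim
  ))
  cat(sprintf("  best cost: %.6g after %d objective evaluations\n",
              x$best_cost, x$evaluations))
  cat("  best position: ",
      paste(signif(x$best_position, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy the convergence trace of a snow leopard fit
#'
#' @param x An [slo_optimize()] result.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `best_cost`,
#'   `mean_cost`, and the `best_position` list-column.
#' @export
tidy.slo_fit <- function(x, ...) {
  x$trace
}

#' One-row summary of a snow leopard fit
#'
#' @inheritParams tidy.slo_fit
#' @return A one-row tibble with the mode, fractional order, population size,
#'   iteration and evaluation counts, initial and final best cost.
#' @export
glance.slo_fit <- function(x, ...) {
  tibble(
    mode = x$config$mode,
    sigma = x$config$sigma,
    pop_size = x$config$pop_size,
    iterations = x$config$max_iter,
    evaluations = x$evaluations,
    initial_best = min(x$initial_costs),
    best_cost = x$best_cost
  )
}

#' Convergence plot for a snow leopard fit
#'
#' Best and mean cost per iteration on a log10 cost axis when all recorded
#' costs are positive, linear otherwise.
#'
#' @param object An [slo_optimize()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slo_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$trace, "iteration", "best_cost", "mean_cost"),
    cols = c("best_cost", "mean_cost"),
    names_to = "series", values_to = "cost"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$cost,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "cost", colour = NULL,
                  title = sprintf("%s SLOA convergence", object$config$mode))
  if (all(df$cost > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
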