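#' Build an optimizer adapter for the trial harness
#'
#' An adapter is a function `(benchmark, seed) -> list(best_cost, fit)` that
#' [run_trials()] can call for any registered benchmark. This constructor
#' wraps [slo_optimize()]; external optimizers can be compared by supplying a
#' function with the same signature.
#'
#' @param mode `"fractional"` or `"classic"`.
#' @param sigma Fractional order (fractional mode only).
#' @param pop_size,max_iter Population size and iteration budget.
#' @param ... Further arguments passed on to [slo_optimize()].
#' @return An adapter function.
#' @export
slo_adapter <- function(mode = c("fractional", "classic"), sigma = 0.9,
                        pop_size = 60L, max_iter = 120L, ...) {
  mode <- match.arg(mode)
  extra <- list(...)
  function(benchmark, seed) {
    fit <- do.call(slo_optimize, c(list(
      objective = benchmark$fn,
      lower = benchmark$lower, upper = benchmark$upper, dim = benchmark$dim,
      pop_size = pop_size, max_iter = max_iter,
      mode = mode, sigma = sigma, seed = seed
    ), extra))
    list(best_cost = fit$best_cost, fit = fit)
  }
}

default_adapters <- function(names) {
  setNames(lapply(names, function(nm) {
    switch(nm,
      "fo-slo" = slo_adapter("fractional"),
      "slo"    = slo_adapter("classic"),
      abort(sprintf("unknown optimizer name '%s'; built-ins: fo-slo, slo", nm))
    )
  }), names)
}

#' Repeated-trial AVG/STD comparison of optimizers on benchmark functions
#'
#' Runs every optimizer `repeats` times on every function with seeds
#' `base_seed, ..., base_seed + repeats - 1` and summarizes the final best
#' costs by their mean (AVG) and sample standard deviation (STD), the
#' standard reporting protocol for metaheuristic validation studies.
#'
#' @param optimizers Named list of adapter functions (see [slo_adapter()]),
#'   or a character vector of built-in names (`"fo-slo"`, `"slo"`).
#' @param functions Character vector of benchmark names ([list_benchmarks()])
#'   or a list of `benchmark_fn` objects.
#' @param dim Dimension for benchmarks given by name, default 10.
#' @param repeats Number of repeated runs R >= 1 per cell, default 10.
#' @param base_seed First seed, default 1.
#' @return An object of class `slo_trials`: list with `runs` (tibble:
#'   `optimizer`, `fn`, `seed`, `best_cost`) and `summary` (tibble:
#'   `fn`, `optimizer`, `avg`, `std`, `n`). A failing adapter produces NA
#'   cells with a warning rather than aborting the sweep.
#' @export
run_trials <- function(optimizers, functions, dim = 10L, repeats = 10L,
                       base_seed = 1L) {
  if (is.character(optimizers)) optimizers <- default_adapters(optimizers)
  if (is.null(names(optimizers)) || any(names(optimizers) == "")) {
    abort("`optimizers` must be a named list of adapters.")
  }
  if (is.character(functions)) {
    functions <- lapply(functions, get_benchmark, dim = dim)
  }
  fn_names <- vapply(functions, function(b) b$name, character(1))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) abort("`repeats` must be >= 1.")
  seeds <- as.integer(base_seed) + seq_len(repeats) - 1L

  grid <- tidyr::expand_grid(
    optimizer = names(optimizers), fn_idx = seq_along(functions), seed = seeds
  )
  runs <- purrr::pmap(grid, function(optimizer, fn_idx, seed) {
    bench <- functions[[fn_idx]]
    best <- tryCatch(
      optimizers[[optimizer]](bench, seed)$best_cost,
      error = function(e) {
        warning(sprintf("adapter '%s' failed on '%s' (seed %d): %s",
                        optimizer, bench$name, seed, conditionMessage(e)),
                call. = FALSE)
        NA_real_
      }
    )
    tibble(optimizer = optimizer, fn = bench$name, seed = seed,
           best_cost = best)
  })
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$fn, .data$optimizer) |>
    dplyr::summarise(
      avg = mean(.data$best_cost),
      std = if (dplyr::n() == 1L) 0 else sd(.data$best_cost),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$fn, fn_names),
                   match(.data$optimizer, names(optimizers)))
  structure(list(runs = runs, summary = summary), class = "slo_trials")
}

#' @export
print.slo_trials <- function(x, ...) {
  cat("<slo_trials> AVG/STD over", max(x$summary$n), "runs\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.slo_trials <- function(x, ...) x$runs

#' @export
glance.slo_trials <- function(x, ...) {
  tibble(
    optimizers = dplyr::n_distinct(x$runs$optimizer),
    functions = dplyr::n_distinct(x$runs$fn),
    repeats = max(x$summary$n),
    failed_runs = sum(is.na(x$runs$best_cost))
  )
}

#' @export
autoplot.slo_trials <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(.data$optimizer, .data$best_cost,
                               fill = .data$optimizer)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$fn), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "final best cost")
}

#' Write a trial report as AVG and STD CSV tables
#'
#' Writes a wide table (rows = functions, one column per optimizer) of AVG
#' cells to `path` and the matching STD cells to a `_std.csv` companion.
#'
#' @param report An [run_trials()] result.
#' @param path Output CSV path for the AVG table.
#' @return Invisibly, a list with the two paths written.
#' @export
write_trial_csv <- function(report, path) {
  stopifnot(inherits(report, "slo_trials"))
  wide <- function(col) {
    tidyr::pivot_wider(
      dplyr::select(report$summary, "fn", "optimizer", dplyr::all_of(col)),
      names_from = "optimizer", values_from = dplyr::all_of(col)
    )
  }
  std_path <- sub("\\.csv$", "_std.csv", path)
  if (identical(std_path, path)) std_path <- paste0(path, "_std.csv")
  readr::write_csv(wide("avg"), path)
  readr::write_csv(wide("std"), std_path)
  invisible(list(avg = path, std = std_path))
}
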