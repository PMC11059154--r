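# Classic unimodal/multimodal analytic test functions with box bounds and
# known optima. Definitions follow the standard forms used throughout the
# metaheuristics literature.

penalty_u <- function(x, a, k, m) {
  sum(ifelse(x > a, k * (x - a)^m, ifelse(x < -a, k * (-x - a)^m, 0)))
}

benchmark_registry <- local({
  reg <- list(
    sphere = list(
      fn = function(x) sum(x^2),
      lower = -100, upper = 100, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    rosenbrock = list(
      fn = function(x) {
        n <- length(x)
        sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
      },
      lower = -30, upper = 30, min_dim = 2L,
      minimizer = function(dim) rep(1, dim)
    ),
    rastrigin = list(
      fn = function(x) sum(x^2 - 10 * cos(2 * pi * x)) + 10 * length(x),
      lower = -5.12, upper = 5.12, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    ackley = list(
      fn = function(x) {
        n <- length(x)
        -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
          exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
      },
      lower = -32, upper = 32, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    griewank = list(
      fn = function(x) {
        sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
      },
      lower = -600, upper = 600, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    schwefel_2_26 = list(
      fn = function(x) {
        418.9828872724339 * length(x) - sum(x * sin(sqrt(abs(x))))
      },
      lower = -500, upper = 500, min_dim = 1L,
      # the per-coordinate minimizer of -x sin(sqrt(x)), found numerically
      # once to full precision
      minimizer = function(dim) rep(420.96874635998194, dim)
    ),
    step = list(
      fn = function(x) sum(floor(x + 0.5)^2),
      lower = -100, upper = 100, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    quartic = list(
      fn = function(x) sum(seq_along(x) * x^4),
      lower = -1.28, upper = 1.28, min_dim = 1L,
      minimizer = function(dim) rep(0, dim)
    ),
    penalized1 = list(
      fn = function(x) {
        n <- length(x)
        y <- 1 + (x + 1) / 4
        (pi / n) * (10 * sin(pi * y[1])^2 +
                      sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                      (y[n] - 1)^2) +
          penalty_u(x, 10, 100, 4)
      },
      lower = -50, upper = 50, min_dim = 2L,
      minimizer = function(dim) rep(-1, dim)
    ),
    penalized2 = list(
      fn = function(x) {
        n <- length(x)
        0.1 * (sin(3 * pi * x[1])^2 +
                 sum((x[-n] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
                 (x[n] - 1)^2 * (1 + sin(2 * pi * x[n])^2)) +
          penalty_u(x, 5, 100, 4)
      },
      lower = -50, upper = 50, min_dim = 2L,
      minimizer = function(dim) rep(1, dim)
    )
  )
  reg
})

#' List the registered benchmark functions
#'
#' @return Character vector of function names accepted by [get_benchmark()].
#' @export
list_benchmarks <- function() names(benchmark_registry)

#' Fetch a benchmark objective with bounds and optimum metadata
#'
#' The suite is the classic unimodal/multimodal collection (sphere,
#' rosenbrock, rastrigin, ackley, griewank, schwefel_2_26, step, noise-free
#' quartic, penalized1, penalized2) at a user-selectable dimension.
#'
#' @param name One of [list_benchmarks()].
#' @param dim Dimension, default 10.
#' @return An object of class `benchmark_fn`: a list with `name`, `dim`,
#'   `fn`, `lower`, `upper` (length-`dim` vectors), `minimizer`, and `fmin`
#'   (the objective evaluated at the stated minimizer).
#' @examples
#' b <- get_benchmark("rastrigin", dim = 2)
#' b$fn(b$minimizer)  # 0
#' @export
get_benchmark <- function(name, dim = 10L) {
  if (!name %in% names(benchmark_registry)) {
    abort(sprintf("unknown benchmark '%s'; registered: %s",
                  name, paste(names(benchmark_registry), collapse = ", ")))
  }
  dim <- as.integer(dim)
  entry <- benchmark_registry[[name]]
  if (is.na(dim) || dim < entry$min_dim) {
    abort(sprintf("'%s' requires dim >= %d.", name, entry$min_dim))
  }
  minimizer <- entry$minimizer(dim)
  structure(
    list(
      name = name, dim = dim, fn = entry$fn,
      lower = rep(entry$lower, dim), upper = rep(entry$upper, dim),
      minimizer = minimizer, fmin = entry$fn(minimizer)
    ),
    class = "benchmark_fn"
  )
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf("<benchmark_fn> %s, dim %d, bounds [%g, %g], f(x*) = %.3g\n",
              x$name, x$dim, x$lower[1], x$upper[1], x$fmin))
  invisible(x)
}
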