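#' Grunwald-Letnikov memory coefficients
#'
#' Truncated binomial weights of the discrete Grunwald-Letnikov fractional
#' derivative of order `sigma`, used by the fractional-order snow leopard
#' updates to weight the current and past accepted positions. The first
#' coefficient multiplies the current position, later ones successively older
#' memory slots:
#' \deqn{c_1 = \sigma,\qquad c_{a+1} = c_a \frac{a - \sigma}{a + 1}.}
#' For `sigma = 1` the weights collapse to `c(1, 0, ..., 0)` and the memory
#' term reduces to the ordinary (memoryless) position update.
#'
#' @param sigma Fractional order, in (0, 1]. Controls memory decay: smaller
#'   values put more weight on older positions.
#' @param depth Number of coefficients (memory window length), >= 1.
#'   Default 4, the window used throughout the package.
#' @return Numeric vector of length `depth`; entries are positive and
#'   strictly decreasing for `sigma` in (0, 1), and their sum never exceeds 1.
#' @examples
#' gl_coefficients(0.5, 4)   # 0.5 0.125 0.0625 0.0390625
#' gl_coefficients(1, 4)     # 1 0 0 0
#' @export
gl_coefficients <- function(sigma, depth = 4L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0 || sigma > 1) {
    abort("`sigma` must be a single number in (0, 1].")
  }
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) abort("`depth` must be an integer >= 1.")
  coeffs <- numeric(depth)
  coeffs[1L] <- sigma
  if (depth > 1L) {
    for (a in seq_len(depth - 1L)) {
      coeffs[a + 1L] <- coeffs[a] * (a - sigma) / (a + 1)
    }
  }
  coeffs
}

#' Initialize a snow leopard population
#'
#' Uniform sampling of `pop_size` candidate solutions inside the box
#' `[lower, upper]^dim`. The population size must be even (breeding pairs the
#' l-th member with the (N-l+1)-th, producing exactly N/2 cubs) and at least 4.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds; scalars are
#'   recycled to `dim`.
#' @param pop_size Even integer >= 4.
#' @param dim Problem dimension, >= 1.
#' @param seed Optional integer; when given the draw is wrapped in
#'   [withr::with_seed()] so the caller's RNG stream is untouched.
#' @return A `pop_size` x `dim` numeric matrix.
#' @export
slo_init_population <- function(lower, upper, pop_size, dim, seed = NULL) {
  bounds <- check_bounds(lower, upper, dim)
  pop_size <- as.integer(pop_size)
  if (is.na(pop_size) || pop_size < 4L || pop_size %% 2L != 0L) {
    abort("`pop_size` must be an even integer >= 4.")
  }
  draw <- function() {
    matrix(
      runif(pop_size * dim,
            min = rep(bounds$lower, each = pop_size),
            max = rep(bounds$upper, each = pop_size)),
      nrow = pop_size, ncol = dim
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_bounds <- function(lower, upper, dim) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) abort("`dim` must be an integer >= 1.")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("bounds must be finite.")
  }
  if (any(lower > upper)) abort("each lower bound must be <= its upper bound.")
  list(lower = lower, upper = upper, dim = dim)
}

#' Evaluate a population against an objective
#'
#' @param positions N x m matrix of candidate solutions.
#' @param objective Function mapping a length-m numeric vector to a finite
#'   scalar cost.
#' @return Numeric cost vector of length N, row order preserved.
#' @export
slo_evaluate <- function(positions, objective) {
  vapply(seq_len(nrow(positions)), function(i) {
    v <- objective(positions[i, ])
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("objective returned a non-finite value for member %d.", i))
    }
    as.numeric(v)
  }, numeric(1))
}

# one uniform draw from {1..n} \ {i}
sample_other <- function(n, i) {
  k <- sample.int(n - 1L, 1L)
  if (k >= i) k + 1L else k
}

# zig-zag motion displacement (per-dimension guide k, scalar r and I)
motion_displacement <- function(z, guide_vals, r, I, s) {
  r * (guide_vals - I * z) * s
}

# preying displacement toward prey f with stride fraction F
preying_displacement <- function(z, f, r, prey_fraction, s) {
  r * ((f - z) * prey_fraction + (f - 2 * z) * (1 - prey_fraction)) * s
}

# Grunwald-Letnikov base term: c1 * live position + sum_a>=2 c_a * memory slot
gl_base <- function(z_live, memory_rows, coeffs) {
  base <- coeffs[1L] * z_live
  if (length(coeffs) > 1L) {
    for (a in 2:length(coeffs)) {
      base <- base + coeffs[a] * memory_rows[[a]]
    }
  }
  base
}

# prey selection: uniform among strictly better members; the incumbent best
# preys on itself (the sign term then produces no movement)
pick_prey <- function(costs, i) {
  better <- which(costs < costs[i])
  if (length(better) == 0L) return(which.min(costs))
  if (length(better) == 1L) return(better)
  better[sample.int(length(better), 1L)]
}

# One greedy update phase over all members, sequential (member-major).
# phase = "motion": per-dimension guide index k, I = round-half-up(1 + r).
# phase = "prey":   prey drawn among strictly better members.
# coeffs/memory implement the fractional-order base term; classic mode passes
# coeffs = 1 so the base is exactly the live position.
slo_phase <- function(positions, costs, objective, lower, upper,
                      phase = c("motion", "prey"),
                      prey_fraction = 0.375,
                      coeffs = 1, memory = NULL) {
  phase <- match.arg(phase)
  n <- nrow(positions)
  m <- ncol(positions)
  depth <- length(coeffs)
  for (i in seq_len(n)) {
    r <- runif(1L)
    z <- positions[i, ]
    if (phase == "motion") {
      I <- if (r >= 0.5) 2 else 1  # round(1 + r), half away from zero
      k <- vapply(seq_len(m), function(d) sample_other(n, i), integer(1))
      s <- sign(costs[i] - costs[k])
      disp <- motion_displacement(z, positions[cbind(k, seq_len(m))], r, I, s)
    } else {
      j <- pick_prey(costs, i)
      s <- sign(costs[i] - costs[j])
      disp <- preying_displacement(z, positions[j, ], r, prey_fraction, s)
    }
    mem_rows <- if (depth > 1L) lapply(memory, function(mm) mm[i, ]) else NULL
    cand <- gl_base(z, mem_rows, coeffs) + disp
    cand <- pmin(pmax(cand, lower), upper)
    cand_cost <- objective(cand)
    if (!is.finite(cand_cost)) {
      abort(sprintf("objective returned a non-finite value for member %d.", i))
    }
    if (cand_cost < costs[i]) {
      positions[i, ] <- cand
      costs[i] <- cand_cost
    }
  }
  list(positions = positions, costs = costs)
}

#' Motion phase (zig-zag travel) of the snow leopard algorithm
#'
#' For each member i a scalar `r ~ U(0,1)` and `I = round(1 + r)` are drawn,
#' a guide index k is redrawn per dimension, and the candidate
#' `z + r (z_k - I z) sign(P_i - P_k)` is clamped to the box, evaluated, and
#' greedily accepted only when its cost is strictly lower.
#'
#' @inheritParams slo_evaluate
#' @param costs Current cost vector, consistent with `positions`.
#' @param lower,upper Per-dimension bounds (recycled).
#' @return List with updated `positions` and `costs`.
#' @export
slo_motion_step <- function(positions, costs, objective, lower, upper) {
  b <- check_bounds(lower, upper, ncol(positions))
  slo_phase(positions, costs, objective, b$lower, b$upper, phase = "motion")
}

#' Preying phase (attack on a better-placed prey)
#'
#' Each member strides a fraction `prey_fraction` (default 0.375, the
#' observed stride share of a snow leopard's attack) of the distance to a
#' prey drawn uniformly among strictly better members, plus the complementary
#' lunge term; greedy acceptance as in the motion phase.
#'
#' @inheritParams slo_motion_step
#' @param prey_fraction Stride fraction F in (0, 1), default 0.375.
#' @return List with updated `positions` and `costs`.
#' @export
slo_preying_step <- function(positions, costs, objective, lower, upper,
                             prey_fraction = 0.375) {
  b <- check_bounds(lower, upper, ncol(positions))
  slo_phase(positions, costs, objective, b$lower, b$upper, phase = "prey",
            prey_fraction = prey_fraction)
}

#' Breeding phase: pair members into midpoints
#'
#' Cub l is the elementwise midpoint of members l and N - l + 1, so exactly
#' N/2 cubs are produced and every cub lies in the convex hull of its parents
#' (hence inside the box).
#'
#' @param positions N x m matrix with even N.
#' @return (N/2) x m matrix of cubs.
#' @export
slo_breeding_step <- function(positions) {
  n <- nrow(positions)
  if (n %% 2L != 0L) abort("breeding requires an even population size.")
  half <- n %/% 2L
  (positions[seq_len(half), , drop = FALSE] +
     positions[n + 1L - seq_len(half), , drop = FALSE]) / 2
}

#' Fatality phase: elitist truncation back to the target size
#'
#' Pools parents and cubs, orders by cost ascending with a stable tie-break
#' (parents before cubs, then lower index), and keeps the best
#' `target_size` members, so the population size stays constant across
#' iterations.
#'
#' @param parents,cubs Position matrices.
#' @param parent_costs,cub_costs Matching cost vectors.
#' @param target_size Number of survivors (at most the pool size).
#' @return List with `positions`, `costs`, and `kept` (pool indices of the
#'   survivors; parents come first in the pool).
#' @export
slo_fatality_step <- function(parents, parent_costs, cubs, cub_costs,
                              target_size) {
  pool <- rbind(parents, cubs)
  costs <- c(parent_costs, cub_costs)
  if (target_size > nrow(pool)) {
    abort("`target_size` exceeds the pooled population size.")
  }
  ord <- order(costs)            # order() is stable: parents (lower pool
  kept <- ord[seq_len(target_size)]  # index) precede cubs on ties
  list(positions = pool[kept, , drop = FALSE], costs = costs[kept],
       kept = kept)
}

#' Run the snow leopard optimizer
#'
#' Minimizes `objective` over the box `[lower, upper]^dim` with the snow
#' leopard lifecycle: per iteration a motion phase, a preying phase, breeding
#' of N/2 midpoint cubs, and elitist fatality back to N members. In
#' `mode = "fractional"` the motion and preying base terms are replaced by a
#' Grunwald-Letnikov weighted sum over the current and the last
#' `memory_depth - 1` accepted position snapshots (one snapshot per phase);
#' `sigma = 1` reproduces the classic algorithm exactly, draw for draw.
#'
#' @param objective Function from a length-`dim` numeric vector to a finite
#'   scalar cost.
#' @param lower,upper Box bounds, scalars or length-`dim` vectors.
#' @param dim Problem dimension.
#' @param pop_size Even population size N, default 60.
#' @param max_iter Iteration count, default 120.
#' @param mode `"fractional"` (default) or `"classic"`.
#' @param sigma Fractional order in (0, 1], default 0.9. Ignored in classic
#'   mode.
#' @param prey_fraction Stride fraction F of the preying phase, default 0.375.
#' @param memory_depth Memory window M >= 1, default 4. Ignored in classic
#'   mode.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @return An object of class `slo_fit`: a list with `best_position`,
#'   `best_cost`, `trace` (tibble with `iteration`, `best_cost`, `mean_cost`,
#'   and a `best_position` list-column, one row per iteration),
#'   `initial_costs`, `evaluations`, and the resolved `config`. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' fit <- slo_optimize(function(x) sum(x^2), lower = -5, upper = 5, dim = 2,
#'                     pop_size = 10, max_iter = 20, seed = 1)
#' glance(fit)
#' @export
slo_optimize <- function(objective, lower, upper, dim,
                         pop_size = 60L, max_iter = 120L,
                         mode = c("fractional", "classic"),
                         sigma = 0.9, prey_fraction = 0.375,
                         memory_depth = 4L, seed = 1L) {
  mode <- match.arg(mode)
  b <- check_bounds(lower, upper, dim)
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (is.na(pop_size) || pop_size < 4L || pop_size %% 2L != 0L) {
    abort("`pop_size` must be an even integer >= 4.")
  }
  if (is.na(max_iter) || max_iter < 1L) abort("`max_iter` must be >= 1.")
  if (prey_fraction <= 0 || prey_fraction >= 1) {
    abort("`prey_fraction` must lie strictly between 0 and 1.")
  }
  memory_depth <- as.integer(memory_depth)
  if (is.na(memory_depth) || memory_depth < 1L) {
    abort("`memory_depth` must be >= 1.")
  }
  coeffs <- if (mode == "fractional") gl_coefficients(sigma, memory_depth) else 1
  n_eval <- 0L
  counting <- function(x) { n_eval <<- n_eval + 1L; objective(x) }

  withr::with_seed(as.integer(seed), {
    positions <- slo_init_population(b$lower, b$upper, pop_size, b$dim)
    costs <- slo_evaluate(positions, counting)
    initial_costs <- costs
    # memory slot a holds the accepted snapshot a phases back; slot 1 is the
    # most recent end-of-phase state (the live matrix stands in for "now")
    memory <- rep(list(positions), length(coeffs))
    trace <- vector("list", max_iter)
    for (it in seq_len(max_iter)) {
      ph1 <- slo_phase(positions, costs, counting, b$lower, b$upper,
                       phase = "motion", coeffs = coeffs, memory = memory)
      positions <- ph1$positions; costs <- ph1$costs
      if (length(coeffs) > 1L) {
        memory <- c(list(positions), memory[-length(memory)])
      }
      ph2 <- slo_phase(positions, costs, counting, b$lower, b$upper,
                       phase = "prey", prey_fraction = prey_fraction,
                       coeffs = coeffs, memory = memory)
      positions <- ph2$positions; costs <- ph2$costs
      if (length(coeffs) > 1L) {
        memory <- c(list(positions), memory[-length(memory)])
      }
      cubs <- slo_breeding_step(positions)
      cub_costs <- slo_evaluate(cubs, counting)
      fat <- slo_fatality_step(positions, costs, cubs, cub_costs, pop_size)
      if (length(coeffs) > 1L) {
        # carry each survivor's memory; cubs start with their own position
        memory <- lapply(memory, function(mm) {
          out <- matrix(0, pop_size, b$dim)
          for (l in seq_len(pop_size)) {
            idx <- fat$kept[l]
            out[l, ] <- if (idx <= pop_size) mm[idx, ] else cubs[idx - pop_size, ]
          }
          out
        })
      }
      positions <- fat$positions; costs <- fat$costs
      best <- which.min(costs)
      trace[[it]] <- tibble(
        iteration = it,
        best_cost = costs[best],
        mean_cost = mean(costs),
        best_position = list(positions[best, ])
      )
    }
    trace <- dplyr::bind_rows(trace)
    best <- which.min(costs)
    structure(
      list(
        best_position = positions[best, ],
        best_cost = costs[best],
        trace = trace,
        initial_costs = initial_costs,
        evaluations = n_eval,
        config = list(
          mode = mode, sigma = if (mode == "fractional") sigma else NA_real_,
          prey_fraction = prey_fraction,
          memory_depth = if (mode == "fractional") memory_depth else NA_integer_,
          pop_size = pop_size, max_iter = max_iter,
          lower = b$lower, upper = b$upper, dim = b$dim,
          seed = as.integer(seed)
        )
      ),
      class = "slo_fit"
    )
  })
}
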