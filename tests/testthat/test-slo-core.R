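test_that("GL coefficients match the closed-form products and recurrence", {
  expect_equal(gl_coefficients(0.5, 4),
               c(0.5, 0.125, 0.0625, 0.0390625), tolerance = 1e-14)
  expect_equal(gl_coefficients(0.9, 4),
               c(0.9, 0.045, 0.0165, 0.0086625), tolerance = 1e-14)
  expect_equal(gl_coefficients(1, 4), c(1, 0, 0, 0))
  withr::with_seed(42, {
    for (rep in 1:25) {
      sigma <- runif(1, 0.01, 0.99)
      cc <- gl_coefficients(sigma, 6)
      expect_identical(cc[1], sigma)
      for (a in 1:5) {
        expect_equal(cc[a + 1], cc[a] * (a - sigma) / (a + 1),
                     tolerance = 1e-14)
      }
      expect_true(all(cc > 0))
      expect_true(all(diff(cc) < 0))
      expect_lte(sum(cc), 1)
    }
  })
  expect_error(gl_coefficients(0, 4), "sigma")
  expect_error(gl_coefficients(1.2, 4), "sigma")
})

test_that("population initialization respects bounds, parity, determinism", {
  p <- slo_init_population(-1, 1, 4, 2, seed = 7)
  expect_identical(dim(p), c(4L, 2L))
  expect_true(all(p >= -1 & p <= 1))
  expect_identical(p, slo_init_population(-1, 1, 4, 2, seed = 7))
  expect_true(all(slo_init_population(0, 0, 4, 3, seed = 1) == 0))
  expect_error(slo_init_population(-1, 1, 5, 2, seed = 1), "even")
  expect_error(slo_init_population(1, -1, 4, 2, seed = 1), "bound")
})

test_that("population evaluation preserves row order and flags bad values", {
  pos <- rbind(c(0, 0), c(1, 1), c(3, 4))
  expect_equal(slo_evaluate(pos, sphere_fn), c(0, 2, 25))
  perm <- pos[c(3, 1, 2), ]
  expect_equal(slo_evaluate(perm, sphere_fn), c(25, 0, 2))
  expect_error(slo_evaluate(rbind(c(1, 1)), function(x) NaN),
               "member 1")
})

test_that("motion and preying displacement formulas match hand evaluation", {
  # z=1, guide=3, r=0.5 so I=2, worse than guide: 1 + 0.5*(3-2*1)*1 = 1.5
  disp <- sloptim:::motion_displacement(1, 3, r = 0.5, I = 2, s = 1)
  expect_equal(1 + disp, 1.5)
  # r = 0 collapses the step; sign 0 (tied costs) collapses it too
  expect_equal(sloptim:::motion_displacement(1, 3, 0, 1, 1), 0)
  expect_equal(sloptim:::motion_displacement(1, 3, 0.7, 2, 0), 0)
  # preying: z=2, f=4, r=1, F=0.375, sign +1 -> 2 + (2*0.375 + 0*0.625) = 2.75
  pd <- sloptim:::preying_displacement(2, 4, r = 1, prey_fraction = 0.375,
                                       s = 1)
  expect_equal(2 + pd, 2.75)
  expect_equal(sloptim:::preying_displacement(2, 4, 0, 0.375, 1), 0)
  # prey at own position with tied costs: no movement
  expect_equal(sloptim:::preying_displacement(2, 2, 0.6, 0.375, 0), 0)
})

test_that("greedy phases never worsen a member and stay in bounds", {
  withr::with_seed(3, {
    pos <- slo_init_population(-5, 5, 8, 3)
    costs <- slo_evaluate(pos, sphere_fn)
    m1 <- slo_motion_step(pos, costs, sphere_fn, -5, 5)
    expect_true(all(m1$costs <= costs))
    expect_true(all(m1$positions >= -5 & m1$positions <= 5))
    m2 <- slo_preying_step(m1$positions, m1$costs, sphere_fn, -5, 5)
    expect_true(all(m2$costs <= m1$costs))
    expect_true(all(m2$positions >= -5 & m2$positions <= 5))
  })
})

test_that("fractional base term sums GL-weighted memory slots", {
  z <- c(2, -1)
  mem <- list(NULL, z, z, z)  # slots 2..4; slot 1 is the live position
  cc <- gl_coefficients(0.5, 4)
  base <- sloptim:::gl_base(z, mem, cc)
  expect_equal(base, 0.7265625 * z, tolerance = 1e-14)
  # sigma = 1: base is exactly the live position
  expect_identical(sloptim:::gl_base(z, mem, gl_coefficients(1, 4)), z)
})

test_that("breeding pairs ends of the population into midpoint cubs", {
  pos <- matrix(c(0, 2, 4, 6), ncol = 1)
  cubs <- slo_breeding_step(pos)
  expect_equal(cubs, matrix(c(3, 3), ncol = 1))
  same <- matrix(1.5, 4, 2)
  expect_true(all(slo_breeding_step(same) == 1.5))
  expect_error(slo_breeding_step(matrix(0, 5, 1)), "even")
})

test_that("fatality keeps the best members with a stable tie-break", {
  parents <- matrix(1:8, ncol = 2)
  cubs <- matrix(101:104, ncol = 2)
  fat <- slo_fatality_step(parents, c(5, 1, 9, 3), cubs, c(7, 2), 4)
  expect_equal(sort(fat$costs), c(1, 2, 3, 5))
  expect_equal(nrow(fat$positions), 4)
  # all-equal costs: stable order keeps the first N of the pool (parents)
  tie <- slo_fatality_step(parents, rep(1, 4), cubs, rep(1, 2), 4)
  expect_identical(tie$kept, 1:4)
  expect_error(slo_fatality_step(parents, rep(1, 4), cubs, rep(1, 2), 7),
               "pool")
})

test_that("the run loop conserves population size and is seed-reproducible", {
  fit <- slo_optimize(sphere_fn, -5, 5, dim = 3, pop_size = 8, max_iter = 30,
                      mode = "fractional", sigma = 0.7, seed = 11)
  expect_s3_class(fit, "slo_fit")
  expect_identical(nrow(fit$trace), 30L)
  expect_true(all(diff(fit$trace$best_cost) <= 0))
  expect_true(all(purrr::map_int(fit$trace$best_position, length) == 3L))
  fit2 <- slo_optimize(sphere_fn, -5, 5, dim = 3, pop_size = 8, max_iter = 30,
                       mode = "fractional", sigma = 0.7, seed = 11)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$best_position, fit2$best_position)
  g <- glance(fit)
  expect_identical(g$evaluations, fit$evaluations)
  expect_lte(g$best_cost, g$initial_best)
})

test_that("classic and fractional sigma = 1 runs share every draw", {
  a <- slo_optimize(sphere_fn, -2, 2, dim = 2, pop_size = 6, max_iter = 15,
                    mode = "classic", seed = 5)
  b <- slo_optimize(sphere_fn, -2, 2, dim = 2, pop_size = 6, max_iter = 15,
                    mode = "fractional", sigma = 1, seed = 5)
  expect_identical(a$trace$best_cost, b$trace$best_cost)
  expect_identical(a$best_position, b$best_position)
})

test_that("tidy and autoplot expose the convergence trace", {
  fit <- slo_optimize(sphere_fn, -1, 1, dim = 2, pop_size = 4, max_iter = 5,
                      seed = 2)
  td <- tidy(fit)
  expect_named(td, c("iteration", "best_cost", "mean_cost", "best_position"))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
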