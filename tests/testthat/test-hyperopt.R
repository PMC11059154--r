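test_that("weight normalization rescales to unit sum", {
  w <- normalize_weights(c(0.5, 0.7, 0.2))
  expect_equal(unname(w), c(0.5, 0.7, 0.2) / 1.4, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(normalize_weights(c(1, 1, 1) / 3)), rep(1 / 3, 3))
  expect_equal(unname(normalize_weights(c(1, 0, 0))), c(1, 0, 0))
  expect_error(normalize_weights(c(0, 0, 0)), "positive")
})

test_that("candidate decode is a grid round-trip with log-uniform rate", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      u <- runif(5)
      cfg <- hp_decode(u)
      expect_true(cfg$blocks %in% 1:3)
      expect_true(cfg$filters %in% 4:32)
      expect_true(cfg$kernel %in% c(3L, 5L))
      expect_true(cfg$dense_units %in% 8:64)
      expect_true(cfg$learning_rate >= 1e-4 && cfg$learning_rate <= 1e-1)
      back <- hp_decode(hp_encode(cfg))
      expect_identical(back[c("blocks", "filters", "kernel", "dense_units")],
                       cfg[c("blocks", "filters", "kernel", "dense_units")])
      expect_equal(back$learning_rate, cfg$learning_rate, tolerance = 1e-12)
    }
  })
  # surjectivity onto grid edges
  expect_identical(hp_decode(rep(0, 5))$filters, 4L)
  expect_identical(hp_decode(rep(1, 5))$filters, 32L)
  expect_error(hp_decode(c(0.5, 0.5, 0.5, 0.5, 1.5)), "\\[0, 1\\]")
})

test_that("parameter counting is analytic and monotone in width", {
  expect_identical(sloptim:::dense_params(10L, 2L), 22L)
  cfg <- list(blocks = 1L, filters = 4L, kernel = 3L, dense_units = 8L,
              learning_rate = 0.01)
  # conv 3x3x1x4+4, flatten 4*8^2, dense 256*8+8, out 8*2+2
  expect_identical(count_parameters(cfg), (9 * 4 + 4) + (256 * 8 + 8) + 18)
  wider <- cfg; wider$dense_units <- 16L
  expect_gt(count_parameters(wider), count_parameters(cfg))
  expect_identical(count_parameters(cfg), count_parameters(cfg))
  # the budget is the largest count in the space
  expect_identical(sloptim:::hp_param_budget(),
                   count_parameters(list(blocks = 3L, filters = 32L,
                                         kernel = 5L, dense_units = 64L,
                                         learning_rate = 0.1)))
})

test_that("composite objective is the weighted mix and is monotone", {
  w <- normalize_weights(c(0.5, 0.7, 0.2))
  res <- list(loss = 0.4, error_rate = 0.1, param_fraction = 0.5)
  expect_equal(composite_objective(res, w), 0.264285714285714,
               tolerance = 1e-12)
  zero <- list(loss = 0, error_rate = 0, param_fraction = 0)
  expect_equal(composite_objective(zero, w), 0)
  one <- list(loss = 1, error_rate = 1, param_fraction = 1)
  expect_equal(composite_objective(one, w), 1, tolerance = 1e-12)
  for (field in c("loss", "error_rate", "param_fraction")) {
    worse <- res; worse[[field]] <- res[[field]] + 0.1
    expect_gt(composite_objective(worse, w), composite_objective(res, w))
  }
})

test_that("training is deterministic and fits separable synthetic data", {
  d <- make_dataset(n_minority = 80, n_majority = 120, seed = 31)
  for (lr in c(1e-4, 1e-2, 1e-1)) {
    u <- hp_encode(list(blocks = 1L, filters = 4L, kernel = 3L,
                        dense_units = 16L, learning_rate = lr))
    r <- train_and_evaluate(u, d, seed = 99)
    expect_lte(r$error_rate, 0.1)
    expect_gte(r$loss, 0)
    expect_true(r$param_fraction > 0 && r$param_fraction <= 1)
  }
  u <- runif(5)
  r1 <- train_and_evaluate(u, d, seed = 7)
  r2 <- train_and_evaluate(u, d, seed = 7)
  expect_identical(r1[c("loss", "error_rate", "param_count")],
                   r2[c("loss", "error_rate", "param_count")])
  expect_error(train_and_evaluate(u, dplyr::filter(d, label == "case"),
                                  seed = 1), "two classes")
})

test_that("a small tuning run improves on the initial population", {
  d <- make_dataset(n_minority = 40, n_majority = 80, seed = 13)
  tuned <- tune_classifier(d, pop_size = 4L, max_iter = 3L, seed = 5,
                           epochs = 100L)
  expect_lte(tuned$best_objective, min(tuned$initial_objectives))
  expect_equal(unname(tuned$weights), c(0.5, 0.7, 0.2) / 1.4)
  expect_equal(tuned$run_log$weights$error, 0.5)
  tuned2 <- tune_classifier(d, pop_size = 4L, max_iter = 3L, seed = 5,
                            epochs = 100L)
  expect_identical(tuned$best_config, tuned2$best_config)
  g <- glance(tuned)
  expect_equal(g$best_objective, tuned$best_objective)
})
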