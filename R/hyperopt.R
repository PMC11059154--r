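# Composite hyperparameter objective over a compact convolutional
# architecture space, scored on tabular demo data by a small seeded MLP.

hp_grid <- list(
  blocks = 1:3,          # conv blocks in the notional architecture
  filters = 4:32,        # filters per block
  kernel = c(3L, 5L),    # square kernel side
  dense_units = 8:64,    # width of the dense head
  log_lr = c(-4, -1)     # log10 learning-rate range
)

#' Decode a unit-cube vector into a classifier configuration
#'
#' Maps `u` in `[0,1]^5` onto the compact candidate grid: conv-block count
#' in \{1,2,3\}, filters per block in \{4..32\}, kernel size in \{3,5\},
#' dense units in \{8..64\}, and a log-uniform learning rate in
#' `[1e-4, 1e-1]`. Decoding is deterministic and surjective onto the grid,
#' and [hp_encode()] maps a configuration back to the centre of its cell so
#' that `hp_decode(hp_encode(cfg))` reproduces `cfg`.
#'
#' @param u Numeric vector of length 5 with entries in [0, 1].
#' @return A list with `blocks`, `filters`, `kernel`, `dense_units`,
#'   `learning_rate`.
#' @export
hp_decode <- function(u) {
  if (length(u) != 5L || any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    abort("`u` must be a numeric vector of length 5 with entries in [0, 1].")
  }
  cell <- function(u1, n) pmin(n - 1L, floor(u1 * n)) + 1L
  list(
    blocks = hp_grid$blocks[cell(u[1], 3L)],
    filters = hp_grid$filters[cell(u[2], 29L)],
    kernel = if (u[3] < 0.5) 3L else 5L,
    dense_units = hp_grid$dense_units[cell(u[4], 57L)],
    learning_rate = 10^(hp_grid$log_lr[1] +
                          diff(hp_grid$log_lr) * u[5])
  )
}

#' Encode a classifier configuration as a unit-cube vector
#'
#' @param cfg A configuration list as returned by [hp_decode()].
#' @return Numeric vector of length 5 in [0, 1].
#' @export
hp_encode <- function(cfg) {
  c(
    (match(cfg$blocks, hp_grid$blocks) - 0.5) / 3,
    (match(cfg$filters, hp_grid$filters) - 0.5) / 29,
    if (cfg$kernel == 3L) 0.25 else 0.75,
    (match(cfg$dense_units, hp_grid$dense_units) - 0.5) / 57,
    (log10(cfg$learning_rate) - hp_grid$log_lr[1]) / diff(hp_grid$log_lr)
  )
}

dense_params <- function(n_in, n_out) n_in * n_out + n_out

#' Analytic parameter count of a decoded architecture
#'
#' Weight and bias counts summed over all layers of the notional compact
#' CNN: `blocks` conv layers (each `kernel x kernel`, `filters` channels,
#' followed by 2x2 pooling) over a 16x16 single-channel input, a flattening
#' step, a dense layer of `dense_units`, and a 2-class output layer.
#'
#' @param cfg A configuration list from [hp_decode()], or a unit-cube vector
#'   which is decoded first.
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg) {
  if (is.numeric(cfg)) cfg <- hp_decode(cfg)
  input_side <- 16L
  total <- 0L
  in_ch <- 1L
  for (b in seq_len(cfg$blocks)) {
    total <- total + cfg$kernel^2 * in_ch * cfg$filters + cfg$filters
    in_ch <- cfg$filters
    input_side <- input_side %/% 2L
  }
  flat <- in_ch * input_side^2
  total <- total + dense_params(flat, cfg$dense_units)
  total + dense_params(cfg$dense_units, 2L)
}

# largest parameter count over the decoded grid, used to normalize the
# parameter term of the composite objective
hp_param_budget <- function() {
  count_parameters(list(blocks = 3L, filters = 32L, kernel = 5L,
                        dense_units = 64L, learning_rate = 0.1))
}

#' Normalize composite-objective weights to sum to one
#'
#' @param weights Numeric vector of three non-negative weights
#'   (loss, error rate, parameter count), at least one positive. The raw
#'   weights 0.5 / 0.7 / 0.2 used in the tuning demo normalize to
#'   `c(0.357..., 0.5, 0.142...)`.
#' @return Named numeric vector `c(loss=, error=, params=)` summing to 1.
#' @export
normalize_weights <- function(weights) {
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0)) {
    abort("`weights` must be three finite non-negative numbers.")
  }
  if (sum(weights) == 0) abort("at least one weight must be positive.")
  setNames(as.numeric(weights) / sum(weights), c("loss", "error", "params"))
}

#' Weighted composite hyperparameter objective
#'
#' `Obj = a1 * loss + a2 * error_rate + a3 * param_fraction`, where the
#' parameter count is normalized by the largest count in the candidate space
#' so all three terms are commensurate, and the weights are normalized to
#' sum to one.
#'
#' @param result An evaluation result from [train_and_evaluate()] (or any
#'   list with `loss`, `error_rate`, `param_fraction`).
#' @param weights Normalized weights from [normalize_weights()].
#' @return Scalar objective value (lower is better).
#' @export
composite_objective <- function(result, weights) {
  weights <- normalize_weights(weights)
  unname(weights["loss"] * result$loss +
           weights["error"] * result$error_rate +
           weights["params"] * result$param_fraction)
}

split_stratified <- function(labels, train_frac, seed) {
  withr::with_seed(as.integer(seed), {
    idx <- unlist(lapply(unique(labels), function(cl) {
      rows <- which(labels == cl)
      sample(rows, max(1L, round(train_frac * length(rows))))
    }))
    sort(idx)
  })
}

#' Train and evaluate the compact stand-in classifier
#'
#' Decodes a candidate, trains a one-hidden-layer network (tanh hidden layer
#' of `dense_units` units, 2-class softmax output) on a stratified 70/30
#' train/test split by full-batch gradient descent with momentum 0.9 at the
#' decoded learning rate for a fixed epoch budget, and reports the training
#' cross-entropy loss, the held-out error rate, and the analytic parameter
#' count of the decoded architecture. All randomness (split, weight
#' initialization) is derived from `seed`, so a fixed candidate and seed
#' give a bit-identical result.
#'
#' @param candidate Unit-cube vector of length 5, or a decoded configuration
#'   list.
#' @param data Data frame with numeric features and a two-class label column.
#' @param label_col Label column name, default `"label"`.
#' @param seed Integer seed, default 1.
#' @param epochs Gradient epochs, default 300.
#' @param train_frac Training fraction of the stratified split, default 0.7.
#' @return An object of class `slo_eval`: list with `loss`, `error_rate`,
#'   `param_count`, `param_fraction`, the decoded `config`, and the held-out
#'   `counts` (confusion tallies).
#' @export
train_and_evaluate <- function(candidate, data, label_col = "label",
                               seed = 1L, epochs = 300L, train_frac = 0.7) {
  cfg <- if (is.numeric(candidate)) hp_decode(candidate) else candidate
  data <- as_tibble(data)
  labels <- data[[label_col]]
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) abort("the dataset must contain two classes.")
  x <- as.matrix(dplyr::select(data, -dplyr::all_of(label_col)))
  y <- as.integer(as.character(labels) == classes[1L]) # class 1 = first level

  train_idx <- split_stratified(labels, train_frac, seed)
  x_tr <- x[train_idx, , drop = FALSE]
  x_te <- x[-train_idx, , drop = FALSE]
  # standardize with training statistics
  mu <- colMeans(x_tr)
  sdev <- pmax(apply(x_tr, 2L, sd), 1e-8)
  x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sdev, "/")
  x_te <- sweep(sweep(x_te, 2L, mu), 2L, sdev, "/")
  y_tr <- y[train_idx]; y_te <- y[-train_idx]

  h <- cfg$dense_units
  p <- ncol(x)
  fit <- withr::with_seed(as.integer(seed), {
    w1 <- matrix(rnorm(p * h, sd = 0.1), p, h); b1 <- numeric(h)
    w2 <- matrix(rnorm(h * 2L, sd = 0.1), h, 2L); b2 <- numeric(2L)
    v <- list(w1 = 0 * w1, b1 = 0 * b1, w2 = 0 * w2, b2 = 0 * b2)
    n_tr <- nrow(x_tr)
    onehot <- cbind(y_tr, 1 - y_tr)
    lr <- cfg$learning_rate; mom <- 0.9
    for (e in seq_len(epochs)) {
      hid <- tanh(sweep(x_tr %*% w1, 2L, b1, "+"))
      logits <- sweep(hid %*% w2, 2L, b2, "+")
      zmax <- apply(logits, 1L, max)
      ex <- exp(logits - zmax)
      prob <- ex / rowSums(ex)
      dlogit <- (prob - onehot) / n_tr
      gw2 <- t(hid) %*% dlogit; gb2 <- colSums(dlogit)
      dhid <- (dlogit %*% t(w2)) * (1 - hid^2)
      gw1 <- t(x_tr) %*% dhid; gb1 <- colSums(dhid)
      v$w1 <- mom * v$w1 - lr * gw1; w1 <- w1 + v$w1
      v$b1 <- mom * v$b1 - lr * gb1; b1 <- b1 + v$b1
      v$w2 <- mom * v$w2 - lr * gw2; w2 <- w2 + v$w2
      v$b2 <- mom * v$b2 - lr * gb2; b2 <- b2 + v$b2
    }
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  })

  predict_prob <- function(xm) {
    hid <- tanh(sweep(xm %*% fit$w1, 2L, fit$b1, "+"))
    logits <- sweep(hid %*% fit$w2, 2L, fit$b2, "+")
    zmax <- apply(logits, 1L, max)
    ex <- exp(logits - zmax)
    ex / rowSums(ex)
  }
  prob_tr <- predict_prob(x_tr)
  eps <- 1e-12
  loss <- -mean(log(pmax(ifelse(y_tr == 1L, prob_tr[, 1L], prob_tr[, 2L]),
                         eps)))
  prob_te <- predict_prob(x_te)
  pred_te <- as.integer(prob_te[, 1L] >= 0.5)
  error_rate <- mean(pred_te != y_te)
  param_count <- count_parameters(cfg)
  counts <- confusion_counts(ifelse(y_te == 1L, classes[1L], classes[2L]),
                             ifelse(pred_te == 1L, classes[1L], classes[2L]),
                             positive = classes[1L])
  structure(
    list(loss = loss, error_rate = error_rate,
         param_count = param_count,
         param_fraction = param_count / hp_param_budget(),
         config = cfg, counts = counts),
    class = "slo_eval"
  )
}

#' @export
print.slo_eval <- function(x, ...) {
  cat(sprintf(
    "<slo_eval> loss %.4f | error rate %.4f | %d params (%.3f of budget)\n",
    x$loss, x$error_rate, x$param_count, x$param_fraction))
  invisible(x)
}

#' Tune the compact classifier with the fractional-order snow leopard
#' optimizer
#'
#' Runs FO-SLOA over the unit cube of encoded candidates with
#' `composite_objective(train_and_evaluate(.), weights)` as the cost. The
#' raw weights default to the loss/error/parameter weighting 0.5 / 0.7 / 0.2
#' and are normalized before use.
#'
#' @inheritParams train_and_evaluate
#' @param weights Raw (unnormalized) objective weights, length 3.
#' @param pop_size,max_iter Optimizer budget, defaults 10 and 15.
#' @param sigma Fractional order, default 0.9.
#' @param mode Optimizer mode, default `"fractional"`.
#' @param seed Seed for the optimizer; candidate evaluation uses its own
#'   fixed internal seed so the objective is deterministic.
#' @param eval_seed Seed used inside every candidate evaluation, default 99.
#' @return An object of class `slo_tune`: list with `best_config`,
#'   `best_result` ([train_and_evaluate()] output for the winner),
#'   `best_objective`, `initial_objectives` (costs of the initial
#'   population), `weights` (normalized), `fit` (the underlying `slo_fit`),
#'   and `run_log` (list echoing the resolved configuration).
#' @export
tune_classifier <- function(data, label_col = "label",
                            weights = c(0.5, 0.7, 0.2),
                            pop_size = 10L, max_iter = 15L, sigma = 0.9,
                            mode = "fractional", seed = 1L,
                            epochs = 300L, eval_seed = 99L) {
  w <- normalize_weights(weights)
  objective <- function(u) {
    res <- train_and_evaluate(u, data, label_col = label_col,
                              seed = eval_seed, epochs = epochs)
    composite_objective(res, w)
  }
  fit <- slo_optimize(objective, lower = 0, upper = 1, dim = 5L,
                      pop_size = pop_size, max_iter = max_iter,
                      mode = mode, sigma = sigma, seed = seed)
  best_cfg <- hp_decode(fit$best_position)
  best_res <- train_and_evaluate(fit$best_position, data,
                                 label_col = label_col,
                                 seed = eval_seed, epochs = epochs)
  structure(
    list(
      best_config = best_cfg,
      best_result = best_res,
      best_objective = fit$best_cost,
      initial_objectives = fit$initial_costs,
      weights = w,
      fit = fit,
      run_log = list(
        tool = "sloptim", version = as.character(packageVersion("sloptim")),
        mode = mode, sigma = sigma, pop_size = pop_size,
        max_iter = max_iter, seed = as.integer(seed),
        eval_seed = as.integer(eval_seed), epochs = as.integer(epochs),
        weights = as.list(w)
      )
    ),
    class = "slo_tune"
  )
}

#' @export
print.slo_tune <- function(x, ...) {
  cat("<slo_tune> best composite objective", signif(x$best_objective, 6), "\n")
  cfg <- x$best_config
  cat(sprintf(
    "  blocks %d | filters %d | kernel %d | dense %d | lr %.2e\n",
    cfg$blocks, cfg$filters, cfg$kernel, cfg$dense_units, cfg$learning_rate))
  cat("  normalized weights:",
      paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
glance.slo_tune <- function(x, ...) {
  tibble(
    best_objective = x$best_objective,
    initial_best = min(x$initial_objectives),
    loss = x$best_result$loss,
    error_rate = x$best_result$error_rate,
    param_count = x$best_result$param_count
  )
}

#' @export
tidy.slo_tune <- function(x, ...) tidy(x$fit)
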