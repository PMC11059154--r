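#' SMOTE: balance a two-class feature table by minority oversampling
#'
#' Generates synthetic minority samples until the class counts are equal.
#' Each synthetic point interpolates a minority sample `z_i` with one of its
#' `k` nearest minority neighbours `z_j` (Euclidean distance):
#' \deqn{Z_{new} = z_i + \gamma (z_j - z_i), \qquad \gamma \sim U(0, 1),}
#' so every synthetic point lies on the closed segment between its two
#' generators. Base samples are cycled through the minority class so the
#' synthetic mass is spread evenly.
#'
#' @param data Data frame with numeric feature columns and one label column.
#' @param label_col Name of the label column, default `"label"`.
#' @param k Number of nearest minority neighbours, default 5 (capped at
#'   minority size minus one).
#' @param seed Integer seed for reproducible draws.
#' @return A tibble: the input rows followed by the synthetic rows (minority
#'   label), with attribute `"synthesis"` — a tibble recording for each
#'   synthetic row the minority row indices `i`, `j` of its generators and
#'   the interpolation weight `gamma`.
#' @examples
#' d <- make_dataset(n_minority = 5, n_majority = 8, seed = 1)
#' table(smote_balance(d, seed = 2)$label)
#' @export
smote_balance <- function(data, label_col = "label", k = 5L, seed = 1L) {
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found.", label_col))
  }
  feats <- dplyr::select(data, -dplyr::all_of(label_col))
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    abort("all feature columns must be numeric.")
  }
  labels <- data[[label_col]]
  counts <- table(labels)
  if (length(counts) != 2L) abort("exactly two classes are required.")
  minority <- names(counts)[which.min(counts)]
  n_needed <- max(counts) - min(counts)
  if (n_needed == 0L) return(data)
  min_idx <- which(labels == minority)
  if (length(min_idx) < 2L) {
    abort("the minority class needs at least 2 samples to interpolate.")
  }
  k <- min(as.integer(k), length(min_idx) - 1L)
  if (k < 1L) abort("`k` must be >= 1.")

  x_min <- as.matrix(feats[min_idx, , drop = FALSE])
  d2 <- as.matrix(stats::dist(x_min))
  # k nearest minority neighbours of each minority sample (self excluded)
  nn <- lapply(seq_len(nrow(x_min)), function(i) {
    order(d2[i, ])[-1L][seq_len(k)]
  })

  synth <- withr::with_seed(as.integer(seed), {
    base_i <- rep_len(sample(seq_len(nrow(x_min))), n_needed)
    purrr::map(seq_len(n_needed), function(s) {
      i <- base_i[s]
      j <- nn[[i]][sample.int(k, 1L)]
      gamma <- runif(1L)
      list(row = x_min[i, ] + gamma * (x_min[j, ] - x_min[i, ]),
           i = i, j = j, gamma = gamma)
    })
  })
  new_rows <- as_tibble(do.call(rbind, purrr::map(synth, "row")))
  names(new_rows) <- names(feats)
  new_rows[[label_col]] <- if (is.factor(labels)) {
    factor(minority, levels = levels(labels))
  } else if (is.numeric(labels)) {
    as.numeric(minority)
  } else {
    minority
  }
  out <- dplyr::bind_rows(data, new_rows[names(data)])
  attr(out, "synthesis") <- tibble(
    i = purrr::map_int(synth, "i"),
    j = purrr::map_int(synth, "j"),
    gamma = purrr::map_dbl(synth, "gamma")
  )
  out
}
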