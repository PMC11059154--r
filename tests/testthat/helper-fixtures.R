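# Shared fixtures, built in code at test time.

sphere_fn <- function(x) sum(x^2)

# Brute-force per-pixel re-implementation of bi-histogram equalization:
# counts pixels directly instead of using cumulative tables, so it is an
# independent oracle for bbhe_enhance().
bbhe_oracle <- function(img) {
  xm <- floor(mean(img))
  low <- img[img <= xm]
  up <- img[img > xm]
  out <- img
  for (idx in seq_along(img)) {
    v <- img[idx]
    if (v <= xm) {
      dl <- sum(low <= v) / length(low)
      out[idx] <- floor(0 + (xm - 0) * dl + 0.5)
    } else {
      du <- sum(up <= v) / length(up)
      out[idx] <- floor((xm + 1) + (255 - xm - 1) * du + 0.5)
    }
  }
  out
}

# Independent tally-based metric computation from raw label vectors.
metrics_oracle <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  div0 <- function(n, d) if (d == 0) 0 else n / d
  prc <- div0(tp, tp + fp)
  sns <- div0(tp, tp + fn)
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = div0(tp + tn, tp + tn + fp + fn),
    prc = prc, sns = sns,
    spc = div0(tn, tn + fp),
    f1 = div0(2 * prc * sns, prc + sns),
    mcc = 100 * div0(tp * tn - fp * fn,
                     sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  )
}

random_gray <- function(nr, nc, seed) {
  withr::with_seed(seed, matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc))
}
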