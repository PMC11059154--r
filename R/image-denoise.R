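# Fuzzy-entropy adaptive median denoising for 8-bit grayscale images.
# Images are plain numeric matrices with values in [0, 255].

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L) {
    abort("`img` must be a non-empty numeric matrix.")
  }
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255)) {
    abort("`img` values must be finite and within [0, 255].")
  }
  img
}

round_half_up <- function(x) floor(x + 0.5)

# Sliding-window statistic with replicate padding. stat_fun is applied to the
# w*w neighborhood of each pixel.
local_window_stat <- function(img, window, stat_fun) {
  rr <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ridx <- pmin(pmax(seq_len(nr + 2L * rr) - rr, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2L * rr) - rr, 1L), nc)
  padded <- img[ridx, cidx, drop = FALSE]
  stack <- matrix(0, nrow = nr * nc, ncol = window * window)
  s <- 0L
  for (dc in 0:(window - 1L)) {
    for (dr in 0:(window - 1L)) {
      s <- s + 1L
      stack[, s] <- as.vector(padded[dr + seq_len(nr), dc + seq_len(nc)])
    }
  }
  matrix(apply(stack, 1L, stat_fun), nrow = nr, ncol = nc)
}

check_window <- function(window) {
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  window
}

#' Fuzzy noisy/noise-free memberships and per-pixel fuzzy entropy
#'
#' Assigns each pixel a degree of membership to the "noisy" class from its
#' robust deviation: with `med` the local window median and `s` the global
#' robust spread of the deviations (median absolute deviation from the local
#' median, floored at 1 grey level), the scaled deviation `d = |x - med| / s`
#' gives \eqn{\mu_N = d^2 / (d^2 + 1)} and \eqn{\mu_F = 1 - \mu_N}. The
#' per-pixel fuzzy entropy is the Shannon entropy of the membership pair,
#' \eqn{E = -\mu_F \log \mu_F - \mu_N \log \mu_N} (natural log, with
#' `0 log 0 = 0`); it vanishes exactly where membership is crisp and peaks at
#' `log(2)` where the pixel is maximally ambiguous.
#'
#' @param img Numeric matrix with values in [0, 255].
#' @param window Odd window size >= 3, default 3.
#' @return An object of class `fuzzy_field`: list of matrices `mu_noise`,
#'   `mu_clean`, `entropy`, `local_median`, plus the `spread` scalar used.
#' @export
fuzzy_memberships <- function(img, window = 3L) {
  check_gray(img)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  window <- check_window(window)
  med <- local_window_stat(img, window, median)
  dev <- abs(img - med)
  spread <- max(1, median(dev))
  d <- dev / spread
  mu_noise <- d^2 / (d^2 + 1)
  mu_clean <- 1 - mu_noise
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  entropy <- -(plogp(mu_clean) + plogp(mu_noise))
  structure(
    list(mu_noise = mu_noise, mu_clean = mu_clean, entropy = entropy,
         local_median = med, spread = spread),
    class = "fuzzy_field"
  )
}

#' @export
print.fuzzy_field <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_field> %d x %d | mean noisy membership %.3f | mean entropy %.3f\n",
    nrow(x$mu_noise), ncol(x$mu_noise), mean(x$mu_noise), mean(x$entropy)))
  invisible(x)
}

#' Fuzzy-entropy weighted adaptive median denoising
#'
#' Blends each pixel with its local window median in proportion to its noisy
#' membership: `y = (1 - w) x + w median(x)` with `w` the per-pixel
#' \eqn{\mu_N} from [fuzzy_memberships()], rounded half-up to integers.
#' Crisp noise pixels (membership near 1) are replaced by the median, clean
#' pixels (membership 0, e.g. on constant regions) pass through unchanged,
#' and every output value stays within the local window range.
#'
#' @inheritParams fuzzy_memberships
#' @return Denoised image matrix, same dimensions, integer values in
#'   [0, 255].
#' @export
wm_denoise <- function(img, window = 3L) {
  field <- fuzzy_memberships(img, window)
  w <- field$mu_noise
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  out <- round_half_up((1 - w) * img + w * field$local_median)
  pmin(pmax(out, 0), 255)
}
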