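#' Brightness-preserving bi-histogram equalization (BBHE)
#'
#' Splits the intensity histogram at the image mean and equalizes the two
#' sub-histograms independently over their own dynamic ranges. With split
#' level `Xm = floor(mean(img))`, full-range endpoints `X0 = 0` and
#' `XL1 = 255`, and `DL`, `DU` the cumulative relative frequencies of the
#' sub-images at or below / above the split:
#' \deqn{f_l(X) = X_0 + (X_m - X_0) D_L(X)}
#' \deqn{f_u(X) = X_{m+1} + (X_{L-1} - X_{m+1}) D_U(X)}
#' Pixels at or below the split are mapped by `f_l` into `[0, Xm]`, pixels
#' above by `f_u` into `[Xm + 1, 255]`, and the two mapped sub-images are
#' recombined; outputs are rounded half-up. Keeping the equalized
#' sub-histograms on opposite sides of the mean is what preserves the
#' overall image brightness relative to plain histogram equalization.
#'
#' @param img Numeric matrix, integer values in [0, 255].
#' @return Enhanced image matrix of the same dimensions, integer values in
#'   [0, 255]; the split-level attribute `"split"` records `Xm`.
#' @examples
#' img <- matrix(c(50, 50, 200, 200), 2, 2)
#' bbhe_enhance(img)  # levels 125 and 255
#' @export
bbhe_enhance <- function(img) {
  check_gray(img)
  if (any(img != floor(img))) {
    abort("`img` must hold integer grey levels for histogram equalization.")
  }
  xm <- floor(mean(img))
  lower_mask <- img <= xm
  out <- img
  # lower sub-histogram: levels 0..xm, mapped onto [0, xm]
  if (any(lower_mask)) {
    counts <- tabulate(img[lower_mask] + 1L, nbins = xm + 1L)
    dl <- cumsum(counts) / sum(counts)
    out[lower_mask] <- round_half_up(0 + (xm - 0) * dl[img[lower_mask] + 1L])
  }
  # upper sub-histogram: levels xm+1..255, mapped onto [xm+1, 255]
  if (any(!lower_mask)) {
    counts <- tabulate(img[!lower_mask] - xm, nbins = 255L - xm)
    du <- cumsum(counts) / sum(counts)
    out[!lower_mask] <- round_half_up(
      (xm + 1) + (255 - xm - 1) * du[img[!lower_mask] - xm]
    )
  }
  attr(out, "split") <- xm
  out
}
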