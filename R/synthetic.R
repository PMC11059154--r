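# Deterministic generators for structured grayscale phantoms and imbalanced
# labelled datasets. These stand in for real knee-MRI scans in tests and
# demos; the geometry is schematic, not anatomical.

#' Generate a knee-MRI-like grayscale phantom
#'
#' Renders a schematic sagittal-slice phantom: a uniform background, a bright
#' ellipse (the joint region), and a diagonal band across it (the ligament).
#' With `tear = TRUE` a gap of width `tear_width` pixels is cut out of the
#' band around the image centre, so a torn and an intact phantom differ only
#' inside that gap. Optional pixel noise is applied after the structure is
#' rendered and the result is clipped to [0, 255] and rounded.
#'
#' @param size Image side length in pixels, default 64.
#' @param background Background grey level, default 40.
#' @param ellipse_level Ellipse grey level, default 120.
#' @param band_level Band grey level, default 220.
#' @param band_width Band half-width in pixels, default 2.
#' @param tear Logical; cut a gap into the band, default `FALSE`.
#' @param tear_width Gap width in pixels, default 6.
#' @param noise One of `"none"`, `"gaussian"`, `"salt_pepper"`.
#' @param noise_sd Gaussian noise standard deviation (grey levels),
#'   default 20.
#' @param noise_rate Salt-and-pepper corruption rate in [0, 1], default 0.05.
#' @param seed Integer seed; the image is a pure function of the arguments.
#' @return A `size` x `size` integer-valued matrix in [0, 255], with
#'   attribute `"tear_mask"` (logical matrix of the gap region).
#' @export
make_phantom <- function(size = 64L, background = 40, ellipse_level = 120,
                         band_level = 220, band_width = 2L,
                         tear = FALSE, tear_width = 6L,
                         noise = c("none", "gaussian", "salt_pepper"),
                         noise_sd = 20, noise_rate = 0.05, seed = 1L) {
  noise <- match.arg(noise)
  size <- as.integer(size)
  if (is.na(size) || size < 8L) abort("`size` must be an integer >= 8.")
  for (lv in c(background, ellipse_level, band_level)) {
    if (lv < 0 || lv > 255) abort("grey levels must lie in [0, 255].")
  }
  cx <- (size + 1) / 2
  rowm <- matrix(seq_len(size), size, size)
  colm <- matrix(seq_len(size), size, size, byrow = TRUE)
  img <- matrix(background, size, size)
  in_ellipse <- ((rowm - cx) / (0.38 * size))^2 +
    ((colm - cx) / (0.28 * size))^2 <= 1
  img[in_ellipse] <- ellipse_level
  in_band <- abs((rowm - cx) - (colm - cx)) <= band_width & in_ellipse
  img[in_band] <- band_level
  tear_mask <- in_band & abs(colm - cx) <= tear_width / 2
  if (isTRUE(tear)) img[tear_mask] <- ellipse_level

  if (noise != "none") {
    img <- withr::with_seed(as.integer(seed), {
      if (noise == "gaussian") {
        img + matrix(rnorm(size * size, sd = noise_sd), size, size)
      } else {
        hit <- matrix(runif(size * size) < noise_rate, size, size)
        salt <- matrix(runif(size * size) < 0.5, size, size)
        img[hit & salt] <- 255
        img[hit & !salt] <- 0
        img
      }
    })
  }
  img <- round_half_up(pmin(pmax(img, 0), 255))
  attr(img, "tear_mask") <- tear_mask
  img
}

#' Generate an imbalanced two-class dataset
#'
#' Tabular mode draws class-conditional Gaussian feature vectors (unit
#' within-class standard deviation) whose class means are `separation`
#' standard deviations apart in Euclidean distance; image mode renders one
#' noisy phantom per sample, torn for the minority ("case") class. The
#' minority/majority imbalance mirrors the situation class-balancing
#' operators such as [smote_balance()] are designed for.
#'
#' @param n_minority,n_majority Per-class sample counts (minority is the
#'   "case" class). Tabular generation requires both >= 1.
#' @param mode `"tabular"` (default) or `"image"`.
#' @param n_features Feature dimension in tabular mode, default 4.
#' @param separation Euclidean distance between class means in within-class
#'   standard deviations, default 6.
#' @param seed Integer seed.
#' @param ... In image mode, extra arguments passed to [make_phantom()].
#' @return Tabular mode: tibble with numeric columns `f1..fp` and a `label`
#'   column (`"case"` / `"control"`). Image mode: tibble with a `label`
#'   column and an `image` list-column of phantom matrices.
#' @export
make_dataset <- function(n_minority = 50L, n_majority = 200L,
                         mode = c("tabular", "image"),
                         n_features = 4L, separation = 6, seed = 1L, ...) {
  mode <- match.arg(mode)
  n_minority <- as.integer(n_minority)
  n_majority <- as.integer(n_majority)
  if (is.na(n_minority) || is.na(n_majority) ||
      n_minority < 1L || n_majority < 1L) {
    abort("both class counts must be >= 1.")
  }
  if (mode == "tabular") {
    p <- as.integer(n_features)
    if (is.na(p) || p < 1L) abort("`n_features` must be >= 1.")
    shift <- separation / sqrt(p)  # per-coordinate offset giving the
    withr::with_seed(as.integer(seed), {  # requested Euclidean separation
      x_min <- matrix(rnorm(n_minority * p, mean = shift), n_minority, p)
      x_maj <- matrix(rnorm(n_majority * p, mean = 0), n_majority, p)
      out <- as_tibble(rbind(x_min, x_maj), .name_repair = "minimal")
      names(out) <- paste0("f", seq_len(p))
      out$label <- c(rep("case", n_minority), rep("control", n_majority))
      out
    })
  } else {
    args <- list(...)
    if (!"noise" %in% names(args)) args$noise <- "gaussian"
    withr::with_seed(as.integer(seed), {
      seeds <- sample.int(2^30, n_minority + n_majority)
      tear <- c(rep(TRUE, n_minority), rep(FALSE, n_majority))
      tibble(
        label = ifelse(tear, "case", "control"),
        image = purrr::map2(tear, seeds, function(tr, sd_) {
          do.call(make_phantom, c(list(tear = tr, seed = sd_), args))
        })
      )
    })
  }
}
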