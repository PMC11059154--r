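# PNG and trace CSV input/output.

#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' Colour images are converted to luminance (Rec. 601 weights); any alpha
#' channel is ignored.
#'
#' @param path PNG file path.
#' @return Numeric matrix with integer values in [0, 255].
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  round_half_up(arr * 255)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param img Numeric matrix with values in [0, 255].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(img, path) {
  check_gray(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a convergence trace as CSV
#'
#' Columns `iteration`, `best_cost`, `mean_cost`, `best_position` (the
#' position vector semicolon-joined into one cell); reals are serialized
#' with 17 significant digits so that [read_trace()] round-trips losslessly.
#'
#' @param trace A trace tibble (e.g. `tidy(fit)`) with those columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  need <- c("iteration", "best_cost", "mean_cost", "best_position")
  if (!all(need %in% names(trace))) {
    abort(sprintf("trace must have columns: %s", paste(need, collapse = ", ")))
  }
  fmt <- function(x) sprintf("%.17g", x)
  out <- tibble(
    iteration = as.integer(trace$iteration),
    best_cost = fmt(trace$best_cost),
    mean_cost = fmt(trace$mean_cost),
    best_position = vapply(trace$best_position,
                           function(v) paste(fmt(v), collapse = ";"),
                           character(1))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a convergence trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A trace tibble with `iteration`, `best_cost`, `mean_cost`, and a
#'   `best_position` list-column. Malformed numeric cells raise an error
#'   naming the offending line (header is line 1).
#' @export
read_trace <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("iteration", "best_cost", "mean_cost", "best_position")
  if (!all(need %in% names(raw))) {
    abort(sprintf("malformed trace CSV: expected columns %s",
                  paste(need, collapse = ", ")))
  }
  parse_num <- function(x, row, what) {
    v <- suppressWarnings(as.numeric(x))
    if (length(x) && any(is.na(v) & !is.na(x))) {
      bad <- which(is.na(v) & !is.na(x))[1L]
      abort(sprintf("parse error at line %d: non-numeric %s cell '%s'",
                    row[bad] + 1L, what, x[bad]))
    }
    v
  }
  rows <- seq_len(nrow(raw))
  tibble(
    iteration = as.integer(parse_num(raw$iteration, rows, "iteration")),
    best_cost = parse_num(raw$best_cost, rows, "best_cost"),
    mean_cost = parse_num(raw$mean_cost, rows, "mean_cost"),
    best_position = purrr::map2(raw$best_position, rows, function(cell, rw) {
      parts <- strsplit(cell, ";", fixed = TRUE)[[1L]]
      parse_num(parts, rep(rw, length(parts)), "best_position")
    })
  )
}
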