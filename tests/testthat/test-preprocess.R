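test_that("memberships are complementary, entropy behaves, salt is flagged", {
  flat <- matrix(100, 8, 8)
  f <- fuzzy_memberships(flat)
  expect_true(all(f$mu_noise == 0))
  expect_true(all(f$mu_clean == 1))
  expect_true(all(f$entropy == 0))

  img <- make_phantom(size = 32, noise = "gaussian", noise_sd = 15, seed = 4)
  g <- fuzzy_memberships(img)
  expect_true(all(g$mu_noise >= 0 & g$mu_noise < 1))
  expect_equal(g$mu_noise + g$mu_clean, matrix(1, 32, 32))
  expect_true(all(g$entropy >= 0 & g$entropy <= log(2) + 1e-12))
  # entropy hits log(2) exactly where membership is half/half
  half <- which(abs(g$mu_noise - 0.5) < 1e-9)
  if (length(half)) expect_equal(g$entropy[half], rep(log(2), length(half)))
  # crisp membership <=> zero entropy
  expect_identical(g$entropy == 0, g$mu_noise == 0 | g$mu_noise == 1)

  salt <- matrix(0, 9, 9); salt[5, 5] <- 255
  fs <- fuzzy_memberships(salt, window = 3)
  expect_gt(fs$mu_noise[5, 5], 0.9)
  expect_error(fuzzy_memberships(salt, window = 4), "odd")
})

test_that("denoising is identity on constants and bounded by the window", {
  flat <- matrix(200, 6, 6)
  expect_identical(wm_denoise(flat), flat)
  img <- make_phantom(size = 32, noise = "salt_pepper", noise_rate = 0.1,
                      seed = 9)
  den <- wm_denoise(img, window = 3)
  expect_true(all(den >= 0 & den <= 255))
  lo <- sloptim:::local_window_stat(img, 3L, min)
  hi <- sloptim:::local_window_stat(img, 3L, max)
  expect_true(all(den >= lo & den <= hi))
})

test_that("denoising lowers the MSE against the clean phantom", {
  clean <- make_phantom(size = 64, noise = "none")
  wins <- 0L
  for (s in 1:10) {
    noisy <- make_phantom(size = 64, noise = "gaussian", noise_sd = 20,
                          seed = s)
    den <- wm_denoise(noisy)
    wins <- wins + (mean((den - clean)^2) < mean((noisy - clean)^2))
  }
  expect_gte(wins, 9L)
})

test_that("bbhe matches the brute-force sub-histogram oracle", {
  for (s in 1:20) {
    img <- random_gray(8, 8, seed = s)
    expect_identical(unclass(bbhe_enhance(img))[seq_along(img)],
                     bbhe_oracle(img)[seq_along(img)])
  }
})

test_that("bbhe splits the range at the mean and keeps monotone maps", {
  img <- make_phantom(size = 32, noise = "gaussian", noise_sd = 30, seed = 2)
  out <- bbhe_enhance(img)
  xm <- attr(out, "split")
  expect_identical(xm, floor(mean(img)))
  low_in <- img <= xm
  expect_true(all(out[low_in] >= 0 & out[low_in] <= xm))
  expect_true(all(out[!low_in] >= xm + 1 & out[!low_in] <= 255))
  # monotone: sort input pixels, mapped values must be non-decreasing within
  # each sub-image
  for (mask in list(low_in, !low_in)) {
    ord <- order(img[mask])
    expect_true(all(diff(out[mask][ord]) >= 0))
  }
})

test_that("bbhe worked examples: constant and two-level images", {
  expect_true(all(bbhe_enhance(matrix(88, 4, 4)) == 88))
  two <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  expect_identical(sort(unique(as.vector(bbhe_enhance(two)))), c(125, 255))
})

test_that("smote balances classes with on-segment synthetic points", {
  d <- make_dataset(n_minority = 12, n_majority = 40, seed = 6)
  bal <- smote_balance(d, k = 5, seed = 8)
  expect_identical(unname(table(bal$label)["case"]),
                   unname(table(bal$label)["control"]))
  syn <- attr(bal, "synthesis")
  x_min <- as.matrix(d[d$label == "case", c("f1", "f2", "f3", "f4")])
  new_rows <- as.matrix(bal[(nrow(d) + 1):nrow(bal),
                            c("f1", "f2", "f3", "f4")])
  for (s in seq_len(nrow(syn))) {
    a <- x_min[syn$i[s], ]; b <- x_min[syn$j[s], ]
    z <- new_rows[s, ]
    expect_equal(z, a + syn$gamma[s] * (b - a), tolerance = 1e-12)
    expect_true(all(z >= pmin(a, b) - 1e-9 & z <= pmax(a, b) + 1e-9))
  }
  # same seed reproduces the same synthetic rows
  bal2 <- smote_balance(d, k = 5, seed = 8)
  expect_identical(bal, bal2)
})

test_that("smote endpoint algebra and degenerate inputs", {
  # gamma = 0 and 1 reproduce the endpoints; midpoint halves the segment
  a <- c(0, 0); b <- c(2, 4)
  expect_equal(a + 0 * (b - a), a)
  expect_equal(a + 1 * (b - a), b)
  expect_equal(a + 0.5 * (b - a), c(1, 2))
  single <- tibble::tibble(f1 = c(0, 1, 2), label = c("case", "control",
                                                      "control"))
  expect_error(smote_balance(single, seed = 1), "at least 2")
})
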