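test_that("default dataset composition reproduces the study counts", {
  comp <- dataset_composition()
  expect_identical(comp$train_total, 194000L)
  expect_identical(comp$test_total, 42500L)
  expect_identical(comp$train_counts, c(rep(9375L, 16), 44000L))
  expect_identical(comp$test_counts, rep(2500L, 17))
  small <- dataset_composition(2, 0, 2)
  expect_identical(small$train_total, 32L)
  expect_error(dataset_composition(-1), "non-negative")
})

test_that("learning/validation split follows the 75:25 rule", {
  sp <- split_train_val(194000, 0.75, seed = 1)
  expect_identical(length(sp$learn), 145500L)
  expect_identical(length(sp$val), 48500L)
  sp4 <- split_train_val(4, 0.75, seed = 1)
  expect_identical(length(sp4$learn), 3L)
  expect_identical(length(sp4$val), 1L)
  sp37 <- split_train_val(37, 0.6, seed = 9)
  expect_identical(sort(c(sp37$learn, sp37$val)), 1:37)      # partition
  expect_identical(intersect(sp37$learn, sp37$val), integer(0))
  # per-epoch resplit draws a different partition; same seed reproduces
  expect_identical(split_train_val(100, seed = 5), split_train_val(100, seed = 5))
  expect_false(identical(split_train_val(100, seed = 5)$learn,
                         split_train_val(100, seed = 6)$learn))
  expect_error(split_train_val(10, ratio = 1.2), "ratio")
})

test_that("noise injection hits the requested SNR and is reproducible", {
  set.seed(2)
  y <- runif(992, 0.01, 1)
  expect_identical(add_noise(y, Inf), y)
  expect_identical(add_noise(y, 30, seed = 7), add_noise(y, 30, seed = 7))
  # Monte-Carlo SNR estimate over many draws
  p_sig <- mean(y^2)
  noise_p <- replicate(400, mean((add_noise(y, 30) - y)^2))
  snr_hat <- 10 * log10(p_sig / mean(noise_p))
  expect_gt(snr_hat, 29); expect_lt(snr_hat, 31)
  # matrix form: per-row SNR
  Y <- matrix(runif(20 * 500, 0.1, 1), 20)
  Yn <- add_noise(Y, 20, seed = 1)
  snr_rows <- 10 * log10(rowMeans(Y^2) / rowMeans((Yn - Y)^2))
  expect_true(all(abs(snr_rows - 20) < 2))
})

test_that("matrix view is a bijective reshape with zero diagonal", {
  y <- rnorm(992)
  m <- to_matrix_view(y)
  expect_identical(dim(m), c(32L, 32L))
  expect_true(all(diag(m) == 0))
  expect_identical(from_matrix_view(m), y)
  pr <- measurement_pairs(32)
  k <- 457
  expect_identical(m[pr$excite[k], pr$sense[k]], y[k])
  ones <- to_matrix_view(rep(1, 12), K = 4)
  expect_identical(ones, matrix(1, 4, 4) - diag(4))
  expect_error(to_matrix_view(rnorm(10)), "length")
})

test_that("small datasets are reproducible and class-balanced", {
  cal <- toy_calib()
  counts <- c(rep(1L, 4), rep(0L, 12), 2L)
  d1 <- generate_dataset(counts, cal, seed = 77, snr_db = 40)
  d2 <- generate_dataset(counts, cal, seed = 77, snr_db = 40)
  expect_identical(d1, d2)
  expect_identical(d1$labels, rep(1:17, times = counts))
  expect_identical(dim(d1$y), c(6L, 56L))
  expect_identical(dim(d1$g), c(6L, toy_fov()$n_fov))
  expect_true(all(d1$g >= 0))
  # noiseless copy kept alongside the noisy features
  expect_false(identical(d1$y, d1$y_clean))
  d3 <- generate_dataset(counts, cal, seed = 78, snr_db = 40)
  expect_false(identical(d1$y, d3$y))
  # save/load round trip
  p <- tempfile(fileext = ".rds")
  write_dataset(d1, p)
  expect_identical(read_dataset(p), d1)
  unlink(p)
})
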