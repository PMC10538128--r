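test_that("electrode spans tile the circle with the requested coverage", {
  for (K in c(2L, 8L, 32L)) for (cov in c(0.3, 0.8)) {
    s <- cceit_sensor(K = K, coverage = cov)
    w <- s$electrode_angular_spans[, "hi"] - s$electrode_angular_spans[, "lo"]
    expect_equal(sum(w), cov * 2 * pi)
    expect_equal(length(w), K)
    # spans are disjoint: gaps between consecutive electrodes are positive
    lo <- s$electrode_angular_spans[, "lo"]; hi <- s$electrode_angular_spans[, "hi"]
    if (K > 1) expect_true(all(lo[-1] > hi[-K]))
  }
  s2 <- cceit_sensor(K = 2, coverage = 0.5)
  w2 <- s2$electrode_angular_spans[, 2] - s2$electrode_angular_spans[, 1]
  expect_equal(sum(w2), pi)
  # electrode 1 centred at the top of the image
  expect_equal(mean(cceit_sensor()$electrode_angular_spans[1, ]), pi / 2)
})

test_that("invalid sensor configurations are rejected", {
  expect_error(cceit_sensor(K = 1), "K = 2")
  expect_error(cceit_sensor(coverage = 1), "coverage")
  expect_error(cceit_sensor(coverage = 0), "coverage")
  expect_error(cceit_sensor(screen_radius = 1.0), "screen_radius")
  expect_error(cceit_grid(fine_n = 100, recon_n = 64), "multiple")
})

test_that("FOV mask count is monotone in the radius and hits the landmarks", {
  g <- grid64()
  expect_equal(build_fov_mask(g, fov_radius = 0)$n_fov, 0L)
  # radius beyond the half-diagonal covers every pixel
  expect_equal(build_fov_mask(g, sqrt(2) * g$half_extent + 1)$n_fov, 4096L)
  radii <- seq(0, 1.4, length.out = 50)
  counts <- vapply(radii, function(r) build_fov_mask(g, r)$n_fov, 0L)
  expect_true(all(diff(counts) >= 0))
  # brute-force recount for a handful of radii
  cc <- cceit:::grid_centres(g, "recon")
  ctr <- cceit:::fov_centre(g)
  for (r in radii[c(7, 19, 33, 46)]) {
    n_bf <- 0L
    for (i in 1:64) for (j in 1:64) {
      d2 <- (cc$X[i, j] - ctr[1])^2 + (cc$Y[i, j] - ctr[2])^2
      if (d2 < r^2) n_bf <- n_bf + 1L
    }
    expect_identical(build_fov_mask(g, r)$n_fov, n_bf)
  }
})

test_that("FOV index map is a bijection and embed/extract round-trip", {
  fov <- fov64()
  expect_identical(fov$n_fov, sum(fov$mask))
  expect_identical(sort(fov$index[fov$mask]), seq_len(fov$n_fov))
  expect_identical(fov$index[fov$pix], seq_len(fov$n_fov))
  v <- rnorm(fov$n_fov)
  expect_identical(fov_extract(fov_embed(v, fov), fov), v)
})

test_that("electrodes sit outside the field of view", {
  s <- default_sensor(); fov <- fov64()
  expect_gt(s$electrode_r[1], fov$radius)
})

test_that("measurement_count matches exhaustive pair enumeration", {
  for (K in 2:40) {
    pairs <- expand.grid(i = seq_len(K), j = seq_len(K))
    pairs <- pairs[pairs$i != pairs$j, ]
    expect_identical(measurement_count(K, TRUE), nrow(pairs))
    expect_identical(measurement_count(K, FALSE), nrow(pairs) %/% 2L)
    expect_identical(nrow(measurement_pairs(K)), nrow(pairs))
  }
  expect_identical(measurement_count(2, TRUE), 2L)
  expect_identical(measurement_count(4, FALSE), 6L)
  expect_error(measurement_count(1), "K must be")
  # no self-pairs, both orders present
  pr <- measurement_pairs(5)
  expect_true(all(pr$excite != pr$sense))
  expect_true(all(paste(pr$sense, pr$excite) %in% paste(pr$excite, pr$sense)))
})
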