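test_that("uniform lossless fields obey the discrete maximum principle", {
  um <- uniform_map(grid64(), "air")
  fld <- solve_fields(um, default_sensor(), excite = 1)
  expect_gte(min(Re(fld$phi)), 0)
  expect_lte(max(Re(fld$phi)), 1)
  expect_lt(fld$residual_norm, 1e-10)
})

test_that("a quarter-turn rotation maps electrode fields onto each other", {
  # K = 32 electrodes: electrode 9 is electrode 1 rotated by exactly 90
  # degrees, a symmetry of the square lattice, so the fields agree to
  # solver precision without interpolation.
  um <- uniform_map(grid64(), "air")
  fld <- solve_fields(um, default_sensor(), excite = c(1, 9))
  n <- grid64()$fine_n
  phi1 <- matrix(Re(fld$phi[, 1]), n, n)
  phi9 <- matrix(Re(fld$phi[, 2]), n, n)
  # rotate phi1 by 90 degrees counter-clockwise (image convention)
  rot90 <- t(phi1[, n:1])
  expect_lt(max(abs(rot90 - phi9)), 1e-9)
})

test_that("capacitance frames are reciprocal for lossy phantoms", {
  cal <- calib64()
  for (seed in 1:3) {
    spec <- sample_phantom(sample(1:17, 1), seed = seed)
    map <- rasterize(spec, grid64(), default_sensor(), fov64())
    fr <- capacitance_frame(map, default_sensor())
    m <- to_matrix_view(fr$c)
    rel <- Mod(m - t(m)) / pmax(Mod(m), 1e-300)
    expect_lt(max(rel[upper.tri(rel)]), 1e-6)
    expect_lt(fr$residual_norm, 1e-10)
  }
})

test_that("total boundary charge vanishes (charge conservation)", {
  sensor <- default_sensor()
  ctx <- forward_context(grid64(), sensor)
  spec <- sample_phantom(7, seed = 3)
  map <- rasterize(spec, grid64(), sensor, fov64())
  fld <- solve_fields(map, sensor, excite = 1, ctx = ctx)
  q <- complex(real = 0)
  mags <- numeric(0)
  for (j in seq_len(sensor$K)) {
    vj <- if (j == 1) 1 else 0
    qj <- cceit:::electrode_flux(fld$phi[, 1], fld$T, ctx, j, vj = vj)
    q <- q + qj; mags <- c(mags, Mod(qj))
  }
  q <- q + cceit:::electrode_flux(fld$phi[, 1], fld$T, ctx, -1L, vj = 0)
  expect_lt(Mod(q) / max(mags), 1e-8)
})

test_that("coaxial capacitance converges to the analytic value", {
  errs <- vapply(c(64L, 128L, 256L), function(n) {
    cx <- coaxial_capacitance(fine_n = n)
    abs(cx$C - cx$C_analytic_effective) / cx$C_analytic_effective
  }, 0)
  expect_true(all(diff(errs) < 0))            # monotone grid convergence
  cx <- coaxial_capacitance(fine_n = 256)
  expect_lt(abs(cx$C - cx$C_analytic_nominal) / cx$C_analytic_nominal, 0.01)
})

test_that("capacitance is homogeneous of degree one in the dielectric", {
  c1 <- coaxial_capacitance(fine_n = 64, eps_r = 1)$C
  c2 <- coaxial_capacitance(fine_n = 64, eps_r = 2)$C
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("frame normalisation honours the calibration endpoints", {
  low <- complex(real = rnorm(10), imaginary = rnorm(10))
  high <- low + complex(real = rnorm(10, 2), imaginary = rnorm(10))
  expect_equal(normalize_frame(low, low, high)$c, rep(0 + 0i, 10))
  expect_equal(normalize_frame(high, low, high)$c, rep(1 + 0i, 10))
  mid <- (low + high) / 2
  expect_equal(normalize_frame(mid, low, high)$c, rep(0.5 + 0i, 10))
  expect_error(normalize_frame(low, low, low), "calibration")
})

test_that("degenerate permittivity raises a solver error", {
  um <- uniform_map(grid64(), "air")
  um$fine[] <- 0
  expect_error(solve_fields(um, default_sensor()), "singular")
})

test_that("measurement features vanish for the empty sensor", {
  cal <- calib64()
  m <- measure_map(uniform_map(grid64(), "air"), cal)
  expect_lt(max(abs(m$y)), 1e-9)
  h <- measure_map(uniform_map(grid64(), "effusion_fluid"), cal)
  expect_true(all(h$y > 0))
  expect_equal(h$frame$c, rep(1 + 0i, length(h$frame$c)))
})
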