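test_that("complex permittivity follows the loss convention", {
  expect_identical(complex_permittivity(12.7, 0), 12.7 + 0i)
  # effusion fluid at 100 MHz: imaginary part = -sigma / (omega eps0)
  eff <- complex_permittivity(70, 1.4)
  expect_equal(Re(eff), 70)
  expect_equal(Im(eff), -1.4 / (2 * pi * 1e8 * 8.8541878128e-12), tolerance = 1e-10)
  expect_equal(Im(eff), -251.65, tolerance = 1e-4)
  # pneumothorax air is numerically lossless
  air <- complex_permittivity(1, 1e-15)
  expect_equal(Re(air), 1)
  expect_lt(abs(Im(air)), 1e-12)
  expect_error(complex_permittivity(1, 0, omega = 0), "omega")
})

test_that("tissue table carries the published dielectric values", {
  tb <- cceit_tissues()
  val <- function(n) unlist(tb[tb$tissue == n, c("eps_r", "sigma")], use.names = FALSE)
  expect_equal(val("lung_inspiration"), c(31.6, 0.306))
  expect_equal(val("lung_expiration"), c(67.1, 0.559))
  expect_equal(val("pneumothorax_air"), c(1, 1e-15))
  expect_equal(val("effusion_fluid"), c(70, 1.4))
  expect_equal(val("electrode_metal"), c(1, 0.0643))
  expect_equal(val("isolation_plastic"), c(2, 1e-21))
  expect_equal(val("spine"), c(10.53, 0.0643))
  expect_equal(val("heart"), c(90.8, 0.733))
  expect_equal(val("aorta"), c(90.8, 0.733))
  expect_equal(val("fat"), c(12.7, 0.068))
})

test_that("phantom sampling is deterministic and class-consistent", {
  a <- sample_phantom(6, seed = 42)
  b <- sample_phantom(6, seed = 42)
  expect_identical(a, b)
  cls <- cceit_classes()
  expect_identical(nrow(cls), 17L)
  h <- sample_phantom(1, seed = 1)
  expect_null(h$disease_left); expect_null(h$disease_right)
  r <- sample_phantom(17, seed = 1)
  expect_true(length(r$random_ellipses) >= 1 && length(r$random_ellipses) <= 4)
  expect_error(sample_phantom(18), "unknown class")
})

test_that("disease partitions conserve the lung and sit on the correct side", {
  g <- grid64()
  cc <- cceit:::grid_centres(g, "recon")
  lung <- ellipse_region(c(-0.1, 0), c(0.4, 0.55), 0.2, "lung_inspiration")
  X <- cc$X / 0.8; Y <- cc$Y / 0.8   # arbitrary consistent units

  # clip fully containing the lung: zero severity
  big <- ellipse_region(c(-0.1, 0), c(2, 2), 0, "lung_inspiration")
  p0 <- apply_disease(lung, "pneumothorax", big, X = X, Y = Y)
  expect_identical(sum(p0$air) + sum(p0$fluid), 0L)
  expect_identical(p0$kept, in_ellipse(X, Y, lung))

  clip <- ellipse_region(c(-0.15, -0.35), c(0.4, 0.55), 0.2, "lung_inspiration")
  pn <- apply_disease(lung, "pneumothorax", clip, X = X, Y = Y)
  ef <- apply_disease(lung, "effusion",
                      ellipse_region(c(-0.15, 0.35), c(0.4, 0.55), 0.2, "x"),
                      X = X, Y = Y)
  inl <- in_ellipse(X, Y, lung)
  for (p in list(pn, ef)) {
    expect_identical(p$kept | p$air | p$fluid, inl)          # conservation
    expect_identical(sum(p$kept & p$air) + sum(p$kept & p$fluid) +
                     sum(p$air & p$fluid), 0L)               # disjoint
  }
  # pneumothorax air collects towards the image top (larger y), effusion
  # fluid towards the bottom
  expect_gt(mean(Y[pn$air]), mean(Y[pn$kept]))
  expect_lt(mean(Y[ef$fluid]), mean(Y[ef$kept]))

  hy <- apply_disease(lung, "hydro", clip, split_y = 0.1, X = X, Y = Y)
  expect_identical(hy$kept | hy$air | hy$fluid, inl)
  expect_true(all(Y[hy$air] > 0.1) && all(Y[hy$fluid] <= 0.1))
  expect_error(apply_disease(lung, "pneumothorax",
                             ellipse_region(c(5, 5), c(0.1, 0.1), 0, "x"),
                             X = X, Y = Y),
               "degenerate")
})

test_that("rasterised phantoms carry the table values and average down", {
  grid <- cceit_grid(fine_n = 128, sensor = default_sensor())
  fov <- build_fov_mask(grid)
  cfg <- phantom_config(center_jitter = 0, rot_jitter = 0, scale_range = c(1, 1))
  spec <- sample_phantom(1, cfg, seed = 5)
  map <- rasterize(spec, grid, default_sensor(), fov)
  expect_true(all(Im(map$fine) <= 0))
  tb <- cceit_tissues()
  # find a fine pixel at each organ centre (FOV units -> physical -> index)
  cc <- cceit:::grid_centres(grid, "fine")
  ctr <- cceit:::fov_centre(grid)
  pix_at <- function(p_fov) {
    p <- ctr + p_fov * fov$radius
    c(which.min(abs(cc$y - p[2])), which.min(abs(cc$x - p[1])))
  }
  lung_name <- paste0("lung_", spec$respiration)
  for (case in list(list(spec$organs$lung_l$center, lung_name),
                    list(spec$organs$heart$center, "heart"),
                    list(spec$organs$spine$center, "spine"),
                    list(spec$organs$fat$center, "heart"))) {
    # note: the thorax centre lies inside the heart ellipse, hence "heart"
    ij <- pix_at(case[[1]])
    want <- complex_permittivity(tb[tb$tissue == case[[2]], ])
    expect_equal(map$fine[ij[1], ij[2]], want)
  }
  # lung tissue values match the respiration phase from Table values
  lung_eps <- complex_permittivity(tb[tb$tissue == lung_name, ])
  expect_true(any(map$fine == lung_eps))
  # reduced map is the block average of the fine map
  expect_equal(map$recon, block_average(map$fine, grid$block))
  expect_equal(dim(map$recon), c(64L, 64L))
  # same seed, same map
  map2 <- rasterize(sample_phantom(1, cfg, seed = 5), grid, default_sensor(), fov)
  expect_identical(map$fine, map2$fine)
})

test_that("pneumothorax air lies above kept lung tissue in rasterised maps", {
  grid <- grid64()
  tb <- cceit_tissues()
  id_air <- match("pneumothorax_air", tb$tissue)
  id_fluid <- match("effusion_fluid", tb$tissue)
  cc <- cceit:::grid_centres(grid, "fine")
  found_air <- found_fluid <- FALSE
  for (seed in 1:6) {
    spec <- sample_phantom(16, seed = seed)  # both lungs hydro
    map <- rasterize(spec, grid, default_sensor(), fov64())
    lung_ids <- match(c("lung_inspiration", "lung_expiration"), tb$tissue)
    if (any(map$tissue_fine == id_air)) {
      found_air <- TRUE
      expect_gt(mean(cc$Y[map$tissue_fine == id_air]),
                mean(cc$Y[map$tissue_fine %in% lung_ids]))
    }
    if (any(map$tissue_fine == id_fluid)) {
      found_fluid <- TRUE
      expect_lt(mean(cc$Y[map$tissue_fine == id_fluid]),
                mean(cc$Y[map$tissue_fine %in% lung_ids]))
    }
    if (found_air && found_fluid) break
  }
  expect_true(found_air && found_fluid)
})
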