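test_that("generator loss reproduces its closed-form examples", {
  y <- matrix(0, 4, 4)
  expect_equal(generator_loss(1, 0.5, y, y), -log(0.5), tolerance = 1e-7)
  expect_equal(generator_loss(1, 0.5, y + 0.1, y),
               -log(0.5) + 100 * 0.01 + 100 * 0.1, tolerance = 1e-7)
  # perfect generator: discriminator fooled and exact image
  expect_lt(generator_loss(1, 1 - 1e-9, y, y), 1e-6)
  # the three terms are the documented sum on random tensors
  set.seed(1)
  yr <- matrix(rnorm(30), 5); yp <- matrix(rnorm(30), 5)
  lp <- runif(3, 0.1, 0.9)
  expect_equal(generator_loss(1, lp, yr, yp),
               mean(-log(lp)) + 100 * mean((yr - yp)^2) + 100 * mean(abs(yr - yp)))
})

test_that("every layer's backward pass matches numerical gradients", {
  ns <- asNamespace("cceit")
  set.seed(11)
  cases <- list(
    list("linear", ns$nn_linear(5, 4), 5, 3, TRUE),
    list("bn-dense", ns$nn_bn(5), 5, 7, TRUE),
    list("bn-spatial", ns$nn_bn(3), 3 * 4 * 4, 2, FALSE),
    list("conv", ns$nn_conv(2, 3, 6, 6), 2 * 6 * 6, 2, FALSE),
    list("convt", ns$nn_convt(3, 2, 3, 3), 3 * 3 * 3, 2, FALSE),
    list("conv1x1", ns$nn_conv(3, 2, 4, 4, k = 1, stride = 1, pad = 0),
         3 * 4 * 4, 2, FALSE)
  )
  for (cs in cases) {
    l <- cs[[2]]; n_in <- cs[[3]]; B <- cs[[4]]; dense <- cs[[5]]
    xv <- rnorm(n_in * B) * 0.5
    shape <- function(v) if (dense) matrix(v, n_in, B) else v
    o <- ns$layer_forward(l, shape(xv), train = TRUE)
    w <- rnorm(length(o))
    wshape <- if (is.matrix(o)) matrix(w, nrow(o), ncol(o)) else w
    f <- function(v) sum(ns$layer_forward(l, shape(v), train = TRUE) * w)
    ns$layer_forward(l, shape(xv), train = TRUE)
    dx <- ns$layer_backward(l, wshape)
    gn <- numeric_grad(f, xv)
    expect_lt(max(abs(as.numeric(dx) - gn)) / max(abs(gn)), 1e-6,
              label = paste(cs[[1]], "input gradient error"))
    for (nm in names(l$par)) {
      p0 <- l$par[[nm]]
      fp <- function(pv) {
        old <- l$par[[nm]]
        l$par[[nm]] <- if (is.matrix(p0)) matrix(pv, nrow(p0), ncol(p0)) else pv
        r <- sum(ns$layer_forward(l, shape(xv), train = TRUE) * w)
        l$par[[nm]] <- old
        r
      }
      ns$layer_forward(l, shape(xv), train = TRUE)
      ns$layer_backward(l, wshape)
      gp <- numeric_grad(fp, as.numeric(p0))
      expect_lt(max(abs(as.numeric(l$grad[[nm]]) - gp)) / max(abs(gp), 1e-8),
                1e-6, label = paste(cs[[1]], nm, "gradient error"))
    }
  }
})

test_that("the U-Net generator's skip wiring backpropagates exactly", {
  ns <- asNamespace("cceit")
  set.seed(12)
  cfg <- cgan_config(channels = c(2L, 3L, 3L, 4L), d_channels = c(2L, 3L, 3L),
                     dropout = 0, seed = 1)
  G <- ns$build_generator(cfg, n_out = 40L)
  cond <- rnorm(1 * 32 * 32 * 2) * 0.1
  o <- ns$gen_forward(G, cond, train = TRUE)
  w <- rnorm(length(o))
  ns$gen_forward(G, cond, train = TRUE)
  ns$gen_backward(G, matrix(w, nrow(o), ncol(o)))
  for (lname in c("e2c", "d2c")) {
    l <- G$layers[[lname]]
    stored <- l$grad$W
    idx <- sample(length(l$par$W), 4)
    for (t in idx) {
      h <- 1e-6; p0 <- l$par$W[t]
      l$par$W[t] <- p0 + h
      fp <- sum(ns$gen_forward(G, cond, train = TRUE) * w)
      l$par$W[t] <- p0 - h
      fm <- sum(ns$gen_forward(G, cond, train = TRUE) * w)
      l$par$W[t] <- p0
      expect_equal(stored[t], (fp - fm) / (2 * h), tolerance = 2e-3)
    }
  }
})

test_that("the FCNN has the documented architecture and parameter count", {
  for (H in c(64L, 1856L)) {
    cfg <- fcnn_config(hidden_size = H)
    set.seed(1)
    m <- build_fcnn(cfg)
    want <- (992 * H + H) + (1856 * H + 1856) + 2 * 992 + 2 * H
    expect_identical(count_params(m), want)
    types <- vapply(m$layers, function(l) l$type, "")
    expect_identical(types, c("bn", "linear", "bn", "relu", "linear"))
  }
  set.seed(1)
  m <- build_fcnn(fcnn_config(hidden_size = 32L))
  out <- reconstruct_ann(m, matrix(rnorm(2 * 992), 2))
  expect_identical(dim(out), c(2L, 1856L))
  expect_true(all(is.finite(out)))
})

test_that("FCNN training is deterministic and can overfit a small set", {
  set.seed(21)
  X <- matrix(rnorm(96 * 992), 96)
  W0 <- matrix(rnorm(992 * 40, sd = 0.3), 992)
  Y <- tanh(X %*% W0) %*% matrix(rnorm(40 * 1856, sd = 0.2), 40)
  cfg <- fcnn_config(hidden_size = 256L, epochs = 8L, batch = 32L, seed = 5)
  m1 <- train_fcnn(X, Y, cfg)
  m2 <- train_fcnn(X, Y, cfg)
  expect_identical(m1$layers[[2]]$par$W, m2$layers[[2]]$par$W)
  expect_identical(m1$history, m2$history)
  # capacity check: training loss collapses by an order of magnitude
  cfg2 <- fcnn_config(hidden_size = 256L, epochs = 150L, batch = 32L, seed = 5)
  m3 <- train_fcnn(X, Y, cfg2)
  expect_lt(tail(m3$history$train_loss, 1), m3$history$train_loss[1] / 10)
  # eval-mode inference is deterministic and order-preserving
  Xt <- matrix(rnorm(5 * 992), 5)
  r1 <- reconstruct_ann(m3, Xt)
  r2 <- reconstruct_ann(m3, Xt)
  expect_identical(r1, r2)
  expect_equal(reconstruct_ann(m3, Xt[3, , drop = FALSE])[1, ], r1[3, ])
})

test_that("cGAN components behave at initialisation and in eval mode", {
  ns <- asNamespace("cceit")
  set.seed(31)
  cfg <- cgan_config(channels = c(4L, 8L, 8L, 8L), d_channels = c(4L, 4L, 4L),
                     seed = 1)
  D <- ns$build_discriminator(cfg)
  img <- rnorm(4096 * 8); cond <- rnorm(1024 * 8)
  p <- ns$disc_forward(D, img, cond, train = TRUE)
  # untrained discriminator sits near chance
  expect_true(all(p > 0.3 & p < 0.7))
  G <- ns$build_generator(cfg, 1856L)
  out <- ns$gen_forward(G, cond, train = FALSE)
  expect_identical(dim(out), c(1856L, 8L))
  # dropout off in eval mode: repeated passes identical
  expect_identical(out, ns$gen_forward(G, cond, train = FALSE))
})

test_that("binary cross-entropy evaluates the textbook formula", {
  expect_equal(bce_loss(0.5, 1), -log(0.5))
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -mean(log(c(0.9, 0.9))))
})
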