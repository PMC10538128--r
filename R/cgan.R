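#' Conditional GAN configuration
#'
#' A Pix2Pix-style conditional GAN: the U-Net generator consumes the
#' 32 x 32 electrode-by-electrode measurement matrix as its condition (no
#' latent vector; dropout in the decoder provides stochasticity during
#' training), and the discriminator judges (condition, image) pairs.  The
#' generator loss is [generator_loss()]: adversarial binary cross-entropy
#' plus mean-square and mean-absolute image terms with weight 100 each.
#'
#' @param channels encoder channel widths, innermost last (default
#'   `c(32, 64, 128, 256)`); the decoder mirrors them.
#' @param d_channels discriminator block channel widths (3 blocks).
#' @param dropout decoder dropout rate.
#' @param lr Adam learning rate (both networks).
#' @param beta1,beta2 Adam moment decay rates.
#' @param lambda_mse,lambda_mae image-loss weights.
#' @param batch mini-batch size.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param d_loss_floor,d_floor_epochs mode-collapse guard: abort if the
#'   mean discriminator loss stays below the floor this many consecutive
#'   epochs.
#' @return list of class `cceit_cgan_config`.
#' @export
cgan_config <- function(channels = c(32L, 64L, 128L, 256L),
                        d_channels = c(32L, 64L, 64L),
                        dropout = 0.5, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                        lambda_mse = 100, lambda_mae = 100,
                        batch = 32L, epochs = 40L, seed = 1L,
                        d_loss_floor = 1e-4, d_floor_epochs = 5L) {
  stopifnot(length(channels) == 4L, length(d_channels) == 3L)
  structure(list(channels = channels, d_channels = d_channels,
                 dropout = dropout, lr = lr, beta1 = beta1, beta2 = beta2,
                 lambda_mse = lambda_mse, lambda_mae = lambda_mae,
                 batch = batch, epochs = epochs, seed = seed,
                 d_loss_floor = d_loss_floor, d_floor_epochs = d_floor_epochs),
            class = "cceit_cgan_config")
}

# channel-first concatenation/split helpers; `rest` = H*W*B
cc_concat <- function(a, Ca, b, Cb) {
  rest <- length(a) %/% Ca
  as.numeric(rbind(matrix(a, Ca), matrix(b, Cb)))
}
cc_split <- function(z, Ca, Cb) {
  m <- matrix(z, Ca + Cb)
  list(a = as.numeric(m[seq_len(Ca), , drop = FALSE]),
       b = as.numeric(m[Ca + seq_len(Cb), , drop = FALSE]))
}

build_generator <- function(cfg, n_out = 1856L) {
  ch <- cfg$channels
  L <- list(
    e1c = nn_conv(1L, ch[1], 32L, 32L), e1a = nn_lrelu(),
    e2c = nn_conv(ch[1], ch[2], 16L, 16L), e2b = nn_bn(ch[2]), e2a = nn_lrelu(),
    e3c = nn_conv(ch[2], ch[3], 8L, 8L), e3b = nn_bn(ch[3]), e3a = nn_lrelu(),
    e4c = nn_conv(ch[3], ch[4], 4L, 4L), e4b = nn_bn(ch[4]), e4a = nn_lrelu(),
    d1c = nn_convt(ch[4], ch[3], 2L, 2L), d1b = nn_bn(ch[3]),
    d1d = nn_dropout(cfg$dropout), d1a = nn_relu(),
    d2c = nn_convt(2L * ch[3], ch[2], 4L, 4L), d2b = nn_bn(ch[2]),
    d2d = nn_dropout(cfg$dropout), d2a = nn_relu(),
    d3c = nn_convt(2L * ch[2], ch[1], 8L, 8L), d3b = nn_bn(ch[1]), d3a = nn_relu(),
    d4c = nn_convt(2L * ch[1], ch[1], 16L, 16L), d4b = nn_bn(ch[1]), d4a = nn_relu(),
    d5c = nn_convt(ch[1], 8L, 32L, 32L), d5a = nn_relu(),
    pix = nn_conv(8L, 1L, 64L, 64L, k = 1L, stride = 1L, pad = 0L),
    out = nn_linear(4096L, n_out)
  )
  g <- new.env(parent = emptyenv())
  g$layers <- L; g$ch <- ch; g$n_out <- n_out
  g
}

gen_forward <- function(g, cond, train = TRUE) {
  L <- g$layers
  f <- function(nm, x) layer_forward(L[[nm]], x, train)
  x1 <- f("e1a", f("e1c", cond))
  x2 <- f("e2a", f("e2b", f("e2c", x1)))
  x3 <- f("e3a", f("e3b", f("e3c", x2)))
  x4 <- f("e4a", f("e4b", f("e4c", x3)))
  y1 <- f("d1a", f("d1d", f("d1b", f("d1c", x4))))
  y2 <- f("d2a", f("d2d", f("d2b", f("d2c", cc_concat(y1, g$ch[3], x3, g$ch[3])))))
  y3 <- f("d3a", f("d3b", f("d3c", cc_concat(y2, g$ch[2], x2, g$ch[2]))))
  y4 <- f("d4a", f("d4b", f("d4c", cc_concat(y3, g$ch[1], x1, g$ch[1]))))
  y5 <- f("d5a", f("d5c", y4))
  p <- f("pix", y5)
  B <- length(p) %/% 4096L
  layer_forward(L$out, matrix(p, 4096L, B), train)
}

gen_backward <- function(g, dout) {
  L <- g$layers
  b <- function(nm, d) layer_backward(L[[nm]], d)
  d <- b("out", dout)
  d <- b("pix", as.numeric(d))
  d <- b("d5c", b("d5a", d))
  dz3 <- b("d4c", b("d4b", b("d4a", d)))
  s3 <- cc_split(dz3, g$ch[1], g$ch[1])
  dz2 <- b("d3c", b("d3b", b("d3a", s3$a)))
  s2 <- cc_split(dz2, g$ch[2], g$ch[2])
  dz1 <- b("d2c", b("d2d", b("d2b", b("d2a", s2$a))))
  s1 <- cc_split(dz1, g$ch[3], g$ch[3])
  dx4 <- b("d1c", b("d1d", b("d1b", b("d1a", s1$a))))
  dx3 <- b("e4c", b("e4b", b("e4a", dx4))) + s1$b
  dx2 <- b("e3c", b("e3b", b("e3a", dx3))) + s2$b
  dx1 <- b("e2c", b("e2b", b("e2a", dx2))) + s3$b
  invisible(b("e1c", b("e1a", dx1)))
}

build_discriminator <- function(cfg) {
  dc <- cfg$d_channels
  L <- list(
    ic = nn_conv(1L, dc[1], 64L, 64L), ia = nn_lrelu(),
    k1c = nn_conv(dc[1] + 1L, dc[2], 32L, 32L), k1b = nn_bn(dc[2]), k1a = nn_lrelu(),
    k2c = nn_conv(dc[2], dc[3], 16L, 16L), k2b = nn_bn(dc[3]), k2a = nn_lrelu(),
    out = nn_linear(dc[3] * 64L, 1L), sig = nn_sigmoid()
  )
  # small head initialisation: the untrained discriminator answers near
  # chance (probability ~0.5), which keeps early generator gradients tame
  L$out$par$W <- L$out$par$W * 0.1
  d <- new.env(parent = emptyenv())
  d$layers <- L; d$dc <- dc
  d
}

disc_forward <- function(d, img, cond, train = TRUE) {
  L <- d$layers
  f <- function(nm, x) layer_forward(L[[nm]], x, train)
  h <- f("ia", f("ic", img))                       # dc1 x 32 x 32
  z <- cc_concat(h, d$dc[1], cond, 1L)
  h <- f("k1a", f("k1b", f("k1c", z)))
  h <- f("k2a", f("k2b", f("k2c", h)))
  B <- length(h) %/% (d$dc[3] * 64L)
  f("sig", f("out", matrix(h, d$dc[3] * 64L, B)))
}

# returns the gradient w.r.t. the image input (needed for the generator step)
disc_backward <- function(d, dout) {
  L <- d$layers
  b <- function(nm, x) layer_backward(L[[nm]], x)
  h <- b("out", b("sig", dout))
  h <- b("k2c", b("k2b", b("k2a", as.numeric(h))))
  h <- b("k1c", b("k1b", b("k1a", h)))
  s <- cc_split(h, d$dc[1], 1L)
  b("ic", b("ia", s$a))
}

grads_snapshot <- function(layers) lapply(layers, function(l) l$grad)
grads_add <- function(layers, snap) {
  for (i in seq_along(layers)) {
    if (!length(layers[[i]]$grad)) next
    for (nm in names(layers[[i]]$grad))
      layers[[i]]$grad[[nm]] <- layers[[i]]$grad[[nm]] + snap[[i]][[nm]]
  }
  invisible(layers)
}

#' Train the conditional GAN reconstruction network
#'
#' Alternates discriminator and generator updates: the discriminator
#' minimises binary cross-entropy on (condition, true image) versus
#' (condition, generated image) pairs; the generator minimises
#' [generator_loss()].  Conditions are the measurement matrices, images
#' the normalised conductivity contrast embedded in the 64 x 64 frame.
#' Deterministic under `cfg$seed`.
#'
#' @param X `n x 992` measurement feature matrix.
#' @param Y `n x n_fov` target image matrix.
#' @param fov the [build_fov_mask()] of the images.
#' @param cfg a [cgan_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `cceit_cgan`: list with generator `G`,
#'   discriminator `D`, `cfg`, `fov`, `history`.
#' @export
train_cgan <- function(X, Y, fov, cfg = cgan_config(), verbose = FALSE) {
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == fov$n_fov)
  K <- (1 + sqrt(1 + 4 * ncol(X))) / 2
  stopifnot(K == round(K))
  K <- as.integer(K)
  set.seed(cfg$seed)
  G <- build_generator(cfg, n_out = ncol(Y))
  D <- build_discriminator(cfg)
  optG <- adam_new(lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2)
  optD <- adam_new(lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2)
  pr <- measurement_pairs(K)
  cond_idx <- pr$excite + (pr$sense - 1L) * K
  emb_idx <- which(fov$mask)
  n <- nrow(X)
  hist <- data.frame(epoch = integer(), d_loss = numeric(), g_loss = numeric(),
                     g_img = numeric())
  low_epochs <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    dl <- gl <- gi <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch)) {
      ix <- ord[start:min(start + cfg$batch - 1L, n)]
      B <- length(ix)
      condm <- matrix(0, K * K, B)
      condm[cond_idx, ] <- t(X[ix, , drop = FALSE])
      cond <- as.numeric(condm)
      real <- t(Y[ix, , drop = FALSE])                 # n_out x B
      embr <- matrix(0, 4096L, B); embr[emb_idx, ] <- real

      fake <- gen_forward(G, cond, train = TRUE)       # n_out x B
      embf <- matrix(0, 4096L, B); embf[emb_idx, ] <- fake

      # --- discriminator update ---
      p_r <- clamp01(disc_forward(D, as.numeric(embr), cond, TRUE))
      lr_ <- bce_loss(p_r, 1)
      disc_backward(D, matrix(-1 / p_r / length(p_r), 1))
      snap <- grads_snapshot(D$layers)
      p_f <- clamp01(disc_forward(D, as.numeric(embf), cond, TRUE))
      lf_ <- bce_loss(p_f, 0)
      disc_backward(D, matrix(1 / (1 - p_f) / length(p_f), 1))
      grads_add(D$layers, snap)
      adam_step(optD, D$layers)
      dl <- dl + (lr_ + lf_) / 2

      # --- generator update ---
      p_g <- clamp01(disc_forward(D, as.numeric(embf), cond, TRUE))
      diffm <- fake - real
      gl <- gl + generator_loss(1, p_g, real, fake, cfg$lambda_mse, cfg$lambda_mae)
      gi <- gi + mean(diffm^2)
      dimg <- disc_backward(D, matrix(-1 / p_g / length(p_g), 1))
      dadv <- matrix(dimg, 4096L, B)[emb_idx, , drop = FALSE]
      dfake <- dadv + cfg$lambda_mse * 2 * diffm / length(diffm) +
        cfg$lambda_mae * sign(diffm) / length(diffm)
      gen_backward(G, dfake)
      adam_step(optG, G$layers)
      nb <- nb + 1L
    }
    dl <- dl / nb; gl <- gl / nb; gi <- gi / nb
    if (!is.finite(gl))
      stop("train_cgan: training diverged (non-finite generator loss) at epoch ", ep)
    low_epochs <- if (dl < cfg$d_loss_floor) low_epochs + 1L else 0L
    if (low_epochs >= cfg$d_floor_epochs)
      stop("train_cgan: discriminator loss collapsed for ", low_epochs,
           " consecutive epochs (mode-collapse guard)")
    hist <- rbind(hist, data.frame(epoch = ep, d_loss = dl, g_loss = gl, g_img = gi))
    if (verbose) cat(sprintf("epoch %3d  D %.4f  G %.4f  img-MSE %.5f\n",
                             ep, dl, gl, gi))
  }
  structure(list(G = G, D = D, cfg = cfg, fov = fov, K = K,
                 cond_idx = cond_idx, history = hist),
            class = "cceit_cgan")
}

#' @export
reconstruct_ann.cceit_cgan <- function(model, X, chunk = 64L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  K <- model$K
  out <- matrix(0, nrow(X), model$G$n_out)
  for (start in seq(1L, nrow(X), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(X))
    B <- length(ix)
    condm <- matrix(0, K * K, B)
    condm[model$cond_idx, ] <- t(X[ix, , drop = FALSE])
    out[ix, ] <- t(gen_forward(model$G, as.numeric(condm), train = FALSE))
  }
  out
}
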