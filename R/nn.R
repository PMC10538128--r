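## Minimal neural-network engine.
##
## Dense and convolutional layers with hand-written backward passes, batch
## normalisation, dropout and an Adam optimiser.  Feature maps are stored
## channel-first as flat numeric vectors in (C, H, W, B) order; dense
## activations as (features x batch) matrices.  Convolutions are lowered to
## GEMM through the compiled im2col/col2im kernels, so the heavy lifting is
## done by BLAS.  All randomness (initialisation, shuffling, dropout) goes
## through R's RNG, which makes training runs reproducible under set.seed.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  cfg <- list(...)
  for (nm in names(cfg)) assign(nm, cfg[[nm]], envir = l)
  l$par <- list(); l$grad <- list()
  l
}

#' @keywords internal
nn_linear <- function(nin, nout) {
  l <- new_layer("linear", nin = nin, nout = nout)
  l$par <- list(W = matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
                b = numeric(nout))
  l
}

#' @keywords internal
nn_bn <- function(d, momentum = 0.9, eps = 1e-5, spatial = NULL) {
  l <- new_layer("bn", d = d, momentum = momentum, eps = eps, spatial = spatial)
  l$par <- list(gamma = rep(1, d), beta = numeric(d))
  l$run_mean <- numeric(d); l$run_var <- rep(1, d)
  l
}

#' @keywords internal
nn_relu <- function() new_layer("relu")
#' @keywords internal
nn_lrelu <- function(slope = 0.2) new_layer("lrelu", slope = slope)
#' @keywords internal
nn_sigmoid <- function() new_layer("sigmoid")
#' @keywords internal
nn_dropout <- function(p = 0.5) new_layer("dropout", p = p)

#' @keywords internal
nn_conv <- function(Cin, Cout, H, W, k = 4L, stride = 2L, pad = 1L) {
  l <- new_layer("conv", Cin = Cin, Cout = Cout, H = H, W = W,
                 k = k, stride = stride, pad = pad,
                 oH = (H + 2 * pad - k) %/% stride + 1L,
                 oW = (W + 2 * pad - k) %/% stride + 1L)
  l$par <- list(W = matrix(rnorm(Cout * Cin * k * k, sd = sqrt(2 / (Cin * k * k))),
                           Cout, Cin * k * k),
                b = numeric(Cout))
  l
}

#' @keywords internal
nn_convt <- function(Cin, Cout, H, W, k = 4L, stride = 2L, pad = 1L) {
  l <- new_layer("convt", Cin = Cin, Cout = Cout, H = H, W = W,
                 k = k, stride = stride, pad = pad,
                 oH = stride * (H - 1L) + k - 2L * pad,
                 oW = stride * (W - 1L) + k - 2L * pad)
  l$par <- list(W = matrix(rnorm(k * k * Cout * Cin, sd = sqrt(2 / (Cout * k * k))),
                           k * k * Cout, Cin),
                b = numeric(Cout))
  l
}

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    linear = {
      l$cache <- x
      l$par$W %*% x + l$par$b
    },
    bn = {
      d <- l$d
      was_matrix <- is.matrix(x)
      xm <- if (was_matrix) x else matrix(x, d)
      if (train) {
        mu <- rowMeans(xm)
        xc <- xm - mu
        v <- rowMeans(xc * xc)
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
      } else {
        mu <- l$run_mean; v <- l$run_var
        xc <- xm - mu
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- xc * invstd
      l$cache <- list(xhat = xhat, invstd = invstd, train = train,
                      was_matrix = was_matrix)
      out <- l$par$gamma * xhat + l$par$beta
      if (!was_matrix) out <- as.numeric(out)
      out
    },
    relu = { m <- (x > 0) * 1; l$cache <- m; x * m },
    lrelu = {
      m <- (x > 0) * 1; l$cache <- m
      a <- l$slope
      x * a + x * ((1 - a) * m)
    },
    sigmoid = { s <- 1 / (1 + exp(-x)); l$cache <- s; s },
    dropout = {
      if (train && l$p > 0) {
        m <- (runif(length(x)) >= l$p) / (1 - l$p)
        l$cache <- m
        x * m
      } else { l$cache <- NULL; x }
    },
    conv = {
      B <- length(x) %/% (l$Cin * l$H * l$W)
      cols <- im2col_chwb(as.numeric(x), l$Cin, l$H, l$W, B, l$k, l$stride, l$pad)
      l$cache <- list(cols = cols, B = B)
      out <- l$par$W %*% cols + l$par$b
      dim(out) <- NULL
      out
    },
    convt = {
      B <- length(x) %/% (l$Cin * l$H * l$W)
      xm <- matrix(x, l$Cin)
      cols <- l$par$W %*% xm
      out <- col2im_chwb(cols, l$Cout, l$oH, l$oW, B, l$k, l$stride, l$pad)
      out <- matrix(out, l$Cout) + l$par$b
      l$cache <- list(xm = xm, B = B)
      dim(out) <- NULL
      as.numeric(out)
    },
    stop("unknown layer type ", l$type))
}


layer_backward <- function(l, dout) {
  switch(l$type,
    linear = {
      x <- l$cache
      l$grad <- list(W = dout %*% t(x), b = rowSums(dout))
      crossprod(l$par$W, dout)
    },
    bn = {
      cc <- l$cache
      dm <- if (cc$was_matrix) dout else matrix(dout, l$d)
      xhat <- cc$xhat
      l$grad <- list(gamma = rowSums(dm * xhat), beta = rowSums(dm))
      dxhat <- dm * l$par$gamma
      if (cc$train) {
        N <- ncol(xhat)
        dx <- cc$invstd / N *
          (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      } else {
        dx <- dxhat * cc$invstd
      }
      if (!cc$was_matrix) dx <- as.numeric(dx)
      dx
    },
    relu = dout * l$cache,
    lrelu = dout * l$slope + dout * ((1 - l$slope) * l$cache),
    sigmoid = dout * l$cache * (1 - l$cache),
    dropout = if (is.null(l$cache)) dout else dout * l$cache,
    conv = {
      cc <- l$cache
      dm <- matrix(dout, l$Cout)
      l$grad <- list(W = dm %*% t(cc$cols), b = rowSums(dm))
      dcols <- crossprod(l$par$W, dm)
      dx <- col2im_chwb(dcols, l$Cin, l$H, l$W, cc$B, l$k, l$stride, l$pad)
      as.numeric(dx)
    },
    convt = {
      cc <- l$cache
      dcols <- im2col_chwb(as.numeric(dout), l$Cout, l$oH, l$oW, cc$B,
                           l$k, l$stride, l$pad)
      dmat <- matrix(dout, l$Cout)
      l$grad <- list(W = dcols %*% t(cc$xm), b = rowSums(dmat))
      dx <- crossprod(l$par$W, dcols)
      dim(dx) <- NULL
      as.numeric(dx)
    },
    stop("unknown layer type ", l$type))
}

net_forward <- function(layers, x, train = TRUE) {
  for (l in layers) x <- layer_forward(l, x, train)
  x
}

net_backward <- function(layers, dout) {
  for (l in rev(layers)) dout <- layer_backward(l, dout)
  dout
}

n_params <- function(layers) sum(vapply(layers, function(l)
  sum(vapply(l$par, length, 0L)), 0))

## ---- Adam -----------------------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e
}

adam_step <- function(opt, layers) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (l in layers) {
    if (!length(l$par) || !length(l$grad)) next
    if (is.null(l$m)) {
      l$m <- lapply(l$par, function(p) p * 0)
      l$v <- lapply(l$par, function(p) p * 0)
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$m[[nm]] <- b1 * l$m[[nm]] + (1 - b1) * g
      l$v[[nm]] <- b2 * l$v[[nm]] + (1 - b2) * g * g
      l$par[[nm]] <- l$par[[nm]] -
        opt$lr * (l$m[[nm]] / corr1) / (sqrt(l$v[[nm]] / corr2) + opt$eps)
    }
  }
  invisible(opt)
}

## ---- losses ---------------------------------------------------------------

clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy
#' @param p predicted probabilities in (0, 1).
#' @param target reference labels (same shape).
#' @return mean binary cross-entropy (scalar).
#' @export
bce_loss <- function(p, target) {
  p <- clamp01(p)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Conditional-GAN generator loss
#'
#' The Pix2Pix-style generator objective: binary cross-entropy of the
#' discriminator's realness output against the reference label, plus
#' heavily weighted mean-square and mean-absolute image terms:
#' `BCE(l_p, l_r) + lambda_mse * MSE(y_r, y_p) + lambda_mae * MAE(y_r, y_p)`.
#'
#' @param l_r reference realness label(s) (usually 1).
#' @param l_p discriminator output probability in (0, 1).
#' @param y_r,y_p reference and predicted images (any equal shape).
#' @param lambda_mse,lambda_mae weights of the image terms (default 100).
#' @return scalar loss.
#' @examples
#' y <- matrix(0, 2, 2)
#' generator_loss(1, 0.5, y, y)  # 0.6931472
#' @export
generator_loss <- function(l_r, l_p, y_r, y_p,
                           lambda_mse = 100, lambda_mae = 100) {
  if (any(l_p <= 0 | l_p >= 1)) l_p <- clamp01(l_p)
  bce_loss(l_p, l_r) +
    lambda_mse * mean((y_r - y_p)^2) +
    lambda_mae * mean(abs(y_r - y_p))
}

## ---- (de)serialisation ----------------------------------------------------

layers_state <- function(layers) lapply(layers, function(l) {
  st <- list(type = l$type, par = l$par)
  if (l$type == "bn") { st$run_mean <- l$run_mean; st$run_var <- l$run_var }
  st
})

layers_restore <- function(layers, state) {
  for (i in seq_along(layers)) {
    layers[[i]]$par <- state[[i]]$par
    if (layers[[i]]$type == "bn") {
      layers[[i]]$run_mean <- state[[i]]$run_mean
      layers[[i]]$run_var <- state[[i]]$run_var
    }
  }
  invisible(layers)
}
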