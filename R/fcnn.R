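#' Fully connected reconstruction network configuration
#'
#' The shallow dense network: batch normalisation of the 992-element
#' measurement vector, one hidden linear layer with batch normalisation
#' and ReLU, and a linear output layer producing the 1856 field-of-view
#' pixels.
#'
#' @param input_size measurement vector length (default 992).
#' @param hidden_size hidden layer width (default 1856, the output width).
#' @param output_size image vector length (default 1856).
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param epochs training epochs.
#' @param seed RNG seed for initialisation, shuffling and splits.
#' @return list of class `cceit_fcnn_config`.
#' @export
fcnn_config <- function(input_size = 992L, hidden_size = 1856L,
                        output_size = 1856L, lr = 1e-3, batch = 64L,
                        epochs = 30L, seed = 1L) {
  structure(list(input_size = input_size, hidden_size = hidden_size,
                 output_size = output_size, lr = lr, batch = batch,
                 epochs = epochs, seed = seed),
            class = "cceit_fcnn_config")
}

#' Build the fully connected reconstruction network
#'
#' Layer sequence: input batch norm, affine `input -> hidden`, batch norm,
#' ReLU, affine `hidden -> output`; no output activation.
#'
#' @param cfg a [fcnn_config()].
#' @return object of class `cceit_fcnn` (untrained).
#' @export
build_fcnn <- function(cfg = fcnn_config()) {
  layers <- list(
    nn_bn(cfg$input_size),
    nn_linear(cfg$input_size, cfg$hidden_size),
    nn_bn(cfg$hidden_size),
    nn_relu(),
    nn_linear(cfg$hidden_size, cfg$output_size)
  )
  structure(list(layers = layers, cfg = cfg, history = NULL),
            class = "cceit_fcnn")
}

#' Number of trainable parameters of a model
#' @param model a `cceit_fcnn`, `cceit_cgan` or `cceit_classifier`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "cceit_cgan"))
    return(n_params(model$G$layers) + n_params(model$D$layers))
  n_params(model$layers)
}

#' Train the fully connected reconstruction network
#'
#' Minimises the mean squared error between predicted and true image
#' vectors with the Adam optimiser; a random 75:25 learning/validation
#' split monitors the validation loss each epoch (optionally resplit every
#' epoch).  Fully deterministic under `cfg$seed`.
#'
#' @param X `n x input_size` matrix of measurement features.
#' @param Y `n x output_size` matrix of target images (normalised
#'   conductivity contrast).
#' @param cfg a [fcnn_config()].
#' @param val_ratio validation fraction (default 0.25).
#' @param resplit logical: draw a fresh split every epoch.
#' @param verbose print per-epoch losses.
#' @return a trained `cceit_fcnn` with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_fcnn <- function(X, Y, cfg = fcnn_config(), val_ratio = 0.25,
                       resplit = FALSE, verbose = FALSE) {
  stopifnot(nrow(X) == nrow(Y))
  set.seed(cfg$seed)
  model <- build_fcnn(cfg)
  layers <- model$layers
  opt <- adam_new(lr = cfg$lr)
  n <- nrow(X)
  sp <- split_train_val(n, 1 - val_ratio)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(cfg$epochs)) {
    if (resplit && ep > 1L) sp <- split_train_val(n, 1 - val_ratio)
    ord <- sample(sp$learn)
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch)) {
      ix <- ord[start:min(start + cfg$batch - 1L, length(ord))]
      xb <- t(X[ix, , drop = FALSE]); yb <- t(Y[ix, , drop = FALSE])
      pred <- net_forward(layers, xb, train = TRUE)
      diffm <- pred - yb
      tl <- tl + mean(diffm^2); nb <- nb + 1L
      net_backward(layers, 2 * diffm / length(diffm))
      adam_step(opt, layers)
    }
    vl <- .fcnn_loss(layers, X[sp$val, , drop = FALSE], Y[sp$val, , drop = FALSE])
    if (!is.finite(vl))
      stop("train_fcnn: training diverged (non-finite validation loss) at epoch ", ep)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb, val_loss = vl))
    if (verbose) cat(sprintf("epoch %3d  train %.5f  val %.5f\n", ep, tl / nb, vl))
  }
  model$layers <- layers
  model$history <- hist
  model
}

.fcnn_loss <- function(layers, X, Y, chunk = 512L) {
  tot <- 0; n <- nrow(X)
  if (n == 0L) return(NA_real_)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    pred <- net_forward(layers, t(X[ix, , drop = FALSE]), train = FALSE)
    tot <- tot + sum((pred - t(Y[ix, , drop = FALSE]))^2)
  }
  tot / (n * ncol(Y))
}

#' Reconstruct images with a trained network
#'
#' Runs the model in evaluation mode (batch statistics frozen, dropout
#' off), so repeated calls on the same input give identical output.
#'
#' @param model a trained `cceit_fcnn` or `cceit_cgan`.
#' @param X `n x 992` matrix of measurement features (one sample per row).
#' @param chunk internal batch size.
#' @return `n x output_size` matrix of reconstructed image vectors, rows in
#'   input order.
#' @export
reconstruct_ann <- function(model, X, chunk = 256L) UseMethod("reconstruct_ann")

#' @export
reconstruct_ann.cceit_fcnn <- function(model, X, chunk = 256L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$cfg$input_size) stop("reconstruct_ann: shape mismatch")
  out <- matrix(0, nrow(X), model$cfg$output_size)
  for (start in seq(1L, nrow(X), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(X))
    out[ix, ] <- t(net_forward(model$layers, t(X[ix, , drop = FALSE]),
                               train = FALSE))
  }
  out
}
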