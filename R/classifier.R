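#' Diagnostic classifier configuration
#'
#' A small convolutional classifier over 64 x 64 conductivity images:
#' three stride-2 convolution blocks with batch normalisation, then one
#' affine layer with softmax over the 17 thorax condition classes.
#'
#' @param channels channel widths of the three convolution blocks.
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param loss `"bce"` (elementwise binary cross-entropy over the softmax
#'   outputs against the one-hot label) or `"ce"` (categorical
#'   cross-entropy).
#' @return list of class `cceit_classifier_config`.
#' @export
classifier_config <- function(channels = c(16L, 32L, 64L), lr = 1e-3,
                              batch = 64L, epochs = 10L, seed = 1L,
                              loss = c("bce", "ce")) {
  structure(list(channels = channels, lr = lr, batch = batch,
                 epochs = epochs, seed = seed, loss = match.arg(loss)),
            class = "cceit_classifier_config")
}

#' Build the diagnostic classifier
#'
#' @param cfg a [classifier_config()].
#' @param n_classes number of output classes (default 17).
#' @return object of class `cceit_classifier` (untrained).
#' @export
build_classifier <- function(cfg = classifier_config(), n_classes = 17L) {
  ch <- cfg$channels
  layers <- list(
    nn_conv(1L, ch[1], 64L, 64L), nn_bn(ch[1]), nn_lrelu(),
    nn_conv(ch[1], ch[2], 32L, 32L), nn_bn(ch[2]), nn_lrelu(),
    nn_conv(ch[2], ch[3], 16L, 16L), nn_bn(ch[3]), nn_lrelu()
  )
  structure(list(layers = layers,
                 head = nn_linear(ch[3] * 64L, n_classes),
                 cfg = cfg, n_classes = n_classes),
            class = "cceit_classifier")
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

clf_logits <- function(model, imgs, train) {
  h <- net_forward(model$layers, imgs, train)
  B <- length(h) %/% (model$cfg$channels[3] * 64L)
  layer_forward(model$head, matrix(h, model$cfg$channels[3] * 64L, B), train)
}

embed_images <- function(Y, fov) {
  emb <- matrix(0, prod(dim(fov$mask)), nrow(Y))
  emb[which(fov$mask), ] <- t(Y)
  as.numeric(emb)
}

#' Train the diagnostic classifier on ground-truth images
#'
#' Trains against one-hot labels with the Adam optimiser and a 75:25
#' learning/validation split.  The default loss is elementwise binary
#' cross-entropy over the 17 softmax outputs; categorical cross-entropy is
#' available via the configuration.
#'
#' @param Y `n x n_fov` matrix of (ground-truth) image vectors on the
#'   normalised conductivity scale.
#' @param labels integer class labels 1..n_classes.
#' @param fov the [build_fov_mask()] describing the image support.
#' @param cfg a [classifier_config()].
#' @param verbose print per-epoch diagnostics.
#' @return trained `cceit_classifier` with `history` (epoch, train loss,
#'   validation accuracy).
#' @export
train_classifier <- function(Y, labels, fov, cfg = classifier_config(),
                             verbose = FALSE) {
  stopifnot(nrow(Y) == length(labels))
  set.seed(cfg$seed)
  model <- build_classifier(cfg)
  all_layers <- c(model$layers, list(model$head))
  opt <- adam_new(lr = cfg$lr)
  n <- nrow(Y)
  sp <- split_train_val(n, 0.75)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_acc = numeric())
  nc <- model$n_classes
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(sp$learn)
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch)) {
      ix <- ord[start:min(start + cfg$batch - 1L, length(ord))]
      B <- length(ix)
      imgs <- embed_images(Y[ix, , drop = FALSE], fov)
      z <- clf_logits(model, imgs, train = TRUE)
      p <- softmax_cols(z)
      tmat <- matrix(0, nc, B); tmat[cbind(labels[ix], seq_len(B))] <- 1
      if (cfg$loss == "bce") {
        pc <- clamp01(p)
        tl <- tl + bce_loss(pc, tmat)
        dldp <- (-tmat / pc + (1 - tmat) / (1 - pc)) / length(p)
        dz <- p * (dldp - rep(colSums(p * dldp), each = nc))
      } else {
        pc <- clamp01(p)
        tl <- tl - mean(colSums(tmat * log(pc)))
        dz <- (p - tmat) / B
      }
      h <- layer_backward(model$head, dz)
      net_backward(model$layers, as.numeric(h))
      adam_step(opt, all_layers)
      nb <- nb + 1L
    }
    pv <- predict_classifier(model, Y[sp$val, , drop = FALSE], fov)
    acc <- mean(max.col(pv) == labels[sp$val])
    if (!is.finite(tl))
      stop("train_classifier: training diverged at epoch ", ep)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb, val_acc = acc))
    if (verbose) cat(sprintf("epoch %3d  loss %.4f  val-acc %.3f\n",
                             ep, tl / nb, acc))
  }
  model$history <- hist
  model
}

#' Class probabilities for images
#'
#' @param model a trained [build_classifier()].
#' @param Y `n x n_fov` image matrix (same scale as training images).
#' @param fov the field-of-view mask.
#' @param chunk internal batch size.
#' @return `n x n_classes` matrix of softmax probabilities (rows sum to 1).
#' @export
predict_classifier <- function(model, Y, fov, chunk = 256L) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  out <- matrix(0, nrow(Y), model$n_classes)
  for (start in seq(1L, nrow(Y), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(Y))
    z <- clf_logits(model, embed_images(Y[ix, , drop = FALSE], fov), train = FALSE)
    out[ix, ] <- t(softmax_cols(z))
  }
  out
}

#' One-vs-rest ROC curves and macro-averaged AUC
#'
#' For each class, treats that class as positive and the rest as negative,
#' computes the ROC curve and AUC of the corresponding probability column,
#' and macro-averages: the average curve is the mean true-positive rate
#' over a common grid of 1001 false-positive rates, and the macro AUC is
#' the mean of the per-class AUCs.  Classes absent from `labels` are
#' skipped with a warning.
#'
#' @param probs `n x n_classes` matrix of class probabilities.
#' @param labels integer true labels (1-based column indices of `probs`).
#' @return object of class `cceit_roc`: list with `per_class` (list of
#'   `fpr`, `tpr`, `auc` per class, `NULL` if skipped), `macro_fpr`,
#'   `macro_tpr`, `macro_auc`.
#' @export
ovr_roc_auc <- function(probs, labels) {
  stopifnot(nrow(probs) == length(labels))
  nc <- ncol(probs)
  grid <- seq(0, 1, length.out = 1001L)
  per <- vector("list", nc)
  tprs <- NULL
  aucs <- numeric(0)
  for (k in seq_len(nc)) {
    pos <- labels == k
    if (!any(pos) || all(pos)) {
      warning("ovr_roc_auc: class ", k, " not represented; skipped")
      next
    }
    r <- pROC::roc(response = factor(as.integer(pos), levels = c(0, 1)),
                   predictor = probs[, k], quiet = TRUE, direction = "<")
    fpr <- 1 - r$specificities
    tpr <- r$sensitivities
    o <- order(fpr, tpr)
    fpr <- fpr[o]; tpr <- tpr[o]
    auc_k <- as.numeric(pROC::auc(r))
    ti <- stats::approx(fpr, tpr, xout = grid, ties = max, rule = 2)$y
    per[[k]] <- list(fpr = fpr, tpr = tpr, auc = auc_k)
    tprs <- rbind(tprs, ti)
    aucs <- c(aucs, auc_k)
  }
  if (!length(aucs)) stop("ovr_roc_auc: no class represented")
  structure(list(per_class = per, macro_fpr = grid,
                 macro_tpr = colMeans(tprs), macro_auc = mean(aucs)),
            class = "cceit_roc")
}

#' @export
print.cceit_roc <- function(x, ...) {
  cat(sprintf("One-vs-rest ROC over %d classes: macro AUC %.4f\n",
              sum(!vapply(x$per_class, is.null, TRUE)), x$macro_auc))
  invisible(x)
}

#' Diagnostic value of reconstructed images
#'
#' Applies a classifier trained on ground-truth images to reconstructed
#' images and reports the macro-averaged one-vs-rest ROC AUC -- the
#' "diagnostic value" of a reconstruction method.
#'
#' @param model a trained classifier.
#' @param Y reconstructed images (`n x n_fov`, normalised conductivity
#'   scale).
#' @param labels true class labels.
#' @param fov field-of-view mask.
#' @return a [ovr_roc_auc()] result.
#' @export
diagnostic_value <- function(model, Y, labels, fov) {
  ovr_roc_auc(predict_classifier(model, Y, fov), labels)
}
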