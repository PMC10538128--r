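#' Pixel-based image quality metrics
#'
#' Computes the four pixel-to-pixel quality measures between a reference
#' image `y` and a reconstruction `y_hat`, both given as vectors on a
#' common display scale (conventionally 0-255, see [to_display_scale()]):
#' \describe{
#'   \item{rmse}{root-mean-square error `sqrt(mean((y - y_hat)^2))`.}
#'   \item{cc}{Pearson correlation coefficient; `NaN` with a warning when
#'     either image has zero variance.}
#'   \item{psnr_db}{peak signal-to-noise ratio
#'     `10 log10(MAX^2 / MSE)` with `MAX` the reference-image maximum,
#'     capped at 99 dB for identical images.}
#'   \item{ssim}{structural similarity index with global (whole-image)
#'     statistics and the standard stabilisers `c1 = (0.01 L)^2`,
#'     `c2 = (0.03 L)^2`.}
#' }
#' Variances and covariances use the population convention (divide by
#' `n`).
#'
#' @param y reference image vector.
#' @param y_hat reconstructed image vector (same length).
#' @param L dynamic range of the display scale (default 255).
#' @return list with `rmse`, `psnr_db`, `ssim`, `cc`.
#' @examples
#' m <- image_metrics(c(0, 0, 255, 255), c(0, 255, 255, 0))
#' m$rmse  # 255 / sqrt(2)
#' m$cc    # 0
#' @export
image_metrics <- function(y, y_hat, L = 255) {
  stopifnot(length(y) == length(y_hat))
  n <- length(y)
  d <- y - y_hat
  mse <- mean(d^2)
  rmse <- sqrt(mse)
  mu_y <- mean(y); mu_h <- mean(y_hat)
  v_y <- mean((y - mu_y)^2); v_h <- mean((y_hat - mu_h)^2)
  cov_yh <- mean((y - mu_y) * (y_hat - mu_h))
  cc <- if (v_y == 0 || v_h == 0) {
    warning("image_metrics: zero-variance image, correlation undefined")
    NaN
  } else cov_yh / sqrt(v_y * v_h)
  psnr <- if (mse == 0) 99 else min(99, 10 * log10(max(y)^2 / mse))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ssim <- ((2 * mu_y * mu_h + c1) * (2 * cov_yh + c2)) /
    ((mu_y^2 + mu_h^2 + c1) * (v_y + v_h + c2))
  list(rmse = rmse, psnr_db = psnr, ssim = ssim, cc = cc)
}

#' Evaluate image pairs over a dataset
#'
#' @param Y reference images, one per row.
#' @param Y_hat reconstructions, one per row (same shape).
#' @param L display-scale dynamic range.
#' @return data.frame with one row per image pair and columns `rmse`,
#'   `psnr_db`, `ssim`, `cc`.
#' @export
evaluate_images <- function(Y, Y_hat, L = 255) {
  stopifnot(all(dim(Y) == dim(Y_hat)))
  out <- lapply(seq_len(nrow(Y)), function(i)
    image_metrics(Y[i, ], Y_hat[i, ], L))
  do.call(rbind, lapply(out, as.data.frame))
}

#' Distributional summary of per-image metrics
#'
#' Mean, median and population standard deviation of each metric over a
#' dataset, together with fixed-width histograms (64 bins over the
#' observed range) describing the dispersion.
#'
#' @param reports data.frame from [evaluate_images()] (one metric per
#'   column), or a numeric vector for a single metric.
#' @return for a data.frame: list per metric with `mean`, `median`, `sd`
#'   and `histogram` (list with `breaks`, `counts`); for a vector, that
#'   single summary.
#' @export
summarize_metrics <- function(reports) {
  summ1 <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) stop("summarize_metrics: empty collection")
    n <- length(x)
    sd_pop <- sqrt(mean((x - mean(x))^2))
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = 65L)
    counts <- tabulate(pmin(64L, findInterval(x, breaks, rightmost.closed = TRUE)),
                       nbins = 64L)
    list(mean = mean(x), median = median(x), sd = sd_pop,
         histogram = list(breaks = breaks, counts = counts))
  }
  if (is.data.frame(reports)) lapply(reports, summ1) else summ1(reports)
}

#' Affine mapping to the display scale
#'
#' Maps image values to the 0-255 display scale by the affine
#' transformation determined by a fixed reference range: `lo` maps to 0 and
#' `hi` to 255.  Metric comparisons use a dataset-wide range per image
#' source (ground truth mapped by the ground-truth range, each method's
#' reconstructions by that method's range), so that methods whose output
#' lives on an arbitrary linear scale - notably back projection - are
#' compared on their rendered images, as a display would show them.
#'
#' @param x numeric vector/matrix of image values.
#' @param range length-2 numeric, the dataset-wide `(lo, hi)`; defaults to
#'   `range(x)`.
#' @param L display maximum (default 255).
#' @return rescaled values (same shape), un-clipped.
#' @export
to_display_scale <- function(x, range = NULL, L = 255) {
  if (is.null(range)) range <- base::range(x)
  if (range[2] == range[1]) stop("to_display_scale: degenerate range")
  (x - range[1]) / (range[2] - range[1]) * L
}

#' Full quality report for a reconstruction method
#'
#' Maps the ground-truth and reconstructed conductivity images to the
#' display scale (each by its own dataset-wide range), evaluates the four
#' pixel metrics per image and summarises their distributions.
#'
#' @param truth `n x N` matrix of ground-truth conductivity images.
#' @param recon `n x N` matrix of reconstructed images (same shape).
#' @param truth_range optional fixed `(lo, hi)` for the truth scale.
#' @return list with `per_image` (data.frame), `summary`
#'   (per-metric summaries) and the ranges used.
#' @export
quality_report <- function(truth, recon, truth_range = NULL) {
  if (is.null(truth_range)) truth_range <- range(truth)
  recon_range <- range(recon)
  yt <- to_display_scale(truth, truth_range)
  yr <- to_display_scale(recon, recon_range)
  per <- evaluate_images(yt, yr)
  list(per_image = per, summary = summarize_metrics(per),
       truth_range = truth_range, recon_range = recon_range)
}
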