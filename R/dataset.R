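#' Dataset composition arithmetic
#'
#' Computes the sample counts of a dataset configuration without generating
#' anything.  The default composition reproduces the study design: a
#' training set of 9375 samples for each of the 16 disease classes plus
#' 44,000 random-ellipse samples (194,000 in total) and a test set of 2500
#' samples for each of the 17 classes (42,500 in total).
#'
#' @param train_per_class training samples per disease class (classes 1-16).
#' @param train_random training samples of the random-ellipse class (17).
#' @param test_per_class test samples per class (all 17 classes).
#' @return list with `train_total`, `test_total`, `train_counts`,
#'   `test_counts` (length-17 integer vectors, by class).
#' @examples
#' dataset_composition()$train_total  # 194000
#' @export
dataset_composition <- function(train_per_class = 9375L,
                                train_random = 44000L,
                                test_per_class = 2500L) {
  if (train_per_class < 0 || train_random < 0 || test_per_class < 0)
    stop("dataset_composition: counts must be non-negative")
  train_counts <- c(rep(as.integer(train_per_class), 16L), as.integer(train_random))
  test_counts <- rep(as.integer(test_per_class), 17L)
  list(train_total = sum(train_counts), test_total = sum(test_counts),
       train_counts = train_counts, test_counts = test_counts)
}

#' Generate a labelled measurement/image dataset
#'
#' Draws phantoms for the requested class counts, simulates and normalises
#' their capacitance frames, and collects the measurement features together
#' with the ground-truth images.  Everything is deterministic under the
#' master `seed`: per-sample seeds are drawn once from it, so a dataset is
#' reproducible sample-by-sample.
#'
#' @param counts length-17 integer vector of samples per class (classes in
#'   order 1..17), or a single integer used for every class.
#' @param calib a [calibrate()] object (fixes sensor, grid and FOV).
#' @param config a [phantom_config()].
#' @param seed master integer seed.
#' @param snr_db signal-to-noise ratio of additive Gaussian measurement
#'   noise in dB; `Inf` (default) for noiseless measurements.
#' @param progress print a dot every 50 samples.
#' @return An object of class `cceit_dataset`: list with
#'   \describe{
#'     \item{y}{`n x M` real matrix, imaginary part of the normalised
#'       measurements (after noise, if any).}
#'     \item{y_clean}{the same before noise injection.}
#'     \item{g}{`n x n_fov` real matrix, normalised ground-truth
#'       conductivity contrast `sigma / sigma_high` of the FOV pixels.}
#'     \item{eps}{`n x n_fov` complex matrix of ground-truth relative
#'       permittivity (reduced grid, FOV pixels).}
#'     \item{labels}{integer class labels 1..17.}
#'     \item{seeds}{per-sample phantom seeds.}
#'     \item{snr_db}{the noise level used.}
#'   }
#' @export
generate_dataset <- function(counts, calib, config = phantom_config(),
                             seed = 1L, snr_db = Inf, progress = FALSE) {
  if (length(counts) == 1L) counts <- rep(as.integer(counts), 17L)
  stopifnot(length(counts) == 17L)
  if (any(counts < 0)) stop("generate_dataset: counts must be non-negative")
  labels <- rep(1:17, times = counts)
  n <- length(labels)
  M <- nrow(measurement_pairs(calib$sensor$K))
  fov <- calib$fov
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  y <- matrix(0, n, M)
  eps <- matrix(0 + 0i, n, fov$n_fov)
  sig_high <- calib$sigma_high
  for (s in seq_len(n)) {
    spec <- sample_phantom(labels[s], config, seed = seeds[s])
    map <- rasterize(spec, calib$grid, calib$sensor, fov, calib$omega)
    y[s, ] <- measure_map(map, calib)$y
    eps[s, ] <- fov_extract(map$recon, fov)
    if (progress && s %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  g <- conductivity_from_eps(eps, calib$omega) / sig_high
  y_clean <- y
  if (is.finite(snr_db))
    y <- add_noise(y, snr_db, seed = seed + 1L)
  structure(list(y = y, y_clean = y_clean, g = g, eps = eps,
                 labels = labels, seeds = seeds, snr_db = snr_db,
                 sigma_high = sig_high),
            class = "cceit_dataset")
}

#' @export
print.cceit_dataset <- function(x, ...) {
  cat(sprintf("CCEIT dataset: %d samples, %d measurements, %d pixels, SNR %s dB\n",
              nrow(x$y), ncol(x$y), ncol(x$g),
              if (is.finite(x$snr_db)) format(x$snr_db) else "Inf"))
  invisible(x)
}

#' Add Gaussian measurement noise at a prescribed SNR
#'
#' Adds zero-mean i.i.d. Gaussian noise to each measurement vector with
#' variance `P_signal / 10^(snr_db / 10)`, where `P_signal` is the mean
#' squared value of that vector.  `snr_db = Inf` returns the input
#' unchanged.
#'
#' @param y numeric vector, or matrix with one measurement vector per row.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed optional seed (global RNG untouched when given).
#' @return noisy vector/matrix of the same shape.
#' @export
add_noise <- function(y, snr_db, seed = NULL) {
  if (!is.finite(snr_db)) return(y)
  with_seed(seed, {
    if (is.matrix(y)) {
      p <- rowMeans(y^2)
      sdn <- sqrt(p / 10^(snr_db / 10))
      y + matrix(rnorm(length(y)), nrow(y), ncol(y)) * sdn
    } else {
      p <- mean(y^2)
      y + rnorm(length(y), sd = sqrt(p / 10^(snr_db / 10)))
    }
  })
}

#' Random learning/validation split
#'
#' Randomly partitions `1..n` into a learning and a validation part with
#' `floor(ratio * n)` learning samples; supports the per-epoch resplit used
#' during network training.
#'
#' @param n number of samples (or a `cceit_dataset`).
#' @param ratio learning fraction, in (0, 1); default 0.75.
#' @param seed optional seed.
#' @return list with integer index vectors `learn` and `val` (disjoint,
#'   exhaustive).
#' @examples
#' lengths(split_train_val(194000, 0.75, seed = 1))  # 145500, 48500
#' @export
split_train_val <- function(n, ratio = 0.75, seed = NULL) {
  if (inherits(n, "cceit_dataset")) n <- nrow(n$y)
  if (!(ratio > 0 && ratio < 1)) stop("split_train_val: ratio must be in (0,1)")
  n <- as.integer(n)
  k <- as.integer(floor(ratio * n))
  with_seed(seed, {
    perm <- sample.int(n)
    list(learn = sort(perm[seq_len(k)]), val = sort(perm[-seq_len(k)]))
  })
}

#' Measurement vector as an electrode-by-electrode matrix
#'
#' Reshapes the length `K (K - 1)` measurement vector into a `K x K` matrix
#' whose row index is the exciting electrode and column index the sensing
#' electrode, with zeros on the diagonal.  The inverse direction recovers
#' the flat vector.
#'
#' @param y measurement vector of length `K (K - 1)` (for
#'   `to_matrix_view`), or a `K x K` matrix (for `from_matrix_view`).
#' @param K number of electrodes; inferred from the length by default.
#' @return a `K x K` matrix, or the flat vector.
#' @export
to_matrix_view <- function(y, K = NULL) {
  if (is.null(K)) {
    K <- (1 + sqrt(1 + 4 * length(y))) / 2
    if (K != round(K)) stop("to_matrix_view: length is not K(K-1) for integer K")
    K <- as.integer(K)
  }
  if (length(y) != K * (K - 1L)) stop("to_matrix_view: length mismatch")
  m <- matrix(0, K, K)
  pr <- measurement_pairs(K)
  m[cbind(pr$excite, pr$sense)] <- y
  m
}

#' @rdname to_matrix_view
#' @export
from_matrix_view <- function(y, K = nrow(y)) {
  stopifnot(is.matrix(y), nrow(y) == ncol(y))
  pr <- measurement_pairs(K)
  y[cbind(pr$excite, pr$sense)]
}

#' Save / load a dataset
#'
#' Datasets are persisted as RDS files (a self-describing binary
#' serialisation shipped with R).
#'
#' @param dataset a `cceit_dataset`.
#' @param path file path.
#' @return `read_dataset` returns the dataset.
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) readRDS(path)

#' Generate ground-truth images only (no measurement simulation)
#'
#' Draws phantoms and rasterises them to normalised conductivity images
#' without solving the forward problem -- orders of magnitude faster than
#' [generate_dataset()].  Used to build the large labelled image sets on
#' which the diagnostic classifier is trained.
#'
#' @param counts length-17 integer vector (or scalar) of samples per class.
#' @param grid a [cceit_grid()].
#' @param sensor a [cceit_sensor()].
#' @param fov a [build_fov_mask()].
#' @param config a [phantom_config()].
#' @param seed master seed.
#' @param omega angular frequency.
#' @return list with `g` (`n x n_fov` normalised conductivity contrast,
#'   `sigma / sigma_high`), `labels`, `seeds`, `sigma_high`.
#' @export
generate_truth_images <- function(counts, grid, sensor = cceit_sensor(),
                                  fov = build_fov_mask(grid),
                                  config = phantom_config(), seed = 1L,
                                  omega = OMEGA_DEFAULT) {
  if (length(counts) == 1L) counts <- rep(as.integer(counts), 17L)
  stopifnot(length(counts) == 17L)
  labels <- rep(1:17, times = counts)
  n <- length(labels)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  g <- matrix(0, n, fov$n_fov)
  sigma_high <- tissue_lookup("effusion_fluid")$sigma
  for (s in seq_len(n)) {
    spec <- sample_phantom(labels[s], config, seed = seeds[s])
    map <- rasterize(spec, grid, sensor, fov, omega)
    g[s, ] <- conductivity_from_eps(fov_extract(map$recon, fov), omega) / sigma_high
  }
  list(g = g, labels = labels, seeds = seeds, sigma_high = sigma_high)
}
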