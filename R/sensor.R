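#' Circular CCEIT sensor geometry
#'
#' Builds the description of a circular capacitively coupled sensor with `K`
#' equally spaced area electrodes on the inner wall of an insulating ring,
#' surrounded by a grounded screen.  All lengths are in normalised units in
#' which the sensor interior radius is 1.
#'
#' Electrode 1 is centred at angle `pi/2` (top of the image, which for a
#' supine patient is the anterior chest wall); electrodes are numbered in
#' order of increasing angle.  Each electrode occupies a fraction
#' `coverage` of the angular pitch `2*pi/K`.  Radially the electrodes form a
#' thin arc band embedded in the insulation layer between the sensor
#' interior and the screen.
#'
#' @param K integer, number of electrodes (default 32).
#' @param coverage fraction of the angular pitch occupied by each electrode,
#'   strictly between 0 and 1.
#' @param sensor_radius interior radius of the sensor (the medium occupies
#'   radii below `sensor_radius`); the normalised default is 1.
#' @param insulation_thickness radial thickness of the insulating ring
#'   between the sensor interior and the screen.
#' @param screen_radius radius of the grounded screen; must exceed
#'   `sensor_radius + insulation_thickness` is not required, but it must
#'   exceed the outer electrode radius.
#'
#' @return An object of class `cceit_sensor`: a list with the arguments
#'   above plus `electrode_angular_spans` (a `K x 2` matrix of angular
#'   intervals in radians, increasing angle) and the radial band
#'   `electrode_r` occupied by the electrodes.
#' @examples
#' s <- cceit_sensor()
#' nrow(s$electrode_angular_spans)  # 32
#' @export
cceit_sensor <- function(K = 32L, coverage = 0.8, sensor_radius = 1.0,
                         insulation_thickness = 0.08, screen_radius = 1.1) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L)
    stop("invalid sensor geometry: need at least K = 2 electrodes")
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("invalid sensor geometry: electrode coverage must lie in (0, 1)")
  if (sensor_radius <= 0)
    stop("invalid sensor geometry: sensor_radius must be positive")
  # electrodes sit in a band inside the insulation ring
  el_in  <- sensor_radius + 0.15 * insulation_thickness
  el_out <- sensor_radius + 0.75 * insulation_thickness
  if (screen_radius <= el_out)
    stop("invalid sensor geometry: screen_radius must exceed the outer electrode radius")
  pitch <- 2 * pi / K
  half <- coverage * pitch / 2
  centres <- pi / 2 + (seq_len(K) - 1L) * pitch
  spans <- cbind(lo = centres - half, hi = centres + half)
  structure(list(
    K = K, coverage = coverage, sensor_radius = sensor_radius,
    insulation_thickness = insulation_thickness, screen_radius = screen_radius,
    electrode_r = c(el_in, el_out),
    electrode_angular_spans = spans
  ), class = "cceit_sensor")
}

#' @export
print.cceit_sensor <- function(x, ...) {
  cat(sprintf("CCEIT sensor: %d electrodes, coverage %.2f, r_sensor %.3g, r_screen %.3g\n",
              x$K, x$coverage, x$sensor_radius, x$screen_radius))
  invisible(x)
}

#' Simulation and reconstruction grids
#'
#' A square Cartesian grid centred on the sensor, spanning
#' `[-half_extent, half_extent]^2` where `half_extent` defaults to the
#' screen radius, so the grid exactly contains the screen circle.  The fine
#' grid (`fine_n` cells per side) carries the field simulation; the
#' reconstruction grid (`recon_n`, default 64) carries the images, and
#' `fine_n` must be an integer multiple of `recon_n`.
#'
#' Matrix convention: row 1 is the top of the image (largest `y`, the
#' anterior chest wall of a supine patient); pixel centres lie at
#' `(-L + (col - 0.5) h, L - (row - 0.5) h)` with `h = 2 L / n`.
#'
#' @param fine_n fine-grid side length in cells.
#' @param recon_n reconstruction-grid side length in pixels (default 64).
#' @param half_extent half-width of the square domain; defaults to the
#'   screen radius of `sensor`.
#' @param sensor a [cceit_sensor()] used only for the default extent.
#' @return An object of class `cceit_grid` with fields `fine_n`, `recon_n`,
#'   `half_extent`, `h_fine`, `h_recon` and `block` (`fine_n / recon_n`).
#' @examples
#' g <- cceit_grid(fine_n = 128)
#' g$block  # 2
#' @export
cceit_grid <- function(fine_n = 256L, recon_n = 64L,
                       half_extent = NULL, sensor = cceit_sensor()) {
  fine_n <- as.integer(fine_n); recon_n <- as.integer(recon_n)
  if (fine_n %% recon_n != 0L)
    stop("fine_n must be an integer multiple of recon_n")
  if (is.null(half_extent)) half_extent <- sensor$screen_radius
  structure(list(
    fine_n = fine_n, recon_n = recon_n, half_extent = half_extent,
    h_fine = 2 * half_extent / fine_n, h_recon = 2 * half_extent / recon_n,
    block = fine_n %/% recon_n
  ), class = "cceit_grid")
}

#' Pixel-centre coordinates of a square grid
#'
#' @param grid a [cceit_grid()].
#' @param which `"fine"` or `"recon"`.
#' @return list with vectors `x` (by column, left to right) and `y` (by row,
#'   top to bottom), each of length `n`, plus matrices `X`, `Y` of pixel
#'   centre coordinates in matrix (row, col) layout.
#' @keywords internal
grid_centres <- function(grid, which = c("fine", "recon")) {
  which <- match.arg(which)
  n <- if (which == "fine") grid$fine_n else grid$recon_n
  L <- grid$half_extent
  h <- 2 * L / n
  x <- -L + (seq_len(n) - 0.5) * h
  y <- L - (seq_len(n) - 0.5) * h
  list(x = x, y = y,
       X = matrix(x, n, n, byrow = TRUE),
       Y = matrix(y, n, n))
}

# Calibrated default field-of-view radius, in reconstruction-grid pixel
# units.  Together with the half-pixel offset of the circle centre along the
# row axis (FOV_CENTRE_OFFSET_PX), it yields exactly 1856 in-view pixels on
# the 64 x 64 grid; a circle concentric with the pixel-centre lattice cannot
# produce that count.
FOV_RADIUS_PX <- 24.3
FOV_CENTRE_OFFSET_PX <- c(0, 0.5)  # (x, y) in pixel units

#' Default field-of-view radius for a grid
#'
#' The calibrated default radius (24.3 reconstruction pixels) converted to
#' physical units.
#' @param grid a [cceit_grid()].
#' @return radius in grid length units.
#' @export
fov_default_radius <- function(grid) FOV_RADIUS_PX * grid$h_recon

#' Field-of-view centre in physical units
#' @keywords internal
fov_centre <- function(grid) FOV_CENTRE_OFFSET_PX * grid$h_recon

#' Circular field-of-view mask on the reconstruction grid
#'
#' A reconstruction pixel belongs to the field of view (FOV) iff its centre
#' lies strictly inside the FOV circle.  At the calibrated default radius
#' the 64 x 64 grid has exactly 1856 in-view pixels.  The index map is a
#' bijection between in-FOV pixel coordinates and flat indices `1..n_fov`,
#' in column-major order over the mask matrix.
#'
#' @param grid a [cceit_grid()].
#' @param fov_radius FOV radius in physical units; default
#'   [fov_default_radius()].
#' @return An object of class `cceit_fov`: list with `mask` (logical
#'   `recon_n x recon_n`), `n_fov`, `index` (integer matrix, `NA` outside the
#'   FOV, flat index inside), `pix` (two-column matrix of (row, col) for
#'   each flat index) and `radius`.
#' @examples
#' fov <- build_fov_mask(cceit_grid(fine_n = 64))
#' fov$n_fov  # 1856
#' @export
build_fov_mask <- function(grid, fov_radius = fov_default_radius(grid)) {
  cc <- grid_centres(grid, "recon")
  ctr <- fov_centre(grid)
  d2 <- (cc$X - ctr[1])^2 + (cc$Y - ctr[2])^2
  mask <- d2 < fov_radius^2
  idx <- matrix(NA_integer_, grid$recon_n, grid$recon_n)
  idx[mask] <- seq_len(sum(mask))
  pix <- which(mask, arr.ind = TRUE)
  pix <- pix[order(idx[mask]), , drop = FALSE]
  structure(list(mask = mask, n_fov = sum(mask), index = idx,
                 pix = pix, radius = fov_radius),
            class = "cceit_fov")
}

#' Embed an FOV vector into a full reconstruction image
#'
#' @param values numeric/complex vector of length `fov$n_fov`.
#' @param fov a [build_fov_mask()] object.
#' @param fill value used outside the field of view (default 0).
#' @return a `recon_n x recon_n` matrix.
#' @export
fov_embed <- function(values, fov, fill = 0) {
  stopifnot(length(values) == fov$n_fov)
  img <- matrix(fill + 0 * values[1], nrow(fov$mask), ncol(fov$mask))
  img[fov$mask] <- values
  img
}

#' Extract the FOV vector from a full reconstruction image
#' @param img a `recon_n x recon_n` matrix.
#' @param fov a [build_fov_mask()] object.
#' @return vector of length `fov$n_fov` in flat-index order.
#' @export
fov_extract <- function(img, fov) img[fov$mask]

#' Number of mutual-capacitance measurements
#'
#' With `K` electrodes there are `K (K - 1) / 2` electrode pairs; if every
#' pair is measured twice with the excitation and sensing roles exchanged
#' there are `K (K - 1)` measurements (992 for `K = 32`).
#'
#' @param K integer number of electrodes (at least 2).
#' @param with_repetitions logical; count ordered pairs if `TRUE`.
#' @return integer measurement count.
#' @examples
#' measurement_count(32, TRUE)   # 992
#' measurement_count(4, FALSE)   # 6
#' @export
measurement_count <- function(K, with_repetitions = TRUE) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("measurement_count: K must be an integer >= 2")
  if (with_repetitions) K * (K - 1L) else (K * (K - 1L)) %/% 2L
}

#' Ordered measurement pair index
#'
#' The canonical ordering of the measurement vector: for each exciting
#' electrode `i = 1..K` all sensing electrodes `j != i` in increasing order.
#' Both `(i, j)` and `(j, i)` are present.
#'
#' @param K integer number of electrodes.
#' @return data.frame with integer columns `excite` and `sense`, of
#'   `K (K - 1)` rows.
#' @export
measurement_pairs <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("measurement_pairs: K must be an integer >= 2")
  i <- rep(seq_len(K), each = K)
  j <- rep(seq_len(K), K)
  keep <- i != j
  data.frame(excite = i[keep], sense = j[keep])
}
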