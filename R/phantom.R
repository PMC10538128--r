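#' Tissue dielectric properties at 100 MHz
#'
#' Relative permittivity and conductivity of the thorax model components at
#' the 100 MHz excitation frequency.  Lung tissue values are given for the
#' inspiration and expiration phases; pneumothorax regions carry the
#' properties of air and pleural-effusion regions those of low-haematocrit
#' blood-like fluid.
#'
#' @return data.frame with columns `tissue`, `eps_r` (relative
#'   permittivity) and `sigma` (conductivity, S/m).
#' @export
cceit_tissues <- function() {
  data.frame(
    tissue = c("air", "lung_inspiration", "lung_expiration",
               "pneumothorax_air", "effusion_fluid",
               "electrode_metal", "isolation_plastic",
               "spine", "heart", "aorta", "fat"),
    eps_r = c(1, 31.6, 67.1, 1, 70, 1, 2, 10.53, 90.8, 90.8, 12.7),
    sigma = c(0, 0.306, 0.559, 1e-15, 1.4, 0.0643, 1e-21, 0.0643,
              0.733, 0.733, 0.068),
    stringsAsFactors = FALSE
  )
}

tissue_lookup <- function(name) {
  tb <- cceit_tissues()
  i <- match(name, tb$tissue)
  if (anyNA(i)) stop("unknown tissue: ", paste(name[is.na(i)], collapse = ", "))
  tb[i, , drop = FALSE]
}

#' Complex relative permittivity of a tissue
#'
#' `eps = eps_r - 1i * sigma / (omega * eps0)`, the relative-permittivity
#' convention for a medium with conductivity `sigma` at angular frequency
#' `omega`.  The imaginary part is non-positive for passive media.
#'
#' @param eps_r relative permittivity (dimensionless), or a data.frame row
#'   from [cceit_tissues()].
#' @param sigma conductivity in S/m (ignored when `eps_r` is a data.frame).
#' @param omega angular frequency in rad/s (default `2 pi 1e8`).
#' @return complex relative permittivity.
#' @examples
#' complex_permittivity(12.7, 0)                      # 12.7+0i
#' Im(complex_permittivity(70, 1.4))                  # about -251.7
#' @export
complex_permittivity <- function(eps_r, sigma = 0, omega = OMEGA_DEFAULT) {
  if (is.data.frame(eps_r)) { sigma <- eps_r$sigma; eps_r <- eps_r$eps_r }
  if (!all(is.finite(omega)) || any(omega <= 0))
    stop("complex_permittivity: omega must be positive")
  complex(real = eps_r, imaginary = -sigma / (omega * EPS0))
}

#' Conductivity from a complex relative permittivity
#' @param eps complex relative permittivity.
#' @param omega angular frequency in rad/s.
#' @return conductivity in S/m.
#' @export
conductivity_from_eps <- function(eps, omega = OMEGA_DEFAULT) {
  -Im(eps) * omega * EPS0
}

#' The 17 thorax condition classes
#'
#' Classes 1 to 16 enumerate the combinations of left and right lung status
#' among healthy, pneumothorax, pleural effusion and hydropneumothorax;
#' class 17 replaces the organs with random ellipses.
#'
#' @return data.frame with columns `class`, `left`, `right`.
#' @export
cceit_classes <- function() {
  st <- c("healthy", "pneumothorax", "effusion", "hydro")
  grid <- expand.grid(right = st, left = st,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(class = 1:17,
                    left = c(grid$left, "random"),
                    right = c(grid$right, "random"),
                    stringsAsFactors = FALSE)
  out
}

#' Elliptical region
#'
#' @param center numeric length-2 centre `(x, y)` in field-of-view radius
#'   units (the FOV circle has radius 1 in these units).
#' @param semi numeric length-2 semi-axes `(a, b)`.
#' @param rot rotation in radians (counter-clockwise).
#' @param tissue tissue name, see [cceit_tissues()].
#' @return list of class `cceit_ellipse`.
#' @export
ellipse_region <- function(center, semi, rot = 0, tissue = "fat") {
  if (any(semi <= 0)) stop("ellipse_region: semi-axes must be positive")
  structure(list(center = as.numeric(center), semi = as.numeric(semi),
                 rot = rot, tissue = tissue), class = "cceit_ellipse")
}

#' Point-in-ellipse test
#' @param X,Y coordinate matrices or vectors (same units as the ellipse).
#' @param ell a [ellipse_region()].
#' @return logical array of the same shape as `X`.
#' @export
in_ellipse <- function(X, Y, ell) {
  dx <- X - ell$center[1]; dy <- Y - ell$center[2]
  co <- cos(ell$rot); si <- sin(ell$rot)
  u <- co * dx + si * dy
  v <- -si * dx + co * dy
  (u / ell$semi[1])^2 + (v / ell$semi[2])^2 <= 1
}

# Deterministic sample lattice over an ellipse (used for area fractions).
ellipse_lattice <- function(ell, m = 81L) {
  r <- max(ell$semi)
  s <- seq(-r, r, length.out = m)
  X <- outer(rep(1, m), s) + ell$center[1]
  Y <- outer(s, rep(1, m)) + ell$center[2]
  keep <- in_ellipse(X, Y, ell)
  cbind(x = X[keep], y = Y[keep])
}

#' Phantom randomisation configuration
#'
#' Defaults for the thorax phantom geometry and its per-sample
#' randomisation.  All coordinates are in field-of-view radius units.
#'
#' @param center_jitter half-width of the uniform jitter applied to every
#'   organ centre coordinate.
#' @param rot_jitter half-width (radians) of the uniform rotation jitter.
#' @param scale_range range of the uniform per-axis size scale factor.
#' @param disease_frac range of the fraction of a lung converted to the
#'   diseased region.
#' @param hydro_split_q range of the quantile used to place the horizontal
#'   air/fluid split of a hydropneumothorax.
#' @param n_random_ellipses range (integers) of the number of ellipses in
#'   the random-ellipse class.
#' @param random_semi range of the random-ellipse semi-axes.
#' @return list of class `cceit_phantom_config`.
#' @export
phantom_config <- function(center_jitter = 0.05, rot_jitter = 10 * pi / 180,
                           scale_range = c(0.9, 1.1),
                           disease_frac = c(0.1, 0.6),
                           hydro_split_q = c(0.3, 0.7),
                           n_random_ellipses = c(1L, 4L),
                           random_semi = c(0.05, 0.3)) {
  structure(list(center_jitter = center_jitter, rot_jitter = rot_jitter,
                 scale_range = scale_range, disease_frac = disease_frac,
                 hydro_split_q = hydro_split_q,
                 n_random_ellipses = n_random_ellipses,
                 random_semi = random_semi),
            class = "cceit_phantom_config")
}

# Baseline (unjittered) organ geometry, FOV-radius units.
base_organs <- function(respiration = "inspiration") {
  lung <- paste0("lung_", respiration)
  list(
    fat     = ellipse_region(c(0, 0), c(0.95, 0.78), 0, "fat"),
    lung_l  = ellipse_region(c(-0.42, 0.02), c(0.34, 0.48),  15 * pi / 180, lung),
    lung_r  = ellipse_region(c(0.42, 0.02), c(0.34, 0.48), -15 * pi / 180, lung),
    heart   = ellipse_region(c(0.10, -0.05), c(0.22, 0.26), 0, "heart"),
    aorta   = ellipse_region(c(-0.02, -0.25), c(0.06, 0.06), 0, "aorta"),
    spine   = ellipse_region(c(0, -0.60), c(0.13, 0.10), 0, "spine")
  )
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

jitter_organ <- function(ell, cfg) {
  ctr <- ell$center + runif(2, -cfg$center_jitter, cfg$center_jitter)
  rot <- ell$rot + runif(1, -cfg$rot_jitter, cfg$rot_jitter)
  semi <- ell$semi * runif(2, cfg$scale_range[1], cfg$scale_range[2])
  ellipse_region(ctr, semi, rot, ell$tissue)
}

# Shift a copy of the lung ellipse along direction u until the fraction of
# the lung lying outside it reaches `frac` (bisection on the shift length).
solve_clip <- function(lung, u, frac) {
  pts <- ellipse_lattice(lung)
  f_at <- function(t) {
    clip <- ellipse_region(lung$center + t * u, lung$semi, lung$rot, lung$tissue)
    mean(!in_ellipse(pts[, 1], pts[, 2], clip))
  }
  lo <- 0; hi <- 2 * sum(lung$semi)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (f_at(mid) < frac) lo <- mid else hi <- mid
  }
  t <- (lo + hi) / 2
  ellipse_region(lung$center + t * u, lung$semi, lung$rot, lung$tissue)
}

sample_disease <- function(lung, kind, cfg) {
  if (kind == "healthy") return(NULL)
  frac <- runif(1, cfg$disease_frac[1], cfg$disease_frac[2])
  sgn <- if (lung$center[1] > 0) 1 else -1
  u <- switch(kind,
    pneumothorax = c(-0.4 * sgn, -1),  # clip moved down and towards centre
    effusion     = c(-0.4 * sgn, 1),   # clip moved up and towards centre
    hydro        = -lung$center        # clip moved towards the model centre
  )
  if (sum(u^2) < 1e-12) u <- c(0, -1)
  u <- u / sqrt(sum(u^2))
  clip <- solve_clip(lung, u, frac)
  split_y <- NA_real_
  if (kind == "hydro") {
    pts <- ellipse_lattice(lung)
    dis <- !in_ellipse(pts[, 1], pts[, 2], clip)
    q <- runif(1, cfg$hydro_split_q[1], cfg$hydro_split_q[2])
    split_y <- if (any(dis)) unname(quantile(pts[dis, 2], q)) else lung$center[2]
  }
  list(kind = kind, clip = clip, split_y = split_y, frac = frac)
}

#' Sample a randomised thorax phantom
#'
#' Draws a phantom specification for the requested condition class.  Organ
#' centres, rotations and per-axis sizes are drawn independently from
#' uniform ranges; disease clipping ellipses are drawn per class; the
#' respiration phase is drawn uniformly from inspiration/expiration.  The
#' same `seed` always reproduces an identical specification.
#'
#' @param class_label integer 1..17, see [cceit_classes()].
#' @param config a [phantom_config()].
#' @param seed optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return An object of class `cceit_phantom`: list with `organs` (named
#'   list of [ellipse_region()]), `disease_left`, `disease_right` (`NULL` or
#'   a list with `kind`, `clip`, `split_y`), `respiration`, `class_label`,
#'   `rng_seed` and, for class 17, `random_ellipses`.
#' @export
sample_phantom <- function(class_label, config = phantom_config(), seed = NULL) {
  cls <- cceit_classes()
  if (!(class_label %in% cls$class)) stop("unknown class label: ", class_label)
  with_seed(seed, {
    respiration <- sample(c("inspiration", "expiration"), 1)
    organs <- lapply(base_organs(respiration), jitter_organ, cfg = config)
    spec <- list(organs = organs, disease_left = NULL, disease_right = NULL,
                 respiration = respiration, class_label = as.integer(class_label),
                 rng_seed = seed, random_ellipses = NULL)
    if (class_label == 17L) {
      n <- sample(seq(config$n_random_ellipses[1], config$n_random_ellipses[2]), 1)
      tset <- setdiff(cceit_tissues()$tissue, c("air"))
      spec$random_ellipses <- lapply(seq_len(n), function(i) {
        rr <- 0.85 * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
        ellipse_region(c(rr * cos(th), rr * sin(th)),
                       runif(2, config$random_semi[1], config$random_semi[2]),
                       runif(1, 0, pi), sample(tset, 1))
      })
    } else {
      row <- cls[cls$class == class_label, ]
      spec$disease_left <- sample_disease(organs$lung_l, row$left, config)
      spec$disease_right <- sample_disease(organs$lung_r, row$right, config)
    }
    structure(spec, class = "cceit_phantom")
  })
}

#' @export
print.cceit_phantom <- function(x, ...) {
  cls <- cceit_classes()[x$class_label, ]
  cat(sprintf("CCEIT phantom: class %d (left %s / right %s), %s\n",
              x$class_label, cls$left, cls$right, x$respiration))
  invisible(x)
}

#' Partition a lung into kept tissue, air and fluid
#'
#' Applies a pleural disease to a lung ellipse on arbitrary coordinate
#' matrices.  Pixels inside `lung` and inside `clip` keep the lung tissue;
#' the rest of the lung becomes air (pneumothorax), effusion fluid
#' (effusion), or is split by the horizontal line `split_y` into air above
#' and fluid below (hydropneumothorax).  `y` increases towards the top of
#' the image (anterior wall of a supine patient).
#'
#' @param lung,clip [ellipse_region()] objects in the same units as `X, Y`.
#' @param kind one of `"pneumothorax"`, `"effusion"`, `"hydro"`.
#' @param split_y horizontal split level (hydro only).
#' @param X,Y coordinate arrays.
#' @return list of logical arrays `kept`, `air`, `fluid` (disjoint, union =
#'   inside of `lung`).
#' @export
apply_disease <- function(lung, kind, clip, split_y = NA_real_, X, Y) {
  inl <- in_ellipse(X, Y, lung)
  inc <- in_ellipse(X, Y, clip)
  if (!any(inl & inc))
    stop("degenerate phantom: clipping ellipse does not overlap the lung")
  kept <- inl & inc
  rest <- inl & !inc
  air <- fluid <- array(FALSE, dim = dim(as.matrix(X)))
  if (kind == "pneumothorax") air <- rest
  else if (kind == "effusion") fluid <- rest
  else if (kind == "hydro") { air <- rest & (Y > split_y); fluid <- rest & !(Y > split_y) }
  else stop("unknown disease kind: ", kind)
  list(kept = kept, air = air, fluid = fluid)
}

#' Rasterise a phantom to a complex permittivity map
#'
#' Paints the phantom onto the fine simulation grid (pixel tissue decided by
#' the pixel centre; later regions override earlier ones: background air,
#' fat-bounded thorax, lungs with their disease partitions, heart, aorta,
#' spine) and converts tissues to complex relative permittivity at `omega`.
#' The reduced map is the block average of the fine map.
#'
#' @param spec a [sample_phantom()] specification.
#' @param grid a [cceit_grid()].
#' @param sensor a [cceit_sensor()] (sets the field-of-view placement).
#' @param fov optional [build_fov_mask()]; built from `grid` by default.
#' @param omega angular frequency, rad/s.
#' @return An object of class `cceit_map`: list with complex matrices
#'   `fine` (`fine_n^2`) and `recon` (`recon_n^2`), the tissue index matrix
#'   `tissue_fine`, `omega`, `grid` and the FOV used.
#' @export
rasterize <- function(spec, grid, sensor = cceit_sensor(),
                      fov = build_fov_mask(grid), omega = OMEGA_DEFAULT) {
  cc <- grid_centres(grid, "fine")
  ctr <- fov_centre(grid)
  R <- fov$radius
  X <- (cc$X - ctr[1]) / R            # FOV-radius units
  Y <- (cc$Y - ctr[2]) / R
  tb <- cceit_tissues()
  tid <- function(name) match(name, tb$tissue)
  tis <- matrix(tid("air"), grid$fine_n, grid$fine_n)

  paint <- function(ell, clipmask = NULL) {
    m <- in_ellipse(X, Y, ell)
    if (!is.null(clipmask)) m <- m & clipmask
    tis[m] <<- tid(ell$tissue)
    m
  }

  org <- spec$organs
  thorax <- paint(org$fat)
  if (spec$class_label == 17L) {
    for (ell in spec$random_ellipses) paint(ell, thorax)
  } else {
    for (side in c("l", "r")) {
      lung <- org[[paste0("lung_", side)]]
      dis <- spec[[if (side == "l") "disease_left" else "disease_right"]]
      if (is.null(dis)) { paint(lung); next }
      part <- apply_disease(lung, dis$kind, dis$clip, dis$split_y, X, Y)
      tis[part$kept] <- tid(lung$tissue)
      tis[part$air] <- tid("pneumothorax_air")
      tis[part$fluid] <- tid("effusion_fluid")
    }
    paint(org$heart); paint(org$aorta); paint(org$spine)
  }

  eps_tab <- complex_permittivity(tb$eps_r, tb$sigma, omega)
  fine <- matrix(eps_tab[tis], grid$fine_n, grid$fine_n)
  recon <- block_average(fine, grid$block)
  structure(list(fine = fine, recon = recon, tissue_fine = tis,
                 omega = omega, grid = grid, fov = fov),
            class = "cceit_map")
}

#' Block-average a matrix by an integer factor
#' @param m a numeric or complex `n x n` matrix, `n` divisible by `b`.
#' @param b block size.
#' @return the `(n/b) x (n/b)` matrix of block means.
#' @export
block_average <- function(m, b) {
  if (b == 1L) return(m)
  n <- nrow(m); k <- n %/% b
  dim(m) <- c(b, k, b, k)
  out <- apply(m, c(2, 4), mean)
  matrix(out, k, k)
}

#' Ground-truth conductivity image of a phantom map
#'
#' @param map a [rasterize()] result.
#' @param which `"recon"` or `"fine"`.
#' @return real matrix of conductivity values (S/m).
#' @export
conductivity_image <- function(map, which = c("recon", "fine")) {
  which <- match.arg(which)
  conductivity_from_eps(map[[which]], map$omega)
}
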