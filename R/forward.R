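#' @import Matrix
NULL

# Cached geometric/topological data for the finite-volume solver.  Everything
# here depends only on (grid, sensor), not on the permittivity map, so it is
# computed once and reused across samples.
.cceit_cache <- new.env(parent = emptyenv())

#' Finite-volume solver context
#'
#' Precomputes the cell classification (unknown / electrode / screen), the
#' face list with unknown-cell orientation, and the assembly index arrays
#' for the fine grid of `grid` and the electrode layout of `sensor`.
#' Results are cached per geometry.
#'
#' @param grid a [cceit_grid()].
#' @param sensor a [cceit_sensor()].
#' @return list used by [solve_fields()] and friends.
#' @export
forward_context <- function(grid, sensor) {
  key <- paste(grid$fine_n, grid$recon_n, grid$half_extent,
               sensor$K, sensor$coverage, sensor$sensor_radius,
               sensor$insulation_thickness, sensor$screen_radius, sep = "|")
  if (!is.null(.cceit_cache[[key]])) return(.cceit_cache[[key]])

  n <- grid$fine_n
  cc <- grid_centres(grid, "fine")
  r <- sqrt(cc$X^2 + cc$Y^2)
  ang <- atan2(cc$Y, cc$X)

  cellclass <- matrix(0L, n, n)             # 0 unknown, -1 screen, k electrode
  border <- matrix(FALSE, n, n)
  border[1, ] <- border[n, ] <- TRUE; border[, 1] <- border[, n] <- TRUE
  cellclass[r >= sensor$screen_radius | border] <- -1L
  band <- r >= sensor$electrode_r[1] & r <= sensor$electrode_r[2]
  pitch <- 2 * pi / sensor$K
  half <- sensor$coverage * pitch / 2
  for (k in seq_len(sensor$K)) {
    ck <- pi / 2 + (k - 1L) * pitch
    d <- (ang - ck + pi) %% (2 * pi) - pi
    sel <- band & abs(d) <= half & cellclass == 0L
    if (!any(sel)) stop("forward_context: electrode ", k,
                        " has no cells on this grid; refine fine_n")
    cellclass[sel] <- k
  }

  unknown <- cellclass == 0L
  unk_id <- matrix(NA_integer_, n, n)
  unk_id[unknown] <- seq_len(sum(unknown))

  # faces between horizontally and vertically adjacent cells
  idx <- matrix(seq_len(n * n), n, n)
  fa <- c(as.vector(idx[, -n]), as.vector(idx[-n, ]))
  fb <- c(as.vector(idx[, -1]), as.vector(idx[-1, ]))
  ca <- cellclass[fa]; cb <- cellclass[fb]
  # orient so that an unknown cell (if any) sits on side a
  swap <- ca != 0L & cb == 0L
  tmp <- fa[swap]; fa[swap] <- fb[swap]; fb[swap] <- tmp
  ca <- cellclass[fa]; cb <- cellclass[fb]
  type <- ifelse(ca == 0L & cb == 0L, 1L, ifelse(ca == 0L, 2L, 3L)) # uu, ud, dd

  medium <- r < sensor$sensor_radius & unknown
  eps_plastic <- complex_permittivity(tissue_lookup("isolation_plastic"))

  ctx <- list(grid = grid, sensor = sensor, n = n,
              cellclass = cellclass, unknown = unknown, unk_id = unk_id,
              n_unknown = sum(unknown), medium = medium,
              fa = fa, fb = fb, type = type,
              uu = which(type == 1L), ud = which(type == 2L), dd = which(type == 3L),
              eps_plastic = eps_plastic)
  ctx$ua_uu <- unk_id[fa[ctx$uu]]; ctx$ub_uu <- unk_id[fb[ctx$uu]]
  ctx$ua_ud <- unk_id[fa[ctx$ud]]; ctx$db_ud <- cellclass[fb[ctx$ud]]
  .cceit_cache[[key]] <- ctx
  ctx
}

# Complex permittivity per fine cell as seen by the solver: the phantom map
# inside the sensor interior, isolation plastic elsewhere (the electrode and
# screen cells are potential-clamped; their value only enters through faces
# shared with unclamped neighbours, where the insulating filler applies).
solver_eps <- function(map, ctx) {
  eps <- rep(ctx$eps_plastic, ctx$n^2)
  eps[ctx$medium] <- map$fine[ctx$medium]
  eps
}

face_transmissibility <- function(eps, ctx) {
  ea <- eps[ctx$fa]; eb <- eps[ctx$fb]
  T <- 2 * ea * eb / (ea + eb)          # harmonic mean, uu faces
  T[ctx$ud] <- 2 * ea[ctx$ud]           # Dirichlet value held at the face
  T
}

assemble_system <- function(T, ctx) {
  uu <- ctx$uu; ud <- ctx$ud
  i <- c(ctx$ua_uu, ctx$ub_uu, ctx$ua_uu, ctx$ub_uu, ctx$ua_ud)
  j <- c(ctx$ua_uu, ctx$ub_uu, ctx$ub_uu, ctx$ua_uu, ctx$ua_ud)
  x <- c(T[uu], T[uu], -T[uu], -T[uu], T[ud])
  U <- ctx$n_unknown
  if (is.complex(x)) {
    Ar <- sparseMatrix(i = i, j = j, x = Re(x), dims = c(U, U))
    Ai <- sparseMatrix(i = i, j = j, x = Im(x), dims = c(U, U))
    list(Ar = Ar, Ai = Ai, complex = TRUE)
  } else {
    list(Ar = sparseMatrix(i = i, j = j, x = x, dims = c(U, U)),
         Ai = NULL, complex = FALSE)
  }
}

rhs_matrix <- function(T, ctx, excites) {
  U <- ctx$n_unknown
  b <- matrix(if (is.complex(T)) 0 + 0i else 0, U, length(excites))
  for (s in seq_along(excites)) {
    sel <- ctx$ud[ctx$db_ud == excites[s]]
    if (length(sel)) {
      rows <- ctx$unk_id[ctx$fa[sel]]
      b[, s] <- b[, s] + as.vector(tapply2(T[sel], rows, U))
    }
  }
  b
}

# grouped sum into a dense vector (complex-safe)
tapply2 <- function(x, g, n) {
  out <- numeric(n)
  if (is.complex(x)) {
    out <- complex(real = as.vector(rowsum_safe(Re(x), g, n)),
                   imaginary = as.vector(rowsum_safe(Im(x), g, n)))
  } else out <- as.vector(rowsum_safe(x, g, n))
  out
}

rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Solve the electrostatic forward problem
#'
#' Solves the discrete `div(eps grad phi) = 0` problem on the fine grid with
#' `phi = 1` on the excited electrode(s) and `phi = 0` on all other
#' electrodes and the screen.  Lossless (purely real) permittivity maps use
#' a sparse Cholesky factorisation; lossy maps solve the equivalent real
#' block system with a sparse LU.  One factorisation serves all
#' excitations.
#'
#' @param map a [rasterize()] permittivity map (or any `cceit_map`).
#' @param sensor a [cceit_sensor()].
#' @param excite integer vector of electrodes to excite (default: all).
#' @param ctx optional precomputed [forward_context()].
#' @return An object of class `cceit_field`: list with `phi` (full-grid
#'   potentials, `fine_n^2 x length(excite)`, Dirichlet values included),
#'   `excite`, and `residual_norm` (max relative residual over the solved
#'   systems).
#' @export
solve_fields <- function(map, sensor = cceit_sensor(), excite = NULL,
                         ctx = forward_context(map$grid, sensor)) {
  if (is.null(excite)) excite <- seq_len(sensor$K)
  eps <- solver_eps(map, ctx)
  if (all(Re(eps)[ctx$medium] == 0) && all(Im(eps)[ctx$medium] == 0))
    stop("solve_fields: singular system (all-zero permittivity)")
  lossless <- all(Im(eps[ctx$medium]) == 0)
  if (lossless) eps <- Re(eps) + 0 * Re(eps) # keep complex off
  T <- face_transmissibility(if (lossless) Re(eps) else eps, ctx)
  sys <- assemble_system(T, ctx)
  b <- rhs_matrix(T, ctx, excite)
  U <- ctx$n_unknown
  if (!sys$complex) {
    ch <- Cholesky(forceSymmetric(sys$Ar), LDL = FALSE)
    x <- as.matrix(solve(ch, Re(b)))
    resid <- max(apply(sys$Ar %*% x - Re(b), 2, function(v) sqrt(sum(v^2))) /
                 apply(Re(b), 2, function(v) sqrt(sum(v^2))))
    phi_u <- x
  } else {
    B <- rbind(cbind(sys$Ar, -sys$Ai), cbind(sys$Ai, sys$Ar))
    fac <- lu(B)
    rb <- rbind(Re(b), Im(b))
    x <- as.matrix(solve(fac, rb))
    xr <- x[1:U, , drop = FALSE]; xi <- x[(U + 1):(2 * U), , drop = FALSE]
    phi_u <- xr + 1i * xi
    Ax <- (as.matrix(sys$Ar %*% xr) - as.matrix(sys$Ai %*% xi)) +
      1i * (as.matrix(sys$Ai %*% xr) + as.matrix(sys$Ar %*% xi))
    resid <- max(sqrt(colSums(Mod(Ax - b)^2)) / sqrt(colSums(Mod(b)^2)))
  }
  # embed into full-grid potentials (Dirichlet values included)
  phi <- matrix(if (sys$complex) 0 + 0i else 0, ctx$n^2, length(excite))
  phi[which(ctx$unknown), ] <- as.matrix(phi_u)
  for (s in seq_along(excite))
    phi[which(ctx$cellclass == excite[s]), s] <- 1
  structure(list(phi = phi, excite = excite, residual_norm = resid,
                 eps = eps, T = T, lossless = !sys$complex),
            class = "cceit_field")
}

# Boundary flux (positive mutual-capacitance convention) of electrode j
# under the field column `phi`, in units of eps0: C = sum over the faces of
# electrode j of T * (phi_neighbour - V_j).
electrode_flux <- function(phi, T, ctx, j, vj = 0) {
  sel_ud <- ctx$ud[ctx$db_ud == j]
  q <- sum(T[sel_ud] * (phi[ctx$fa[sel_ud]] - vj))
  dd <- ctx$dd
  if (length(dd)) {
    ca <- ctx$cellclass[ctx$fa[dd]]; cb <- ctx$cellclass[ctx$fb[dd]]
    sa <- dd[ca == j & cb != j]; sb <- dd[cb == j & ca != j]
    if (length(sa)) q <- q + sum(T[sa] * (phi[ctx$fb[sa]] - vj))
    if (length(sb)) q <- q + sum(T[sb] * (phi[ctx$fa[sb]] - vj))
  }
  q
}

#' Simulate the mutual-capacitance measurement frame
#'
#' Solves the field for every exciting electrode and integrates the normal
#' flux of `eps * E` through the closed face contour surrounding each
#' sensing electrode (Gauss law), giving the `M = K (K - 1)` ordered mutual
#' capacitances per unit depth, in farads per metre.
#'
#' @inheritParams solve_fields
#' @return An object of class `cceit_frame`: list with complex vector `c`
#'   (ordered as [measurement_pairs()]), `kind = "raw"`, `K`, and the solver
#'   residual.
#' @export
capacitance_frame <- function(map, sensor = cceit_sensor(),
                              ctx = forward_context(map$grid, sensor)) {
  K <- sensor$K
  fld <- solve_fields(map, sensor, seq_len(K), ctx)
  Cm <- matrix(if (fld$lossless) 0 else 0 + 0i, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    Cm[i, j] <- electrode_flux(fld$phi[, i], fld$T, ctx, j)
  pr <- measurement_pairs(K)
  structure(list(c = EPS0 * Cm[cbind(pr$excite, pr$sense)], kind = "raw",
                 K = K, residual_norm = fld$residual_norm),
            class = "cceit_frame")
}

#' Normalize a measurement frame between two calibration frames
#'
#' Componentwise complex normalisation `(raw - low) / (high - low)`, where
#' `low` is the empty-sensor frame and `high` the frame for the sensor
#' filled with a high-conductivity material.  The imaginary part of the
#' result is the signal used by the reconstruction methods.
#'
#' @param raw,low,high `cceit_frame` objects (or bare complex vectors) with
#'   identical ordering.
#' @return a `cceit_frame` with `kind = "normalized"`.
#' @export
normalize_frame <- function(raw, low, high) {
  cv <- function(x) if (inherits(x, "cceit_frame")) x$c else x
  r <- cv(raw); l <- cv(low); h <- cv(high)
  stopifnot(length(r) == length(l), length(l) == length(h))
  den <- h - l
  if (any(Mod(den) == 0)) stop("calibration error: high and low frames coincide componentwise")
  structure(list(c = (r - l) / den, kind = "normalized",
                 K = if (inherits(raw, "cceit_frame")) raw$K else NA_integer_),
            class = "cceit_frame")
}

#' Uniform-medium permittivity map
#'
#' @param grid a [cceit_grid()].
#' @param tissue tissue name filling the sensor interior.
#' @param omega angular frequency.
#' @return a `cceit_map` whose fine map is constant.
#' @export
uniform_map <- function(grid, tissue = "air", omega = OMEGA_DEFAULT) {
  eps <- complex_permittivity(tissue_lookup(tissue), omega = omega)
  fine <- matrix(eps, grid$fine_n, grid$fine_n)
  structure(list(fine = fine, recon = block_average(fine, grid$block),
                 tissue_fine = NULL, omega = omega, grid = grid,
                 fov = NULL), class = "cceit_map")
}

#' Sensitivity (Jacobian) matrix of the capacitance measurements
#'
#' Computes the exact Jacobian of the discrete mutual capacitances with
#' respect to the complex relative permittivity of each reconstruction
#' pixel, evaluated at a reference map (default: the empty sensor).  Using
#' the discrete adjoint identity `C(i,j) = -eps0 sum_f T_f dphi_i dphi_j`,
#' the row for measurement `(i, j)` and pixel `k` is
#' `-eps0 sum over faces of the pixel's fine cells of
#' (dT_f / d eps) dphi_i dphi_j`, which coincides with the continuum
#' field-product formula `-(1 / V_i V_j) int grad phi_i . grad phi_j dA` up
#' to discretisation.  At the lossless air reference the matrix is real.
#'
#' @param sensor a [cceit_sensor()].
#' @param grid a [cceit_grid()].
#' @param fov a [build_fov_mask()].
#' @param ref_map reference map (default [uniform_map()] with air).
#' @param ctx optional [forward_context()].
#' @return An object of class `cceit_sensitivity`: list with `S`
#'   (`M x n_fov`, real at a lossless reference), `S_norm` (rows scaled to
#'   unit maximum absolute value), `pairs`, `fov`, `ref` description.
#' @export
sensitivity_matrix <- function(sensor = cceit_sensor(), grid, fov,
                               ref_map = uniform_map(grid),
                               ctx = forward_context(grid, sensor)) {
  K <- sensor$K
  fld <- solve_fields(ref_map, sensor, seq_len(K), ctx)
  eps <- fld$eps
  # face-difference of the potentials, all excitations at once
  Dphi <- fld$phi[ctx$fa, , drop = FALSE] - fld$phi[ctx$fb, , drop = FALSE]

  # map fine cells to FOV flat indices
  blk <- grid$block
  n <- ctx$n
  rows <- ((seq_len(n) - 1L) %/% blk) + 1L
  pixrow <- matrix(rows, n, n); pixcol <- matrix(rows, n, n, byrow = TRUE)
  fovidx <- fov$index[cbind(as.vector(pixrow), as.vector(pixcol))]
  cell_ok <- !is.na(fovidx) & as.vector(ctx$medium)

  # dT/deps weights for each face side restricted to FOV medium cells
  ea <- eps[ctx$fa]; eb <- eps[ctx$fb]
  wa <- 2 * (eb / (ea + eb))^2          # uu faces, derivative wrt side a
  wb <- 2 * (ea / (ea + eb))^2
  wa[ctx$ud] <- 2                       # half-cell Dirichlet face
  wb[ctx$ud] <- 0
  wa[ctx$dd] <- 0; wb[ctx$dd] <- 0
  keep_a <- cell_ok[ctx$fa]; keep_b <- cell_ok[ctx$fb]
  ii <- c(fovidx[ctx$fa[keep_a]], fovidx[ctx$fb[keep_b]])
  jj <- c(which(keep_a), which(keep_b))
  xxr <- c(Re(wa)[keep_a], Re(wb)[keep_b])
  cplx <- !fld$lossless
  Mr <- sparseMatrix(i = ii, j = jj, x = xxr, dims = c(fov$n_fov, length(ctx$fa)))
  Mi <- if (cplx) sparseMatrix(i = ii, j = jj,
                               x = c(Im(wa)[keep_a], Im(wb)[keep_b]),
                               dims = c(fov$n_fov, length(ctx$fa))) else NULL

  pr <- measurement_pairs(K)
  S <- matrix(if (cplx) 0 + 0i else 0, nrow(pr), fov$n_fov)
  done <- new.env(parent = emptyenv())
  for (m in seq_len(nrow(pr))) {
    i <- pr$excite[m]; j <- pr$sense[m]
    key <- paste(min(i, j), max(i, j))
    prev <- done[[key]]
    if (!is.null(prev)) { S[m, ] <- S[prev, ]; next }
    p <- Dphi[, i] * Dphi[, j]
    row <- if (cplx) {
      as.vector(Mr %*% Re(p) - Mi %*% Im(p)) +
        1i * as.vector(Mr %*% Im(p) + Mi %*% Re(p))
    } else as.vector(Mr %*% p)
    S[m, ] <- -EPS0 * row
    done[[key]] <- m
  }
  rmax <- apply(abs(S), 1, max)
  structure(list(S = S, S_norm = S / rmax, pairs = pr, fov = fov,
                 ref = "empty sensor (air)"),
            class = "cceit_sensitivity")
}

#' Calibrate the sensor: reference frames and effective sensitivity
#'
#' Computes the empty-sensor (`low`) and filled-sensor (`high`) calibration
#' frames, the sensitivity matrix at the empty reference, and the effective
#' real sensitivity `S_eff` relating the imaginary part of the normalised
#' measurements to the normalised contrast image
#' `g = (eps - eps_low) / (eps_high - eps_low)` (real, 0 for the empty
#' medium, 1 for the calibration material):
#' `S_eff[m, k] = S[m, k] * Im((eps_high - eps_low) / (c_high - c_low)[m])`.
#'
#' @param sensor a [cceit_sensor()].
#' @param grid a [cceit_grid()].
#' @param fov a [build_fov_mask()].
#' @param high_tissue calibration material for the `high` frame (default
#'   the pleural-effusion fluid).
#' @param omega angular frequency.
#' @return An object of class `cceit_calibration`: list with frames
#'   `c_low`, `c_high`, scalars `eps_low`, `eps_high`, `sigma_high`,
#'   matrices `S` (raw Jacobian), `S_eff`, `S_lbp` (row-normalised
#'   `S_eff`), plus `sensor`, `grid`, `fov`.
#' @export
calibrate <- function(sensor = cceit_sensor(), grid = cceit_grid(),
                      fov = build_fov_mask(grid),
                      high_tissue = "effusion_fluid", omega = OMEGA_DEFAULT) {
  ctx <- forward_context(grid, sensor)
  low_map <- uniform_map(grid, "air", omega)
  high_map <- uniform_map(grid, high_tissue, omega)
  c_low <- capacitance_frame(low_map, sensor, ctx)
  c_high <- capacitance_frame(high_map, sensor, ctx)
  sens <- sensitivity_matrix(sensor, grid, fov, low_map, ctx)
  eps_low <- complex_permittivity(tissue_lookup("air"), omega = omega)
  eps_high <- complex_permittivity(tissue_lookup(high_tissue), omega = omega)
  den <- Mod(c_high$c - c_low$c)
  if (any(den == 0)) stop("calibrate: degenerate calibration span")
  # y is the positive normalised conductance (0 empty, ~1 filled), so the
  # effective sensitivity carries the matching sign: loss contrast g raises y.
  scale <- -Im(eps_high - eps_low) / den
  S_eff <- Re(sens$S) * scale
  rmax <- apply(abs(S_eff), 1, max)
  structure(list(c_low = c_low, c_high = c_high,
                 eps_low = eps_low, eps_high = eps_high,
                 sigma_high = conductivity_from_eps(eps_high, omega),
                 S = sens$S, S_eff = S_eff, S_lbp = S_eff / rmax,
                 sensitivity = sens, sensor = sensor, grid = grid, fov = fov,
                 omega = omega),
            class = "cceit_calibration")
}

#' Measurement feature vector of a phantom map
#'
#' Simulates the raw frame and returns the normalised imaginary component
#' used by all reconstruction methods: the imaginary (conductance-like)
#' parts of the mutual capacitances, normalised by the magnitude of the
#' calibration span, `y = (Im c_low - Im c) / |c_high - c_low|` (zero for
#' the empty sensor, approaching 1 for the filled sensor).  The
#' magnitude denominator is bounded away from zero for every electrode
#' pair, whereas the imaginary part of the span itself changes sign for
#' remote pairs.  (The componentwise complex normalisation of
#' [normalize_frame()] is also returned; its imaginary part vanishes at
#' both calibration points and is not used as the reconstruction feature.)
#'
#' @param map a [rasterize()] map.
#' @param calib a [calibrate()] object.
#' @return list with `y` (real vector length M), the normalised complex
#'   frame `frame`, and the raw frame `raw`.
#' @export
measure_map <- function(map, calib) {
  ctx <- forward_context(calib$grid, calib$sensor)
  raw <- capacitance_frame(map, calib$sensor, ctx)
  nf <- normalize_frame(raw, calib$c_low, calib$c_high)
  y <- (Im(calib$c_low$c) - Im(raw$c)) / Mod(calib$c_high$c - calib$c_low$c)
  list(y = y, frame = nf, raw = raw)
}

#' Coaxial two-ring capacitor on the fine grid
#'
#' A validation case with a closed-form answer: a disk electrode of radius
#' `r_inner` at potential 1 inside a grounded ring at `r_outer`, uniform
#' dielectric in between.  The analytic capacitance per unit depth is
#' `2 pi eps0 eps_r / log(r_outer / r_inner)`.  Returns the simulated
#' capacitance together with the area-equivalent radii of the rasterised
#' electrodes (the discrete conductors are staircase polygons; their
#' area-equivalent radii are the geometrically faithful arguments for the
#' analytic formula).
#'
#' @param fine_n grid resolution.
#' @param r_inner,r_outer nominal radii.
#' @param eps_r relative permittivity of the dielectric.
#' @param half_extent half-width of the square domain.
#' @return list with `C` (F/m), `C_analytic_nominal`, `C_analytic_effective`,
#'   `r_inner_eff`, `r_outer_eff`.
#' @export
coaxial_capacitance <- function(fine_n = 256L, r_inner = 0.35, r_outer = 0.95,
                                eps_r = 1, half_extent = 1.0) {
  n <- as.integer(fine_n)
  L <- half_extent; h <- 2 * L / n
  x <- -L + (seq_len(n) - 0.5) * h
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(rev(x), n, n)
  r <- sqrt(X^2 + Y^2)
  inner <- r <= r_inner
  outer <- r >= r_outer
  unknown <- !(inner | outer)
  unk_id <- matrix(NA_integer_, n, n); unk_id[unknown] <- seq_len(sum(unknown))
  idx <- matrix(seq_len(n * n), n, n)
  fa <- c(as.vector(idx[, -n]), as.vector(idx[-n, ]))
  fb <- c(as.vector(idx[, -1]), as.vector(idx[-1, ]))
  ua <- unknown[fa]; ub <- unknown[fb]
  swap <- !ua & ub; tmp <- fa[swap]; fa[swap] <- fb[swap]; fb[swap] <- tmp
  ua <- unknown[fa]; ub <- unknown[fb]
  Tf <- rep(eps_r, length(fa)); Tf[ua & !ub] <- 2 * eps_r  # Dirichlet at face
  uu <- ua & ub; ud <- ua & !ub
  i <- c(unk_id[fa[uu]], unk_id[fb[uu]], unk_id[fa[uu]], unk_id[fb[uu]], unk_id[fa[ud]])
  j <- c(unk_id[fa[uu]], unk_id[fb[uu]], unk_id[fb[uu]], unk_id[fa[uu]], unk_id[fa[ud]])
  xv <- c(Tf[uu], Tf[uu], -Tf[uu], -Tf[uu], Tf[ud])
  U <- sum(unknown)
  A <- sparseMatrix(i = i, j = j, x = xv, dims = c(U, U))
  b <- numeric(U)
  sel <- which(ud & inner[fb])
  for (s in sel) b[unk_id[fa[s]]] <- b[unk_id[fa[s]]] + Tf[s]
  phi_u <- as.vector(solve(Cholesky(forceSymmetric(A), LDL = FALSE), b))
  phi <- numeric(n * n); phi[which(unknown)] <- phi_u; phi[inner] <- 1
  selo <- which(ud & outer[fb])
  C <- EPS0 * sum(Tf[selo] * phi[fa[selo]])
  r_in_eff <- sqrt(sum(inner) * h^2 / pi)
  r_out_eff <- sqrt((n^2 - sum(outer)) * h^2 / pi)
  list(C = C,
       C_analytic_nominal = 2 * pi * EPS0 * eps_r / log(r_outer / r_inner),
       C_analytic_effective = 2 * pi * EPS0 * eps_r / log(r_out_eff / r_in_eff),
       r_inner_eff = r_in_eff, r_outer_eff = r_out_eff)
}
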