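#' Linear back projection
#'
#' One-step reconstruction `eps = eps_min + t(S_norm) %*% c_n`, where
#' `S_norm` is the row-normalised sensitivity matrix (each row scaled to
#' unit maximum absolute value) and `c_n` the normalised measurement
#' vector.  The result is on the arbitrary back-projection scale; it is
#' mapped to the display scale before metric computation.
#'
#' @param S_norm `M x N` row-normalised sensitivity matrix.
#' @param c_n measurement vector of length `M`.
#' @param eps_min offset added to every pixel; defaults to 0, the value of
#'   the empty-sensor reference image on the normalised conductivity scale.
#' @return numeric vector of length `N`.
#' @examples
#' S <- t(matrix(c(1, 0, 0, 1, 1, 1), 2, 3))  # 2 x 3 toy, transposed below
#' lbp(t(S), c(0.2, 0.5), 1)                  # 1.2 1.5 1.7
#' @export
lbp <- function(S_norm, c_n, eps_min = 0) {
  if (ncol(S_norm) == length(c_n) && nrow(S_norm) != length(c_n))
    stop("lbp: S_norm must be M x N with length(c_n) == M")
  if (nrow(S_norm) != length(c_n)) stop("lbp: dimension mismatch")
  as.vector(eps_min + crossprod(S_norm, c_n))
}

#' Tikhonov-regularised pseudoinverse reconstruction
#'
#' Solves `(t(S) S + alpha I) eps = t(S) c_n` by a symmetric
#' positive-definite (Cholesky) solve.  The default regularisation
#' parameter is `alpha = 1e-9`.
#'
#' @param S `M x N` sensitivity matrix.
#' @param c_n measurement vector of length `M` (or an `M x B` matrix of
#'   several measurement vectors in columns).
#' @param alpha regularisation parameter, strictly positive.
#' @return numeric vector of length `N` (or `N x B` matrix).
#' @export
tpinv <- function(S, c_n, alpha = 1e-9) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("tpinv: alpha must be strictly positive")
  cn <- if (is.matrix(c_n)) c_n else matrix(c_n, ncol = 1)
  if (nrow(cn) != nrow(S)) stop("tpinv: dimension mismatch")
  G <- crossprod(S)
  diag(G) <- diag(G) + alpha
  R <- chol(G)
  out <- backsolve(R, forwardsolve(t(R), crossprod(S, cn)))
  if (is.matrix(c_n)) out else as.vector(out)
}

#' Batch algebraic reconstruction
#'
#' Applies LBP or TPINV to each measurement vector (rows of `Y`).  LBP uses
#' the row-normalised sensitivity matrix; TPINV uses the raw Jacobian in
#' physical units (farads per unit relative permittivity) exactly as the
#' one-step formula prescribes, with the default `alpha = 1e-9`.  Both
#' outputs live on a method-specific linear scale that is mapped to the
#' display range before metric computation (see [quality_report()]).
#'
#' @param calib a [calibrate()] object.
#' @param Y `n x M` matrix of measurement features (normalised imaginary
#'   components), one sample per row.
#' @param method `"lbp"` or `"tpinv"`.
#' @param alpha TPINV regularisation (default `1e-9`).
#' @param eps_min LBP offset (default 0).
#' @return `n x N` matrix of reconstructed images.
#' @export
reconstruct_algebraic <- function(calib, Y, method = c("lbp", "tpinv"),
                                  alpha = 1e-9, eps_min = 0) {
  method <- match.arg(method)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  switch(method,
    lbp = t(eps_min + crossprod(calib$S_lbp, t(Y))),
    tpinv = t(tpinv(Re(calib$S), t(Y), alpha)))
}
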