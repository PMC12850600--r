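# Fiber-response (Standard Model) forward model: three-compartment
# axially-symmetric kernel, its Legendre rotational invariants K_l(b|xi),
# and spherical-convolution signal synthesis.

#' Standard Model kernel parameters
#'
#' Three compartments sharing one fiber orientation: an intra-axonal
#' "stick" (signal fraction `f`, axial diffusivity `Da`), an axially
#' symmetric extra-axonal tensor (fraction 1 - f - fw, diffusivities
#' `Depar`, `Deperp`), and isotropic free water (fraction `fw`, diffusivity
#' `Dw` frozen at 3 um^2/ms).
#'
#' @param f intra-axonal fraction in [0, 1].
#' @param Da intra-axonal axial diffusivity (um^2/ms).
#' @param Depar,Deperp extra-axonal axial / radial diffusivities (um^2/ms).
#' @param fw free-water fraction; f + fw <= 1.
#' @param Dw free-water diffusivity (constant, kept in metadata).
#' @return list of class `sm_params`.
#' @export
sm_params <- function(f, Da, Depar, Deperp, fw = 0, Dw = 3) {
  if (f < 0 || fw < 0 || f + fw > 1 + 1e-12)
    stop("sm_params: need 0 <= f, fw and f + fw <= 1")
  if (any(c(Da, Depar, Deperp) <= 0)) stop("sm_params: diffusivities must be > 0")
  if (Deperp > Depar + 1e-12) stop("sm_params: Deperp must be <= Depar")
  structure(list(f = f, Da = Da, Depar = Depar, Deperp = Deperp,
                 fw = fw, Dw = Dw), class = "sm_params")
}

#' Standard Model kernel response
#'
#' \deqn{K(b, \zeta) = f e^{-b D_a \zeta^2} + f_w e^{-b D_w}
#'   + (1 - f - f_w) e^{-b (D_{e\|} - D_{e\perp})\zeta^2 - b D_{e\perp}}}
#' where \eqn{\zeta = \hat g \cdot \hat n} is the cosine between encoding
#' and fiber. Vectorized over `b` and `zeta` (recycled).
#'
#' @param b b-value(s) (ms/um^2), >= 0.
#' @param zeta cosine(s) in [-1, 1].
#' @param xi `sm_params`.
#' @param ... extra scalar protocol parameters (TE, t, ...); accepted and
#'   ignored by the Standard Model kernel.
#' @export
sm_kernel <- function(b, zeta, xi, ...) {
  stopifnot(inherits(xi, "sm_params"), all(b >= 0))
  z2 <- zeta^2
  xi$f * exp(-b * xi$Da * z2) +
    xi$fw * exp(-b * xi$Dw) +
    (1 - xi$f - xi$fw) * exp(-b * (xi$Depar - xi$Deperp) * z2 - b * xi$Deperp)
}

#' Rotational invariants of the kernel
#'
#' \eqn{K_l(b|\xi) = \int_0^1 K(b,\zeta|\xi) P_l(\zeta) d\zeta} by
#' fixed-order Gauss-Legendre quadrature. \eqn{K_0(0) = 1} and
#' \eqn{K_l(0) = 0} for l > 0; \eqn{K_2 < 0} for anisotropic kernels.
#'
#' @param b b-value vector (ms/um^2).
#' @param xi `sm_params`.
#' @param lmax maximum even degree (default 2; up to 8 for simulation).
#' @param order quadrature order.
#' @return length(b) x (lmax/2 + 1) matrix, columns l = 0, 2, ...
#' @export
kernel_invariants <- function(b, xi, lmax = 2, order = 64) {
  gl <- gauss_legendre(order, 0, 1)
  ls <- seq(0, lmax, by = 2)
  # K(b_i, zeta_q): length(b) x order
  Kv <- outer(b, gl$nodes, function(bb, zz) sm_kernel(bb, zz, xi))
  out <- sapply(ls, function(l)
    Kv %*% (gl$weights * assoc_legendre(l, 0, gl$nodes)))
  out <- matrix(out, length(b), length(ls))
  colnames(out) <- paste0("l", ls)
  out
}

# Vectorized library evaluation: K_l(b_i | xi_j) matrices for a table of
# parameter draws. Loops over quadrature nodes so memory stays N_b x N_xi.
sm_invariant_matrices <- function(b, xi_table, lmax = 2, order = 64) {
  gl <- gauss_legendre(order, 0, 1)
  ls <- seq(0, lmax, by = 2)
  Nb <- length(b)
  Nxi <- nrow(xi_table)
  f <- xi_table$f; fw <- xi_table$fw
  fe <- 1 - f - fw
  Da <- xi_table$Da; Dpar <- xi_table$Depar; Dperp <- xi_table$Deperp
  Dw <- if ("Dw" %in% names(xi_table)) xi_table$Dw else rep(3, Nxi)
  K <- lapply(ls, function(l) matrix(0, Nb, Nxi))
  names(K) <- paste0("l", ls)
  Pl <- lapply(ls, function(l) assoc_legendre(l, 0, gl$nodes))
  ew <- exp(outer(-b, Dw)) # free water: zeta-independent
  for (q in seq_len(order)) {
    z2 <- gl$nodes[q]^2
    # N_b x N_xi kernel values at this node
    Kq <- exp(outer(-b * z2, Da)) * rep(f, each = Nb) +
      ew * rep(fw, each = Nb) +
      exp(outer(-b, Dperp) + outer(-b * z2, Dpar - Dperp)) * rep(fe, each = Nb)
    for (il in seq_along(ls))
      K[[il]] <- K[[il]] + (gl$weights[q] * Pl[[il]][q]) * Kq
  }
  K
}

#' Closed-form K_0 of a pure stick (erf expression)
#'
#' \eqn{\int_0^1 e^{-bD\zeta^2} d\zeta = \sqrt{\pi/(4bD)}\,\mathrm{erf}(\sqrt{bD})};
#' fast path / oracle for quadrature validation.
#' @param b b-value(s); @param D axial diffusivity.
#' @export
stick_k0 <- function(b, D) {
  x <- b * D
  out <- rep(1, length(x))
  nz <- x > 0
  erf <- function(u) 2 * stats::pnorm(u * sqrt(2)) - 1
  out[nz] <- sqrt(pi / (4 * x[nz])) * erf(sqrt(x[nz]))
  out
}

#' Spherical-convolution signal synthesis
#'
#' \eqn{S_k = \sum_{lm} K_l(b_k|\xi)\, p_{lm} Y_{lm}(\hat g_k)}: the
#' SH-product form of the convolution of the kernel with the fODF.
#'
#' @param xi `sm_params`.
#' @param fodf `sh_coefficients` (p_00 = 1 for a normalized fODF).
#' @param b b-value per measurement.
#' @param g K x 3 matrix of unit directions per measurement.
#' @param lmax maximum even degree used (defaults to the fODF's).
#' @export
convolve_signal <- function(xi, fodf, b, g, lmax = fodf$lmax) {
  stopifnot(lmax <= fodf$lmax)
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  idx <- sh_index_table(lmax)
  Kl <- kernel_invariants(b, xi, lmax) # K x n_l
  Y <- sh_basis(g, lmax)               # K x ncoef
  p <- fodf$coef[seq_len(nrow(idx))]
  drop((Y * Kl[, idx$l / 2 + 1, drop = FALSE]) %*% p)
}

#' Batch spherical-convolution synthesis under one protocol
#'
#' Vectorized [convolve_signal()] for a table of kernel parameters and a
#' matrix of fODF coefficients sharing one (b, g) protocol.
#'
#' @param xi_table data.frame of Standard Model parameter draws.
#' @param fodf_coef nvox x K matrix of real Racah coefficients.
#' @param b,g protocol (length-K b-values, K x 3 directions).
#' @param lmax maximum even degree.
#' @return nvox x K signal matrix.
#' @export
convolve_signal_table <- function(xi_table, fodf_coef, b, g, lmax = 2) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  idx <- sh_index_table(lmax)
  Kl <- sm_invariant_matrices(b, xi_table, lmax = lmax) # per l: K x nvox
  Y <- sh_basis(g, lmax)
  S <- matrix(0, nrow(xi_table), length(b))
  ls <- seq(0, lmax, by = 2)
  for (il in seq_along(ls)) {
    sel <- idx$l == ls[il]
    A <- fodf_coef[, sel, drop = FALSE] %*% t(Y[, sel, drop = FALSE])
    S <- S + A * t(Kl[[il]])
  }
  S
}

#' Brute-force convolution by spherical quadrature (oracle)
#'
#' Direct numerical integration of the convolution of the degree-truncated
#' kernel with the fODF over the sphere; used to validate the SH product.
#'
#' @inheritParams convolve_signal
#' @param n_theta,n_phi quadrature grid size.
#' @export
convolve_signal_quadrature <- function(xi, fodf, b, g, lmax = fodf$lmax,
                                       n_theta = 40, n_phi = 80) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  quad <- sphere_quad_grid(n_theta, n_phi)
  P <- eval_expansion(fodf, quad$dirs)
  Kl <- kernel_invariants(b, xi, lmax) # per measurement
  ls <- seq(0, lmax, by = 2)
  S <- numeric(length(b))
  ct <- g %*% t(quad$dirs) # K x Q cosines
  for (k in seq_along(b)) {
    # degree-truncated kernel: sum_l (2l+1) K_l P_l(zeta)
    Kz <- numeric(ncol(ct))
    for (il in seq_along(ls))
      Kz <- Kz + (2 * ls[il] + 1) * Kl[k, il] * assoc_legendre(ls[il], 0, ct[k, ])
    S[k] <- sum(quad$weights * P * Kz)
  }
  S
}
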