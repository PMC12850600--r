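# Spherical-harmonic machinery in Racah normalization.
#
# Convention used throughout: real symmetric (even-degree) harmonics
# R_{lm}(n) with the Racah normalization
#     mean over the sphere of R_{lm} R_{l'm'} = delta_ll' delta_mm' / (2l+1),
# so that R_00 == 1 and R_{l0}(n) = P_l(cos theta). Complex accessors follow
# the Condon-Shortley phase convention. Coefficient vectors are ordered by
# even degree l ascending, then order m = -l..l.

#' Index table for even-degree spherical-harmonic coefficients
#'
#' @param lmax maximum even degree.
#' @return data.frame with columns `l` and `m`, one row per coefficient, in
#'   the package's canonical ordering (l ascending, m = -l..l).
#' @export
sh_index_table <- function(lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  ls <- seq(0, lmax, by = 2)
  data.frame(
    l = rep(ls, times = 2 * ls + 1),
    m = unlist(lapply(ls, function(l) seq(-l, l)))
  )
}

# associated Legendre P_l^m(x) WITHOUT the Condon-Shortley phase, m >= 0.
# Standard stable recursion; x vectorized.
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, l >= m)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    fact <- seq(1, 2 * m - 1, by = 2) # (2m-1)!!
    pmm <- prod(fact) * somx2^m
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Evaluate a single real Racah-normalized spherical harmonic
#'
#' Real basis: \eqn{R_{l0} = P_l(\cos\theta)}; for \eqn{m > 0},
#' \eqn{R_{lm} = \sqrt{2 (l-m)!/(l+m)!} P_l^m(\cos\theta)\cos m\phi} and
#' \eqn{R_{l,-m}} carries \eqn{\sin m\phi}. Under the uniform probability
#' measure on the sphere these satisfy
#' \eqn{\langle R_{lm} R_{l'm'} \rangle = \delta_{ll'}\delta_{mm'}/(2l+1)}.
#'
#' @param l even degree; @param m order, |m| <= l.
#' @param dirs unit direction(s): length-3 vector or n x 3 matrix.
#' @return numeric vector of values.
#' @export
eval_sh <- function(l, m, dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  if (abs(m) > l) stop("eval_sh: |m| must be <= l")
  ct <- clamp(dirs[, 3], -1, 1)
  am <- abs(m)
  P <- assoc_legendre(l, am, ct)
  if (m == 0) return(P)
  phi <- atan2(dirs[, 2], dirs[, 1])
  # sqrt(2 (l-m)!/(l+m)!)
  nrm <- sqrt(2 / prod((l - am + 1):(l + am)))
  if (m > 0) nrm * P * cos(am * phi) else nrm * P * sin(am * phi)
}

#' Basis matrix of all even-degree real harmonics up to lmax
#'
#' @param dirs n x 3 matrix of unit directions.
#' @param lmax maximum even degree.
#' @return n x K matrix, columns ordered as [sh_index_table()].
#' @export
sh_basis <- function(dirs, lmax) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  idx <- sh_index_table(lmax)
  Y <- matrix(0, nrow(dirs), nrow(idx))
  for (k in seq_len(nrow(idx))) Y[, k] <- eval_sh(idx$l[k], idx$m[k], dirs)
  colnames(Y) <- sprintf("l%dm%+d", idx$l, idx$m)
  Y
}

#' Container for even-degree SH coefficients
#'
#' @param coef numeric vector in canonical ordering (see [sh_index_table()]).
#' @param lmax maximum even degree (inferred when missing).
#' @return object of class `sh_coefficients`.
#' @export
sh_coefficients <- function(coef, lmax = NULL) {
  if (is.null(lmax)) {
    # K = sum_{even l<=lmax} (2l+1); invert
    lmax <- 0
    while (nrow(sh_index_table(lmax)) < length(coef)) lmax <- lmax + 2
  }
  idx <- sh_index_table(lmax)
  stopifnot(length(coef) == nrow(idx))
  structure(list(coef = as.numeric(coef), lmax = lmax, normalization = "racah"),
            class = "sh_coefficients")
}

#' @export
print.sh_coefficients <- function(x, ...) {
  cat(sprintf("<sh_coefficients> lmax=%d (%d real Racah coefficients)\n",
              x$lmax, length(x$coef)))
  invisible(x)
}

#' Evaluate an SH expansion at directions
#' @param coeffs `sh_coefficients`.
#' @param dirs n x 3 unit directions.
#' @export
eval_expansion <- function(coeffs, dirs) {
  drop(sh_basis(dirs, coeffs$lmax) %*% coeffs$coef)
}

#' Complex-basis accessor
#'
#' Returns the complex Racah coefficients \eqn{c_{lm}} (Condon-Shortley
#' phase) equivalent to the stored real basis: the expansions agree pointwise
#' and \eqn{\sum_m |c_{lm}|^2 = \sum_m p_{lm}^2} per degree.
#' @param coeffs `sh_coefficients`.
#' @return complex vector in the same (l, m) ordering.
#' @export
sh_complex <- function(coeffs) {
  idx <- sh_index_table(coeffs$lmax)
  p <- coeffs$coef
  cc <- complex(real = p) # m = 0 entries already correct
  for (k in which(idx$m != 0)) {
    l <- idx$l[k]; m <- idx$m[k]; am <- abs(m)
    kp <- which(idx$l == l & idx$m == am)
    km <- which(idx$l == l & idx$m == -am)
    if (m > 0) cc[k] <- (-1)^am * complex(real = p[kp], imaginary = -p[km]) / sqrt(2)
    else       cc[k] <- complex(real = p[kp], imaginary = p[km]) / sqrt(2)
  }
  cc
}

#' Real coefficients from complex Racah coefficients
#' @param cc complex vector in canonical ordering.
#' @param lmax maximum even degree.
#' @export
sh_from_complex <- function(cc, lmax) {
  idx <- sh_index_table(lmax)
  p <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    l <- idx$l[k]; m <- idx$m[k]; am <- abs(m)
    if (m == 0) { p[k] <- Re(cc[k]); next }
    kp <- which(idx$l == l & idx$m == am)
    km <- which(idx$l == l & idx$m == -am)
    if (m > 0) p[k] <- Re(((-1)^am * cc[kp] + cc[km]) / sqrt(2))
    else       p[k] <- Re(complex(imaginary = 1) * ((-1)^am * cc[kp] - cc[km]) / sqrt(2))
  }
  sh_coefficients(p, lmax)
}

#' Project samples of an even function on [0,1] onto a Legendre polynomial
#'
#' Computes \eqn{\int_0^1 f(\zeta) P_l(\zeta) d\zeta} by fixed-order
#' Gauss-Legendre quadrature (exact for polynomial f of matching degree).
#'
#' @param f function of zeta (vectorized), or numeric vector of samples at
#'   the quadrature nodes returned by `gauss_legendre(order, 0, 1)`.
#' @param l even degree.
#' @param order quadrature order (default 64).
#' @export
legendre_project <- function(f, l, order = 64) {
  stopifnot(l %% 2 == 0)
  gl <- gauss_legendre(order, 0, 1)
  fv <- if (is.function(f)) f(gl$nodes) else f
  stopifnot(length(fv) == order)
  Pl <- assoc_legendre(l, 0, gl$nodes)
  sum(gl$weights * fv * Pl)
}

#' Product quadrature grid on the unit sphere
#'
#' Gauss-Legendre in cos(theta) times uniform trapezoid in phi; weights sum
#' to 1 (uniform probability measure). Exact for spherical polynomials of
#' degree < min(2 n_theta, n_phi).
#'
#' @param n_theta,n_phi numbers of nodes.
#' @return list(dirs = n x 3 matrix, weights = n-vector summing to 1).
#' @export
sphere_quad_grid <- function(n_theta = 24, n_phi = 48) {
  key <- sprintf("sq_%d_%d", n_theta, n_phi)
  g <- .pipe_cache[[key]]
  if (!is.null(g)) return(g)
  gl <- gauss_legendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$nodes, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_theta)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$weights / 2, each = n_phi) / n_phi
  g <- list(dirs = dirs, weights = w)
  .pipe_cache[[key]] <- g
  g
}

# rotation matrix for ZYZ Euler angles: R = Rz(alpha) Ry(beta) Rz(gamma)
#' @export
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rotate SH coefficients by a ZYZ rotation
#'
#' Applies the per-degree (Wigner) rotation in the real Racah basis so that
#' the rotated expansion satisfies \eqn{f'(n) = f(R^{-1} n)}. The per-degree
#' block matrices are obtained by exact quadrature collocation (machine
#' precision for lmax <= 8); degree invariants are preserved.
#'
#' @param coeffs `sh_coefficients`.
#' @param euler numeric length-3 (alpha, beta, gamma) ZYZ angles, or a 3 x 3
#'   rotation matrix.
#' @export
wigner_rotate <- function(coeffs, euler) {
  R <- if (is.matrix(euler)) euler else euler_zyz(euler[1], euler[2], euler[3])
  M <- sh_rotation_matrix(R, coeffs$lmax)
  sh_coefficients(drop(M %*% coeffs$coef), coeffs$lmax)
}

#' Per-degree rotation matrix in the real Racah basis
#' @param R 3 x 3 rotation matrix.
#' @param lmax maximum even degree.
#' @return K x K block-diagonal matrix acting on coefficient vectors.
#' @export
sh_rotation_matrix <- function(R, lmax) {
  idx <- sh_index_table(lmax)
  # quadrature exact for products of two degree-lmax harmonics
  g <- sphere_quad_grid(lmax + 2, 2 * lmax + 4)
  Y <- .pipe_cache[[sprintf("shb_%d", lmax)]]
  if (is.null(Y)) {
    Y <- sh_basis(g$dirs, lmax)
    .pipe_cache[[sprintf("shb_%d", lmax)]] <- Y
  }
  Yr <- sh_basis(g$dirs %*% R, lmax) # rows: R^{-1} n_q  (n_q %*% R == t(t(R) %*% n))
  M <- t(Y * g$weights) %*% Yr
  M * (2 * idx$l + 1) # row scaling by (2l+1)
}

#' Uniform random rotations on SO(3)
#'
#' ZYZ Euler angles drawn from the invariant (Haar) measure
#' \eqn{\propto \sin\beta \, d\alpha \, d\beta \, d\gamma}.
#'
#' @param count number of rotations.
#' @param seed optional integer seed.
#' @return data.frame with columns alpha, beta, gamma.
#' @export
sample_so3_uniform <- function(count, seed = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    alpha = stats::runif(count, 0, 2 * pi),
    beta = acos(stats::runif(count, -1, 1)),
    gamma = stats::runif(count, 0, 2 * pi)
  )
}

#' Rotational invariant of one degree
#'
#' \eqn{p_l = \sqrt{\sum_m p_{lm}^2 / (2l+1)}}; with this convention
#' \eqn{p_0 = 1} for a normalized fODF, and \eqn{p_l} is invariant under
#' [wigner_rotate()].
#'
#' @param coeffs `sh_coefficients` (or bare coefficient vector).
#' @param l even degree.
#' @export
rotational_invariant <- function(coeffs, l) {
  if (inherits(coeffs, "sh_coefficients")) {
    idx <- sh_index_table(coeffs$lmax)
    stopifnot(l <= coeffs$lmax)
    v <- coeffs$coef[idx$l == l]
  } else {
    v <- coeffs
    stopifnot(length(v) == 2 * l + 1)
  }
  sqrt(sum(v^2) / (2 * l + 1))
}
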