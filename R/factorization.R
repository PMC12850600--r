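# Kernel library over (b, xi), per-degree SVD factorization
# K_l(b|xi) ~ sum_n s_n u_n(b) v_n(xi), and barycentric Chebyshev
# interpolation of the protocol basis u_n(b) on [0, bmax].

#' Uniform prior ranges used to build the SVD kernel library
#'
#' @return named list of c(lo, hi) ranges for f, Da, Depar, Deperp, fw.
#' @export
sm_library_priors <- function() {
  list(f = c(0.05, 0.95), Da = c(1, 3), Depar = c(1, 3),
       Deperp = c(0.1, 1.2), fw = c(0, 1))
}

#' Uniform prior ranges used to train the regressor
#' @export
sm_training_priors <- function() {
  list(f = c(0.05, 0.95), Da = c(0.5, 3), Depar = c(0.5, 3),
       Deperp = c(0.1, 1.5), fw = c(0, 1))
}

# draw a table of SM parameters from uniform priors, rejection-resampled to
# enforce f + fw <= 1 and Deperp <= Depar
draw_sm_table <- function(n, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (priors$f[1] + priors$fw[1] > 1)
    stop("priors unsatisfiable: min f + min fw > 1")
  draw1 <- function(m) {
    d <- data.frame(
      f = stats::runif(m, priors$f[1], priors$f[2]),
      Da = stats::runif(m, priors$Da[1], priors$Da[2]),
      Depar = stats::runif(m, priors$Depar[1], priors$Depar[2]),
      Deperp = stats::runif(m, priors$Deperp[1], priors$Deperp[2]),
      fw = stats::runif(m, priors$fw[1], priors$fw[2])
    )
    d[d$f + d$fw <= 1 & d$Deperp <= d$Depar, , drop = FALSE]
  }
  out <- draw1(n)
  while (nrow(out) < n) out <- rbind(out, draw1(n))
  out <- out[seq_len(n), ]
  rownames(out) <- NULL
  out
}

#' Chebyshev nodes of the first kind on [0, bmax]
#'
#' Roots of the degree-n Chebyshev polynomial mapped to [0, bmax], returned
#' sorted ascending.
#' @param n node count; @param bmax upper end (ms/um^2).
#' @export
cheb_nodes <- function(n, bmax = 10) {
  k <- seq_len(n)
  sort((cos((2 * k - 1) * pi / (2 * n)) + 1) * bmax / 2)
}

#' Build the kernel library K_l(b_i | xi_j)
#'
#' Samples `n_xi` parameter sets from the priors and evaluates the kernel
#' rotational invariants at the `n_b` Chebyshev nodes on [0, bmax].
#' Deterministic under `seed`.
#'
#' @param priors named list of ranges (default [sm_library_priors()]).
#' @param n_xi number of parameter samples (full-scale default 50000;
#'   tests use ~5000).
#' @param n_b number of Chebyshev nodes (full-scale 1000; tests 128).
#' @param bmax maximum b-value (ms/um^2).
#' @param lmax maximum even degree.
#' @param seed integer seed.
#' @return object of class `kernel_library`.
#' @export
build_library <- function(priors = sm_library_priors(), n_xi = 5000,
                          n_b = 128, bmax = 10, lmax = 2, seed = 1) {
  xi <- draw_sm_table(n_xi, priors, seed = seed)
  b <- cheb_nodes(n_b, bmax)
  K <- sm_invariant_matrices(b, xi, lmax = lmax)
  structure(list(lmax = lmax, b_nodes = b, bmax = bmax, xi = xi, K = K,
                 priors = priors, seed = seed, kernel = "standard_model"),
            class = "kernel_library")
}

#' @export
print.kernel_library <- function(x, ...) {
  cat(sprintf("<kernel_library> %s: %d xi samples x %d Chebyshev nodes on [0, %g], lmax=%d\n",
              x$kernel, nrow(x$xi), length(x$b_nodes), x$bmax, x$lmax))
  invisible(x)
}

#' Truncated per-degree SVD factorization of the kernel library
#'
#' For each even l, computes the SVD of the n_b x n_xi matrix of
#' \eqn{K_l(b_i|\xi_j)} and keeps `n_comp` components (or as many as an
#' energy tolerance requires). Singular vectors have a fixed sign
#' convention: the largest-magnitude element of each u_n is positive.
#'
#' @param library `kernel_library`.
#' @param n_comp integer (per-l recycled) component count; NULL = choose by
#'   `energy_tol` with cap `n_cap`.
#' @param energy_tol keep components until relative residual energy drops
#'   below this (default 1e-6).
#' @param n_cap hard cap on components per degree.
#' @return object of class `factorized_basis`: per-l s (vector), u (n_b x
#'   N_l at the Chebyshev nodes), v (n_xi x N_l), plus provenance.
#' @export
svd_factorize <- function(library, n_comp = NULL, energy_tol = 1e-6,
                          n_cap = 8) {
  ls <- seq(0, library$lmax, by = 2)
  if (!is.null(n_comp)) n_comp <- rep(n_comp, length.out = length(ls))
  fac <- list()
  recon_err <- numeric(length(ls))
  for (il in seq_along(ls)) {
    M <- library$K[[il]]
    sv <- svd(M)
    if (is.null(n_comp)) {
      tot <- sum(sv$d^2)
      resid <- 1 - cumsum(sv$d^2) / tot
      N <- min(which(resid < energy_tol)[1], n_cap)
      if (is.na(N)) N <- n_cap
    } else {
      N <- n_comp[il]
      if (N > min(dim(M))) stop("svd_factorize: requested more components than min(n_b, n_xi)")
    }
    u <- sv$u[, seq_len(N), drop = FALSE]
    v <- sv$v[, seq_len(N), drop = FALSE]
    s <- sv$d[seq_len(N)]
    # sign convention: largest |u| element positive
    for (n in seq_len(N)) {
      i <- which.max(abs(u[, n]))
      if (u[i, n] < 0) { u[, n] <- -u[, n]; v[, n] <- -v[, n] }
    }
    R <- u %*% (s * t(v))
    recon_err[il] <- max(abs(R - M))
    fac[[paste0("l", ls[il])]] <- list(l = ls[il], s = s, u = u, v = v, N = N)
  }
  structure(list(lmax = library$lmax, b_nodes = library$b_nodes,
                 bmax = library$bmax, factors = fac,
                 recon_err = stats::setNames(recon_err, paste0("l", ls)),
                 kernel = library$kernel, priors = library$priors,
                 seed = library$seed, n_xi = nrow(library$xi),
                 version = "1"),
            class = "factorized_basis")
}

#' @export
print.factorized_basis <- function(x, ...) {
  ns <- vapply(x$factors, function(f) as.integer(f$N), integer(1))
  cat(sprintf("<factorized_basis> %s, lmax=%d, components: %s; max in-library recon err %.2e\n",
              x$kernel, x$lmax,
              paste(sprintf("N_%s=%d", sub("l", "", names(ns)), ns), collapse = ", "),
              max(x$recon_err)))
  invisible(x)
}

# barycentric weights for Chebyshev points of the first kind (ascending
# order): w_k proportional to (-1)^k sin(theta_k)
cheb_bary_weights <- function(n) {
  k <- seq_len(n)
  th <- (2 * (n - k + 1) - 1) * pi / (2 * n) # theta of ascending nodes
  (-1)^(k) * sin(th)
}

#' Barycentric Chebyshev interpolation of a protocol basis function
#'
#' Evaluates \eqn{u_n^{(l)}(b)} between the stored Chebyshev nodes; exact at
#' the nodes; no extrapolation beyond [0, bmax].
#'
#' @param basis `factorized_basis`.
#' @param l even degree.
#' @param n component index (may be a vector; returns a matrix).
#' @param b evaluation b-values within [0, bmax].
#' @return length(b) x length(n) matrix (dropped to vector for single n).
#' @export
interp_u <- function(basis, l, n, b) {
  if (any(b < 0 | b > basis$bmax))
    stop(sprintf("interp_u: b out of range [0, %g] (no extrapolation)", basis$bmax))
  f <- basis$factors[[paste0("l", l)]]
  if (is.null(f)) stop("interp_u: degree not in basis")
  stopifnot(all(n >= 1 & n <= f$N))
  xs <- basis$b_nodes
  w <- cheb_bary_weights(length(xs))
  D <- outer(b, xs, `-`)
  hit <- abs(D) < 1e-13
  D[hit] <- 1 # avoid Inf; exact rows overwritten below
  C <- sweep(1 / D, 2, w, `*`)
  U <- f$u[, n, drop = FALSE]
  out <- (C %*% U) / rowSums(C)
  if (any(hit)) {
    ih <- which(rowSums(hit) > 0)
    for (i in ih) out[i, ] <- U[which(hit[i, ])[1], ]
  }
  drop(out)
}

#' Tissue-basis projections v_n(xi) for arbitrary parameters
#'
#' Evaluates the kernel invariants at the Chebyshev nodes for `xi` and
#' projects onto the stored left singular vectors:
#' \eqn{v_n = u_n^t K_l(b_{nodes}|\xi)/s_n}. For in-library samples this
#' reproduces the stored right singular vector column.
#'
#' @param basis `factorized_basis`.
#' @param xi `sm_params`, or a data.frame of parameter draws.
#' @return named list per degree of length-N (or nrow(xi) x N) projections.
#' @export
project_v <- function(basis, xi) {
  tab <- if (inherits(xi, "sm_params"))
    data.frame(f = xi$f, Da = xi$Da, Depar = xi$Depar,
               Deperp = xi$Deperp, fw = xi$fw, Dw = xi$Dw)
  else xi
  K <- sm_invariant_matrices(basis$b_nodes, tab, lmax = basis$lmax)
  out <- list()
  for (nm in names(basis$factors)) {
    f <- basis$factors[[nm]]
    ok <- f$s > 1e-14 * f$s[1]
    if (!all(ok)) warning("project_v: dropping components with negligible singular value")
    il <- which(names(basis$factors) == nm)
    V <- t(K[[il]]) %*% f$u[, ok, drop = FALSE]
    V <- sweep(V, 2, f$s[ok], `/`)
    out[[nm]] <- if (inherits(xi, "sm_params")) drop(V) else V
  }
  out
}

#' Reconstruct K_l(b | xi) from the factorized basis
#'
#' \eqn{K_l(b|\xi) \approx \sum_n s_n u_n(b) v_n(\xi)} with u interpolated
#' by [interp_u()] and v from [project_v()] (or supplied).
#'
#' @param basis `factorized_basis`.
#' @param b b-values.
#' @param xi `sm_params`.
#' @param v optional precomputed [project_v()] output.
#' @return length(b) x n_degrees matrix like [kernel_invariants()].
#' @export
reconstruct_invariants <- function(basis, b, xi = NULL, v = NULL) {
  if (is.null(v)) v <- project_v(basis, xi)
  ls <- seq(0, basis$lmax, by = 2)
  out <- matrix(0, length(b), length(ls))
  colnames(out) <- paste0("l", ls)
  for (il in seq_along(ls)) {
    f <- basis$factors[[il]]
    U <- matrix(interp_u(basis, ls[il], seq_len(f$N), b), length(b), f$N)
    out[, il] <- U %*% (f$s * v[[il]])
  }
  out
}

#' Save / load a factorized basis as versioned JSON (text, lossless)
#' @param basis `factorized_basis`; @param path file path.
#' @export
write_basis <- function(basis, path) {
  obj <- basis
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(obj$factors)) {
    f <- obj$factors[[nm]]
    f$u <- matrix(unlist(f$u), ncol = f$N)
    f$v <- matrix(unlist(f$v), ncol = f$N)
    obj$factors[[nm]] <- f
  }
  structure(obj, class = "factorized_basis")
}
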