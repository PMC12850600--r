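#' @keywords internal
"_PACKAGE"

# package-level cache for quadrature rules, STF basis tensors, solid-harmonic
# polynomial tables -- all deterministic, built on first use
.pipe_cache <- new.env(parent = emptyenv())

#' Gauss-Legendre quadrature rule
#'
#' Nodes and weights for \eqn{\int_a^b f(x) dx}, computed by the Golub-Welsch
#' eigenvalue method on the Jacobi matrix of the Legendre recurrence.
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with `nodes` and `weights`, nodes ascending.
#' @export
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1, b > a)
  key <- sprintf("gl_%d", n)
  rule <- .pipe_cache[[key]]
  if (is.null(rule)) {
    if (n == 1L) {
      rule <- list(x = 0, w = 2)
    } else {
      k <- seq_len(n - 1)
      beta <- k / sqrt(4 * k^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1)] <- beta
      J[cbind(k + 1, k)] <- beta
      e <- eigen(J, symmetric = TRUE)
      ord <- order(e$values)
      rule <- list(x = e$values[ord], w = 2 * (e$vectors[1, ord])^2)
    }
    .pipe_cache[[key]] <- rule
  }
  list(nodes = (rule$x + 1) * (b - a) / 2 + a,
       weights = rule$w * (b - a) / 2)
}

# Moore-Penrose pseudoinverse via SVD with relative singular-value cutoff.
# Returns the pinv and the effective rank / conditioning as attributes.
pinv <- function(A, rel_tol = 1e-8) {
  s <- svd(A)
  keep <- s$d > rel_tol * s$d[1]
  r <- sum(keep)
  P <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(P, "rank") <- r
  attr(P, "condition") <- if (r > 0) s$d[1] / s$d[r] else Inf
  P
}

# normalize rows of an n x 3 matrix to unit length
unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  M / nrm
}

# clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_square3 <- function(M) is.matrix(M) && all(dim(M) == c(3L, 3L)) && all(is.finite(M))
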