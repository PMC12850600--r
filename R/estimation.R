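# Voxelwise linear estimation of protocol-free gamma coefficients
# gamma_nlm = s_n v_n(xi) p_lm from measurements under per-voxel protocols,
# their rotational invariants gamma_nl, and virtual-shell resampling.

#' Column index of the factorized design
#'
#' One row per (l, n, m) column: degrees ascending, components n = 1..N_l,
#' orders m = -l..l.
#' @param basis `factorized_basis`.
#' @export
design_columns <- function(basis) {
  ls <- seq(0, basis$lmax, by = 2)
  do.call(rbind, lapply(ls, function(l) {
    N <- basis$factors[[paste0("l", l)]]$N
    expand.grid(m = seq(-l, l), n = seq_len(N), l = l)[, c("n", "l", "m")]
  }))
}

#' Protocol design matrix of the factorized signal model
#'
#' Entries \eqn{\alpha_{nlm}(b_k, \hat g_k) = u_n^{(l)}(b_k) Y_{lm}(\hat g_k)}.
#' Per-(l, n) blocks whose b-value support is too poor to separate the
#' components are flagged as deficient (QC attribute `deficient_blocks`);
#' with `strict = TRUE` a rank-deficient design raises an error.
#'
#' @param basis `factorized_basis`.
#' @param b measurement b-values (<= bmax).
#' @param g K x 3 unit directions.
#' @param strict error (rather than flag) on rank deficiency.
#' @param rel_tol singular-value cutoff for the pseudoinverse.
#' @return object of class `design_matrix`: `alpha`, cached `pinv`,
#'   `condition`, `columns`, `deficient_blocks`.
#' @export
design_matrix <- function(basis, b, g, strict = FALSE, rel_tol = 1e-8) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  stopifnot(length(b) == nrow(g))
  cols <- design_columns(basis)
  ls <- seq(0, basis$lmax, by = 2)
  Y <- sh_basis(g, basis$lmax)
  idxY <- sh_index_table(basis$lmax)
  A <- matrix(0, length(b), nrow(cols))
  for (il in seq_along(ls)) {
    l <- ls[il]
    f <- basis$factors[[paste0("l", l)]]
    U <- matrix(interp_u(basis, l, seq_len(f$N), b), length(b), f$N)
    for (n in seq_len(f$N)) for (m in seq(-l, l)) {
      jc <- which(cols$l == l & cols$n == n & cols$m == m)
      A[, jc] <- U[, n] * Y[, idxY$l == l & idxY$m == m]
    }
  }
  # block deficiency: per degree, can the n-components be separated?
  deficient <- character(0)
  for (il in seq_along(ls)) {
    l <- ls[il]
    jc <- which(cols$l == l)
    sv <- svd(A[, jc, drop = FALSE], nu = 0, nv = 0)$d
    r <- sum(sv > rel_tol * max(sv, 1e-300))
    if (r < length(jc))
      deficient <- c(deficient, sprintf("l=%d (rank %d of %d)", l, r, length(jc)))
  }
  if (strict && length(deficient))
    stop("design_matrix: rank-deficient blocks: ", paste(deficient, collapse = "; "))
  P <- pinv(A, rel_tol)
  structure(list(alpha = A, pinv = P, condition = attr(P, "condition"),
                 rank = attr(P, "rank"), columns = cols,
                 deficient_blocks = deficient),
            class = "design_matrix")
}

#' Linear gamma fit for one voxel
#'
#' \eqn{\hat\gamma = \alpha^\dagger S}: Moore-Penrose pseudoinverse solution,
#' least-squares optimal and linear in the signal.
#'
#' @param design `design_matrix`.
#' @param signal measurement vector (length = rows of the design).
#' @return named numeric vector of gamma coefficients (NA if the signal is
#'   not finite).
#' @export
fit_gamma <- function(design, signal) {
  stopifnot(length(signal) == nrow(design$alpha))
  out <- rep(NA_real_, ncol(design$alpha))
  if (all(is.finite(signal))) out <- drop(design$pinv %*% signal)
  names(out) <- sprintf("n%d_l%d_m%+d", design$columns$n, design$columns$l,
                        design$columns$m)
  out
}

#' Rotational invariants of gamma coefficients
#'
#' \eqn{\gamma_{1l} = \sqrt{\sum_m \gamma_{1lm}^2/(2l+1)}}; for n > 1 the
#' m-wise ratios to the n = 1 coefficients are averaged:
#' \eqn{\gamma_{nl} = \gamma_{1l} \langle \gamma_{nlm}/\gamma_{1lm}\rangle_m}.
#' Noiseless, this returns \eqn{s_n v_n(\xi) p_l} up to the basis sign
#' convention. Where all \eqn{|\gamma_{1lm}|} are below `floor` the
#' invariant is undefined (NA) rather than zero.
#'
#' @param gamma coefficient vector from [fit_gamma()].
#' @param columns column index (data.frame n, l, m).
#' @param floor absolute floor for the reference coefficients.
#' @return named vector gamma_nl ordered by (l, n).
#' @export
gamma_invariants <- function(gamma, columns, floor = 1e-10) {
  ls <- sort(unique(columns$l))
  out <- numeric(0)
  for (l in ls) {
    ns <- sort(unique(columns$n[columns$l == l]))
    g1 <- gamma[columns$l == l & columns$n == 1]
    g1l <- sqrt(sum(g1^2) / (2 * l + 1))
    vals <- stats::setNames(rep(NA_real_, length(ns)),
                            sprintf("n%d_l%d", ns, l))
    if (is.finite(g1l) && max(abs(g1)) >= floor) {
      vals[1] <- g1l
      ok <- abs(g1) >= floor * max(abs(g1))
      for (n in ns[ns > 1]) {
        gn <- gamma[columns$l == l & columns$n == n]
        vals[sprintf("n%d_l%d", n, l)] <- g1l * mean(gn[ok] / g1[ok])
      }
    }
    out <- c(out, vals)
  }
  out
}

# protocol hash for pseudoinverse sharing: b rounded to 1e-4, g to 1e-5
protocol_hash <- function(b, g) {
  paste(c(sprintf("%.4f", b), sprintf("%.5f", g)), collapse = ",")
}

#' Fit gamma coefficients over a volume
#'
#' Per voxel, interpolates the protocol basis onto that voxel's effective
#' encodings, forms the pseudoinverse, and projects the signal. Voxels whose
#' protocols agree after rounding (b to 1e-4, directions to 1e-5) share one
#' cached pseudoinverse.
#'
#' @param basis `factorized_basis`.
#' @param dwi nvox x K signal matrix (or 4-D array reshaped internally),
#'   b=0-normalized.
#' @param protocols `voxel_protocols`.
#' @param mask logical vector of voxels to fit (default all).
#' @return object of class `gamma_field`: `gamma` (nvox x ncoef),
#'   `invariants` (nvox x n_nl), `mask`, `condition`, `qc`, `columns`.
#' @export
fit_volume <- function(basis, dwi, protocols, mask = NULL) {
  if (length(dim(dwi)) == 4)
    dwi <- matrix(dwi, prod(dim(dwi)[1:3]), dim(dwi)[4])
  nvox <- nrow(dwi)
  stopifnot(nvox == nrow(protocols$b), ncol(dwi) == ncol(protocols$b))
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  zero_sig <- rowSums(abs(dwi), na.rm = TRUE) == 0
  bad <- !is.finite(rowSums(dwi))
  fit_mask <- mask & !zero_sig & !bad
  cols <- design_columns(basis)
  gamma <- matrix(NA_real_, nvox, nrow(cols))
  cond <- rep(NA_real_, nvox)
  inv1 <- gamma_invariants(rep(1, nrow(cols)), cols)
  invs <- matrix(NA_real_, nvox, length(inv1),
                 dimnames = list(NULL, names(inv1)))
  cache <- new.env(parent = emptyenv())
  n_unique <- 0L
  for (v in which(fit_mask)) {
    h <- protocol_hash(protocols$b[v, ], protocols$g[v, , ])
    D <- cache[[h]]
    if (is.null(D)) {
      D <- design_matrix(basis, protocols$b[v, ],
                         matrix(protocols$g[v, , ], ncol = 3))
      cache[[h]] <- D
      n_unique <- n_unique + 1L
    }
    gamma[v, ] <- drop(D$pinv %*% dwi[v, ])
    cond[v] <- D$condition
    invs[v, ] <- gamma_invariants(gamma[v, ], cols)
  }
  qc <- list(n_fit = sum(fit_mask), n_masked_out = sum(mask & !fit_mask),
             zero_signal = which(zero_sig & mask),
             nonfinite_signal = which(bad & mask),
             n_unique_protocols = n_unique)
  structure(list(gamma = gamma, invariants = invs, mask = fit_mask,
                 condition = cond, qc = qc, columns = cols,
                 basis_id = basis_id(basis)),
            class = "gamma_field")
}

# short provenance identifier of a basis (kernel, sizes, truncation, seed)
basis_id <- function(basis) {
  ns <- paste(vapply(basis$factors, function(f) as.integer(f$N), integer(1)),
              collapse = "-")
  sprintf("%s_lmax%d_nb%d_nxi%d_N%s_seed%s_v%s", basis$kernel, basis$lmax,
          length(basis$b_nodes), basis$n_xi, ns, basis$seed, basis$version)
}

#' Resample the fitted signal onto virtual shells
#'
#' Evaluates \eqn{S(b, \hat g) = \alpha(b, \hat g)\,\hat\gamma} at target
#' b-values over a uniform direction set, and projects to per-degree signal
#' invariants \eqn{S_l(b)}. This reconstructs clean shelled data from
#' arbitrarily deformed acquisitions.
#'
#' @param gfield `gamma_field` (or a bare gamma coefficient vector).
#' @param basis `factorized_basis`.
#' @param b_targets target b-values (<= bmax).
#' @param dirs optional direction set; default is an exact quadrature grid.
#' @return list with `S` (nvox x n_b x n_dirs array), `S_l` (nvox x n_b x
#'   n_degrees), `b`, `dirs`.
#' @export
resample_signal <- function(gfield, basis, b_targets, dirs = NULL) {
  gamma <- if (inherits(gfield, "gamma_field")) gfield$gamma
           else matrix(gfield, nrow = 1)
  quad <- NULL
  if (is.null(dirs)) {
    quad <- sphere_quad_grid(basis$lmax + 2, 2 * basis$lmax + 4)
    dirs <- quad$dirs
  }
  ls <- seq(0, basis$lmax, by = 2)
  nvox <- nrow(gamma)
  S <- array(NA_real_, c(nvox, length(b_targets), nrow(dirs)))
  Sl <- array(NA_real_, c(nvox, length(b_targets), length(ls)),
              dimnames = list(NULL, NULL, paste0("l", ls)))
  Y <- sh_basis(dirs, basis$lmax)
  idxY <- sh_index_table(basis$lmax)
  for (ib in seq_along(b_targets)) {
    D <- design_matrix(basis, rep(b_targets[ib], nrow(dirs)), dirs)
    Sb <- gamma %*% t(D$alpha) # nvox x ndirs
    S[, ib, ] <- Sb
    # SH projection over the direction set (exact on the quadrature grid)
    W <- if (!is.null(quad)) quad$weights else rep(1 / nrow(dirs), nrow(dirs))
    for (il in seq_along(ls)) {
      sel <- idxY$l == ls[il]
      Slm <- (Sb * rep(W, each = nvox)) %*% Y[, sel, drop = FALSE] *
        (2 * ls[il] + 1)
      Sl[, ib, il] <- sqrt(rowSums(Slm^2) / (2 * ls[il] + 1))
    }
  }
  list(S = S, S_l = Sl, b = b_targets, dirs = dirs)
}
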