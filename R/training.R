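# Train-once regression: synthetic fODFs, protocol-free training data in
# gamma space, and the cubic polynomial regressor mapping gamma features to
# kernel parameters and fODF invariants.

#' Draw Standard Model parameters from the training priors
#'
#' Independent uniform draws f ~ U(0.05, 0.95), Da ~ U(0.5, 3),
#' Depar ~ U(0.5, 3), Deperp ~ U(0.1, 1.5), fw ~ U(0, 1),
#' rejection-resampled to enforce f + fw <= 1 (and Deperp <= Depar).
#'
#' @param count number of samples.
#' @param seed integer seed.
#' @param priors prior ranges (default [sm_training_priors()]).
#' @return data.frame with one row per sample.
#' @export
sample_kernel_priors <- function(count, seed = NULL,
                                 priors = sm_training_priors()) {
  stopifnot(count >= 1)
  draw_sm_table(count, priors, seed = seed)
}

#' Sample random two-lobe fODFs
#'
#' Each fODF mixes two axially symmetric lobes with exponentially decaying
#' invariants \eqn{p_l = C\lambda^l} (C fixed by the drawn p_2, i.e.
#' \eqn{C = p_2/\lambda^2}), p_2 ~ U(0.02, 0.9), lambda ~ U(0.5, 0.9),
#' each lobe independently rotated by an SO(3)-uniform rotation, mixed with
#' weight w ~ U(0, 1). Normalization p_00 = 1 always holds.
#'
#' @param count number of fODFs.
#' @param seed integer seed.
#' @param lmax maximum even degree (default 6).
#' @return list: `coef` (count x K matrix of real Racah coefficients),
#'   `params` (data.frame of generating parameters incl. the mixture
#'   invariants p_2, p_4, p_6).
#' @export
sample_fodf <- function(count = 1, seed = NULL, lmax = 6) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sh_index_table(lmax)
  ls <- seq(2, lmax, by = 2)
  par <- data.frame(
    p2_1 = stats::runif(count, 0.02, 0.9),
    p2_2 = stats::runif(count, 0.02, 0.9),
    lambda_1 = stats::runif(count, 0.5, 0.9),
    lambda_2 = stats::runif(count, 0.5, 0.9),
    w = stats::runif(count, 0, 1)
  )
  rot <- sample_so3_uniform(2 * count)
  coef <- matrix(0, count, nrow(idx))
  coef[, idx$l == 0] <- 1
  # an axial lobe rotated to axis u has p_lm = p_l0 * Y_lm(u) with
  # p_l0 = sqrt(2l+1) p_l  (addition theorem); invariants are preserved
  axes <- t(vapply(seq_len(2 * count), function(i)
    drop(euler_zyz(rot$alpha[i], rot$beta[i], rot$gamma[i]) %*% c(0, 0, 1)),
    numeric(3)))
  Ylobe <- sh_basis(axes, lmax)
  for (k in seq_len(count)) {
    lob <- function(j) {
      p2 <- par[[paste0("p2_", j)]][k]
      lam <- par[[paste0("lambda_", j)]][k]
      C <- p2 / lam^2
      v <- numeric(nrow(idx))
      v[idx$l == 0] <- 1
      for (l in ls) {
        pl0 <- sqrt(2 * l + 1) * C * lam^l
        v[idx$l == l] <- pl0 * Ylobe[2 * (k - 1) + j, idx$l == l]
      }
      v
    }
    coef[k, ] <- par$w[k] * lob(1) + (1 - par$w[k]) * lob(2)
  }
  for (l in ls)
    par[[paste0("p", l)]] <- apply(coef[, idx$l == l, drop = FALSE], 1,
                                   function(v) sqrt(sum(v^2) / (2 * l + 1)))
  list(coef = coef, params = par, lmax = lmax)
}

# gamma coefficients s_n v_n(xi) p_lm for tables of xi draws and fODF
# coefficients; returns nvox x ncol matrix in design_columns() ordering
gamma_forward <- function(basis, xi_table, fodf_coef) {
  cols <- design_columns(basis)
  idx <- sh_index_table(max(cols$l))
  V <- project_v(basis, xi_table) # list per l: n x N
  n <- nrow(xi_table)
  G <- matrix(0, n, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    l <- cols$l[j]; nn <- cols$n[j]; m <- cols$m[j]
    f <- basis$factors[[paste0("l", l)]]
    sv <- f$s[nn] * V[[paste0("l", l)]][, nn]
    p <- fodf_coef[, which(idx$l == l & idx$m == m)]
    G[, j] <- sv * p
  }
  colnames(G) <- sprintf("n%d_l%d_m%+d", cols$n, cols$l, cols$m)
  G
}

#' Generate a protocol-free training set in gamma space
#'
#' Per sample, draws kernel parameters and a two-lobe fODF, and computes the
#' noiseless tissue coefficients \eqn{\gamma_{nlm} = s_n v_n(\xi) p_{lm}}.
#' With `noise = list(kind = "snr", snr, b, g)`, measurement noise at the
#' reference protocol is propagated through the protocol pseudoinverse:
#' features become \eqn{\alpha^\dagger(\alpha\gamma + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2 I)} with \eqn{\sigma = 1/SNR} of the
#' b=0 signal. This keeps training consistent with estimation even when the
#' reference protocol leaves parts of gamma unidentifiable.
#'
#' @param basis `factorized_basis`.
#' @param n_samples number of training samples.
#' @param noise list(kind = "none") or list(kind = "snr", snr = 50,
#'   b = ..., g = ...) giving the reference protocol.
#' @param seed integer seed.
#' @param feature_kind "gamma_nl" (rotational invariants, default) or
#'   "gamma_nlm" (raw coefficients).
#' @return object of class `training_set`: `features`, `targets`,
#'   provenance fields.
#' @export
make_training_set <- function(basis, n_samples, noise = list(kind = "none"),
                              seed = 1,
                              feature_kind = c("gamma_nl", "gamma_nlm")) {
  feature_kind <- match.arg(feature_kind)
  set.seed(seed)
  xi <- sample_kernel_priors(n_samples)
  fodf <- sample_fodf(n_samples, lmax = max(2, basis$lmax))
  G <- gamma_forward(basis, xi, fodf$coef)
  cols <- design_columns(basis)
  if (noise$kind == "snr") {
    # propagate measurement noise at the reference protocol through the
    # pseudoinverse: gamma stays exact, noise has covariance
    # sigma^2 pinv(alpha) pinv(alpha)^t
    D <- design_matrix(basis, noise$b, noise$g)
    sigma <- 1 / noise$snr
    E <- matrix(stats::rnorm(n_samples * length(noise$b), sd = sigma),
                n_samples, length(noise$b))
    G <- G + E %*% t(D$pinv)
    colnames(G) <- sprintf("n%d_l%d_m%+d", cols$n, cols$l, cols$m)
  }
  features <- if (feature_kind == "gamma_nlm") G else
    t(apply(G, 1, gamma_invariants, columns = cols))
  targets <- cbind(xi[, c("f", "Da", "Depar", "Deperp", "fw")],
                   p2 = fodf$params$p2)
  if (basis$lmax >= 4) targets$p4 <- fodf$params$p4
  structure(list(features = as.matrix(features), targets = targets,
                 feature_kind = feature_kind, noise = noise, seed = seed,
                 basis_id = basis_id(basis)),
            class = "training_set")
}

# exponent table of all monomials of total degree <= W in nf variables,
# enumerated degree by degree (C(nf + W, W) rows; never materializes the
# full (W+1)^nf lattice)
monomial_exponents <- function(nf, W) {
  rows <- list(rep(0L, nf))
  compose <- function(total, pos, current) {
    if (pos == nf) {
      current[nf] <- total
      rows[[length(rows) + 1L]] <<- current
      return(invisible())
    }
    for (k in 0:total) {
      current[pos] <- k
      compose(total - k, pos + 1L, current)
    }
  }
  for (d in seq_len(W)) compose(d, 1L, integer(nf))
  do.call(rbind, rows)
}

monomial_design <- function(X, ex) {
  n <- nrow(X)
  M <- matrix(1, n, nrow(ex))
  for (j in seq_len(nrow(ex))) for (k in which(ex[j, ] > 0))
    M[, j] <- M[, j] * X[, k]^ex[j, k]
  M
}

#' Fit the polynomial regressor
#'
#' Per-target ordinary least squares over all monomials of total degree
#' <= W in the standardized features (default cubic, W = 3). Solved by SVD
#' with a relative cutoff; deterministic.
#'
#' @param train `training_set`.
#' @param W polynomial degree.
#' @return object of class `trained_regressor`.
#' @export
fit_polynomial <- function(train, W = 3) {
  X <- train$features
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  ex <- monomial_exponents(ncol(Z), W)
  M <- monomial_design(Z, ex)
  if (nrow(M) < 2 * ncol(M))
    warning("fit_polynomial: few samples relative to monomial count")
  P <- pinv(M, rel_tol = 1e-10)
  if (attr(P, "rank") < ncol(M))
    warning("fit_polynomial: ill-conditioned normal equations, SVD cutoff applied")
  tg <- as.matrix(train$targets)[ok, , drop = FALSE]
  coefs <- P %*% tg
  resid <- M %*% coefs - tg
  rmse <- sqrt(colMeans(resid^2))
  ranges <- c(sm_training_priors(), list(p2 = c(0, 1), p4 = c(0, 1)))
  structure(list(coefficients = coefs, exponents = ex, degree = W,
                 feature_names = colnames(X),
                 standardize = list(mu = mu, sd = sdv),
                 target_names = colnames(tg),
                 clamp = ranges[colnames(tg)],
                 in_sample_rmse = rmse,
                 feature_kind = train$feature_kind, noise = train$noise,
                 seed = train$seed, basis_id = train$basis_id,
                 version = "1"),
            class = "trained_regressor")
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat(sprintf("<trained_regressor> degree %d polynomial, %d features (%s) -> %s\n",
              x$degree, length(x$feature_names), x$feature_kind,
              paste(x$target_names, collapse = ", ")))
  cat(sprintf("  in-sample RMSE: %s\n",
              paste(sprintf("%s %.3g", x$target_names, x$in_sample_rmse),
                    collapse = ", ")))
  invisible(x)
}

#' Predict tissue parameters from gamma features
#'
#' Vectorized over voxels. Predictions are clamped to the prior support
#' (QC-flagged); rows with missing features are flagged, not predicted.
#'
#' @param regressor `trained_regressor`.
#' @param features matrix (nvox x nf) of gamma features in training order,
#'   or a `gamma_field` (its invariants or gamma are used according to the
#'   regressor's feature kind).
#' @param check_basis basis id to verify provenance against (optional
#'   string or `factorized_basis`).
#' @return data.frame of predictions plus attributes `clamped` and
#'   `missing` (logical matrices / vectors).
#' @export
predict_regressor <- function(regressor, features, check_basis = NULL) {
  if (!is.null(check_basis)) {
    id <- if (inherits(check_basis, "factorized_basis")) basis_id(check_basis)
          else check_basis
    if (!identical(id, regressor$basis_id))
      stop("predict_regressor: basis/regressor provenance mismatch: ",
           id, " vs ", regressor$basis_id)
  }
  if (inherits(features, "gamma_field")) {
    if (!is.null(check_basis) && inherits(check_basis, "factorized_basis") &&
        !identical(features$basis_id, regressor$basis_id))
      stop("predict_regressor: gamma_field fitted with a different basis")
    features <- if (regressor$feature_kind == "gamma_nl") features$invariants
                else features$gamma
  }
  features <- as.matrix(features)
  stopifnot(ncol(features) == length(regressor$feature_names))
  missing <- !stats::complete.cases(features)
  out <- matrix(NA_real_, nrow(features), length(regressor$target_names),
                dimnames = list(NULL, regressor$target_names))
  clamped <- matrix(FALSE, nrow(features), length(regressor$target_names),
                    dimnames = list(NULL, regressor$target_names))
  if (any(!missing)) {
    Z <- sweep(sweep(features[!missing, , drop = FALSE], 2,
                     regressor$standardize$mu), 2, regressor$standardize$sd, `/`)
    M <- monomial_design(Z, regressor$exponents)
    pred <- M %*% regressor$coefficients
    for (j in seq_along(regressor$target_names)) {
      rng <- regressor$clamp[[regressor$target_names[j]]]
      if (is.null(rng)) next # no physical range known for this target
      cl <- pred[, j] < rng[1] | pred[, j] > rng[2]
      clamped[!missing, j] <- cl
      pred[, j] <- clamp(pred[, j], rng[1], rng[2])
    }
    out[!missing, ] <- pred
  }
  res <- as.data.frame(out)
  attr(res, "clamped") <- clamped
  attr(res, "missing") <- missing
  res
}

#' Save / load a trained regressor as versioned JSON
#' @param regressor `trained_regressor`; @param path file path.
#' @export
write_regressor <- function(regressor, path) {
  obj <- regressor
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- matrix(unlist(obj$coefficients),
                             ncol = length(obj$target_names),
                             dimnames = list(NULL, obj$target_names))
  obj$exponents <- matrix(unlist(obj$exponents),
                          ncol = length(obj$feature_names))
  structure(obj, class = "trained_regressor")
}
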