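# Gradient-coil tensor field L(r), effective diffusion encodings, and the
# nonlinearity tensor N = L^t L with its isotropic/anisotropic invariants.
#
# Units fixed package-wide: b in ms/um^2, diffusivities in um^2/ms,
# positions in mm. L and N are dimensionless.

#' Voxel grid geometry
#'
#' @param shape integer length-3 (nx, ny, nz).
#' @param affine 4 x 4 matrix mapping 0-based voxel indices to scanner mm;
#'   default centers the grid on the isocenter with `voxel_size` spacing.
#' @param voxel_size voxel edge length(s) in mm (used when affine missing).
#' @return list of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, affine = NULL, voxel_size = c(2, 2, 2)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (is.null(affine)) {
    voxel_size <- rep(voxel_size, length.out = 3)
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(shape = shape, affine = affine), class = "grid_geometry")
}

#' Scanner-frame coordinates (mm) of every voxel
#'
#' Voxel order is R array order: x index fastest.
#' @param grid `grid_geometry`.
#' @return nvox x 3 matrix.
#' @export
grid_coords <- function(grid) {
  sh <- grid$shape
  ijk <- as.matrix(expand.grid(i = 0:(sh[1] - 1), j = 0:(sh[2] - 1),
                               k = 0:(sh[3] - 1)))
  xyz <- cbind(ijk, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Solid-harmonic coil model
#'
#' Calibration representation of the longitudinal field of each gradient
#' coil: \eqn{B_z^{(axis)}(r)/G^\circ = \sum c_{lm} R_0^{1-l} P_{lm}(r)},
#' where \eqn{P_{lm}(r) = |r|^l R_{lm}(\hat r)} are regular solid harmonics
#' (homogeneous polynomials of degree l) and \eqn{R_0} the reference radius.
#' The ideal coil is the pure linear term with unit coefficient:
#' (l=1, m=1) for x, (l=1, m=-1) for y, (l=1, m=0) for z.
#'
#' @param coefficients data.frame with columns `axis` ("x","y","z"), `l`,
#'   `m`, `coef` (dimensionless).
#' @param ref_radius reference radius in mm.
#' @return object of class `coil_harmonic_model`.
#' @export
coil_harmonic_model <- function(coefficients, ref_radius = 250) {
  stopifnot(all(c("axis", "l", "m", "coef") %in% names(coefficients)),
            all(coefficients$axis %in% c("x", "y", "z")),
            all(abs(coefficients$m) <= coefficients$l))
  if (!any(coefficients$l >= 1))
    stop("invalid coil model: no linear (degree >= 1) term")
  structure(list(coefficients = coefficients, ref_radius = ref_radius,
                 max_degree = max(coefficients$l)),
            class = "coil_harmonic_model")
}

#' The ideal (perfectly linear) coil model
#' @param ref_radius reference radius in mm.
#' @export
ideal_coil_model <- function(ref_radius = 250) {
  coil_harmonic_model(data.frame(
    axis = c("x", "y", "z"), l = 1L, m = c(1L, -1L, 0L), coef = 1
  ), ref_radius)
}

# Monomial (exponent table + coefficients) representation of the regular
# solid harmonic |r|^l R_lm(r-hat): an exact homogeneous degree-l polynomial,
# obtained once per (l, m) by collocation on well-spread unit vectors.
solid_harmonic_poly <- function(l, m) {
  key <- sprintf("shp_%d_%d", l, m)
  pol <- .pipe_cache[[key]]
  if (!is.null(pol)) return(pol)
  ex <- expand.grid(a = 0:l, b = 0:l, c = 0:l)
  ex <- ex[rowSums(ex) == l, , drop = FALSE]
  M <- nrow(ex)
  # deterministic spread points (Fibonacci sphere), overdetermined solve
  n <- 2 * M + 8
  k <- seq_len(n) - 0.5
  ct <- 1 - 2 * k / n
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- pi * (1 + sqrt(5)) * k
  D <- cbind(st * cos(ph), st * sin(ph), ct)
  V <- sapply(seq_len(M), function(j)
    D[, 1]^ex$a[j] * D[, 2]^ex$b[j] * D[, 3]^ex$c[j])
  y <- eval_sh_any(l, m, D)
  coef <- qr.solve(V, y)
  coef[abs(coef) < 1e-12] <- 0
  pol <- list(ex = as.matrix(ex), coef = coef)
  .pipe_cache[[key]] <- pol
  pol
}

# eval_sh for any (also odd) degree l >= 0 -- needed for solid harmonics
eval_sh_any <- function(l, m, dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  ct <- clamp(dirs[, 3], -1, 1)
  am <- abs(m)
  P <- assoc_legendre(l, am, ct)
  if (m == 0) return(P)
  phi <- atan2(dirs[, 2], dirs[, 1])
  nrm <- sqrt(2 / prod((l - am + 1):(l + am)))
  if (m > 0) nrm * P * cos(am * phi) else nrm * P * sin(am * phi)
}

# gradient of the solid harmonic polynomial at points xyz (n x 3, mm units
# already scaled; polynomial is in raw coordinates)
solid_harmonic_grad <- function(l, m, xyz) {
  pol <- solid_harmonic_poly(l, m)
  n <- nrow(xyz)
  G <- matrix(0, n, 3)
  for (j in seq_along(pol$coef)) {
    e <- pol$ex[j, ]
    cf <- pol$coef[j]
    mono <- function(a, b, c) {
      v <- rep(cf, n)
      if (a > 0) v <- v * xyz[, 1]^a
      if (b > 0) v <- v * xyz[, 2]^b
      if (c > 0) v <- v * xyz[, 3]^c
      v
    }
    if (e[1] > 0) G[, 1] <- G[, 1] + e[1] * mono(e[1] - 1, e[2], e[3])
    if (e[2] > 0) G[, 2] <- G[, 2] + e[2] * mono(e[1], e[2] - 1, e[3])
    if (e[3] > 0) G[, 3] <- G[, 3] + e[3] * mono(e[1], e[2], e[3] - 1)
  }
  G
}

#' Expand a coil model into a gradient-coil tensor field on a grid
#'
#' \eqn{L_{ij}(r) = \partial (B_z^{(j)}/G_j^\circ) / \partial x_i} with the
#' derivatives computed analytically from the monomial representation of the
#' solid harmonics (no finite differences).
#'
#' @param model `coil_harmonic_model`.
#' @param grid `grid_geometry` whose coordinates are in the coil frame.
#' @return object of class `gnl_field`: matrix `L` (nvox x 9, row-major
#'   Lxx, Lxy, Lxz, Lyx, ... Lzz) plus grid geometry.
#' @export
expand_coil_field <- function(model, grid) {
  stopifnot(inherits(model, "coil_harmonic_model"), inherits(grid, "grid_geometry"))
  xyz <- grid_coords(grid)
  nvox <- nrow(xyz)
  L <- matrix(0, nvox, 9)
  jcol <- c(x = 1L, y = 2L, z = 3L)
  R0 <- model$ref_radius
  cf <- model$coefficients
  for (k in seq_len(nrow(cf))) {
    j <- jcol[[cf$axis[k]]]
    G <- solid_harmonic_grad(cf$l[k], cf$m[k], xyz) * (cf$coef[k] * R0^(1 - cf$l[k]))
    for (i in 1:3) L[, (i - 1) * 3 + j] <- L[, (i - 1) * 3 + j] + G[, i]
  }
  if (!all(is.finite(L))) stop("expand_coil_field: non-finite L entries")
  gnl_field(L, grid)
}

#' Construct a gradient-coil tensor field
#' @param L nvox x 9 matrix, row-major (Lxx, Lxy, Lxz, Lyx, ..., Lzz).
#' @param grid `grid_geometry` with matching voxel count.
#' @export
gnl_field <- function(L, grid) {
  stopifnot(inherits(grid, "grid_geometry"), ncol(L) == 9,
            nrow(L) == prod(grid$shape), all(is.finite(L)))
  structure(list(L = L, grid = grid), class = "gnl_field")
}

#' Identity gradient-coil field (no nonlinearity)
#' @param grid `grid_geometry`.
#' @export
identity_field <- function(grid) {
  L <- matrix(rep(as.numeric(diag(3)), each = prod(grid$shape)),
              prod(grid$shape), 9)
  # row-major flattening of identity equals column-major here (symmetric)
  gnl_field(L, grid)
}

#' Extract the 3 x 3 L matrix of one voxel
#' @param field `gnl_field`; @param ivox 1-based voxel index (x fastest).
#' @export
field_L <- function(field, ivox) {
  matrix(field$L[ivox, ], 3, 3, byrow = TRUE)
}

#' Effective B-tensor under gradient nonlinearity
#'
#' \eqn{B(r) = L B^\circ L^t}. Preserves symmetry and positive
#' semi-definiteness; for invertible L the rank of the nominal B-tensor is
#' unchanged (in particular LTE stays rank 1).
#'
#' @param L 3 x 3 coil tensor.
#' @param B0 3 x 3 symmetric PSD nominal B-tensor (ms/um^2).
#' @export
effective_btensor <- function(L, B0) {
  stopifnot(is_square3(L), is_square3(B0))
  if (max(abs(B0 - t(B0))) > 1e-10 * max(1, max(abs(B0))))
    stop("effective_btensor: B0 must be symmetric")
  B <- L %*% B0 %*% t(L)
  (B + t(B)) / 2
}

#' Effective LTE encoding (b-value and direction)
#'
#' \eqn{b = b^\circ \hat g^{\circ t} N \hat g^\circ} with \eqn{N = L^t L},
#' and \eqn{\hat g = L\hat g^\circ / |L\hat g^\circ|}.
#'
#' @param L 3 x 3 coil tensor.
#' @param b0 nominal b-value (ms/um^2), >= 0.
#' @param g0 nominal unit direction.
#' @return list(b, g).
#' @export
effective_lte <- function(L, b0, g0) {
  stopifnot(is_square3(L), b0 >= 0)
  g0 <- as.numeric(g0)
  stopifnot(abs(sum(g0^2) - 1) < 1e-6)
  Lg <- drop(L %*% g0)
  nrm <- sqrt(sum(Lg^2))
  if (nrm < 1e-12)
    stop("degenerate encoding: L annihilates the nominal direction")
  list(b = b0 * sum(Lg^2), g = Lg / nrm)
}

# symmetric trace-free basis matrices M^{2m} with g^t M^{2m} g = R_{2m}(g)
# (real Racah basis); exact, cached
stf_basis_2 <- function() {
  B <- .pipe_cache[["stf2"]]
  if (!is.null(B)) return(B)
  g <- sphere_quad_grid(6, 12)
  D <- g$dirs
  # quadratic-form design: x^2, y^2, z^2, 2xy, 2xz, 2yz
  Q <- cbind(D[, 1]^2, D[, 2]^2, D[, 3]^2,
             2 * D[, 1] * D[, 2], 2 * D[, 1] * D[, 3], 2 * D[, 2] * D[, 3])
  B <- lapply(-2:2, function(m) {
    y <- eval_sh(2, m, D)
    v <- qr.solve(Q, y)
    v[abs(v) < 1e-12] <- 0
    matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
  })
  names(B) <- sprintf("m%+d", -2:2)
  .pipe_cache[["stf2"]] <- B
  B
}

#' Irreducible decomposition of the nonlinearity tensor
#'
#' \eqn{N = L^t L = N_0 \delta + \sum_m N_{2m} \mathcal{Y}^{2m}} with
#' \eqn{N_0 = tr(N)/3} and the five \eqn{N_{2m}} in the real Racah basis.
#' The scalar invariant is \eqn{N_2 = \sqrt{\sum_m N_{2m}^2/5}}, normalized
#' so that the standard deviation of \eqn{N(\hat g) = \hat g^t N \hat g}
#' over uniform directions equals \eqn{N_2} exactly.
#'
#' @param L 3 x 3 coil tensor.
#' @return list of class `nonlinearity_decomposition` with N, N0, N2m, N2.
#' @export
nonlinearity_decomposition <- function(L) {
  stopifnot(is_square3(L))
  N <- t(L) %*% L
  N0 <- sum(diag(N)) / 3
  A <- N - N0 * diag(3)
  B <- stf_basis_2()
  # solve A = sum_m N2m * B[[m]] exactly (both sides symmetric trace-free)
  X <- sapply(B, function(M) c(M[1, 1], M[2, 2], M[1, 2], M[1, 3], M[2, 3]))
  a <- c(A[1, 1], A[2, 2], A[1, 2], A[1, 3], A[2, 3])
  N2m <- drop(qr.solve(X, a))
  names(N2m) <- names(B)
  structure(list(N = N, N0 = N0, N2m = N2m, N2 = sqrt(sum(N2m^2) / 5)),
            class = "nonlinearity_decomposition")
}

#' Reconstruct N from its irreducible parts (round-trip check)
#' @param dec `nonlinearity_decomposition`.
#' @export
reconstruct_N <- function(dec) {
  B <- stf_basis_2()
  N <- dec$N0 * diag(3)
  for (m in seq_along(B)) N <- N + dec$N2m[m] * B[[m]]
  N
}

#' Mean and standard deviation of N(g) over uniform directions
#'
#' Closed form: mean is \eqn{N_0}; the standard deviation depends only on
#' the anisotropic part and equals \eqn{N_2}.
#'
#' @param dec `nonlinearity_decomposition`.
#' @return list(mean, sd).
#' @export
directional_stats <- function(dec) {
  stopifnot(inherits(dec, "nonlinearity_decomposition"))
  list(mean = dec$N0, sd = dec$N2)
}

#' Nominal diffusion protocol
#'
#' @param bval numeric vector of nominal b-values (ms/um^2).
#' @param bvec 3 x K or K x 3 matrix of nominal unit directions (FSL-style
#'   3 x K accepted).
#' @param extra optional data.frame of additional scalar protocol
#'   parameters (TE, Delta, delta, ... in ms), one row per volume.
#' @return object of class `nominal_protocol` (data.frame b, gx, gy, gz).
#' @export
nominal_protocol <- function(bval, bvec, extra = NULL) {
  bval <- as.numeric(bval)
  if (nrow(bvec) == 3 && ncol(bvec) != 3) bvec <- t(bvec)
  if (length(bval) == 3 && nrow(bvec) == 3 && ncol(bvec) == 3)
    bvec <- t(bvec) # ambiguous 3x3: assume FSL rows
  stopifnot(nrow(bvec) == length(bval), all(bval >= 0))
  g <- as.matrix(bvec)
  nz <- bval > 0
  nrm <- sqrt(rowSums(g^2))
  if (any(nz & nrm < 1e-6))
    stop("nominal_protocol: zero direction with b > 0")
  g[nz, ] <- g[nz, , drop = FALSE] / nrm[nz]
  g[!nz, ] <- matrix(rep(c(0, 0, 1), sum(!nz)), ncol = 3, byrow = TRUE)
  p <- data.frame(b = bval, gx = g[, 1], gy = g[, 2], gz = g[, 3])
  if (!is.null(extra)) p <- cbind(p, extra)
  structure(p, class = c("nominal_protocol", "data.frame"))
}

#' Deform a nominal protocol voxelwise through a coil tensor field
#'
#' Applies [effective_lte()] to every encoding in every voxel: b(r, g0) =
#' b0 N(r, g0), g(r) = L g0/|L g0|. b = 0 volumes pass through unchanged
#' (canonical direction (0,0,1)).
#'
#' @param field `gnl_field`.
#' @param nominal `nominal_protocol`.
#' @return object of class `voxel_protocols`: `b` (nvox x K), `g` (array
#'   nvox x K x 3), `degenerate` flags, plus the nominal protocol.
#' @export
deform_protocol <- function(field, nominal) {
  stopifnot(inherits(field, "gnl_field"), nrow(nominal) >= 1)
  K <- nrow(nominal)
  nvox <- nrow(field$L)
  G <- as.matrix(nominal[, c("gx", "gy", "gz")])
  b0 <- nominal$b
  Lm <- field$L # nvox x 9 row-major
  # N components per voxel: N = L^t L
  # N_ab = sum_i L_ia L_ib ; columns of Lm: (i-1)*3 + a
  colN <- function(a, b)
    Lm[, a] * Lm[, b] + Lm[, 3 + a] * Lm[, 3 + b] + Lm[, 6 + a] * Lm[, 6 + b]
  Nm <- cbind(colN(1, 1), colN(2, 2), colN(3, 3),
              colN(1, 2), colN(1, 3), colN(2, 3))
  Qm <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
              2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  bratio <- Nm %*% t(Qm) # nvox x K : g0' N g0
  beff <- unname(sweep(bratio, 2, b0, `*`))
  # effective directions: g'_i = sum_j L_ij g_j (kept as nvox x K matrices
  # so single-voxel grids do not drop dimensions)
  gc <- lapply(1:3, function(i)
    unname(Lm[, (i - 1) * 3 + (1:3), drop = FALSE] %*% t(G)))
  nrm <- sqrt(gc[[1]]^2 + gc[[2]]^2 + gc[[3]]^2)
  degen <- nrm < 1e-12
  nrm[degen] <- 1
  gc <- lapply(gc, function(m) m / nrm)
  # b = 0 volumes: untouched, canonical direction
  zero <- which(b0 == 0)
  if (length(zero)) {
    beff[, zero] <- 0
    gc[[1]][, zero] <- 0; gc[[2]][, zero] <- 0; gc[[3]][, zero] <- 1
    degen[, zero] <- FALSE
  }
  g <- array(0, c(nvox, K, 3))
  for (i in 1:3) g[, , i] <- gc[[i]]
  structure(list(b = beff, g = g, degenerate = degen, nominal = nominal,
                 grid = field$grid),
            class = "voxel_protocols")
}

#' Constant (single-protocol) voxel protocols
#' @param nominal `nominal_protocol`; @param nvox number of voxels.
#' @export
uniform_protocols <- function(nominal, nvox = 1L) {
  K <- nrow(nominal)
  g <- array(0, c(nvox, K, 3))
  G <- as.matrix(nominal[, c("gx", "gy", "gz")])
  for (i in 1:3) g[, , i] <- matrix(G[, i], nvox, K, byrow = TRUE)
  structure(list(b = matrix(nominal$b, nvox, K, byrow = TRUE), g = g,
                 degenerate = matrix(FALSE, nvox, K), nominal = nominal,
                 grid = NULL),
            class = "voxel_protocols")
}

#' Motion-aware effective B-tensor
#'
#' For a volume acquired after rigid-body motion (rotation R, translation t
#' from acquired to final frame), the coil tensor is evaluated at the
#' original position \eqn{r_0 = R^{-1}(r - t)} and the result rotated into
#' the final frame: \eqn{B = R L(r_0) B^\circ L^t(r_0) R^t}.
#'
#' @param field `gnl_field`.
#' @param B0 nominal 3 x 3 symmetric B-tensor.
#' @param R 3 x 3 proper rotation.
#' @param t translation vector (mm).
#' @param r position in the final frame (mm).
#' @param strict if TRUE, error when r0 falls outside the field grid;
#'   default clamps to the nearest voxel with a warning.
#' @export
motion_adjusted_btensor <- function(field, B0, R, t = c(0, 0, 0), r,
                                    strict = FALSE) {
  stopifnot(is_square3(R))
  if (max(abs(t(R) %*% R - diag(3))) > 1e-8 || det(R) < 0)
    stop("motion_adjusted_btensor: R must be a proper rotation")
  r0 <- drop(t(R) %*% (as.numeric(r) - as.numeric(t)))
  ijk <- drop(solve(field$grid$affine, c(r0, 1)))[1:3]
  sh <- field$grid$shape
  out_of_grid <- any(ijk < -0.5) || any(ijk > sh - 0.5)
  if (out_of_grid) {
    if (strict) stop("motion_adjusted_btensor: r0 outside the field grid")
    warning("motion_adjusted_btensor: r0 outside grid, clamping to nearest voxel")
  }
  ijk <- pmin(pmax(round(ijk), 0), sh - 1)
  ivox <- 1 + ijk[1] + sh[1] * (ijk[2] + sh[2] * ijk[3])
  L0 <- field_L(field, ivox)
  R %*% effective_btensor(L0, B0) %*% t(R)
}
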