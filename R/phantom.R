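# Fully synthetic, ground-truth-labeled DWI phantom with spatially varying
# protocols: parametric gradient-coil field, tissue maps, forward signal
# synthesis and noise, plus the shelled-vs-deformed noise-propagation
# experiment.

#' Synthetic gradient-coil tensor field
#'
#' Parametric stand-in for a measured coil field: identity at the
#' isocenter, smooth quadratic departures growing radially so that the
#' maximum b-value modulation |N(g) - 1| over the grid and over directions
#' approximately equals `strength` at the grid boundary. The isotropic part
#' N0 increases monotonically along rays from the isocenter.
#'
#' @param strength target maximum |N(g) - 1| (e.g. 0.2 for 20 percent
#'   b-value modulation); 0 gives the identity field.
#' @param grid `grid_geometry`.
#' @return `gnl_field`.
#' @export
synth_L_field <- function(strength, grid) {
  stopifnot(strength >= 0)
  xyz <- grid_coords(grid)
  rmax <- max(sqrt(rowSums(xyz^2)), 1e-9)
  rho2 <- rowSums(xyz^2) / rmax^2
  # fixed anisotropic symmetric profile, leading eigenvalue 1/2 so that
  # N - I = 2 s rho^2 A + O(s^2) peaks at ~ strength; mild antisymmetric
  # part to make L non-symmetric (direction deflections) without changing N
  # at first order
  Rf <- euler_zyz(0.4, 0.3, -0.2)
  A <- Rf %*% diag(c(0.5, 0.2, 0.35)) %*% t(Rf)
  Wa <- matrix(c(0, 0.05, -0.03, -0.05, 0, 0.02, 0.03, -0.02, 0), 3, 3)
  M <- A + Wa
  nvox <- nrow(xyz)
  L <- matrix(0, nvox, 9)
  for (i in 1:3) for (j in 1:3)
    L[, (i - 1) * 3 + j] <- (i == j) + strength * rho2 * M[i, j]
  gnl_field(L, grid)
}

#' Approximately uniform direction set by electrostatic repulsion
#'
#' Fibonacci-sphere start refined by a few hundred iterations of antipodal
#' Coulomb repulsion; deterministic.
#'
#' @param n number of directions.
#' @param n_iter repulsion iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsion_dirs <- function(n, n_iter = 200) {
  k <- seq_len(n) - 0.5
  ct <- 1 - k / n # hemisphere start (antipodal symmetry)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- pi * (1 + sqrt(5)) * k
  D <- cbind(st * cos(ph), st * sin(ph), ct)
  if (n == 1) return(matrix(c(0, 0, 1), 1))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    Fo <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      for (sgn in c(1, -1)) { # repel both each point and its antipode
        dv <- matrix(D[i, ], n, 3, byrow = TRUE) - sgn * D
        d2 <- rowSums(dv^2)
        sel <- d2 > 1e-12
        Fo[i, ] <- Fo[i, ] + colSums(dv[sel, , drop = FALSE] / d2[sel]^1.5)
      }
    }
    D <- unit_rows(D + step * Fo / n)
    step <- step * 0.97
  }
  D
}

#' Multi-shell nominal protocol with repulsed directions
#'
#' Default shells (b, N) = (1, 25), (2, 60), (8, 50) plus `n_b0` b = 0
#' volumes.
#'
#' @param shells data.frame with columns b and n.
#' @param n_b0 number of b = 0 volumes prepended.
#' @return `nominal_protocol`.
#' @export
shelled_protocol <- function(shells = data.frame(b = c(1, 2, 8),
                                                 n = c(25, 60, 50)),
                             n_b0 = 1) {
  b <- rep(0, n_b0)
  g <- matrix(rep(c(0, 0, 1), n_b0), ncol = 3, byrow = TRUE)
  for (i in seq_len(nrow(shells))) {
    b <- c(b, rep(shells$b[i], shells$n[i]))
    g <- rbind(g, repulsion_dirs(shells$n[i]))
  }
  nominal_protocol(b, g)
}

#' Specification of a synthetic DWI phantom
#'
#' Default: three tissue regions (coherent single-fiber white matter, a
#' crossing-fiber region, and a free-water border), the 135-direction
#' three-shell protocol, and a quadratic coil field.
#'
#' @param shape grid shape (default 32 x 32 x 8).
#' @param voxel_size mm.
#' @param gnl_strength coil-field strength (max |N - 1|).
#' @param protocol `nominal_protocol`.
#' @param snr b=0 SNR; Inf = noiseless.
#' @param noise_model "gaussian" (default, emulating complex-domain
#'   denoised data) or "rician".
#' @param fodf_lmax band limit of the ground-truth fODFs (default 2,
#'   matched to the estimation library; raise to study the effect of
#'   out-of-band fODF content on a band-limited fit).
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 8), voxel_size = c(6, 6, 6),
                         gnl_strength = 0.2, protocol = shelled_protocol(),
                         snr = Inf, noise_model = c("gaussian", "rician"),
                         fodf_lmax = 2, seed = 1) {
  structure(list(grid = grid_geometry(shape, voxel_size = voxel_size),
                 gnl_strength = gnl_strength, protocol = protocol,
                 snr = snr, noise_model = match.arg(noise_model),
                 fodf_lmax = fodf_lmax, seed = seed),
            class = "phantom_spec")
}

# ground-truth tissue maps for the default three-region phantom:
# angular sectors inside an ellipsoidal "head" mask -- region 1
# (single-fiber WM), region 2 (crossing WM), region 3 (free-water border).
# Sectors depend on the in-plane angle only while the nonlinearity maps
# (N0) are radial, so the tissue layout is geometrically orthogonal to the
# coil field: any tissue-N0 correlation in fitted maps is a
# gradient-nonlinearity imprint, not phantom anatomy.
phantom_tissue <- function(spec) {
  set.seed(spec$seed + 1)
  xyz <- grid_coords(spec$grid)
  sh <- spec$grid$shape
  semi <- pmax(abs(spec$grid$affine[cbind(1:3, 1:3)]) * (sh - 1) / 2, 1e-9)
  mask <- rowSums(sweep(xyz, 2, semi, `/`)^2) <= 1
  phi <- atan2(xyz[, 2], xyz[, 1])
  region <- ifelse(phi < -pi / 3, 1L, ifelse(phi < pi / 3, 2L, 3L))
  nvox <- nrow(xyz)
  xi <- data.frame(f = numeric(nvox), Da = numeric(nvox),
                   Depar = numeric(nvox), Deperp = numeric(nvox),
                   fw = numeric(nvox))
  xi[region == 1, ] <- list(0.7, 2.2, 2.0, 0.6, 0.05)
  xi[region == 2, ] <- list(0.5, 2.0, 1.8, 0.8, 0.1)
  xi[region == 3, ] <- list(0.1, 2.0, 1.5, 1.0, 0.85)
  # smooth non-radial tissue gradients so maps vary within regions (a
  # gradient-nonlinearity imprint would otherwise dominate any correlation)
  span <- function(u) (u - min(u)) / max(max(u) - min(u), 1e-9) - 0.5
  tx <- span(xyz[, 1] + 0.5 * xyz[, 3])
  ty <- span(xyz[, 2] - 0.5 * xyz[, 3])
  xi$f <- clamp(xi$f + 0.2 * tx, 0.05, 0.95)
  xi$Deperp <- clamp(xi$Deperp + 0.3 * ty, 0.1, 1.2)
  xi$Depar <- clamp(xi$Depar + 0.3 * tx, 1, 3)
  xi$fw <- clamp(xi$fw + 0.1 * ty, 0, 0.9)
  xi$fw <- pmin(xi$fw, 1 - xi$f)
  lmax <- if (!is.null(spec$fodf_lmax)) spec$fodf_lmax else 2
  idx <- sh_index_table(lmax)
  fodf <- matrix(0, nvox, nrow(idx))
  fodf[, 1] <- 1
  # region 1: single lobe along x; region 2: equal-weight crossing x/y;
  # region 3: nearly isotropic residual lobe
  lobe <- function(axis, p2, lam) {
    v <- numeric(nrow(idx))
    v[1] <- 1
    Y <- sh_basis(matrix(axis, 1), lmax)
    for (l in seq(2, lmax, 2))
      v[idx$l == l] <- sqrt(2 * l + 1) * (p2 / lam^2) * lam^l * Y[1, idx$l == l]
    v
  }
  l1 <- lobe(c(1, 0, 0), 0.7, 0.8)
  l2 <- lobe(c(0, 1, 0), 0.7, 0.8)
  liso <- lobe(c(0, 0, 1), 0.1, 0.6)
  fodf[region == 1, ] <- matrix(l1, sum(region == 1), nrow(idx), byrow = TRUE)
  fodf[region == 2, ] <- matrix((l1 + l2) / 2, sum(region == 2), nrow(idx),
                                byrow = TRUE)
  fodf[region == 3, ] <- matrix(liso, sum(region == 3), nrow(idx),
                                byrow = TRUE)
  # smooth anisotropy modulation (keeps p_00 = 1, scales p_l for l >= 2)
  aniso <- clamp(1 + 0.35 * tx, 0.55, 1.35)
  fodf[, idx$l >= 2] <- fodf[, idx$l >= 2, drop = FALSE] * aniso
  p2 <- apply(fodf[, idx$l == 2, drop = FALSE], 1,
              function(v) sqrt(sum(v^2) / 5))
  list(xi = xi, fodf = fodf, region = region, p2 = p2, lmax = lmax,
       mask = mask)
}

#' Simulate a DWI phantom
#'
#' Per voxel: the nominal protocol is deformed through the coil field, the
#' signal synthesized by spherical convolution of the Standard Model kernel
#' with the voxel fODF, and noise added at the stated b=0 SNR (Gaussian by
#' default; Rician takes the magnitude of complex Gaussian noise).
#'
#' @param spec `phantom_spec`.
#' @return list: `dwi` (nvox x K matrix), `protocols` (`voxel_protocols`),
#'   `field` (`gnl_field`), `truth` (tissue tables), `spec`.
#' @export
simulate_dwi <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  field <- synth_L_field(spec$gnl_strength, spec$grid)
  protocols <- deform_protocol(field, spec$protocol)
  truth <- phantom_tissue(spec)
  nvox <- nrow(protocols$b)
  K <- ncol(protocols$b)
  dwi <- matrix(0, nvox, K)
  # voxels share tissue within regions; signals still differ voxelwise via
  # the deformed protocols
  for (v in seq_len(nvox)) {
    xi <- sm_params(truth$xi$f[v], truth$xi$Da[v], truth$xi$Depar[v],
                    truth$xi$Deperp[v], truth$xi$fw[v])
    fod <- sh_coefficients(truth$fodf[v, ], truth$lmax)
    dwi[v, ] <- convolve_signal(xi, fod, protocols$b[v, ],
                                matrix(protocols$g[v, , ], ncol = 3))
  }
  dwi[!truth$mask, ] <- 0 # outside the ellipsoidal head mask
  if (is.finite(spec$snr)) {
    set.seed(spec$seed)
    sigma <- 1 / spec$snr
    if (spec$noise_model == "gaussian") {
      dwi <- dwi + matrix(stats::rnorm(nvox * K, sd = sigma), nvox, K)
    } else {
      dwi <- sqrt((dwi + matrix(stats::rnorm(nvox * K, sd = sigma), nvox, K))^2 +
                    matrix(stats::rnorm(nvox * K, sd = sigma), nvox, K)^2)
    }
  }
  list(dwi = dwi, protocols = protocols, field = field, truth = truth,
       spec = spec)
}

#' Shelled-versus-deformed noise propagation experiment
#'
#' Simulates the same tissue voxels (a) under the nominal shelled protocol
#' with an identity coil field and (b) under voxelwise protocols deformed by
#' a synthetic coil field, fits gamma, predicts parameters with one trained
#' regressor, and tabulates bias and RMSE per parameter and SNR. The
#' protocol-independence claim is that both arms agree within Monte-Carlo
#' error.
#'
#' @param basis `factorized_basis`.
#' @param regressor `trained_regressor`.
#' @param snrs vector of b=0 SNR values (may include Inf).
#' @param n_voxels tissue draws per SNR.
#' @param gnl_strength coil-field strength of the deformed arm.
#' @param protocol nominal protocol.
#' @param seed integer seed.
#' @return data.frame: snr, arm, parameter, bias, rmse.
#' @export
noise_propagation_experiment <- function(basis, regressor, snrs = c(Inf, 50),
                                         n_voxels = 500, gnl_strength = 0.2,
                                         protocol = shelled_protocol(),
                                         seed = 1) {
  set.seed(seed)
  xi <- sample_kernel_priors(n_voxels)
  fodf <- sample_fodf(n_voxels, lmax = max(2, basis$lmax))
  targets <- cbind(xi[, c("f", "Da", "Depar", "Deperp", "fw")],
                   p2 = fodf$params$p2)
  # deformed arm: spread the voxels across a small grid of the synthetic
  # field (one voxel protocol each)
  side <- ceiling(n_voxels^(1 / 3))
  grid <- grid_geometry(c(side, side, side), voxel_size = c(10, 10, 10))
  field <- synth_L_field(gnl_strength, grid)
  prots <- deform_protocol(field, protocol)
  pick <- seq_len(n_voxels) %% nrow(prots$b) + 1
  G0 <- as.matrix(protocol[, c("gx", "gy", "gz")])
  out <- list()
  for (snr in snrs) {
    for (arm in c("shelled", "deformed")) {
      S <- matrix(0, n_voxels, nrow(protocol))
      for (v in seq_len(n_voxels)) {
        p <- sm_params(xi$f[v], xi$Da[v], xi$Depar[v], xi$Deperp[v], xi$fw[v])
        fod <- sh_coefficients(fodf$coef[v, ], fodf$lmax)
        if (arm == "shelled") {
          S[v, ] <- convolve_signal(p, fod, protocol$b, G0)
        } else {
          w <- pick[v]
          S[v, ] <- convolve_signal(p, fod, prots$b[w, ],
                                    matrix(prots$g[w, , ], ncol = 3))
        }
      }
      if (is.finite(snr))
        S <- S + matrix(stats::rnorm(length(S), sd = 1 / snr), nrow(S))
      vox_prot <- if (arm == "shelled") uniform_protocols(protocol, n_voxels)
        else {
          sub <- prots
          sub$b <- prots$b[pick, , drop = FALSE]
          sub$g <- prots$g[pick, , , drop = FALSE]
          sub$degenerate <- prots$degenerate[pick, , drop = FALSE]
          sub
        }
      gf <- fit_volume(basis, S, vox_prot)
      pred <- predict_regressor(regressor, gf)
      for (par in colnames(pred)) {
        if (!par %in% names(targets)) next
        err <- pred[[par]] - targets[[par]]
        out[[length(out) + 1]] <- data.frame(
          snr = snr, arm = arm, parameter = par,
          bias = mean(err, na.rm = TRUE),
          rmse = sqrt(mean(err^2, na.rm = TRUE)))
      }
    }
  }
  do.call(rbind, out)
}
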