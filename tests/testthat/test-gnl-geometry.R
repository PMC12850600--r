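# Gradient-coil tensor field, effective encodings, nonlinearity invariants.

test_that("expand_coil_field: ideal coils, isocenter limit, FD oracle", {
  grid <- grid_geometry(c(5, 5, 5), voxel_size = c(40, 40, 40))
  f <- expand_coil_field(ideal_coil_model(), grid)
  expect_lt(max(abs(sweep(f$L, 2, as.numeric(diag(3))))), 1e-12)

  # degree-3 additions have zero gradient at the isocenter
  mod3 <- coil_harmonic_model(rbind(
    ideal_coil_model()$coefficients,
    data.frame(axis = "x", l = 3L, m = 2L, coef = 0.3)))
  g1 <- grid_geometry(c(1, 1, 1)) # single voxel at the isocenter
  f0 <- expand_coil_field(mod3, g1)
  expect_equal(matrix(f0$L, 3, 3, byrow = TRUE), diag(3), tolerance = 1e-12)

  # degree-0-only model is invalid
  expect_error(coil_harmonic_model(
    data.frame(axis = "x", l = 0L, m = 0L, coef = 1)), "linear")

  # random degree <= 5 model vs central finite differences of Bz
  set.seed(3)
  extra <- expand.grid(axis = c("x", "y", "z"), l = c(2L, 4L, 5L))
  extra$m <- vapply(extra$l, function(l) sample(seq(-l, l), 1), integer(1))
  extra$coef <- rnorm(nrow(extra)) * 0.05
  mod <- coil_harmonic_model(rbind(ideal_coil_model()$coefficients,
                                   extra[, c("axis", "l", "m", "coef")]))
  fld <- expand_coil_field(mod, grid)
  xyz <- grid_coords(grid)
  h <- 1e-3
  bz <- function(axis, pts) { # independent evaluation of Bz/G from harmonics
    cf <- mod$coefficients[mod$coefficients$axis == axis, ]
    out <- numeric(nrow(pts))
    r <- sqrt(rowSums(pts^2))
    hat <- pts / pmax(r, 1e-12)
    for (k in seq_len(nrow(cf))) {
      out <- out + cf$coef[k] * 250^(1 - cf$l[k]) * r^cf$l[k] *
        pipemri:::eval_sh_any(cf$l[k], cf$m[k], hat)
    }
    out
  }
  for (i in 1:3) for (j in 1:3) {
    xp <- xyz; xp[, i] <- xp[, i] + h
    xm <- xyz; xm[, i] <- xm[, i] - h
    fd <- (bz(c("x", "y", "z")[j], xp) - bz(c("x", "y", "z")[j], xm)) / (2 * h)
    expect_lt(max(abs(fd - fld$L[, (i - 1) * 3 + j]) / pmax(1, abs(fd))), 1e-4)
  }
})

test_that("effective_btensor: identity, rank preservation, validation", {
  B0 <- 1.5 * outer(c(1, 0, 0), c(1, 0, 0))
  expect_equal(effective_btensor(diag(3), B0), B0)
  expect_error(effective_btensor(diag(3), matrix(1:9, 3)), "symmetric")
  B <- effective_btensor(diag(c(1.2, 1, 1)), outer(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(B, diag(c(1.44, 0, 0)))
  expect_equal(sum(diag(B)), 1.44)

  # LTE rank preserved for random invertible L (property, 1000 draws)
  set.seed(8)
  for (i in 1:1000) {
    L <- diag(3) + matrix(rnorm(9, sd = 0.2), 3)
    g0 <- rnorm(3); g0 <- g0 / sqrt(sum(g0^2))
    ev <- eigen(effective_btensor(L, outer(g0, g0)), symmetric = TRUE)$values
    expect_lt(max(abs(ev[2:3])), 1e-12 * ev[1])
  }
})

test_that("effective_lte deforms b and direction as b0 g'Ng, Lg/|Lg|", {
  r <- effective_lte(diag(3), 2, c(0, 1, 0))
  expect_equal(r$b, 2); expect_equal(r$g, c(0, 1, 0))
  r <- effective_lte(diag(c(1.2, 1, 1)), 1, c(1, 0, 0))
  expect_equal(r$b, 1.44); expect_equal(r$g, c(1, 0, 0))
  r <- effective_lte(diag(c(1.2, 1, 1)), 1, c(0, 1, 0))
  expect_equal(r$b, 1); expect_equal(r$g, c(0, 1, 0))
  L <- diag(c(0, 1, 1)) # annihilates x
  expect_error(effective_lte(L, 1, c(1, 0, 0)), "degenerate")
})

test_that("nonlinearity_decomposition: invariants, reconstruction, rotations", {
  d <- nonlinearity_decomposition(diag(3))
  expect_equal(d$N0, 1); expect_equal(d$N2, 0)
  expect_equal(unname(d$N2m), rep(0, 5))

  d <- nonlinearity_decomposition(diag(c(1.2, 1, 1)))
  expect_equal(d$N0, 3.44 / 3)

  R <- euler_zyz(0.5, 1.2, -0.3)
  dr <- nonlinearity_decomposition(R)
  expect_equal(dr$N0, 1, tolerance = 1e-12)
  expect_lt(dr$N2, 1e-12)

  # reconstruction N0 d_ij + sum N2m Y^2m == N to 1e-12, random symmetric N
  set.seed(11)
  for (i in 1:50) {
    L <- diag(3) + matrix(rnorm(9, sd = 0.3), 3)
    dec <- nonlinearity_decomposition(L)
    expect_lt(max(abs(reconstruct_N(dec) - dec$N)), 1e-12)
    # N2 = 0 iff isotropic
    if (dec$N2 < 1e-12)
      expect_lt(max(abs(dec$N - dec$N0 * diag(3))), 1e-10)
  }
})

test_that("directional_stats matches the Monte-Carlo oracle", {
  d <- nonlinearity_decomposition(diag(3))
  s <- directional_stats(d)
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)

  # diag(1.44, 1, 1): exact var = 0.44^2 * 4/45 (frozen from the MC oracle)
  d <- nonlinearity_decomposition(diag(c(1.2, 1, 1)))
  s <- directional_stats(d)
  expect_equal(s$mean, 1.146667, tolerance = 1e-6)
  expect_equal(s$sd^2, 0.0172088889, tolerance = 1e-8)

  # random N vs brute force over uniform directions, 3 MC standard errors
  set.seed(12)
  nmc <- 2e5
  u <- unit_rows(matrix(rnorm(3 * nmc), ncol = 3))
  for (i in 1:10) {
    L <- diag(3) + matrix(rnorm(9, sd = 0.25), 3)
    dec <- nonlinearity_decomposition(L)
    Ng <- rowSums((u %*% dec$N) * u)
    expect_equal(mean(Ng), dec$N0, tolerance = 4 * stats::sd(Ng) / sqrt(nmc))
    mc_sd <- stats::sd(Ng)
    se_sd <- mc_sd / sqrt(2 * (nmc - 1)) # MC standard error of a std dev
    expect_lt(abs(mc_sd - dec$N2), 3 * se_sd + 1e-6)
  }
})

test_that("deform_protocol applies effective_lte voxelwise", {
  grid <- grid_geometry(c(2, 2, 2), voxel_size = c(100, 100, 100))
  nom <- nominal_protocol(c(0, rep(1, 6)),
                          rbind(c(0, 0, 0), diag(3), -diag(3)))
  idf <- identity_field(grid)
  vp <- deform_protocol(idf, nom)
  expect_equal(vp$b, matrix(nom$b, 8, 7, byrow = TRUE))

  g1 <- grid_geometry(c(1, 1, 1))
  fld <- gnl_field(matrix(c(1.2, 0, 0, 0, 1, 0, 0, 0, 1), 1, 9, byrow = TRUE), g1)
  vp1 <- deform_protocol(fld, nom)
  expect_equal(vp1$b[1, ], c(0, 1.44, 1, 1, 1.44, 1, 1))
  # b = 0 keeps the canonical direction
  expect_equal(drop(vp1$g[1, 1, ]), c(0, 0, 1))

  # cross-module consistency: b/b0 equals N(r, g0) from the decomposition
  f2 <- synth_L_field(0.25, grid)
  vp2 <- deform_protocol(f2, nom)
  for (v in c(1, 8)) {
    dec <- nonlinearity_decomposition(field_L(f2, v))
    for (k in 2:7) {
      g0 <- as.numeric(nom[k, c("gx", "gy", "gz")])
      expect_equal(vp2$b[v, k] / nom$b[k], drop(t(g0) %*% dec$N %*% g0),
                   tolerance = 1e-12)
    }
  }
})

test_that("motion_adjusted_btensor evaluates L at the original position", {
  grid <- grid_geometry(c(5, 5, 5), voxel_size = c(40, 40, 40))
  fld <- synth_L_field(0.2, grid)
  B0 <- 2 * outer(c(1, 0, 0), c(1, 0, 0))
  r <- c(40, -40, 40)
  expect_equal(motion_adjusted_btensor(fld, B0, diag(3), c(0, 0, 0), r),
               effective_btensor(field_L(fld, 1 +
                 sum(c(1, 5, 25) * (round(solve(grid$affine, c(r, 1))[1:3])))), B0),
               tolerance = 1e-12)

  # identity L: any (R, t) just rotates B0
  R <- euler_zyz(0.3, 0.7, -0.1)
  idf <- identity_field(grid)
  expect_equal(motion_adjusted_btensor(idf, B0, R, c(5, -3, 2), r),
               R %*% B0 %*% t(R), tolerance = 1e-12)

  # translation moving r0 to the isocenter (L(0) = I) gives rotated B0
  t0 <- r - drop(R %*% c(0, 0, 0)) # r0 = R^-1 (r - t) = 0
  expect_equal(motion_adjusted_btensor(fld, B0, R, t0, r),
               R %*% B0 %*% t(R), tolerance = 1e-12)

  # out-of-grid: warn + clamp by default, error in strict mode
  far <- c(1000, 0, 0)
  expect_warning(motion_adjusted_btensor(fld, B0, diag(3), c(0, 0, 0), far),
                 "clamp")
  expect_error(motion_adjusted_btensor(fld, B0, diag(3), c(0, 0, 0), far,
                                       strict = TRUE), "outside")
  expect_error(motion_adjusted_btensor(fld, B0, 2 * diag(3), c(0, 0, 0), r),
               "rotation")
})
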