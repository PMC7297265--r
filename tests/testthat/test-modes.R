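## Shared small systems for the eigen tests
lattice_modes <- local({
  mesh <- build_alpha_shape(make_lattice(3), alpha = 10)
  sys <- assemble(mesh, elastic_params(E = 1, nu = 0.3))
  list(mesh = mesh, sys = sys, modes = solve_modes(sys))
})

test_that("connected solids have six rigid modes, disjoint ones twelve", {
  expect_identical(lattice_modes$modes$n_rigid, 6L)
  cube <- make_lattice(2)$coords
  two <- point_set(rbind(cube, sweep(cube, 2, c(20, 0, 0), "+")))
  suppressWarnings({
    mesh2 <- build_alpha_shape(two, alpha = 2)
    sys2 <- assemble(mesh2, elastic_params())
  })
  expect_identical(solve_modes(sys2)$n_rigid, 12L)
})

test_that("sparse eigenpairs match the dense decomposition", {
  ## <= 300 DOF so both paths are exercised on the same operator
  mesh <- build_alpha_shape(make_bar(11, 3, 3, spacing = 1.5), alpha = 3)
  sys <- assemble(mesh, elastic_params(E = 1, nu = 0.3))
  dn <- solve_modes(sys)                                  # dense (297 DOF)
  sp <- solve_modes(sys, n_modes = 16, dense_limit = 10)  # forced Krylov
  expect_equal(sp$values[7:16], dn$values[7:16], tolerance = 1e-9)
  for (k in 7:16) {
    ## vectors defined up to sign (and M-norm fixed)
    d <- min(max(abs(sp$vectors[, k] - dn$vectors[, k])),
             max(abs(sp$vectors[, k] + dn$vectors[, k])))
    expect_lt(d, 1e-6)
  }
  ## M-orthonormality
  G <- t(dn$vectors[, 7:16]) %*% as.matrix(sys$M %*% dn$vectors[, 7:16])
  expect_equal(unclass(G), diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  ## mass-weighted modes have unit Euclidean norm
  expect_equal(colSums(dn$mass_weighted[, 7:16]^2), rep(1, 10),
               tolerance = 1e-8)
})

test_that("wavenumber conversion agrees with an SI re-derivation", {
  expect_identical(to_wavenumbers(0), 0)
  f <- unit_constants()$wavenumber_factor
  expect_equal(to_wavenumbers((1 / f)^2), 1, tolerance = 1e-12)
  ## independent SI route: kcal/mol -> J, amu -> kg, A -> m, c in cm/s
  lam <- c(0.3, 2.5, 40)
  om_si <- sqrt(lam * 4184 / 6.02214076e23 / 1.66053907e-27 / 1e-20) /
    (2 * pi * 2.997925e10)
  expect_equal(to_wavenumbers(lam), om_si, tolerance = 1e-6)
  expect_equal(f, 108.59, tolerance = 1e-4)
  expect_error(to_wavenumbers(c(1, -0.5)), "negative")
})

test_that("wavenumbers are invariant under rigid transformation of the input", {
  coords <- random_cloud(25, seed = 2, scale = 3)
  w0 <- solve_modes(assemble(build_alpha_shape(coords, alpha = Inf),
                             elastic_params(rho = 1)))$wavenumbers
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- sweep(coords %*% t(R), 2, c(3, 4, -2), "+")
  w1 <- solve_modes(assemble(build_alpha_shape(moved, alpha = Inf),
                             elastic_params(rho = 1)))$wavenumbers
  expect_equal(w1[7:30], w0[7:30], tolerance = 1e-6)
})

test_that("power-law fit recovers constructed exponents", {
  ## G ~ omega^2 when omega_k = sqrt(k)
  expect_equal(spectrum_and_powerfit(sqrt(1:400))$exponent, 2,
               tolerance = 0.05)
  ## uniform spacing: G linear in omega
  expect_equal(spectrum_and_powerfit((1:400) / 40)$exponent, 1,
               tolerance = 0.05)
  expect_error(spectrum_and_powerfit(1:5), "at least 20")
})

test_that("modal fluctuations equal the deflated pseudo-inverse trace", {
  sys <- lattice_modes$sys
  md <- lattice_modes$modes
  pr <- mean_square_fluctuations(md, E = 1, T_K = 298)
  ## oracle: mass-weighted pseudo-inverse route (Moore-Penrose via MASS)
  Md <- as.matrix(sys$M)
  e <- eigen(Md, symmetric = TRUE)
  Mh <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  Mhi <- solve(Mh)
  Km <- Mhi %*% as.matrix(sys$K) %*% Mhi
  G <- Mhi %*% MASS::ginv(Km) %*% Mhi
  kB <- unit_constants()$kB
  msf_oracle <- kB * 298 * vapply(seq_len(sys$n_nodes), function(i)
    sum(diag(G[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)])), numeric(1))
  expect_equal(pr$msf, msf_oracle, tolerance = 1e-8)
  ## scaling laws
  expect_equal(mean_square_fluctuations(md, E = 2, T_K = 298)$msf,
               pr$msf / 2, tolerance = 1e-12)
  expect_equal(mean_square_fluctuations(md, E = 1, T_K = 596)$msf,
               2 * pr$msf, tolerance = 1e-12)
  expect_equal(pr$bfactor, 8 * pi^2 / 3 * pr$msf, tolerance = 1e-15)
})

test_that("modulus calibration is self-consistent and scales correctly", {
  pr <- mean_square_fluctuations(lattice_modes$modes, E = 1)
  b_at_2 <- pr$bfactor / 2
  fit <- calibrate_young_modulus(pr, b_at_2)
  expect_equal(fit$E, 2, tolerance = 1e-10)
  expect_equal(fit$pearson, 1, tolerance = 1e-10)
  fit10 <- calibrate_young_modulus(pr, 10 * b_at_2)
  expect_equal(fit10$E, 0.2, tolerance = 1e-10)
  expect_equal(fit$E_GPa / fit$E, unit_constants()$E_unit_GPa,
               tolerance = 1e-12)
  expect_error(calibrate_young_modulus(pr, rep(1, nrow(pr))), "variance")
})

test_that("overlaps form a Parseval frame and rank conformational changes", {
  md <- lattice_modes$modes
  n <- md$n_nodes
  set.seed(4)
  for (i in 1:5) {
    d <- matrix(rnorm(3 * n), ncol = 3)
    rep_ <- overlap(d, md)
    ## Parseval over the complete basis (non-rigid part reported, rigid
    ## projections recovered here)
    dv <- as.vector(t(d))
    rigid_part <- crossprod(md$mass_weighted[, 1:6], dv) / sqrt(sum(dv^2))
    expect_equal(sum(rep_$per_mode$overlap^2) + sum(rigid_part^2), 1,
                 tolerance = 1e-8)
    expect_true(all(abs(rep_$per_mode$overlap) <= 1 + 1e-12))
    expect_true(all(diff(rep_$per_mode$cumulative) >= -1e-15))
  }
  ## self-overlap of a mass-weighted mode
  q10 <- matrix(md$mass_weighted[, 10], ncol = 3, byrow = TRUE)
  rep10 <- overlap(q10, md)
  expect_equal(rep10$alpha1, 1, tolerance = 1e-8)
  expect_identical(rep10$n_alpha1, 4L)    # mode 10 = 4th non-rigid
  expect_identical(rep10$n_sigma90, 4L)
  ## two-mode combination: delta3 = 1, n_sigma90 = 2
  q12 <- (md$mass_weighted[, 7] + md$mass_weighted[, 8]) / sqrt(2)
  rep12 <- overlap(matrix(q12, ncol = 3, byrow = TRUE), md)
  expect_equal(rep12$delta3, 1, tolerance = 1e-8)
  expect_identical(rep12$n_sigma90, 2L)
  expect_error(overlap(matrix(0, n, 3), md), "zero displacement")
  expect_error(overlap(matrix(1, 5, 3), md), "node count")
})

test_that("benchmark summaries average overlap metrics across pairs", {
  md <- lattice_modes$modes
  set.seed(9)
  reports <- lapply(1:3, function(i)
    overlap(matrix(rnorm(3 * md$n_nodes), ncol = 3), md))
  one <- benchmark_metrics(reports[[1]])
  expect_equal(one$alpha1, reports[[1]]$alpha1)
  avg <- benchmark_metrics(reports, label = "solid")
  expect_equal(avg$alpha1, mean(vapply(reports, `[[`, 1, "alpha1")))
  expect_equal(avg$n_sigma90,
               mean(vapply(reports, `[[`, 1, "n_sigma90")))
  expect_identical(avg$n_pairs, 3L)
})

test_that("superposition removes rigid offsets before overlap analysis", {
  coords <- random_cloud(20, seed = 14, scale = 4)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(coords %*% t(R), 2, c(1, -2, 3), "+")
  fit <- superpose(moved, coords)
  expect_equal(fit, coords, tolerance = 1e-8, ignore_attr = TRUE)
  d <- conformational_displacement(coords, moved)
  expect_lt(max(abs(d)), 1e-8)
  ## with an internal deformation on top, only the rigid part is removed
  deformed <- moved + 0.05 * matrix(sin(seq_len(60)), ncol = 3)
  d2 <- conformational_displacement(coords, deformed)
  expect_gt(sqrt(sum(d2^2)), 0.01)
})
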