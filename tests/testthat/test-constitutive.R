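test_that("arcade direction honors the zone structure and stays unit-norm", {
  n <- c(0, 0, 1); s <- c(1, 0, 0)
  expect_equal(as.numeric(arcade_direction(0, n, s)), s)
  expect_equal(as.numeric(arcade_direction(1, n, s)), -n)
  d <- arcade_direction(seq(0, 1, by = 0.01), n, s)
  expect_lt(max(abs(rowSums(d^2) - 1)), 1e-10)
  ## continuity in depth
  steps <- sqrt(rowSums(diff(d)^2))
  expect_lt(max(steps), 0.05)
  ## superficial zone returns the split line exactly
  expect_equal(as.numeric(arcade_direction(0.1, n, s)), s)
  ## deep zone returns the inward normal exactly
  expect_equal(as.numeric(arcade_direction(0.9, n, s)), -n)
  expect_error(arcade_direction(1.5, n, s), "normalized_depth")
  expect_error(arcade_direction(0.5, n, c(0, 0.6, 0.8)), "tangent")
})

test_that("fibril law is tension-only with the stated strain stiffening", {
  p <- frpe_params(fibril_E0_MPa = 2, fibril_Eeps_MPa = 100)
  expect_equal(fibril_stress_1d(-0.1, p), 0)
  expect_equal(fibril_stress_1d(0.05, p), (2 + 100 * 0.05) * 0.05)  # 0.35 MPa
  ## initial slope equals E0 (finite-difference oracle)
  h <- 1e-8
  expect_equal(fibril_stress_1d(h, p) / h, 2, tolerance = 1e-6)
  ## monotone non-decreasing
  eps <- seq(-0.5, 0.5, by = 0.01)
  expect_true(all(diff(fibril_stress_1d(eps, p)) >= 0))
  expect_error(fibril_stress_1d(-1.5, p), "exceed")
})

test_that("Neo-Hookean matrix stress is objective with the right moduli", {
  p <- frpe_params()
  expect_equal(matrix_stress(diag(3), p), matrix(0, 3, 3))
  ## frame indifference: pure rotation gives zero stress
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(matrix_stress(R, p), matrix(0, 3, 3), tolerance = 1e-12)
  ## small-strain uniaxial tangent matches the analytic isotropic moduli
  e <- 1e-6
  lc <- cartimech:::lame_constants(p)
  s <- matrix_stress(diag(c(1 + e, 1, 1)), p)
  expect_equal(s[1, 1] / e, lc$lambda + 2 * lc$mu, tolerance = 1e-3)
  expect_equal(s[2, 2] / e, lc$lambda, tolerance = 1e-3)
  expect_error(matrix_stress(diag(c(-1, 1, 1)), p), "inversion")
})

test_that("effective stress composes matrix and tension-only fibrils", {
  p <- frpe_params(primary_density_fraction = 1, n_secondary = 0L)
  m <- c(1, 0, 0)
  r0 <- effective_stress(diag(3), m, p)
  expect_equal(r0$stress, matrix(0, 3, 3))
  expect_equal(r0$fibril_strain, 0)

  ## compression along the fibril: identical to the matrix alone
  Fc <- diag(c(0.97, 1, 1))
  rc <- effective_stress(Fc, m, p)
  expect_equal(rc$stress, matrix_stress(Fc, p))
  expect_lt(rc$fibril_strain, 0)

  ## 2% tension along the fibril: difference equals the 1-D law on the dyad
  Ft <- diag(c(1.02, 1, 1))
  rt <- effective_stress(Ft, m, p)
  dd <- rt$stress - matrix_stress(Ft, p)
  expect_equal(dd, fibril_stress_1d(0.02, p) * tcrossprod(c(1, 0, 0)),
               tolerance = 1e-8)
  expect_equal(rt$fibril_strain, 0.02)
})

test_that("effective stress is objective under random rotations", {
  p <- frpe_params()
  set.seed(5)
  for (k in 1:5) {
    F1 <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    m <- rnorm(3); m <- m / sqrt(sum(m^2))
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    a <- effective_stress(q %*% F1, m, p)$stress
    b <- q %*% effective_stress(F1, m, p)$stress %*% t(q)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("meniscus elasticity tensor degenerates, solves and rotates correctly", {
  ## isotropic degeneracy
  E <- 20; nu <- 0.3
  iso <- meniscus_params(E_circumferential_MPa = E, E_transverse_MPa = E,
                         G_MPa = E / (2 * (1 + nu)),
                         nu_in_plane = nu, nu_out_of_plane = nu)
  C <- meniscus_elasticity_tensor(iso, c(1, 0, 0))$C_local
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  Ciso <- matrix(0, 6, 6); Ciso[1:3, 1:3] <- lam
  diag(Ciso)[1:3] <- lam + 2 * mu; diag(Ciso)[4:6] <- mu
  expect_equal(C, Ciso, tolerance = 1e-10)

  ## uniaxial stress along the circumferential axis returns E_c
  p <- meniscus_params()
  Cl <- meniscus_elasticity_tensor(p, c(1, 0, 0))$C_local
  S <- solve(Cl)
  expect_equal(1 / S[1, 1], p$E_circumferential_MPa, tolerance = 1e-10)

  ## strain energy is invariant under rotation of the direction
  set.seed(9)
  eps_g <- rnorm(6, sd = 0.01)
  for (k in 1:3) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    out <- meniscus_elasticity_tensor(p, a)
    Te <- cartimech:::strain_rotation(t(out$R))   # global -> local strains
    e_loc <- as.numeric(Te %*% eps_g)
    w_local <- 0.5 * sum(e_loc * (out$C_local %*% e_loc))
    w_global <- 0.5 * sum(eps_g * (out$C_global %*% eps_g))
    expect_equal(w_global, w_local, tolerance = 1e-10)
  }
  expect_error(meniscus_params(nu_in_plane = 0.9, nu_out_of_plane = 0.9),
               "positive-definite")
})
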