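## brute-force between-class variance maximization, the Otsu oracle
otsu_brute <- function(mids, counts) {
  w <- counts / sum(counts)
  mu <- sum(w * mids)
  best <- -Inf; kbest <- NA
  for (k in seq_len(length(mids) - 1)) {
    w0 <- sum(w[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(w[1:k] * mids[1:k]) / w0
    m1 <- (mu - w0 * m0) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-15) { best <- sb; kbest <- k }
  }
  (mids[kbest] + mids[kbest + 1]) / 2
}

test_that("Otsu threshold maximizes between-class variance", {
  expect_gt(otsu_threshold(c(rep(10, 40), rep(100, 60))), 10)
  expect_lt(otsu_threshold(c(rep(10, 40), rep(100, 60))), 100)
  ## perfect bimodality: between-class variance equals the global variance
  x <- c(rep(0, 50), rep(255, 50))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0); expect_lt(thr, 255)
  lo <- x <= thr
  w0 <- mean(lo); w1 <- 1 - w0
  sb <- w0 * w1 * (mean(x[lo]) - mean(x[!lo]))^2
  expect_equal(sb, mean((x - mean(x))^2), tolerance = 1e-12)
  ## random bimodal mixtures match the exhaustive-search oracle
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(300, 40, 8), rnorm(200, 160, 20))
    h <- hist(x, breaks = seq(min(x), max(x), length.out = 257), plot = FALSE)
    expect_equal(otsu_threshold(list(mids = h$mids, counts = h$counts)),
                 otsu_brute(h$mids, h$counts))
  }
  expect_error(otsu_threshold(rep(7, 10)), "single-valued")
})

test_that("phantom calibration recovers the affine HU model", {
  ## noiseless phantoms: exact recovery
  vol <- make_ct_volume(noise_sd = 0, hu_slope = 1.5, hu_intercept = -30)
  cur <- fit_hu_vbmd(vol)
  ## HU = -30 + 1.5 rho  =>  rho = (HU + 30) / 1.5
  expect_equal(cur$hu_slope, 1 / 1.5, tolerance = 1e-10)
  expect_equal(cur$hu_intercept, 30 / 1.5, tolerance = 1e-10)
  expect_equal(cur$r_squared, 1, tolerance = 1e-12)

  ## noisy fit equals the closed-form normal-equations oracle
  vol2 <- make_ct_volume(noise_sd = 8, seed = 5)
  cur2 <- fit_hu_vbmd(vol2)
  means <- vapply(seq_along(vol2$phantom_densities), function(k)
    mean(vol2$hu[vol2$phantom_labels == k]), numeric(1))
  X <- cbind(1, means)
  beta <- solve(crossprod(X), crossprod(X, vol2$phantom_densities))
  expect_equal(cur2$hu_intercept, beta[1], tolerance = 1e-10)
  expect_equal(cur2$hu_slope, beta[2], tolerance = 1e-10)

  ## two phantoms: exact interpolation, R^2 = 1
  vol3 <- make_ct_volume(phantom_densities = c(100, 400), noise_sd = 0)
  expect_equal(fit_hu_vbmd(vol3)$r_squared, 1)
})

test_that("calibration round trip recovers the slope across noisy seeds", {
  ## stochastic property: estimate within 3 standard errors
  slopes <- vapply(1:25, function(sd1) {
    v <- make_ct_volume(noise_sd = 10, seed = sd1, hu_slope = 1.2,
                        hu_intercept = -40)
    fit_hu_vbmd(v)$hu_slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1 / 1.2), 3 * se + 1e-4)
})

test_that("density-elasticity power law behaves as specified", {
  cur <- calibration_curve(1, 0, a_MPa = 6850, b = 1.49)
  expect_equal(as.numeric(density_to_modulus(0, cur)), 0)
  expect_equal(as.numeric(density_to_modulus(1000, cur)), 6850)  # rho = 1 g/cm^3
  lin <- calibration_curve(1, 0, a_MPa = 100, b = 1)
  expect_equal(as.numeric(density_to_modulus(800, lin)),
               2 * as.numeric(density_to_modulus(400, lin)))
  e <- density_to_modulus(c(-5, 10), cur)
  expect_equal(as.numeric(e[1]), 0)
  expect_equal(attr(e, "n_clamped"), 1L)
})

test_that("element mapping integrates the modulus field conservatively", {
  comp <- flat_comp()
  mesh <- comp$mesh
  ## constant field maps exactly
  ec <- map_modulus_to_elements(function(p) rep(42, nrow(p)), mesh, order = 2)
  expect_equal(as.numeric(ec), rep(42, nrow(mesh$elems)), tolerance = 1e-12)
  ## linear field on a tet: one-point rule equals the centroid value
  tet <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     matrix(1:4, 1), elem_type = "tet4")
  lf <- function(p) 2 + 3 * p[, 1] - p[, 2] + 0.5 * p[, 3]
  et <- map_modulus_to_elements(lf, tet, order = 1)
  expect_equal(as.numeric(et), lf(rbind(colMeans(tet$nodes))), tolerance = 1e-12)
  ## quadratic field on one hex: increasing order converges to the analytic
  ## element average (monotone improvement)
  hex <- volume_mesh(as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[, c("x", "y", "z")],
                     matrix(c(1, 2, 4, 3, 5, 6, 8, 7), 1))
  qf <- function(p) p[, 1]^2 + 2 * p[, 2]^2
  exact <- 1 / 3 + 2 / 3
  e1 <- abs(as.numeric(map_modulus_to_elements(qf, hex, order = 1)) - exact)
  e2 <- abs(as.numeric(map_modulus_to_elements(qf, hex, order = 2)) - exact)
  expect_lt(e2, 1e-12)
  expect_gt(e1, e2)
  ## conservation: sum E_e V_e matches the integral within 0.5%
  f <- function(p) 500 + 100 * sin(p[, 1]) + 30 * p[, 3]^2
  em <- map_modulus_to_elements(f, mesh, order = 2)
  vols <- cartimech:::element_volumes(mesh)
  expect_equal(sum(as.numeric(em) * vols), attr(em, "integral_MPa_mm3"),
               tolerance = 0.005)
})

test_that("full bone calibration pipeline runs on a phantom volume", {
  vol <- make_ct_volume(noise_sd = 0, hu_slope = 1, hu_intercept = 0,
                        dim_vox = c(40L, 20L, 16L))
  ## small bone slab inside the volume (mm coordinates)
  nodes <- as.matrix(expand.grid(x = c(1, 3, 5), y = c(1, 2, 3),
                                 z = c(0.5, 1.5, 2.5)))[, c("x", "y", "z")]
  nid <- function(i, j, k) (k - 1) * 9 + (j - 1) * 3 + i
  elems <- NULL
  for (k in 1:2) for (j in 1:2) for (i in 1:2)
    elems <- rbind(elems, c(nid(i, j, k), nid(i + 1, j, k),
                            nid(i + 1, j + 1, k), nid(i, j + 1, k),
                            nid(i, j, k + 1), nid(i + 1, j, k + 1),
                            nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1)))
  mesh <- volume_mesh(nodes, elems)
  out <- calibrate_bone(vol, mesh)
  expect_length(out$E_MPa, nrow(elems))
  expect_true(all(out$E_MPa >= 0))
})
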