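## Material laws: fibril-reinforced porohyperelastic cartilage (elastic
## strain-stiffening fibrils over a compressible Neo-Hookean matrix),
## transversely isotropic elastic meniscus, and the depth-dependent
## Benninghoff arcade fibril orientation field.

#' Fibril-reinforced poroelastic material parameters
#'
#' Constants of the cartilage material: a compressible Neo-Hookean
#' non-fibrillar matrix (proteoglycans + fluid), tension-only collagen
#' fibrils with linearly strain-stiffening modulus
#' `sigma_f = (E0 + Eeps * eps_f) * eps_f`, and Darcy permeability.
#' The defaults are literature-informed values for human knee cartilage;
#' every entry is configurable.
#'
#' @param matrix_E_MPa Young's modulus of the non-fibrillar matrix (MPa)
#' @param matrix_nu Poisson ratio of the non-fibrillar matrix
#' @param permeability_mm4_per_Ns Darcy permeability (mm^4 / N s)
#' @param fibril_E0_MPa initial fibril network modulus (MPa)
#' @param fibril_Eeps_MPa strain-dependent fibril modulus (MPa)
#' @param primary_density_fraction fraction of total fibril density carried
#'   by the primary (arcade-oriented) fibril family; the remainder is split
#'   evenly over the secondary directions
#' @param n_secondary number of isotropically distributed secondary fibril
#'   directions
#' @param solid_volume_fraction solid fraction of the biphasic mixture
#'   (metadata; the mixture is treated as intrinsically incompressible)
#' @param superficial_fraction,deep_fraction normalized-depth boundaries of
#'   the superficial and deep collagen zones
#' @return object of class `frpe_params`
#' @export
frpe_params <- function(matrix_E_MPa = 0.31, matrix_nu = 0.42,
                        permeability_mm4_per_Ns = 2e-3,
                        fibril_E0_MPa = 0.47, fibril_Eeps_MPa = 150,
                        primary_density_fraction = 0.75,
                        n_secondary = 13L,
                        solid_volume_fraction = 0.2,
                        superficial_fraction = 0.15, deep_fraction = 0.70) {
  check_scalar(matrix_E_MPa, "matrix_E_MPa", 0, Inf)
  check_scalar(matrix_nu, "matrix_nu", -1, 0.5, strict_upper = TRUE)
  check_scalar(permeability_mm4_per_Ns, "permeability", 0, Inf, strict_lower = TRUE)
  check_scalar(fibril_E0_MPa, "fibril_E0_MPa", 0, Inf)
  check_scalar(fibril_Eeps_MPa, "fibril_Eeps_MPa", 0, Inf)
  check_scalar(primary_density_fraction, "primary_density_fraction", 0, 1)
  check_scalar(superficial_fraction, "superficial_fraction", 0, 1)
  check_scalar(deep_fraction, "deep_fraction", 0, 1)
  if (deep_fraction <= superficial_fraction)
    stopf("deep_fraction must exceed superficial_fraction")
  structure(list(matrix_E_MPa = matrix_E_MPa, matrix_nu = matrix_nu,
                 permeability_mm4_per_Ns = permeability_mm4_per_Ns,
                 fibril_E0_MPa = fibril_E0_MPa, fibril_Eeps_MPa = fibril_Eeps_MPa,
                 primary_density_fraction = primary_density_fraction,
                 n_secondary = as.integer(n_secondary),
                 solid_volume_fraction = solid_volume_fraction,
                 superficial_fraction = superficial_fraction,
                 deep_fraction = deep_fraction,
                 units = list(modulus = "MPa", permeability = "mm^4/(N s)")),
            class = "frpe_params")
}

#' @export
print.frpe_params <- function(x, ...) {
  cat(sprintf(paste0("<frpe_params> matrix E=%.3g MPa nu=%.2f, k=%.2g mm^4/Ns, ",
                     "fibrils E0=%.3g Eeps=%.3g MPa (primary %.0f%%, %d secondary)\n"),
              x$matrix_E_MPa, x$matrix_nu, x$permeability_mm4_per_Ns,
              x$fibril_E0_MPa, x$fibril_Eeps_MPa,
              100 * x$primary_density_fraction, x$n_secondary))
  invisible(x)
}

lame_constants <- function(params) {
  E <- params$matrix_E_MPa; nu <- params$matrix_nu
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

## deterministic, approximately uniform unit directions (Fibonacci sphere)
secondary_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Benninghoff arcade fibril direction
#'
#' Depth-continuous primary collagen fibril direction: equal to the surface
#' split-line direction in the superficial zone, to the inward surface
#' normal (pointing toward the bone) in the deep zone, and a spherical
#' linear interpolation between them through the middle zone.
#'
#' @param normalized_depth scalar or vector in \[0, 1\] (0 = articular
#'   surface, 1 = bone interface)
#' @param surface_normal unit outward normal(s), 3-vector or matrix
#' @param split_line unit split-line tangent(s)
#' @param superficial_fraction,deep_fraction zone boundaries
#' @return matrix of unit fibril directions (one per row)
#' @export
arcade_direction <- function(normalized_depth, surface_normal, split_line,
                             superficial_fraction = 0.15, deep_fraction = 0.70) {
  d <- as.numeric(normalized_depth)
  if (any(d < -1e-12 | d > 1 + 1e-12))
    stopf("normalized_depth must lie in [0, 1]")
  d <- pmin(1, pmax(0, d))
  nmat <- matrix(surface_normal, ncol = 3)
  smat <- matrix(split_line, ncol = 3)
  if (nrow(nmat) == 1) nmat <- nmat[rep(1, length(d)), , drop = FALSE]
  if (nrow(smat) == 1) smat <- smat[rep(1, length(d)), , drop = FALSE]
  if (max(abs(rowSums(nmat^2) - 1)) > 1e-8 || max(abs(rowSums(smat^2) - 1)) > 1e-8)
    stopf("surface_normal and split_line must be unit vectors")
  if (max(abs(rowSums(nmat * smat))) > 1e-8)
    stopf("split_line must be tangent to the surface")
  a <- smat                          # superficial end
  b <- -nmat                         # deep end (toward bone)
  s <- (d - superficial_fraction) / (deep_fraction - superficial_fraction)
  s <- pmin(1, pmax(0, s))
  ## a and b are orthogonal, so slerp reduces to cos/sin blending
  out <- a * cos(s * pi / 2) + b * sin(s * pi / 2)
  row_normalize(out)
}

#' Tension-only fibril stress (1-D)
#'
#' `sigma_f = (E0 + Eeps * eps) * eps` for tensile fibril strain, zero in
#' compression.
#'
#' @param fibril_strain engineering fibril strain(s), stretch minus one
#' @param params an [frpe_params()]
#' @return fibril stress (MPa), same length as the input
#' @export
fibril_stress_1d <- function(fibril_strain, params) {
  if (any(fibril_strain <= -1)) stopf("fibril strain must exceed -1")
  eps <- pmax(0, fibril_strain)
  (params$fibril_E0_MPa + params$fibril_Eeps_MPa * eps) * eps
}

## tangent modulus of the 1-D fibril law (d sigma / d eps), tension only
fibril_tangent_1d <- function(fibril_strain, params) {
  active <- fibril_strain > 0
  ifelse(active,
         params$fibril_E0_MPa + 2 * params$fibril_Eeps_MPa * pmax(0, fibril_strain),
         0)
}

#' Compressible Neo-Hookean matrix stress
#'
#' Effective Cauchy stress of the non-fibrillar matrix,
#' `sigma = mu/J (B - I) + lambda ln(J)/J I`, zero at the identity.
#'
#' @param F 3x3 deformation gradient
#' @param params an [frpe_params()]
#' @return symmetric 3x3 Cauchy stress (MPa)
#' @export
matrix_stress <- function(F, params) {
  F <- matrix(F, 3, 3)
  J <- det(F)
  if (J <= 0) stopf("element inversion: det(F) = %.3g <= 0", J)
  lc <- lame_constants(params)
  B <- F %*% t(F)
  s <- lc$mu / J * (B - diag(3)) + lc$lambda * log(J) / J * diag(3)
  (s + t(s)) / 2
}

#' Fibril-reinforced effective stress at a material point
#'
#' Total effective Cauchy stress: the Neo-Hookean matrix stress plus
#' tension-only fibril contributions from the primary (arcade-oriented)
#' family and `n_secondary` isotropically distributed secondary directions,
#' each push-forwarded to the current configuration as
#' `rho_i sigma_f(lambda_i - 1) n_i (x) n_i` with `n_i = F m_i / lambda_i`.
#'
#' @param F 3x3 deformation gradient
#' @param primary_direction unit reference direction of the primary fibrils
#' @param params an [frpe_params()]
#' @return list with `stress` (3x3, MPa) and `fibril_strain` (primary family
#'   engineering strain, stretch minus one)
#' @export
effective_stress <- function(F, primary_direction, params) {
  F <- matrix(F, 3, 3)
  sig <- matrix_stress(F, params)
  dirs <- rbind(primary_direction / sqrt(sum(primary_direction^2)))
  dens <- params$primary_density_fraction
  if (params$n_secondary > 0 && params$primary_density_fraction < 1) {
    sec <- secondary_directions(params$n_secondary)
    dirs <- rbind(dirs, sec)
    dens <- c(dens, rep((1 - params$primary_density_fraction) / params$n_secondary,
                        params$n_secondary))
  }
  eps_primary <- NA_real_
  for (i in seq_len(nrow(dirs))) {
    m <- dirs[i, ]
    fm <- as.numeric(F %*% m)
    lam <- sqrt(sum(fm^2))
    eps <- lam - 1
    if (i == 1) eps_primary <- eps
    if (eps > 0) {
      n <- fm / lam
      sig <- sig + dens[i] * fibril_stress_1d(eps, params) * tcrossprod(n)
    }
  }
  list(stress = sig, fibril_strain = eps_primary)
}

## --- meniscus ---------------------------------------------------------------

#' Transversely isotropic meniscus parameters
#'
#' @param E_circumferential_MPa modulus along the circumferential fibre axis
#' @param E_transverse_MPa in-plane (radial/axial) modulus
#' @param G_MPa axial shear modulus (circumferential-transverse planes)
#' @param nu_in_plane Poisson ratio in the transverse (isotropic) plane
#' @param nu_out_of_plane Poisson ratio coupling the circumferential axis to
#'   the transverse plane (strain in plane per strain along the axis)
#' @return object of class `meniscus_params`; positive definiteness of the
#'   resulting elasticity tensor is verified at construction
#' @export
meniscus_params <- function(E_circumferential_MPa = 120,
                            E_transverse_MPa = 20,
                            G_MPa = 50,
                            nu_in_plane = 0.3,
                            nu_out_of_plane = 0.3) {
  p <- structure(list(E_circumferential_MPa = E_circumferential_MPa,
                      E_transverse_MPa = E_transverse_MPa,
                      G_MPa = G_MPa, nu_in_plane = nu_in_plane,
                      nu_out_of_plane = nu_out_of_plane,
                      units = "MPa"),
                 class = "meniscus_params")
  C <- meniscus_elasticity_tensor(p, c(1, 0, 0))$C_local
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("meniscus parameter combination gives a non-positive-definite elasticity tensor")
  p
}

## Strain transformation matrix T such that eps'_voigt = T %*% eps_voigt for
## the tensor rotation eps' = Q eps Q^T, Voigt order (11,22,33,12,23,13) with
## engineering shear strains.
strain_rotation <- function(Q) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(1, 3))
  M <- matrix(0, 6, 6)
  for (I in 1:6) {
    i <- idx[I, 1]; j <- idx[I, 2]
    fac <- if (I > 3) 2 else 1          # shear rows carry engineering factor
    for (J in 1:3) {
      k <- idx[J, 1]
      M[I, J] <- fac * Q[i, k] * Q[j, k]
    }
    for (J in 4:6) {
      k <- idx[J, 1]; l <- idx[J, 2]
      M[I, J] <- fac * (Q[i, k] * Q[j, l] + Q[i, l] * Q[j, k]) / 2
    }
  }
  M
}

#' Transversely isotropic elasticity tensor for the meniscus
#'
#' Builds the 6x6 stiffness (Voigt order 11,22,33,12,23,13, engineering
#' shear) in a local frame whose first axis is the circumferential fibre
#' direction, together with the rotation that maps it to the global frame.
#'
#' @param params a [meniscus_params()]
#' @param circumferential_direction unit 3-vector, local fibre axis
#' @return list with `C_local`, `C_global` (6x6 stiffness, MPa) and the
#'   3x3 rotation `R` (columns = local axes in global coordinates)
#' @export
meniscus_elasticity_tensor <- function(params, circumferential_direction) {
  Ea <- params$E_circumferential_MPa
  Et <- params$E_transverse_MPa
  G <- params$G_MPa
  nut <- params$nu_in_plane        # within transverse plane
  nua <- params$nu_out_of_plane    # axis-to-plane
  ## compliance in local frame, axis = 1
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / Ea
  S[2, 2] <- S[3, 3] <- 1 / Et
  S[1, 2] <- S[2, 1] <- -nua / Ea
  S[1, 3] <- S[3, 1] <- -nua / Ea
  S[2, 3] <- S[3, 2] <- -nut / Et
  S[4, 4] <- 1 / G                 # 12 shear (axis involved)
  S[6, 6] <- 1 / G                 # 13 shear (axis involved)
  S[5, 5] <- 2 * (1 + nut) / Et    # 23 shear (transverse plane)
  C <- solve(S)
  a <- circumferential_direction / sqrt(sum(circumferential_direction^2))
  ## build orthonormal frame (a, t1, t2)
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - a * sum(ref * a); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(a[2] * t1[3] - a[3] * t1[2],
          a[3] * t1[1] - a[1] * t1[3],
          a[1] * t1[2] - a[2] * t1[1])
  R <- cbind(a, t1, t2)            # local -> global
  Te <- strain_rotation(t(R))      # global strain -> local strain
  Cg <- t(Te) %*% C %*% Te
  Cg <- (Cg + t(Cg)) / 2
  list(C_local = C, C_global = Cg, R = R)
}
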