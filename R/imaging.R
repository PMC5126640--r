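## CT-side computations: Otsu thresholding, HU -> vBMD phantom calibration,
## density -> Young's modulus power law, and element-wise modulus mapping by
## numerical integration of the continuum field.

#' Otsu threshold of an intensity histogram
#'
#' Exhaustive maximization of the between-class variance over all candidate
#' thresholds; ties are broken by the lower threshold.
#'
#' @param x either a numeric vector of intensities, or a list/data frame
#'   with `mids` and `counts` (a precomputed histogram)
#' @param n_bins number of histogram bins when raw intensities are given
#' @return the threshold value (class boundary); intensities strictly above
#'   it belong to the upper class
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  if (is.list(x)) {
    mids <- x$mids; counts <- as.numeric(x$counts)
  } else {
    x <- as.numeric(x)
    if (!length(x)) stopf("empty intensity input")
    if (length(unique(x)) < 2)
      stopf("Otsu threshold undefined for single-valued input")
    h <- hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
              plot = FALSE)
    mids <- h$mids; counts <- h$counts
  }
  if (sum(counts > 0) < 2)
    stopf("Otsu threshold undefined for single-valued input")
  w <- counts / sum(counts)
  ## candidate threshold after bin k: classes [1..k], [k+1..n]
  n <- length(mids)
  w0 <- cumsum(w)[-n]
  w1 <- 1 - w0
  mu_all <- sum(w * mids)
  mu0 <- cumsum(w * mids)[-n]
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n - 1)
  sb[valid] <- (mu_all * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sb)                      # which.max returns the first (lower) tie
  (mids[k] + mids[k + 1]) / 2
}

#' Calibration curve container
#'
#' @param hu_slope,hu_intercept HU -> vBMD affine map (mg/cm^3 per HU and
#'   mg/cm^3)
#' @param r_squared coefficient of determination of the phantom fit
#' @param residuals fit residuals (mg/cm^3)
#' @param a_MPa,b density -> modulus power law `E = a * rho^b` with rho in
#'   g/cm^3
#' @return object of class `calibration_curve`
#' @export
calibration_curve <- function(hu_slope, hu_intercept, r_squared = NA_real_,
                              residuals = numeric(0),
                              a_MPa = 6850, b = 1.49) {
  if (hu_slope <= 0) stopf("HU->density slope must be positive")
  if (a_MPa <= 0) stopf("density-elasticity coefficient must be positive")
  structure(list(hu_slope = hu_slope, hu_intercept = hu_intercept,
                 r_squared = r_squared, residuals = residuals,
                 a_MPa = a_MPa, b = b,
                 units = list(density = "mg/cm^3", modulus = "MPa",
                              power_law_density = "g/cm^3")),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> vBMD = %.4g * HU + %.4g (R^2 = %.4f); E = %g * rho^%g MPa\n",
              x$hu_slope, x$hu_intercept, x$r_squared, x$a_MPa, x$b))
  invisible(x)
}

#' Fit the HU to vBMD calibration from phantom ROIs
#'
#' Ordinary least squares of the known phantom densities on the ROI mean
#' intensities, optionally weighted by ROI voxel counts.
#'
#' @param volume an [make_ct_volume()] result (or any list with `hu`,
#'   `phantom_labels`, `phantom_densities`)
#' @param weight_by_voxels weight the fit by ROI voxel counts
#' @param a_MPa,b power-law constants stored on the returned curve
#' @return a [calibration_curve()]
#' @export
fit_hu_vbmd <- function(volume, weight_by_voxels = FALSE,
                        a_MPa = 6850, b = 1.49) {
  labs <- volume$phantom_labels
  dens <- volume$phantom_densities
  np <- length(dens)
  mean_hu <- vapply(seq_len(np), function(k) mean(volume$hu[labs == k]),
                    numeric(1))
  nvox <- vapply(seq_len(np), function(k) sum(labs == k), numeric(1))
  if (any(nvox == 0)) stopf("phantom ROI %d is empty", which(nvox == 0)[1])
  if (max(mean_hu) - min(mean_hu) < 1e-9)
    stopf("phantom ROI intensities are identical: calibration is rank-deficient")
  fit <- if (weight_by_voxels) lm(dens ~ mean_hu, weights = nvox)
  else lm(dens ~ mean_hu)
  sl <- unname(coef(fit)[2])
  if (sl <= 0) stopf("calibration slope is non-positive; check phantom data")
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((dens - mean(dens))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  calibration_curve(hu_slope = sl, hu_intercept = unname(coef(fit)[1]),
                    r_squared = r2, residuals = res,
                    a_MPa = a_MPa, b = b)
}

#' Convert calibrated density to Young's modulus
#'
#' Power law `E = a * rho^b` with rho in g/cm^3 (inputs are mg/cm^3, the
#' vBMD convention). Negative calibrated densities are clamped to zero; the
#' number of clamped values is attached as an attribute.
#'
#' @param vbmd volumetric bone mineral density (mg/cm^3), scalar or array
#' @param curve a [calibration_curve()]
#' @return Young's modulus (MPa), same shape as the input
#' @export
density_to_modulus <- function(vbmd, curve) {
  n_neg <- sum(vbmd < 0)
  rho <- pmax(vbmd, 0) / 1000          # mg/cm^3 -> g/cm^3
  E <- curve$a_MPa * rho^curve$b
  attr(E, "n_clamped") <- n_neg
  E
}

#' Convert a HU volume (or values) to modulus via a calibration curve
#' @param hu HU values
#' @param curve a [calibration_curve()]
#' @return Young's moduli (MPa)
#' @export
hu_to_modulus <- function(hu, curve) {
  density_to_modulus(curve$hu_intercept + curve$hu_slope * hu, curve)
}

## Gauss-Legendre points/weights on [-1, 1]
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

#' Map a continuum modulus field onto mesh elements
#'
#' Per-element Young's modulus as the volume average of the continuum field
#' computed by Gaussian quadrature of the requested order, for hex8 and
#' tet4 meshes. The total integral of E over the mesh is preserved between
#' the field and the element table (within quadrature accuracy).
#'
#' @param field function of (x, y, z) (vectorized over matrix rows) giving
#'   the modulus (MPa)
#' @param mesh a `volume_mesh`
#' @param order quadrature order per direction (hex8) or a tet rule
#'   selector (1 = centroid, 4 = four-point)
#' @return numeric per-element moduli with attribute `integral_MPa_mm3`
#' @export
map_modulus_to_elements <- function(field, mesh, order = 2) {
  E <- nrow(mesh$elems)
  val <- numeric(E)
  tot <- 0
  if (mesh$elem_type == "hex8") {
    gl <- gauss_legendre(order)
    for (e in seq_len(E)) {
      X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
      s <- 0; vol <- 0
      for (i in seq_len(order)) for (j in seq_len(order)) for (k in seq_len(order)) {
        sh <- hex_shape(c(gl$x[i], gl$x[j], gl$x[k]))
        J <- crossprod(sh$dN, X)
        dv <- det(J) * gl$w[i] * gl$w[j] * gl$w[k]
        p <- as.numeric(crossprod(sh$N, X))
        fv <- field(matrix(p, 1, 3))
        s <- s + fv * dv
        vol <- vol + dv
      }
      val[e] <- s / vol
      tot <- tot + s
    }
  } else if (mesh$elem_type == "tet4") {
    for (e in seq_len(E)) {
      X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
      vol <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
      pts <- if (order <= 1) matrix(colMeans(X), 1, 3) else {
        a <- 0.5854101966249685; b <- 0.1381966011250105
        L <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
        L %*% X
      }
      fv <- mean(field(pts))
      val[e] <- fv
      tot <- tot + fv * vol
    }
  } else stopf("unsupported element type %s", mesh$elem_type)
  attr(val, "integral_MPa_mm3") <- tot
  val
}

#' Full bone calibration pipeline for a phantom volume
#'
#' Fits the HU to vBMD calibration, converts the calibrated density field
#' to a continuum modulus field, and maps it onto the elements of a bone
#' mesh by numerical integration.
#'
#' @param volume an [make_ct_volume()] result
#' @param mesh the bone `volume_mesh` positioned in the volume's
#'   coordinate frame (mm; the volume origin is at (0, 0, 0))
#' @inheritParams fit_hu_vbmd
#' @param order quadrature order for [map_modulus_to_elements()]
#' @return list with the `curve` and per-element `E_MPa`
#' @export
calibrate_bone <- function(volume, mesh, weight_by_voxels = FALSE,
                           a_MPa = 6850, b = 1.49, order = 2) {
  curve <- fit_hu_vbmd(volume, weight_by_voxels, a_MPa, b)
  vs <- volume$voxel_size_mm
  dims <- dim(volume$hu)
  field <- function(p) {
    ii <- pmin(pmax(round(p[, 1] / vs + 0.5), 1), dims[1])
    jj <- pmin(pmax(round(p[, 2] / vs + 0.5), 1), dims[2])
    kk <- pmin(pmax(round(p[, 3] / vs + 0.5), 1), dims[3])
    as.numeric(hu_to_modulus(volume$hu[cbind(ii, jj, kk)], curve))
  }
  list(curve = curve, E_MPa = map_modulus_to_elements(field, mesh, order))
}
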