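## Synthetic fixtures: idealized tibial compartment, stance-phase load
## protocol, CT phantom volume, and parametric defect footprints.
##
## All generators are pure functions of (spec, seed). Units repo-wide:
## mm, N, MPa, s; densities in mg/cm^3.

#' Compartment specification
#'
#' Parameters of the idealized medial tibial compartment: a shallow spherical
#' dish carrying a cartilage layer of spatially varying thickness, contacted
#' by a rigid spherical indenter standing in for the femoral condyle.
#'
#' @param plateau_extent_mm length-2 vector, anterior-posterior and
#'   medial-lateral extent of the meshed patch (mm)
#' @param thickness_base_mm base cartilage thickness (mm)
#' @param thickness_gradient_mm_per_mm length-2 vector, linear in-plane
#'   thickness gradient (mm/mm)
#' @param thickness_bump_mm optional central thickness bump amplitude (mm)
#' @param surface_curvature_radius_mm radius of the spherical dish (mm);
#'   the default is an effective, meniscus-conformed tibial surface that
#'   yields physiological contact areas against the default indenter
#' @param meniscus_enabled generate a partial-annulus meniscus wedge with
#'   horn attachment node sets
#' @param indenter_radius_mm radius of the rigid spherical indenter (mm)
#' @param target_element_size_mm in-plane target element edge length (mm)
#' @param split_line_angle_deg surface split-line direction, degrees from the
#'   anterior-posterior axis
#' @param split_line_swirl_deg_per_mm optional linear swirl of the split-line
#'   angle across the medial-lateral coordinate
#' @param meniscus_element_size_mm meniscus element size (mm)
#' @param seed integer seed (generators are deterministic; carried for
#'   provenance)
#' @return an object of class `compartment_spec`
#' @export
compartment_spec <- function(plateau_extent_mm = c(20, 20),
                             thickness_base_mm = 2.0,
                             thickness_gradient_mm_per_mm = c(0.05, 0),
                             thickness_bump_mm = 0.6,
                             surface_curvature_radius_mm = 45,
                             meniscus_enabled = FALSE,
                             indenter_radius_mm = 35,
                             target_element_size_mm = 1.0,
                             split_line_angle_deg = 0,
                             split_line_swirl_deg_per_mm = 0,
                             meniscus_element_size_mm = 0.8,
                             seed = 1L) {
  stopifnot(length(plateau_extent_mm) == 2)
  if (any(plateau_extent_mm <= 0)) stopf("plateau extents must be positive")
  check_scalar(target_element_size_mm, "target_element_size_mm", 0, Inf,
               strict_lower = TRUE)
  check_scalar(surface_curvature_radius_mm, "surface_curvature_radius_mm",
               max(plateau_extent_mm), Inf, strict_lower = TRUE)
  check_scalar(indenter_radius_mm, "indenter_radius_mm", 0, Inf, strict_lower = TRUE)
  spec <- structure(list(
    plateau_extent_mm = as.numeric(plateau_extent_mm),
    thickness_base_mm = thickness_base_mm,
    thickness_gradient_mm_per_mm = as.numeric(thickness_gradient_mm_per_mm),
    thickness_bump_mm = thickness_bump_mm,
    surface_curvature_radius_mm = surface_curvature_radius_mm,
    meniscus_enabled = isTRUE(meniscus_enabled),
    indenter_radius_mm = indenter_radius_mm,
    target_element_size_mm = target_element_size_mm,
    split_line_angle_deg = split_line_angle_deg,
    split_line_swirl_deg_per_mm = split_line_swirl_deg_per_mm,
    meniscus_element_size_mm = meniscus_element_size_mm,
    seed = as.integer(seed)), class = "compartment_spec")
  tr <- range(spec_thickness_corners(spec))
  if (tr[1] <= 0.5 || tr[2] >= 6.0)
    stopf("thickness profile range (%.2f, %.2f) mm outside the allowed (0.5, 6.0) mm",
          tr[1], tr[2])
  spec
}

spec_thickness_corners <- function(spec, center = c(0, 0)) {
  hx <- spec$plateau_extent_mm[1] / 2; hy <- spec$plateau_extent_mm[2] / 2
  g <- expand.grid(x = center[1] + seq(-hx, hx, length.out = 9),
                   y = center[2] + seq(-hy, hy, length.out = 9))
  thickness_at(spec, g$x, g$y)
}

#' Analytic articular surface height of a compartment (mm)
#' @param spec a `compartment_spec` (or a `compartment`)
#' @param x,y in-plane coordinates (mm)
#' @export
surface_height_at <- function(spec, x, y) {
  if (inherits(spec, "compartment")) spec <- spec$spec
  Rc <- spec$surface_curvature_radius_mm
  Rc - sqrt(Rc^2 - (x^2 + y^2))
}

#' Analytic cartilage thickness profile (mm)
#' @inheritParams surface_height_at
#' @export
thickness_at <- function(spec, x, y) {
  if (inherits(spec, "compartment")) spec <- spec$spec
  sig <- max(spec$plateau_extent_mm) / 5
  spec$thickness_base_mm +
    spec$thickness_gradient_mm_per_mm[1] * x +
    spec$thickness_gradient_mm_per_mm[2] * y +
    spec$thickness_bump_mm * exp(-(x^2 + y^2) / (2 * sig^2))
}

#' Outward (articular-side) surface normal
#' @inheritParams surface_height_at
#' @return matrix with one unit normal per row
#' @export
surface_normal_at <- function(spec, x, y) {
  if (inherits(spec, "compartment")) spec <- spec$spec
  Rc <- spec$surface_curvature_radius_mm
  den <- sqrt(Rc^2 - (x^2 + y^2))
  row_normalize(cbind(-x / den, -y / den, rep(1, length(x))))
}

split_line_at <- function(spec, x, y) {
  if (inherits(spec, "compartment")) spec <- spec$spec
  phi <- (spec$split_line_angle_deg + spec$split_line_swirl_deg_per_mm * y) * pi / 180
  a <- cbind(cos(phi), sin(phi), rep(0, length(x)))
  n <- surface_normal_at(spec, x, y)
  d <- a - n * rowSums(a * n)
  row_normalize(d)
}

#' Generate the idealized compartment geometry
#'
#' Builds a layered hexahedral cartilage mesh (at least four element layers
#' through the thickness) between the analytic articular surface and the
#' bone interface offset along the local surface normal by the thickness
#' profile, together with the intact surface triangulation, per-vertex
#' thickness and split-line fields, the rigid spherical indenter, and (when
#' enabled) a meniscus wedge with horn attachment node sets.
#'
#' @param spec a [compartment_spec()]
#' @param patch_center optional in-plane center of the meshed patch (mm);
#'   used to build submodel meshes around a defect location on the same
#'   analytic surface
#' @return an object of class `compartment` with elements `mesh`,
#'   `intact_surface`, `indenter`, `meniscus`, `horn_attachments`, `spec`
#' @export
make_compartment <- function(spec, patch_center = c(0, 0)) {
  if (!inherits(spec, "compartment_spec")) stopf("spec must be a compartment_spec")
  h <- spec$target_element_size_mm
  hx <- spec$plateau_extent_mm[1] / 2; hy <- spec$plateau_extent_mm[2] / 2
  tmin <- min(spec_thickness_corners(spec, patch_center))
  if (h > tmin)
    stopf("target element size %.2f mm exceeds minimum cartilage thickness %.2f mm",
          h, tmin)
  nx <- max(2L, round(spec$plateau_extent_mm[1] / h))
  ny <- max(2L, round(spec$plateau_extent_mm[2] / h))
  nz <- max(4L, round(mean(spec_thickness_corners(spec, patch_center)) / h))
  xs <- patch_center[1] + seq(-hx, hx, length.out = nx + 1)
  ys <- patch_center[2] + seq(-hy, hy, length.out = ny + 1)
  ## through-thickness layers graded toward the articular surface so the
  ## superficial collagen zone (top 15%) is resolved by at least two layers
  dks <- seq(0, 1, length.out = nz + 1)^1.6

  g <- expand.grid(x = xs, y = ys)          # column (i,j) grid, x fastest
  zsurf <- surface_height_at(spec, g$x, g$y)
  thick <- thickness_at(spec, g$x, g$y)
  nrm <- surface_normal_at(spec, g$x, g$y)
  spl <- split_line_at(spec, g$x, g$y)
  ncol_grid <- nrow(g)

  nodes <- matrix(0, ncol_grid * (nz + 1), 3)
  for (k in 0:nz) {
    idx <- k * ncol_grid + seq_len(ncol_grid)
    d <- dks[k + 1]
    nodes[idx, ] <- cbind(g$x, g$y, zsurf) - nrm * (d * thick)
  }
  nid <- function(i, j, k) k * ncol_grid + (j - 1L) * (nx + 1L) + i

  ne <- nx * ny * nz
  elems <- matrix(0L, ne, 8)
  e <- 0L
  for (kl in 0:(nz - 1)) {
    ktop <- kl; kbot <- kl + 1L     # k grows with depth; bottom face is deeper
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      e <- e + 1L
      elems[e, ] <- c(nid(i, j, kbot), nid(i + 1L, j, kbot),
                      nid(i + 1L, j + 1L, kbot), nid(i, j + 1L, kbot),
                      nid(i, j, ktop), nid(i + 1L, j, ktop),
                      nid(i + 1L, j + 1L, ktop), nid(i, j + 1L, ktop))
    }
  }

  surf_nodes <- seq_len(ncol_grid)
  bone_nodes <- nz * ncol_grid + seq_len(ncol_grid)
  top_elems <- which(rep(0:(nz - 1), each = nx * ny) == 0)
  bot_elems <- which(rep(0:(nz - 1), each = nx * ny) == nz - 1)
  side_nodes <- which(abs(abs(rep(g$x - patch_center[1], nz + 1)) - hx) < 1e-9 |
                        abs(abs(rep(g$y - patch_center[2], nz + 1)) - hy) < 1e-9)

  face_sets <- list(
    surface = cbind(top_elems, 2L),   # zmax local face = articular side
    bone = cbind(bot_elems, 1L))

  fields <- list(
    depth = rep(dks, each = ncol_grid),
    thickness = rep(thick, nz + 1),
    normal = nrm[rep(seq_len(ncol_grid), nz + 1), , drop = FALSE],
    split_line = spl[rep(seq_len(ncol_grid), nz + 1), , drop = FALSE])

  mesh <- volume_mesh(nodes, elems,
                      material = rep(1L, ne),
                      node_sets = list(surface = surf_nodes, bone = bone_nodes,
                                       sides = side_nodes),
                      face_sets = face_sets,
                      fields = fields)
  attr(mesh, "grid") <- list(nx = nx, ny = ny, nz = nz, xs = xs, ys = ys,
                             ncol_grid = ncol_grid)

  ## intact surface triangulation (two triangles per grid cell)
  tris <- matrix(0L, 2L * nx * ny, 3)
  tt <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j, 0L); b <- nid(i + 1L, j, 0L)
    cc <- nid(i + 1L, j + 1L, 0L); d <- nid(i, j + 1L, 0L)
    tris[tt + 1L, ] <- c(a, b, cc); tris[tt + 2L, ] <- c(a, cc, d)
    tt <- tt + 2L
  }
  intact_surface <- surface_mesh(nodes[surf_nodes, , drop = FALSE],
                                 matrix(match(tris, surf_nodes), ncol = 3),
                                 fields = list(thickness = thick,
                                               split_line = spl))

  cen_z <- surface_height_at(spec, 0, 0)
  indenter <- list(radius = spec$indenter_radius_mm,
                   center = c(0, 0, cen_z + spec$indenter_radius_mm),
                   mesh = sphere_cap_mesh(c(0, 0, cen_z + spec$indenter_radius_mm),
                                          spec$indenter_radius_mm,
                                          cap_angle = asin(min(0.9, 0.6 * max(hx, hy) /
                                                                 spec$indenter_radius_mm))))
  meniscus <- NULL; horns <- list()
  if (spec$meniscus_enabled) {
    men <- make_meniscus(spec)
    meniscus <- men$mesh
    horns <- men$horns
  }

  structure(list(spec = spec, mesh = mesh, intact_surface = intact_surface,
                 indenter = indenter, meniscus = meniscus,
                 horn_attachments = horns),
            class = "compartment")
}

#' @export
print.compartment <- function(x, ...) {
  g <- attr(x$mesh, "grid")
  cat(sprintf("<compartment> %dx%dx%d hex grid, thickness %.2f-%.2f mm, indenter R=%.0f mm%s\n",
              g$nx, g$ny, g$nz, min(x$mesh$fields$thickness),
              max(x$mesh$fields$thickness), x$indenter$radius,
              if (is.null(x$meniscus)) "" else ", meniscus enabled"))
  invisible(x)
}

## triangulated spherical cap (indenter surrogate surface, pole pointing down)
sphere_cap_mesh <- function(center, radius, cap_angle, n_theta = 12L, n_phi = 24L) {
  th <- seq(0, cap_angle, length.out = n_theta + 1)[-1]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  pts <- rbind(c(0, 0, -radius))
  for (t1 in th) for (p1 in ph)
    pts <- rbind(pts, radius * c(sin(t1) * cos(p1), sin(t1) * sin(p1), -cos(t1)))
  pts <- sweep(pts, 2, center, `+`)
  tris <- NULL
  idx <- function(it, ip) 1L + (it - 1L) * n_phi + ((ip - 1L) %% n_phi) + 1L
  for (ip in seq_len(n_phi)) tris <- rbind(tris, c(1L, idx(1, ip), idx(1, ip + 1)))
  if (n_theta > 1) for (it in seq_len(n_theta - 1)) for (ip in seq_len(n_phi)) {
    a <- idx(it, ip); b <- idx(it, ip + 1); cc <- idx(it + 1, ip); d <- idx(it + 1, ip + 1)
    tris <- rbind(tris, c(a, b, d), c(a, d, cc))
  }
  surface_mesh(pts, tris)
}

## partial-annulus meniscus wedge with horn attachment node sets
make_meniscus <- function(spec) {
  h <- spec$meniscus_element_size_mm
  hx <- spec$plateau_extent_mm[1] / 2
  ri <- 0.45 * hx; ro <- 0.85 * hx
  th0 <- -2.2; th1 <- 2.2                    # C-shape opening, radians
  nt <- max(8L, ceiling((th1 - th0) * (ri + ro) / 2 / h))
  nr <- max(2L, ceiling((ro - ri) / h))
  nzm <- 2L
  ths <- seq(th0, th1, length.out = nt + 1)
  rs <- seq(ri, ro, length.out = nr + 1)
  grid <- expand.grid(th = ths, r = rs)
  x <- grid$r * cos(grid$th); y <- grid$r * sin(grid$th)
  zb <- surface_height_at(spec, x, y) + 0.1   # rests just above cartilage
  wedge_h <- 1.0 + 3.0 * (grid$r - ri) / (ro - ri)  # thin inner, tall outer rim
  ncg <- nrow(grid)
  nodes <- NULL
  for (k in 0:nzm) nodes <- rbind(nodes, cbind(x, y, zb + wedge_h * k / nzm))
  nid <- function(it, ir, k) k * ncg + (ir - 1L) * (nt + 1L) + it
  elems <- NULL
  for (k in 0:(nzm - 1)) for (ir in seq_len(nr)) for (it in seq_len(nt)) {
    elems <- rbind(elems, c(nid(it, ir, k), nid(it + 1L, ir, k),
                            nid(it + 1L, ir + 1L, k), nid(it, ir + 1L, k),
                            nid(it, ir, k + 1L), nid(it + 1L, ir, k + 1L),
                            nid(it + 1L, ir + 1L, k + 1L), nid(it, ir + 1L, k + 1L)))
  }
  horn_a <- as.integer(sapply(0:nzm, function(k) sapply(seq_len(nr + 1), function(ir) nid(1L, ir, k))))
  horn_p <- as.integer(sapply(0:nzm, function(k) sapply(seq_len(nr + 1), function(ir) nid(nt + 1L, ir, k))))
  ## circumferential direction field (unit tangent of the annulus)
  circ <- row_normalize(cbind(-y, x, 0))
  mesh <- volume_mesh(nodes, elems, material = rep(2L, nrow(elems)),
                      node_sets = list(horn_anterior = horn_a,
                                       horn_posterior = horn_p),
                      fields = list(circumferential = circ[rep(seq_len(ncg), nzm + 1), ]))
  list(mesh = mesh, horns = list(anterior = horn_a, posterior = horn_p))
}

## --- gait protocol -----------------------------------------------------------

#' Gait (stance-phase) loading specification
#'
#' @param body_mass_kg subject body mass (kg); the axial force waveform is
#'   scaled by body weight
#' @param peak_multiples_of_bw axial force at the two stance peaks in
#'   multiples of body weight; the default is the share transmitted through
#'   direct cartilage-cartilage contact of the medial compartment (the
#'   menisci bypass roughly half of the compartment load)
#' @param peak_times_pct_stance stance-phase times of the two peaks (%)
#' @param n_time_points number of protocol samples over 0-100% stance
#' @param stance_duration_s stance-phase duration (s)
#' @param peak_width_pct Gaussian bump width (standard deviation, % stance)
#' @return an object of class `gait_spec`
#' @export
gait_spec <- function(body_mass_kg = 71,
                      peak_multiples_of_bw = c(0.85, 1.0),
                      peak_times_pct_stance = c(15, 85),
                      n_time_points = 101L,
                      stance_duration_s = 0.6,
                      peak_width_pct = 6) {
  check_scalar(body_mass_kg, "body_mass_kg", 0, Inf, strict_lower = TRUE)
  stopifnot(length(peak_multiples_of_bw) == 2, length(peak_times_pct_stance) == 2)
  if (any(peak_times_pct_stance <= 0) || any(peak_times_pct_stance >= 100))
    stopf("peak times must lie in (0, 100) %% stance")
  if (diff(peak_times_pct_stance) <= 0)
    stopf("peak times must be strictly increasing")
  check_scalar(stance_duration_s, "stance_duration_s", 0, Inf, strict_lower = TRUE)
  structure(list(body_mass_kg = body_mass_kg,
                 peak_multiples_of_bw = as.numeric(peak_multiples_of_bw),
                 peak_times_pct_stance = as.numeric(peak_times_pct_stance),
                 n_time_points = as.integer(n_time_points),
                 stance_duration_s = stance_duration_s,
                 peak_width_pct = peak_width_pct), class = "gait_spec")
}

#' Two-peak stance-phase load protocol
#'
#' The axial force is a sum of two Gaussian bumps in % stance whose
#' amplitudes are solved so the force at each configured peak time equals
#' exactly `peak_multiple * body_mass_kg * 9.81` N.
#'
#' @param spec a [gait_spec()]
#' @return an object of class `load_protocol` with `times_s`, `stance_pct`,
#'   `axial_force_N`, `flexion_deg`
#' @export
make_gait_protocol <- function(spec) {
  if (!inherits(spec, "gait_spec")) stopf("spec must be a gait_spec")
  s <- seq(0, 100, length.out = spec$n_time_points)
  g <- 9.81
  pk <- spec$peak_times_pct_stance
  sig <- spec$peak_width_pct
  targets <- spec$peak_multiples_of_bw * spec$body_mass_kg * g
  bump <- function(x, c0) exp(-(x - c0)^2 / (2 * sig^2))
  M <- rbind(c(bump(pk[1], pk[1]), bump(pk[1], pk[2])),
             c(bump(pk[2], pk[1]), bump(pk[2], pk[2])))
  A <- solve(M, targets)
  force <- A[1] * bump(s, pk[1]) + A[2] * bump(s, pk[2])
  flex <- 18 * bump(s, pk[1]) + 6 * bump(s, pk[2]) + 2  # stand-in waveform
  structure(list(times_s = s / 100 * spec$stance_duration_s,
                 stance_pct = s,
                 axial_force_N = force,
                 flexion_deg = flex,
                 spec = spec,
                 units = list(force = "N", time = "s")),
            class = "load_protocol")
}

#' @export
print.load_protocol <- function(x, ...) {
  cat(sprintf("<load_protocol> %d samples over %.2f s, peak force %.1f N\n",
              length(x$times_s), max(x$times_s), max(x$axial_force_N)))
  invisible(x)
}

#' @export
plot.load_protocol <- function(x, ...) {
  graphics::plot(x$stance_pct, x$axial_force_N, type = "l",
                 xlab = "stance [%]", ylab = "axial force [N]", ...)
  invisible(x)
}

## --- CT phantom volume -------------------------------------------------------

#' Synthetic CT volume with calibration phantoms
#'
#' Generates an intensity volume containing one cylindrical rod per phantom
#' whose mean intensity is an affine function of the known volumetric bone
#' mineral density, plus Gaussian noise. Default voxel size 0.2 mm isotropic.
#'
#' @param phantom_densities known vBMDs of the rods (mg/cm^3); at least two
#'   distinct values are required for downstream calibration
#' @param noise_sd Gaussian intensity noise standard deviation (HU)
#' @param seed integer RNG seed
#' @param hu_slope,hu_intercept the affine HU response, HU = intercept +
#'   slope * density
#' @param voxel_size_mm isotropic voxel size (mm)
#' @param dim_vox volume dimensions in voxels
#' @return an object of class `hu_volume` with the array, phantom ROI label
#'   mask, true densities and metadata
#' @export
make_ct_volume <- function(phantom_densities = c(0, 100, 200, 400, 800),
                           noise_sd = 5, seed = 1L,
                           hu_slope = 1.2, hu_intercept = -40,
                           voxel_size_mm = 0.2,
                           dim_vox = c(60L, 24L, 20L)) {
  if (length(phantom_densities) < 2)
    stopf("at least two phantom densities are required")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  np <- length(phantom_densities)
  arr <- array(hu_intercept, dim = dim_vox)
  labels <- array(0L, dim = dim_vox)
  rad <- 4
  cx <- round(seq(rad + 2, dim_vox[1] - rad - 1, length.out = np))
  cy <- round(dim_vox[2] / 2)
  ix <- slice.index(arr, 1); iy <- slice.index(arr, 2)
  for (k in seq_len(np)) {
    inrod <- (ix - cx[k])^2 + (iy - cy)^2 <= rad^2
    arr[inrod] <- hu_intercept + hu_slope * phantom_densities[k]
    labels[inrod] <- k
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(derive_seed(seed, "ct_noise"))
    arr <- arr + array(rnorm(length(arr), sd = noise_sd), dim = dim_vox)
  }
  structure(list(hu = arr, voxel_size_mm = voxel_size_mm,
                 phantom_labels = labels,
                 phantom_densities = as.numeric(phantom_densities),
                 truth = list(hu_slope = hu_slope, hu_intercept = hu_intercept,
                              noise_sd = noise_sd, seed = as.integer(seed)),
                 units = list(intensity = "HU", density = "mg/cm^3",
                              voxel = "mm")),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("<hu_volume> %s voxels @ %.2f mm, %d phantoms (vBMD %s mg/cm^3)\n",
              paste(dim(x$hu), collapse = "x"), x$voxel_size_mm,
              length(x$phantom_densities),
              paste(x$phantom_densities, collapse = ", ")))
  invisible(x)
}

#' Write an `hu_volume` to NIfTI (requires RNifti)
#' @param vol an `hu_volume`
#' @param path output .nii path
#' @export
write_hu_volume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required to write NIfTI volumes")
  img <- RNifti::asNifti(vol$hu, pixdim = rep(vol$voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## --- defect footprints -------------------------------------------------------

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Parametric defect specification
#'
#' The footprint is a closed polygon in the local tangent-plane chart at the
#' defect center; its area is scaled to match the request exactly.
#' `depth_fraction` is the maximum normalized penetration depth (defect depth
#' divided by local cartilage thickness).
#'
#' @param footprint_area_mm2 target footprint area (mm^2); default is the
#'   clinically measured 5.2 mm^2
#' @param depth_fraction normalized penetration depth in (0, 1]; default 0.63
#' @param center defect center in surface coordinates (mm)
#' @param shape one of "circular", "elliptical", "irregular"
#' @param n_vertices polygon resolution
#' @param seed integer seed (used by the irregular shape only)
#' @param label free-text label (e.g. an ICRS grade annotation)
#' @return an object of class `defect_spec`
#' @export
make_defect <- function(footprint_area_mm2 = 5.2, depth_fraction = 0.63,
                        center = c(0, 0),
                        shape = c("circular", "elliptical", "irregular"),
                        n_vertices = 64L, seed = 1L, label = "ICRS-3") {
  shape <- match.arg(shape)
  check_scalar(footprint_area_mm2, "footprint_area_mm2", 0, Inf, strict_lower = TRUE)
  check_scalar(depth_fraction, "depth_fraction", 0, 1, strict_lower = TRUE)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- switch(shape,
    circular = rep(1, n_vertices),
    elliptical = 1 / sqrt(cos(th)^2 / 2^2 + sin(th)^2 / 0.5^2) / sqrt(2 * 0.5),
    irregular = {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(derive_seed(seed, "defect_shape"))
      co <- rnorm(3, sd = c(0.12, 0.08, 0.05))
      ph <- runif(3, 0, 2 * pi)
      1 + co[1] * cos(th + ph[1]) + co[2] * cos(2 * th + ph[2]) +
        co[3] * cos(3 * th + ph[3])
    })
  poly <- cbind(r * cos(th), r * sin(th))
  poly <- poly * sqrt(footprint_area_mm2 / polygon_area(poly))
  structure(list(footprint = poly, depth_fraction = depth_fraction,
                 center = as.numeric(center), shape = shape, label = label,
                 area_mm2 = polygon_area(poly),
                 full_thickness = depth_fraction >= 1,
                 seed = as.integer(seed), units = "mm"),
            class = "defect_spec")
}

#' @export
print.defect_spec <- function(x, ...) {
  cat(sprintf("<defect_spec> %s, area %.3f mm^2, depth fraction %.2f%s, center (%.1f, %.1f)\n",
              x$shape, x$area_mm2, x$depth_fraction,
              if (x$full_thickness) " (full thickness)" else "",
              x$center[1], x$center[2]))
  invisible(x)
}
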