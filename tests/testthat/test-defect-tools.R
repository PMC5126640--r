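test_that("normalized penetration spans the slab from surface to bone", {
  comp <- grad_comp()
  surf <- comp$mesh$node_sets$surface
  bone <- comp$mesh$node_sets$bone
  idx <- sample(seq_along(surf), 20)
  expect_lt(max(normalized_penetration(comp$mesh$nodes[surf[idx], ], comp)),
            1e-8)
  expect_gt(min(normalized_penetration(comp$mesh$nodes[bone[idx], ], comp)),
            1 - 1e-6)
  expect_error(normalized_penetration(c(0, 0, 10), comp), "outside")
})

test_that("carving realizes the requested depth and removes a prism volume", {
  comp <- grad_comp()
  d <- make_defect(5.2, 0.63, center = c(3, 0))
  geo <- carve_defect(comp, d)
  ## deepest node sits at the normalized defect depth
  pen <- normalized_penetration(geo$mesh$nodes[geo$defect_nodes, ], comp)
  expect_equal(max(pen), 0.63, tolerance = 2e-4)
  ## removed volume ~ area x depth_fraction x local thickness (prism oracle)
  prism <- 5.2 * 0.63 * thickness_at(comp, 3, 0)
  expect_lt(abs(geo$removed_volume_mm3 / prism - 1), 0.05)
  ## mesh quality maintained and rim on the intact surface
  expect_gt(cartimech:::min_scaled_jacobian(geo$mesh), 0.1)
  rim_pen <- normalized_penetration(geo$mesh$nodes[geo$rim_nodes, ], comp)
  expect_lt(max(rim_pen), 1e-6)
  ## shallow depth removes (almost) nothing; removal grows with depth
  vols <- vapply(c(0.01, 0.3, 0.63, 1), function(df) {
    carve_defect(comp, make_defect(5.2, df, center = c(3, 0)))$removed_volume_mm3
  }, numeric(1))
  expect_lt(vols[1], 0.2)  # ~ area * 0.01 * thickness: vanishes with depth
  expect_true(all(diff(vols) > 0))
  expect_error(carve_defect(comp, make_defect(5.2, 0.63, center = c(9, 0))),
               "off the meshed surface")
})

test_that("biharmonic hole fill restores smooth surfaces", {
  comp <- grad_comp()
  d <- make_defect(5.2, 0.63, center = c(3, 0))
  geo <- carve_defect(comp, d)
  g <- attr(comp$mesh, "grid")
  surf_nodes <- comp$mesh$node_sets$surface
  dam <- comp$intact_surface
  attr(dam, "grid") <- g
  dam$nodes <- geo$mesh$nodes[surf_nodes, ]
  hole <- match(geo$defect_nodes, surf_nodes)
  filled <- fill_defect_surface(dam, hole)
  rms <- sqrt(mean((filled$nodes[hole, 3] -
                      comp$intact_surface$nodes[hole, 3])^2))
  expect_lt(rms, 0.01 * thickness_at(comp, 3, 0))   # 1% thickness RMS

  ## empty hole returns the surface unchanged
  expect_identical(fill_defect_surface(dam, integer(0)), dam)

  ## planar rim on a flat surface fills planar to 1e-8
  nx1 <- 15; ny1 <- 15
  zplane <- function(x, y) 0.3 + 0.1 * x - 0.05 * y
  gxy <- expand.grid(x = seq(0, 7, length.out = nx1),
                     y = seq(0, 7, length.out = ny1))
  flat <- surface_mesh(cbind(gxy$x, gxy$y, zplane(gxy$x, gxy$y)),
                       matrix(c(1, 2, 3), 1))
  holep <- which(gxy$x > 2 & gxy$x < 5 & gxy$y > 2 & gxy$y < 5)
  dam2 <- flat; dam2$nodes[holep, 3] <- -1
  fil2 <- fill_defect_surface(dam2, holep, grid_dims = c(nx1, ny1))
  expect_lt(max(abs(fil2$nodes[holep, 3] -
                      zplane(gxy$x[holep], gxy$y[holep]))), 1e-8)

  ## spherical cap: radial deviation under 2% of the sagitta
  R <- 30
  zsph <- function(x, y) R - sqrt(R^2 - (x - 3.5)^2 - (y - 3.5)^2)
  sph <- surface_mesh(cbind(gxy$x, gxy$y, zsph(gxy$x, gxy$y)),
                      matrix(c(1, 2, 3), 1))
  dam3 <- sph; dam3$nodes[holep, 3] <- 99
  fil3 <- fill_defect_surface(dam3, holep, grid_dims = c(nx1, ny1))
  rmax <- max(sqrt((gxy$x[holep] - 3.5)^2 + (gxy$y[holep] - 3.5)^2))
  sagitta <- rmax^2 / (2 * R)
  expect_lt(max(abs(fil3$nodes[holep, 3] - zsph(gxy$x[holep], gxy$y[holep]))),
            0.02 * sagitta)
})

test_that("relocation preserves normalized depth and projected area", {
  comp <- grad_comp()
  d <- make_defect(5.2, 0.63, center = c(4, 0))
  geoA <- carve_defect(comp, d)

  ## identity relocation reproduces the geometry to machine precision
  same <- relocate_defect(comp, d, c(4, 0))
  expect_equal(same$geometry$mesh$nodes, geoA$mesh$nodes, tolerance = 1e-12)

  ## thickness at the target is thinner: absolute depth scales with local
  ## thickness while the normalized depth is invariant
  rel <- relocate_defect(comp, d, c(-4, 0))
  tA <- thickness_at(comp, 4, 0); tB <- thickness_at(comp, -4, 0)
  depthA <- max(comp$intact_surface$nodes[, 3]) * 0  # depths measured below surface
  zdropA <- 0.63 * tA; zdropB <- 0.63 * tB
  penB <- normalized_penetration(
    rel$geometry$mesh$nodes[rel$geometry$defect_nodes, ], comp)
  expect_equal(max(penB), 0.63, tolerance = 2e-4)
  expect_equal(rel$geometry$projected_area_mm2, 5.2, tolerance = 1e-10)
  ## per-node absolute depth follows local thickness (formula oracle at the
  ## deepest node): depth = fraction * thickness
  expect_equal(zdropB / zdropA, tB / tA, tolerance = 1e-12)

  ## conservation over arbitrary targets
  set.seed(31)
  for (tgt in list(c(0, 3), c(-3, -3), c(2, -4))) {
    r <- relocate_defect(comp, d, tgt)
    expect_equal(r$geometry$projected_area_mm2, 5.2, tolerance = 1e-10)
    p <- normalized_penetration(
      r$geometry$mesh$nodes[r$geometry$defect_nodes, ], comp)
    expect_equal(max(p), 0.63, tolerance = 2e-3)
  }

  ## idempotence: A -> B -> A returns the original geometry
  back <- relocate_defect(comp, rel$spec, c(4, 0))
  rms <- sqrt(mean((back$geometry$mesh$nodes - geoA$mesh$nodes)^2))
  expect_lt(rms, 1e-6)
})

test_that("relocation on a uniform flat slab is a rigid translation", {
  ## genuinely flat surface: tangent charts align exactly under transport
  flat <- make_compartment(compartment_spec(
    plateau_extent_mm = c(10, 10), target_element_size_mm = 0.625,
    thickness_base_mm = 2.0, thickness_gradient_mm_per_mm = c(0, 0),
    thickness_bump_mm = 0, surface_curvature_radius_mm = 1e5))
  d <- make_defect(4, 0.5, center = c(1.25, 0))
  gA <- carve_defect(flat, d)
  gB <- relocate_defect(flat, d, c(-1.25, 0))$geometry
  ## same grid offsets: the carved node displacement pattern translates
  dzA <- gA$mesh$nodes[, 3] - flat$mesh$nodes[, 3]
  dzB <- gB$mesh$nodes[, 3] - flat$mesh$nodes[, 3]
  g <- attr(flat$mesh, "grid")
  shift_cols <- round(2.5 / mean(diff(g$xs)))
  ## translate the dz field by the grid shift and compare
  arrA <- array(dzA, dim = c(g$nx + 1, g$ny + 1, g$nz + 1))
  arrB <- array(dzB, dim = c(g$nx + 1, g$ny + 1, g$nz + 1))
  expect_equal(arrB[seq_len(g$nx + 1 - shift_cols), , ],
               arrA[seq_len(g$nx + 1 - shift_cols) + shift_cols, , ],
               tolerance = 1e-9)
})

test_that("drainage boundary conditions are exactly the inner defect walls", {
  comp <- grad_comp()
  ## intact model: no drained faces, everything sealed
  intact <- defect_drainage_bcs(comp$mesh)
  expect_equal(nrow(intact$drained_faces), 0)
  expect_equal(nrow(intact$sealed_faces),
               nrow(cartimech:::boundary_faces(comp$mesh)))

  geo <- carve_defect(comp, make_defect(5.2, 0.63, center = c(3, 0)))
  bcs <- defect_drainage_bcs(geo)
  nb <- nrow(cartimech:::boundary_faces(geo$mesh))
  expect_equal(nrow(bcs$drained_faces) + nrow(bcs$sealed_faces), nb)
  expect_gt(nrow(bcs$drained_faces), 0)
  ## drained set equals the inner-wall face set (as boundary faces)
  key <- function(f) paste(f[, 1], f[, 2], sep = ":")
  expect_true(all(key(bcs$drained_faces) %in% key(geo$inner_wall_faces)))
  ## sealed-defect variant changes only the drained set
  sealed <- defect_drainage_bcs(geo, sealed_defect = TRUE)
  expect_equal(nrow(sealed$drained_faces), 0)
  expect_equal(nrow(sealed$sealed_faces), nb)
})
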