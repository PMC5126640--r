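test_that("thickness profiles are realized exactly in the generated mesh", {
  const_spec <- compartment_spec(plateau_extent_mm = c(8, 8),
                                 thickness_base_mm = 2.0,
                                 thickness_gradient_mm_per_mm = c(0, 0),
                                 thickness_bump_mm = 0,
                                 target_element_size_mm = 1)
  comp <- make_compartment(const_spec)
  surf <- comp$mesh$node_sets$surface
  expect_equal(unname(comp$mesh$fields$thickness[surf]),
               rep(2.0, length(surf)))

  lin_spec <- compartment_spec(plateau_extent_mm = c(10, 10),
                               thickness_base_mm = 2.0,
                               thickness_gradient_mm_per_mm = c(0.1, 0),
                               thickness_bump_mm = 0,
                               target_element_size_mm = 1)
  lin <- make_compartment(lin_spec)
  th <- lin$mesh$fields$thickness[lin$mesh$node_sets$surface]
  expect_equal(range(th), c(1.5, 2.5))   # t0 +/- gradient * extent/2

  ## thickness equals distance to the bone interface along the local normal
  d <- sqrt(rowSums((lin$mesh$nodes[lin$mesh$node_sets$surface, ] -
                       lin$mesh$nodes[lin$mesh$node_sets$bone, ])^2))
  expect_lt(max(abs(d / th - 1)), 0.01)
})

test_that("generated meshes are layered hexes with valid geometry fields", {
  comp <- flat_comp()
  g <- attr(comp$mesh, "grid")
  expect_gte(g$nz, 4)
  expect_gt(cartimech:::min_scaled_jacobian(comp$mesh), 0)
  sl <- comp$mesh$fields$split_line
  nr <- comp$mesh$fields$normal
  expect_lt(max(abs(rowSums(sl^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(sl * nr))), 1e-8)
  ## determinism: identical spec twice gives bitwise-identical meshes
  again <- make_compartment(comp$spec)
  expect_identical(again$mesh$nodes, comp$mesh$nodes)
  expect_identical(again$mesh$elems, comp$mesh$elems)
})

test_that("element size larger than minimum thickness is rejected", {
  expect_error(make_compartment(compartment_spec(
    plateau_extent_mm = c(8, 8), thickness_base_mm = 1.2,
    thickness_gradient_mm_per_mm = c(0, 0), thickness_bump_mm = 0,
    target_element_size_mm = 1.5)), "element size")
})

test_that("gait protocol hits the configured peaks and rests at the ends", {
  gp <- make_gait_protocol(gait_spec(body_mass_kg = 71,
                                     peak_multiples_of_bw = c(1, 1),
                                     peak_times_pct_stance = c(15, 85),
                                     n_time_points = 101L))
  bw <- 71 * 9.81
  expect_equal(gp$axial_force_N[gp$stance_pct == 15], bw, tolerance = 0.001)
  expect_equal(gp$axial_force_N[gp$stance_pct == 85], bw, tolerance = 0.001)
  expect_lte(gp$axial_force_N[1], 0.05 * bw)
  expect_lte(gp$axial_force_N[101], 0.05 * bw)
  expect_equal(gp$stance_pct, 0:100)

  ## doubling body mass scales the waveform exactly
  gp2 <- make_gait_protocol(gait_spec(body_mass_kg = 142,
                                      peak_multiples_of_bw = c(1, 1),
                                      n_time_points = 101L))
  expect_equal(gp2$axial_force_N, 2 * gp$axial_force_N)

  expect_error(gait_spec(peak_times_pct_stance = c(85, 15)), "increasing")
})

test_that("CT phantom volume realizes the affine intensity model", {
  vol <- make_ct_volume(noise_sd = 0, hu_slope = 1, hu_intercept = 0)
  means <- vapply(seq_along(vol$phantom_densities), function(k)
    mean(vol$hu[vol$phantom_labels == k]), numeric(1))
  expect_equal(means, vol$phantom_densities)
  expect_equal(vol$voxel_size_mm, 0.2)

  v1 <- make_ct_volume(noise_sd = 5, seed = 11)
  v2 <- make_ct_volume(noise_sd = 5, seed = 11)
  expect_identical(v1$hu, v2$hu)

  degenerate <- make_ct_volume(phantom_densities = c(100, 100, 100),
                               noise_sd = 0)
  expect_error(fit_hu_vbmd(degenerate), "rank-deficient")
  expect_error(make_ct_volume(noise_sd = -1), "non-negative")
})

test_that("defect footprints match the requested area and shape contracts", {
  d <- make_defect(5.2, 0.63)
  expect_equal(d$area_mm2, 5.2, tolerance = 1e-10)
  ## circular footprint radius ~ sqrt(A/pi)
  r <- sqrt(rowSums(d$footprint^2))
  expect_equal(mean(r), sqrt(5.2 / pi), tolerance = 0.01)
  expect_false(d$full_thickness)
  expect_true(make_defect(5.2, 1.0)$full_thickness)

  i1 <- make_defect(4, 0.5, shape = "irregular", seed = 3)
  i2 <- make_defect(4, 0.5, shape = "irregular", seed = 3)
  expect_identical(i1$footprint, i2$footprint)
  expect_equal(i1$area_mm2, 4, tolerance = 1e-10)

  expect_error(make_defect(5.2, 0), "depth_fraction")
  expect_error(make_defect(-1, 0.5), "footprint_area_mm2")
})
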