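test_that("poroelastic solver matches the consolidation series oracle", {
  bm <- consolidation_fix()
  expect_lte(bm$err_settlement, 0.02)
  expect_lte(bm$err_pressure, 0.02)
  expect_true(all(bm$states$converged))
})

test_that("drained and undrained limits bracket the transient response", {
  bm <- consolidation_fix()
  p <- frpe_params(matrix_E_MPa = 1.0, matrix_nu = 0.3,
                   permeability_mm4_per_Ns = 1e-2,
                   fibril_E0_MPa = 0, fibril_Eeps_MPa = 0)
  lc <- cartimech:::lame_constants(p)
  drained <- 0.1 * 1 / (lc$lambda + 2 * lc$mu)
  hold <- bm$times > 10
  ## instantaneous (undrained) response is stiffer than the drained limit
  expect_lt(bm$settlement_mm[which(hold)[1]], drained)
  ## settlement approaches the drained elastic value from below
  expect_equal(utils::tail(bm$settlement_mm, 1), drained, tolerance = 0.01)
  expect_true(all(diff(bm$settlement_mm) > -1e-12))
})

test_that("zero-force protocol returns a zero state", {
  comp <- flat_comp()
  prob <- fe_problem(
    comp$mesh, list("1" = frpe_params()),
    fixed_u = list(list(nodes = comp$mesh$node_sets$bone, dims = 1:3, value = 0)),
    traction = list(faces = "surface", direction = c(0, 0, -1), scale = 1))
  st <- solve_protocol(prob, list(times_s = c(0.1, 0.2),
                                  axial_force_N = c(0, 0)),
                       measure_steps = "none")
  expect_lt(max(abs(st$U)), 1e-10)
  expect_lt(max(abs(st$P)), 1e-10)
})

test_that("uniform-strain patch state is stress-uniform and divergence-free", {
  ## 2x2x2 box with one interior node; prescribe a uniform-strain field
  nodes <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) / 2
  nid <- function(i, j, k) (k - 1L) * 9L + (j - 1L) * 3L + i
  elems <- NULL
  for (k in 1:2) for (j in 1:2) for (i in 1:2)
    elems <- rbind(elems, c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                            nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                            nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1)))
  mesh <- volume_mesh(nodes, elems)
  p <- frpe_params(fibril_E0_MPa = 0, fibril_Eeps_MPa = 0)
  prob <- fe_problem(mesh, list("1" = p))
  eps0 <- c(0.001, -0.0005, 0.002, 0.0008, -0.0002, 0.0004)
  E <- rbind(c(eps0[1], eps0[4] / 2, eps0[6] / 2),
             c(eps0[4] / 2, eps0[2], eps0[5] / 2),
             c(eps0[6] / 2, eps0[5], eps0[3]))
  U <- as.vector(t(nodes %*% E))
  sys <- assemble(prob, U, P = numeric(nrow(nodes)), dt = 1)
  ## stress is uniform at every quadrature point and matches D eps exactly
  lc <- cartimech:::lame_constants(p)
  tr0 <- sum(eps0[1:3])
  expect_equal(unname(sys$sig[, 1]),
               rep(lc$lambda * tr0 + 2 * lc$mu * eps0[1], nrow(sys$sig)),
               tolerance = 1e-12)
  expect_equal(unname(sys$sig[, 4]), rep(lc$mu * eps0[4], nrow(sys$sig)),
               tolerance = 1e-12)
  ## divergence of the uniform stress vanishes at the interior node
  interior <- nid(2L, 2L, 2L)
  expect_lt(max(abs(sys$Ru[3 * (interior - 1) + 1:3])), 1e-12)
})

test_that("horn springs assemble to the configured total stiffness", {
  comp <- fixture("meniscus_comp", function() {
    make_compartment(compartment_spec(plateau_extent_mm = c(10, 10),
                                      target_element_size_mm = 1.25,
                                      thickness_base_mm = 2.0,
                                      thickness_gradient_mm_per_mm = c(0, 0),
                                      thickness_bump_mm = 0,
                                      meniscus_enabled = TRUE))
  })
  expect_false(is.null(comp$meniscus))
  springs <- horn_springs(comp, total_per_horn_N_mm = 350)
  ks <- spring_group_stiffness(springs, n_nodes = nrow(comp$meniscus$nodes))
  expect_equal(unname(ks["anterior_horn"]), 350)
  expect_equal(unname(ks["posterior_horn"]), 350)
  ## direct-summation oracle on the assembled diagonal
  Ks <- cartimech:::spring_matrix(springs, nrow(comp$meniscus$nodes))
  nd <- springs$node[springs$group == "anterior_horn"]
  expect_equal(sum(Matrix::diag(Ks)[3 * (nd - 1) + 3]),
               sum(springs$k[springs$group == "anterior_horn"]))
})

test_that("contact is frictionless and engages only on penetration", {
  fx <- indent_fix()
  st <- fx$states
  expect_true(all(st$converged))
  ## force balance at every step within 0.5%
  rel <- abs(st$contact_force_N[3, ] + st$applied_force_N) /
    pmax(st$applied_force_N, 1)
  expect_lt(max(rel), 0.005)
  ## lifting the indenter far above the surface produces no force
  kA <- cartimech:::tributary_areas(fx$comp$mesh,
                                    fx$comp$mesh$face_sets$surface) * 300
  cn <- sort(unique(as.vector(cartimech:::face_nodes(
    fx$comp$mesh, fx$comp$mesh$face_sets$surface))))
  ce <- cartimech:::contact_eval(fx$comp$mesh$nodes, st$U[, 3] * 0, cn, kA,
                                 fx$comp$indenter$center,
                                 fx$comp$indenter$radius, w = 5)
  expect_equal(ce$n_active, 0L)
  expect_equal(ce$total, c(0, 0, 0))
  ## at the converged peak state, every contact force is along the sphere
  ## normal (frictionless): tangential component is zero by construction
  ce2 <- cartimech:::contact_eval(fx$comp$mesh$nodes, st$U[, 2], cn, kA,
                                  fx$comp$indenter$center,
                                  fx$comp$indenter$radius, w = st$w[2])
  expect_gt(ce2$n_active, 0)
  tang <- ce2$forces - ce2$normals * rowSums(ce2$forces * ce2$normals)
  expect_lt(max(abs(tang)), 1e-8 * max(abs(ce2$forces)))
  ## contact load spreads with force: more nodes active at the higher load
  ce_lo <- cartimech:::contact_eval(fx$comp$mesh$nodes, st$U[, 1], cn, kA,
                                    fx$comp$indenter$center,
                                    fx$comp$indenter$radius, w = st$w[1])
  expect_gte(ce2$n_active, ce_lo$n_active)
})

test_that("strain measures agree with the eigenvalue oracle", {
  m0 <- strain_measures(rep(0, 6))
  expect_equal(unname(m0[1, c("e1", "e2", "e3", "shear")]), rep(0, 4))
  md <- strain_measures(c(0.1, 0, -0.2, 0, 0, 0))
  expect_equal(unname(md[1, c("e1", "e2", "e3")]), c(0.1, 0, -0.2))
  expect_equal(unname(md[1, "shear"]), 0.3)
  v <- rand_sym6(50, sd = 0.2, seed = 12)
  pr <- strain_measures(v)[, c("e1", "e2", "e3")]
  expect_equal(unname(pr), unname(eigen_oracle(v)), tolerance = 1e-9)
})

test_that("rigid-body translation leaves all strain measures unchanged", {
  fx <- indent_fix()
  shift <- c(5, -7, 3)
  comp <- fx$comp
  mesh2 <- comp$mesh
  mesh2$nodes <- sweep(mesh2$nodes, 2, shift, `+`)
  prob2 <- fe_problem(
    mesh2, list("1" = frpe_params()),
    fixed_u = list(list(nodes = mesh2$node_sets$bone, dims = 1:3, value = 0),
                   list(nodes = mesh2$node_sets$sides, dims = 1:2, value = 0)),
    contact = list(center = comp$indenter$center + shift,
                   radius = comp$indenter$radius, faces = "surface",
                   mode = "force"))
  st2 <- solve_protocol(prob2, fx$protocol, measure_steps = 2)
  m1 <- fx$states$measures[[2]]
  m2 <- st2$measures[[2]]
  for (cn in c("e1", "e3", "shear", "fibril", "sig1"))
    expect_equal(m2[, cn], m1[, cn], tolerance = 5e-4)
})

test_that("submodel boundary interpolation reproduces global fields exactly", {
  comp <- flat_comp()
  nn <- nrow(comp$mesh$nodes)
  lin <- function(p) 0.01 * (p[, 1] + 2 * p[, 2] + 3 * p[, 3])
  gl <- structure(list(times = 0.1, stance_pct = 100,
                       U = matrix(as.vector(t(cbind(lin(comp$mesh$nodes),
                                                    2 * lin(comp$mesh$nodes),
                                                    -lin(comp$mesh$nodes)))),
                                  ncol = 1),
                       P = matrix(0.3 * comp$mesh$nodes[, 3], ncol = 1),
                       w = 0, mesh = comp$mesh), class = "fe_states")
  ## identity case: the submodel is the global mesh itself
  bn <- comp$mesh$node_sets$sides
  bcs <- submodel_bcs(gl, comp$mesh, bn)
  expect_equal(bcs$u[seq(1, 3 * length(bcs$nodes), 3), 1],
               lin(comp$mesh$nodes[bcs$nodes, ]), tolerance = 1e-10)
  ## refined interior submodel: linear fields are reproduced to 1e-10
  sub <- make_compartment(compartment_spec(
    plateau_extent_mm = c(4, 4), target_element_size_mm = 0.5,
    thickness_base_mm = 2.0, thickness_gradient_mm_per_mm = c(0, 0),
    thickness_bump_mm = 0))
  bn2 <- cartimech:::submodel_boundary_nodes(sub$mesh)
  bcs2 <- submodel_bcs(gl, sub$mesh, bn2)
  expect_equal(bcs2$u[seq(2, 3 * length(bcs2$nodes), 3), 1],
               2 * lin(sub$mesh$nodes[bcs2$nodes, ]), tolerance = 1e-9)
  expect_equal(bcs2$p[, 1], 0.3 * sub$mesh$nodes[bcs2$nodes, 3],
               tolerance = 1e-9)
  ## constant field: all boundary values equal that constant
  glc <- gl
  glc$U <- matrix(rep(c(0.2, -0.1, 0.05), nn), ncol = 1)
  bcs3 <- submodel_bcs(glc, sub$mesh, bn2)
  expect_equal(unname(bcs3$u[, 1]),
               rep(c(0.2, -0.1, 0.05), length(bcs3$nodes)), tolerance = 1e-10)
  expect_error(submodel_bcs(gl, volume_mesh(rbind(c(99, 99, 99)) %x%
                                              rep(1, 8) + 0.1 * flat_comp()$mesh$nodes[1:8, ],
                                            matrix(1:8, 1)), 1:8),
               "outside")
})

test_that("loading-rate independence holds in drained conditions", {
  ## elastic fibrils: the drained end state is identical for two ramp rates
  p <- frpe_params(matrix_E_MPa = 1.0, matrix_nu = 0.3,
                   permeability_mm4_per_Ns = 1,
                   fibril_E0_MPa = 0.5, fibril_Eeps_MPa = 50)
  setup <- confined_compression_problem(n_elem = 6, params = p)
  run <- function(t_ramp) {
    times <- c(seq(t_ramp / 5, t_ramp, length.out = 5),
               t_ramp + c(20, 100, 400))
    force <- 0.02 * setup$area * pmin(times / t_ramp, 1)
    solve_protocol(setup$prob, list(times_s = times, axial_force_N = force),
                   measure_steps = "none")
  }
  s1 <- run(1); s2 <- run(10)
  expect_equal(s1$U[, 8], s2$U[, 8], tolerance = 1e-5)
})
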