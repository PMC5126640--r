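## Shared fixtures, built once per test session. Everything is generated in
## code; sizes are kept small so the whole suite stays fast.

.fx <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## small flat compartment (no thickness variation) for solver tests
flat_comp <- function() fixture("flat_comp", function() {
  make_compartment(compartment_spec(
    plateau_extent_mm = c(10, 10), target_element_size_mm = 1.25,
    thickness_base_mm = 2.0, thickness_gradient_mm_per_mm = c(0, 0),
    thickness_bump_mm = 0))
})

## finer compartment with a linear thickness gradient for defect tests
grad_comp <- function() fixture("grad_comp", function() {
  make_compartment(compartment_spec(
    plateau_extent_mm = c(14, 14), target_element_size_mm = 0.5,
    thickness_base_mm = 2.5, thickness_gradient_mm_per_mm = c(0.1, 0),
    thickness_bump_mm = 0, surface_curvature_radius_mm = 100))
})

## default consolidation benchmark, reused by several assertions
consolidation_fix <- function() fixture("consolidation", function() {
  suppressWarnings(consolidation_benchmark())
})

## small indentation solve over a 5-point two-level load history
indent_fix <- function() fixture("indent", function() {
  comp <- flat_comp()
  prob <- fe_problem(
    comp$mesh, list("1" = frpe_params()),
    fixed_u = list(list(nodes = comp$mesh$node_sets$bone, dims = 1:3, value = 0),
                   list(nodes = comp$mesh$node_sets$sides, dims = 1:2, value = 0)),
    contact = list(center = comp$indenter$center, radius = comp$indenter$radius,
                   faces = "surface", mode = "force"))
  pro <- list(times_s = c(0.05, 0.1, 0.15),
              axial_force_N = c(60, 200, 100),
              stance_pct = c(20, 50, 80))
  st <- solve_protocol(prob, pro, measure_steps = "all")
  list(comp = comp, prob = prob, protocol = pro, states = st)
})

## synthetic measures matrix with named columns for failure tests
fake_measures <- function(e1 = 0, e3 = 0, shear = 0, fibril = 0, sig1 = 0,
                          n = 5) {
  cbind(e1 = rep_len(e1, n), e2 = 0, e3 = rep_len(e3, n),
        shear = rep_len(shear, n), axial = 0, lateral = 0,
        fibril = rep_len(fibril, n), sig1 = rep_len(sig1, n), p = 0)
}

rand_sym6 <- function(n, sd = 0.1, seed = 42) {
  set.seed(seed)
  matrix(rnorm(6 * n, sd = sd), n, 6)
}

## reference 3x3 eigenvalues through base eigen(), descending
eigen_oracle <- function(v) {
  t(apply(v, 1, function(r) {
    m <- matrix(c(r[1], r[4], r[6], r[4], r[2], r[5], r[6], r[5], r[3]), 3, 3)
    sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
}
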