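## Submodeling: re-solving a refined local region with boundary conditions
## interpolated from a coarser global solution.

#' Interpolate submodel boundary conditions from a global solution
#'
#' Displacements and pore pressures at the submodel boundary nodes are
#' interpolated from the global element shape functions (trilinear) at each
#' stored time point; the submodel interior is left unconstrained. The
#' global indenter track is carried along so the submodel contact can be
#' driven in displacement mode.
#'
#' @param global_states an `fe_states` from the global solve
#' @param submesh the submodel `volume_mesh`
#' @param boundary_nodes submodel node indices forming the cut boundary
#' @return list with `nodes`, displacement matrix `u` (3 nb x steps, dof
#'   blocks per node), pressure matrix `p` (nb x steps), and indenter track
#'   `w`
#' @export
submodel_bcs <- function(global_states, submesh, boundary_nodes) {
  boundary_nodes <- sort(unique(as.integer(boundary_nodes)))
  pts <- submesh$nodes[boundary_nodes, , drop = FALSE]
  ## tol_out absorbs the chordal gap between the submodel's fine sampling
  ## of the curved surfaces and the global mesh's trilinear faces
  loc <- tryCatch(
    locate_points(global_states$mesh, pts, tol_out = 0.08),
    error = function(e)
      stopf("submodel boundary node outside the global mesh (%s)",
            conditionMessage(e)))
  nt <- length(global_states$times)
  nb <- length(boundary_nodes)
  uvals <- matrix(0, 3 * nb, nt)
  pvals <- matrix(0, nb, nt)
  for (s in seq_len(nt)) {
    Uf <- matrix(global_states$U[, s], ncol = 3, byrow = TRUE)
    vals <- interp_at(global_states$mesh, loc,
                      cbind(Uf, global_states$P[, s]))
    uvals[, s] <- as.vector(t(vals[, 1:3, drop = FALSE]))
    pvals[, s] <- vals[, 4]
  }
  list(nodes = boundary_nodes, u = uvals, p = pvals, w = global_states$w)
}

## boundary node set of a generated submodel: side and bone nodes
submodel_boundary_nodes <- function(submesh) {
  sort(unique(c(submesh$node_sets$sides, submesh$node_sets$bone)))
}

#' Build and solve a driven submodel
#'
#' Constructs the `fe_problem` for a submodel whose cut boundary follows a
#' global solution ([submodel_bcs()]) and whose articular surface contacts
#' the same rigid indenter in displacement mode (the indenter track comes
#' from the global solve).
#'
#' @param submesh submodel `volume_mesh` (a generated compartment mesh)
#' @param materials material list as in [fe_problem()]
#' @param bcs a [submodel_bcs()] result
#' @param protocol the load protocol shared with the global solve
#' @param indenter `list(center =, radius =)` of the global indenter
#' @param drained_nodes,drained_values extra pressure Dirichlet data
#'   (defect-wall drainage), merged with the boundary pressures
#' @param config a [solver_config()]
#' @param measure_steps forwarded to [solve_protocol()]
#' @return an `fe_states`
#' @export
solve_submodel <- function(submesh, materials, bcs, protocol, indenter,
                           drained_nodes = integer(), drained_values = NULL,
                           config = solver_config(),
                           measure_steps = "all") {
  nt <- length(protocol$times_s)
  if (ncol(bcs$u) != nt) stopf("submodel BCs and protocol have different step counts")
  dn <- c(bcs$nodes, drained_nodes)
  dv <- rbind(bcs$p,
              if (length(drained_nodes)) {
                drained_values %||% matrix(0, length(drained_nodes), nt)
              })
  keep <- !duplicated(dn)
  prob <- fe_problem(
    submesh, materials,
    fixed_u = list(list(nodes = bcs$nodes, dims = 1:3, value = bcs$u)),
    drained_nodes = dn[keep],
    drained_values = dv[keep, , drop = FALSE],
    contact = list(center = indenter$center, radius = indenter$radius,
                   faces = "surface", mode = "displacement", w = bcs$w),
    config = config)
  solve_protocol(prob, protocol, measure_steps = measure_steps)
}
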