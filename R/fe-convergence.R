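## Mesh-convergence study for the submodeling workflow: solve the toy
## spherical-indentation scenario, then re-solve the submodel at a series
## of element sizes and compare the peak analyzed parameters between
## successive refinement levels against the <2% acceptance rule.

## short ramp-and-hold protocol to the first-peak stance force
ramp_protocol <- function(peak_N, n_steps = 6L, duration_s = 0.15) {
  f <- seq(0, 1, length.out = n_steps + 1)[-1]
  list(times_s = f * duration_s, axial_force_N = peak_N * f,
       stance_pct = f * 100)
}

## Gauss-point extrapolation matrix: the 8 quadrature values define a
## trilinear polynomial; evaluating it at the element corners gives the
## standard O(h^2) nodal recovery (factors (1 +/- sqrt(3))/2)
extrap_matrix <- function() {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  E <- matrix(0, 8, 8)
  for (a in 1:8) for (q in 1:8)
    E[a, q] <- prod((1 + sqrt(3) * s[a, ] * s[q, ]) / 2)
  E
}

## element-volume-weighted nodal projection with Gauss-point extrapolation
nodal_measures <- function(mesh, measures) {
  q <- fe_quadrature(mesh$nodes, mesh$elems)
  ve <- rowSums(matrix(q$wdet, ncol = 8, byrow = TRUE))
  Emat <- extrap_matrix()
  nn <- nrow(mesh$nodes)
  out <- matrix(0, nn, ncol(measures))
  wt <- numeric(nn)
  for (a in 1:8) {
    idx <- mesh$elems[, a]
    add <- rowsum(rep(ve, 1), idx, reorder = FALSE)
    wt[as.integer(rownames(add))] <- wt[as.integer(rownames(add))] + add
  }
  for (c1 in seq_len(ncol(measures))) {
    M <- matrix(measures[, c1], nrow = 8)        # 8 qp x E (element-major)
    Vex <- Emat %*% M                            # extrapolated corner values
    acc <- numeric(nn)
    for (a in 1:8) {
      add <- rowsum(Vex[a, ] * ve, mesh$elems[, a], reorder = FALSE)
      acc[as.integer(rownames(add))] <- acc[as.integer(rownames(add))] + add
    }
    out[, c1] <- acc / pmax(wt, 1e-30)
  }
  colnames(out) <- colnames(measures)
  out
}

## peak analyzed parameters of a state history (nodal-projected fields),
## optionally restricted to an interior analysis window
peak_parameters <- function(states, node_mask = NULL) {
  steps <- which(!vapply(states$measures, is.null, logical(1)))
  peaks <- c(min_principal = -Inf, shear = -Inf, max_stress = -Inf,
             fibril = -Inf)
  for (s in steps) {
    nm <- nodal_measures(states$mesh, states$measures[[s]])
    if (!is.null(node_mask)) nm <- nm[node_mask, , drop = FALSE]
    peaks["min_principal"] <- max(peaks["min_principal"], max(-nm[, "e3"]))
    peaks["shear"] <- max(peaks["shear"], max(nm[, "shear"]))
    peaks["max_stress"] <- max(peaks["max_stress"], max(nm[, "sig1"]))
    peaks["fibril"] <- max(peaks["fibril"], max(nm[, "fibril"]))
  }
  peaks
}

#' Submodel mesh-convergence study
#'
#' Runs the toy spherical-indentation scenario (intact compartment, ramp to
#' the first stance peak), then solves the driven submodel at each element
#' size in `levels` and reports, per analyzed parameter (peak compressive
#' principal strain, peak shear strain, peak maximum principal stress, peak
#' fibril strain, all from nodal-projected fields), the relative difference
#' between successive levels. A level passes when all four differences
#' against the next finer mesh are below `rule_pct`.
#'
#' @param compartment a [compartment_spec()] for the global model; the
#'   default toy scenario uses a flat thickness profile
#' @param levels submodel element sizes (mm), coarse to fine; the default
#'   compares the standard ~0.3 mm density with one uniform refinement
#' @param submodel_extent_mm side length of the square submodel region (mm)
#' @param margin_mm boundary skin excluded from the peak evaluation: the
#'   interpolated cut-boundary conditions inherit gradient kinks from the
#'   coarse global field, so peaks are analyzed over the interior window
#'   (the literature procedure likewise evaluates around the defect, well
#'   inside the submodel)
#' @param materials material list
#' @param peak_N ramp target force (N); default is the first-peak stance
#'   force of [gait_spec()] defaults
#' @param n_steps ramp steps
#' @param solver a [solver_config()]
#' @param rule_pct acceptance rule on the relative differences (%)
#' @return object of class `convergence_study`: the per-level peak table,
#'   relative differences (%), and the pass flag
#' @export
convergence_study <- function(compartment = NULL,
                              levels = c(0.3, 0.15),
                              submodel_extent_mm = 3.6,
                              margin_mm = 1.2,
                              materials = list("1" = frpe_params()),
                              peak_N = NULL,
                              n_steps = 5L,
                              solver = solver_config(),
                              rule_pct = 2) {
  if (length(levels) < 2) stopf("at least two refinement levels are required")
  if (is.unsorted(rev(levels), strictly = TRUE))
    stopf("levels must be strictly decreasing element sizes")
  if (is.null(compartment))
    compartment <- compartment_spec(plateau_extent_mm = c(16, 16),
                                    thickness_base_mm = 2.0,
                                    thickness_gradient_mm_per_mm = c(0, 0),
                                    thickness_bump_mm = 0,
                                    target_element_size_mm = 1.5)
  gait <- gait_spec()
  if (is.null(peak_N))
    peak_N <- gait$peak_multiples_of_bw[1] * gait$body_mass_kg * 9.81
  comp <- make_compartment(compartment)
  protocol <- ramp_protocol(peak_N, n_steps = n_steps)
  global <- solve_protocol(global_problem(comp, materials, solver), protocol,
                           measure_steps = "none")
  if (!is.null(global$failure)) stopf("global toy solve did not converge")

  peaks <- NULL
  n_elements <- integer(0)
  for (li in seq_along(levels)) {
    spec <- compartment
    spec$target_element_size_mm <- levels[li]
    spec$plateau_extent_mm <- rep(submodel_extent_mm, 2)
    sub_comp <- make_compartment(spec, patch_center = c(0, 0))
    bnodes <- submodel_boundary_nodes(sub_comp$mesh)
    bcs <- submodel_bcs(global, sub_comp$mesh, bnodes)
    st <- solve_submodel(sub_comp$mesh, materials, bcs, protocol,
                         comp$indenter, config = solver,
                         measure_steps = length(protocol$times_s))
    if (!is.null(st$failure)) {
      warning(sprintf("submodel level %g mm did not converge; partial table",
                      levels[li]), call. = FALSE)
      break
    }
    half <- submodel_extent_mm / 2 - margin_mm
    mask <- abs(sub_comp$mesh$nodes[, 1]) <= half + 1e-9 &
      abs(sub_comp$mesh$nodes[, 2]) <= half + 1e-9
    peaks <- rbind(peaks, peak_parameters(st, node_mask = mask))
    n_elements <- c(n_elements, nrow(sub_comp$mesh$elems))
  }
  rownames(peaks) <- paste0(levels[seq_len(nrow(peaks))], "mm")
  rel_diff <- NULL
  if (nrow(peaks) >= 2) {
    fine <- peaks[-1, , drop = FALSE]
    coarse <- peaks[-nrow(peaks), , drop = FALSE]
    ## parameters that are (numerically) zero at every level are converged
    scale_ref <- pmax(abs(fine), 1e-6 * max(abs(peaks)))
    rel_diff <- 100 * abs(coarse - fine) / scale_ref
    rownames(rel_diff) <- paste(head(rownames(peaks), -1), "vs",
                                tail(rownames(peaks), -1))
  }
  structure(list(levels = levels[seq_len(nrow(peaks))], peaks = peaks,
                 n_elements = n_elements,
                 rel_diff_pct = rel_diff, rule_pct = rule_pct,
                 pass = !is.null(rel_diff) && all(rel_diff < rule_pct),
                 complete = nrow(peaks) == length(levels)),
            class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat("<convergence_study> peak analyzed parameters per submodel density\n")
  print(round(x$peaks, 5))
  if (!is.null(x$rel_diff_pct)) {
    cat("relative differences (%):\n")
    print(round(x$rel_diff_pct, 3))
    cat(sprintf("rule: all < %g%% -> %s\n", x$rule_pct,
                if (x$pass) "PASS" else "NOT MET"))
  }
  invisible(x)
}
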