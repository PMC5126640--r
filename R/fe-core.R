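## Quasi-static mixed displacement-pressure poroelastic solver.
##
## Discretization: equal-order trilinear u-p interpolation on hex8 meshes
## with polynomial pressure-projection stabilization, backward Euler in
## time, tension-only fibril reinforcement, penalty-regularized frictionless
## contact against a rigid analytic sphere, and grounded horn springs.
## Kinematics are geometrically linear; logarithmic strain measures are
## extracted from the displacement gradient for reporting.

#' Solver configuration
#'
#' @param newton_tol relative Newton residual tolerance
#' @param max_iter maximum Newton iterations per time step
#' @param contact_penalty_N_mm3 contact penalty stiffness per unit tributary
#'   area (N/mm^3)
#' @param stab_coeff pressure-projection stabilization coefficient
#'   (dimensionless; scaled internally by the inverse constrained modulus)
#' @param contact_smooth_mm penetration band over which the penalty force is
#'   C1-smoothed (mm); regularizes the hard pressure-overclosure law
#' @param max_dw_mm cap on the indenter height update per force-balance
#'   (secant) iteration (mm)
#' @param max_du_mm trust-region cap on the largest nodal displacement
#'   increment per Newton iteration (mm)
#' @param verbose print per-step convergence summaries
#' @return object of class `solver_config`
#' @export
solver_config <- function(newton_tol = 1e-6, max_iter = 40,
                          contact_penalty_N_mm3 = 300,
                          stab_coeff = 0.25,
                          contact_smooth_mm = 0.05,
                          max_dw_mm = 0.5,
                          max_du_mm = 0.5,
                          verbose = FALSE) {
  check_scalar(newton_tol, "newton_tol", 0, Inf, strict_lower = TRUE)
  check_scalar(contact_penalty_N_mm3, "contact_penalty_N_mm3", 0, Inf,
               strict_lower = TRUE)
  check_scalar(stab_coeff, "stab_coeff", 0, Inf)
  structure(list(newton_tol = newton_tol, max_iter = as.integer(max_iter),
                 contact_penalty_N_mm3 = contact_penalty_N_mm3,
                 stab_coeff = stab_coeff,
                 contact_smooth_mm = contact_smooth_mm,
                 max_dw_mm = max_dw_mm, max_du_mm = max_du_mm,
                 verbose = isTRUE(verbose)),
            class = "solver_config")
}

#' Grounded spring set
#'
#' Linear springs from mesh nodes to fixed anchors (isotropic in the three
#' translations), used for the meniscal horn attachments.
#'
#' @param nodes node indices
#' @param stiffness_N_mm per-spring stiffness (recycled)
#' @param group group label (recycled)
#' @return object of class `spring_set` (a data frame)
#' @export
spring_set <- function(nodes, stiffness_N_mm, group = "springs") {
  if (any(stiffness_N_mm <= 0)) stopf("spring stiffness must be positive")
  structure(data.frame(node = as.integer(nodes),
                       k = rep_len(stiffness_N_mm, length(nodes)),
                       group = rep_len(group, length(nodes)),
                       stringsAsFactors = FALSE),
            class = c("spring_set", "data.frame"))
}

#' Meniscal horn attachment springs
#'
#' Distributes a total spring constant of `total_per_horn_N_mm` (350 N/mm by
#' default) evenly over each horn attachment node set of a compartment with
#' meniscus enabled.
#'
#' @param compartment a [make_compartment()] result with meniscus enabled
#' @param total_per_horn_N_mm total stiffness per horn (N/mm)
#' @export
horn_springs <- function(compartment, total_per_horn_N_mm = 350) {
  h <- compartment$horn_attachments
  if (!length(h)) stopf("compartment has no horn attachments (meniscus disabled?)")
  out <- rbind(spring_set(h$anterior, total_per_horn_N_mm / length(h$anterior),
                          "anterior_horn"),
               spring_set(h$posterior, total_per_horn_N_mm / length(h$posterior),
                          "posterior_horn"))
  class(out) <- c("spring_set", "data.frame")
  out
}

spring_matrix <- function(springs, n_nodes) {
  dofs <- as.vector(t(outer(3 * (springs$node - 1), 1:3, `+`)))
  ks <- rep(springs$k, each = 3)
  Matrix::sparseMatrix(i = dofs, j = dofs, x = ks,
                       dims = c(3 * n_nodes, 3 * n_nodes))
}

#' Total stiffness of each spring group
#'
#' Computed from the assembled spring matrix: every node of a group is given
#' a unit displacement along `direction` and the group's reaction force
#' component along that direction is summed.
#'
#' @param springs a [spring_set()]
#' @param n_nodes number of mesh nodes sizing the assembled matrix
#' @param direction direction of the unit test displacement
#' @return named numeric vector of group stiffnesses (N/mm)
#' @export
spring_group_stiffness <- function(springs, n_nodes = max(springs$node),
                                   direction = c(0, 0, 1)) {
  direction <- direction / sqrt(sum(direction^2))
  Ks <- spring_matrix(springs, n_nodes)
  vapply(split(seq_len(nrow(springs)), springs$group), function(ii) {
    U <- numeric(3 * n_nodes)
    nd <- springs$node[ii]
    for (i in 1:3) U[3 * (nd - 1) + i] <- direction[i]
    f <- as.numeric(Ks %*% U)
    sum(vapply(nd, function(n1) sum(f[3 * (n1 - 1) + 1:3] * direction),
               numeric(1)))
  }, numeric(1))
}

## --- problem definition ------------------------------------------------------

#' Define a poroelastic finite-element problem
#'
#' @param mesh a hex8 `volume_mesh`
#' @param materials named list mapping material id (as character) to an
#'   [frpe_params()] (poroelastic cartilage), `list(type = "meniscus",
#'   params = meniscus_params())`, or `list(type = "elastic", C = <6x6>)`
#' @param fixed_u list of displacement constraints, each
#'   `list(nodes =, dims =, value =)`; `value` may be a scalar, a function of
#'   time, or a matrix (constrained dofs x time steps)
#' @param drained_nodes nodes with pore pressure fixed to zero
#'   (free-draining boundary); everywhere else is sealed (no flux)
#' @param drained_values optional matrix (length(drained_nodes) x time steps)
#'   of prescribed pore pressures, used for submodel boundaries; defaults to
#'   zero (free draining)
#' @param traction `list(faces =, direction =, scale =)`: surface load with
#'   magnitude `scale * axial_force(t)` per unit area
#' @param contact rigid spherical indenter:
#'   `list(center =, radius =, faces = "surface", mode = "force")` driven by
#'   the protocol axial force through its control point, or
#'   `mode = "displacement"` with a per-step vertical position series `w`
#' @param springs optional [spring_set()]
#' @param config a [solver_config()]
#' @return object of class `fe_problem`
#' @export
fe_problem <- function(mesh, materials, fixed_u = list(),
                       drained_nodes = integer(), drained_values = NULL,
                       traction = NULL, contact = NULL, springs = NULL,
                       config = solver_config()) {
  if (mesh$elem_type != "hex8")
    stopf("the poroelastic solver requires a hex8 mesh")
  structure(list(mesh = mesh, materials = materials, fixed_u = fixed_u,
                 drained_nodes = as.integer(drained_nodes),
                 drained_values = drained_values,
                 traction = traction, contact = contact, springs = springs,
                 config = config),
            class = "fe_problem")
}

## per-quadrature-point material data and constant matrices
prepare_fe <- function(prob) {
  mesh <- prob$mesh
  nn <- nrow(mesh$nodes)
  E <- nrow(mesh$elems)
  q <- fe_quadrature(mesh$nodes, mesh$elems)
  if (q$min_detJ <= 0)
    stopf("mesh has non-positive Jacobians (min detJ = %g)", q$min_detJ)
  EQ <- E * 8L

  matids <- as.character(mesh$material)
  D0 <- array(0, dim = c(6, 6, EQ))
  kperm <- numeric(E)
  alpha <- numeric(E)
  frpe_mask <- rep(FALSE, EQ)
  frpe_par <- NULL
  for (id in unique(matids)) {
    m <- prob$materials[[id]]
    if (is.null(m)) stopf("no material definition for id %s", id)
    sel_e <- which(matids == id)
    sel_q <- rep((sel_e - 1L) * 8L, each = 8L) + 1:8
    if (inherits(m, "frpe_params")) {
      lc <- lame_constants(m)
      D <- matrix(0, 6, 6)
      D[1:3, 1:3] <- lc$lambda
      diag(D)[1:3] <- lc$lambda + 2 * lc$mu
      diag(D)[4:6] <- lc$mu
      D0[, , sel_q] <- D
      kperm[sel_e] <- m$permeability_mm4_per_Ns
      alpha[sel_e] <- prob$config$stab_coeff / (lc$lambda + 2 * lc$mu)
      frpe_mask[sel_q] <- TRUE
      frpe_par <- m
    } else if (identical(m$type, "meniscus")) {
      circ <- mesh$fields$circumferential
      if (is.null(circ)) stopf("meniscus material requires a circumferential field")
      cq <- fe_interp_qp(mesh$elems, q$Nshape, circ)
      for (pt in sel_q)
        D0[, , pt] <- meniscus_elasticity_tensor(m$params, cq[pt, ])$C_global
      kperm[sel_e] <- 1e-10
      alpha[sel_e] <- prob$config$stab_coeff / max(diag(D0[, , sel_q[1]]))
    } else if (identical(m$type, "elastic")) {
      D0[, , sel_q] <- m$C
      kperm[sel_e] <- m$permeability %||% 1e-10
      alpha[sel_e] <- prob$config$stab_coeff / max(diag(m$C))
    } else stopf("unknown material type for id %s", id)
  }

  ## fibril architecture at quadrature points
  arch <- NULL
  if (any(frpe_mask) && !is.null(frpe_par) &&
      (frpe_par$fibril_E0_MPa > 0 || frpe_par$fibril_Eeps_MPa > 0)) {
    if (!is.null(mesh$fields$depth)) {
      fv <- cbind(mesh$fields$depth, mesh$fields$normal, mesh$fields$split_line)
      fq <- fe_interp_qp(mesh$elems, q$Nshape, fv)
      nq <- row_normalize(fq[, 2:4, drop = FALSE])
      sq <- fq[, 5:7, drop = FALSE]
      sq <- row_normalize(sq - nq * rowSums(sq * nq))
      prim <- arcade_direction(pmin(1, pmax(0, fq[, 1])), nq, sq,
                               frpe_par$superficial_fraction,
                               frpe_par$deep_fraction)
    } else {
      prim <- matrix(rep(c(0, 0, 1), each = EQ), ncol = 3)
    }
    u_of <- function(m) cbind(m[, 1]^2, m[, 2]^2, m[, 3]^2,
                              m[, 1] * m[, 2], m[, 2] * m[, 3], m[, 1] * m[, 3])
    sec <- secondary_directions(frpe_par$n_secondary)
    arch <- list(primary = prim, u_primary = u_of(prim),
                 u_secondary = u_of(sec),
                 rho_primary = frpe_par$primary_density_fraction,
                 rho_secondary = if (frpe_par$n_secondary > 0)
                   (1 - frpe_par$primary_density_fraction) / frpe_par$n_secondary
                 else 0,
                 params = frpe_par, mask = frpe_mask)
  }

  ## isotropic fast path when every material is FRPE (lambda, mu per point)
  iso <- NULL
  if (all(vapply(prob$materials[unique(matids)], inherits, logical(1),
                 "frpe_params"))) {
    lam <- mu <- numeric(EQ)
    for (id in unique(matids)) {
      lc <- lame_constants(prob$materials[[id]])
      sel_q <- rep((which(matids == id) - 1L) * 8L, each = 8L) + 1:8
      lam[sel_q] <- lc$lambda; mu[sel_q] <- lc$mu
    }
    iso <- list(lambda = lam, mu = mu)
  }

  base <- fe_qhs_triplets(mesh$elems, q$dNdx, q$wdet, q$Nshape, kperm, alpha)
  nn3 <- 3L * nn
  Qmat <- Matrix::sparseMatrix(i = base$qi, j = base$qj, x = base$qx,
                               dims = c(nn3, nn))
  Hmat <- Matrix::sparseMatrix(i = base$hi, j = base$hj, x = base$hx,
                               dims = c(nn, nn))
  Smat <- Matrix::sparseMatrix(i = base$hi, j = base$hj, x = base$sx,
                               dims = c(nn, nn))
  k0 <- fe_stiff_triplets(mesh$elems, q$dNdx, q$wdet, as.numeric(D0))
  list(q = q, D0 = D0, EQ = EQ, nn = nn, arch = arch, base = base, k0 = k0,
       Q = Qmat, H = Hmat, S = Smat, frpe = frpe_par, iso = iso)
}

## linear part of the effective stress (EQ x 6), eps in engineering Voigt
stress_linear <- function(D0, eps, iso = NULL) {
  if (!is.null(iso)) {
    tr <- eps[, 1] + eps[, 2] + eps[, 3]
    ltr <- iso$lambda * tr
    return(cbind(ltr + 2 * iso$mu * eps[, 1],
                 ltr + 2 * iso$mu * eps[, 2],
                 ltr + 2 * iso$mu * eps[, 3],
                 iso$mu * eps[, 4], iso$mu * eps[, 5], iso$mu * eps[, 6]))
  }
  sig <- matrix(0, nrow(eps), 6)
  Dm <- matrix(D0, nrow = 36)
  for (I in 1:6) for (J in 1:6)
    sig[, I] <- sig[, I] + Dm[I + 6 * (J - 1), ] * eps[, J]
  sig
}

## fibril stress and (optionally) tangent over all quadrature points
fibril_response <- function(arch, eps, want_tangent = TRUE) {
  EQ <- nrow(eps)
  sig <- matrix(0, EQ, 6)
  Dfib <- if (want_tangent) matrix(0, 36, EQ) else NULL
  pms <- arch$params
  mask <- arch$mask
  E0 <- pms$fibril_E0_MPa; Ee <- pms$fibril_Eeps_MPa
  ## primary family (direction varies per point)
  up <- arch$u_primary
  epsf_primary <- rowSums(up * eps)
  ef <- ifelse(mask, epsf_primary, 0)
  act <- ef > 0
  if (any(act)) {
    efa <- pmax(ef, 0)
    sf <- arch$rho_primary * (E0 + Ee * efa) * efa
    sig <- sig + sf * up
    if (want_tangent) {
      et <- ifelse(act, arch$rho_primary * (E0 + 2 * Ee * efa), 0)
      for (I in 1:6) for (J in I:6) {
        v <- et * up[, I] * up[, J]
        Dfib[I + 6 * (J - 1), ] <- Dfib[I + 6 * (J - 1), ] + v
        if (I != J) Dfib[J + 6 * (I - 1), ] <- Dfib[J + 6 * (I - 1), ] + v
      }
    }
  }
  ## secondary families: fixed global directions, vectorized across the set
  if (arch$rho_secondary > 0) {
    US <- t(arch$u_secondary)                    # 6 x ns
    EF <- eps %*% US                             # EQ x ns
    EF[!mask, ] <- 0
    EFa <- pmax(EF, 0)
    SF <- arch$rho_secondary * (E0 + Ee * EFa) * EFa
    sig <- sig + SF %*% arch$u_secondary
    if (want_tangent) {
      ET <- arch$rho_secondary * (E0 + 2 * Ee * EFa) * (EF > 0)
      ## Dfib (36 x EQ) += sum_s (u_s u_s^T) et_s  = U36 %*% t(ET)
      U36 <- vapply(seq_len(ncol(US)), function(k) as.numeric(tcrossprod(US[, k])),
                    numeric(36))
      Dfib <- Dfib + U36 %*% t(ET)
    }
  }
  list(sig = sig, Dfib = Dfib, fibril_strain = epsf_primary)
}

## strain, effective stress and optional fibril tangent for a displacement state
compute_stress <- function(prob, pre, U, want_tangent = TRUE) {
  g <- fe_gradu(prob$mesh$elems, pre$q$dNdx, U)
  m9 <- matrix(g, nrow = 9)
  eps <- cbind(m9[1, ], m9[5, ], m9[9, ],
               m9[2, ] + m9[4, ], m9[6, ] + m9[8, ], m9[3, ] + m9[7, ])
  sig <- stress_linear(pre$D0, eps, pre$iso)
  fib <- NULL
  if (!is.null(pre$arch)) {
    fib <- fibril_response(pre$arch, eps, want_tangent)
    sig <- sig + fib$sig
  }
  list(g = g, eps = eps, sig = sig, fib = fib)
}

## consistent nodal forces for a unit traction along `direction` on a face set
traction_forces <- function(mesh, faces, direction) {
  nn <- nrow(mesh$nodes)
  f <- numeric(3 * nn)
  gp <- 1 / sqrt(3)
  gps <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  fn <- face_nodes(mesh, faces)
  for (i in seq_len(nrow(fn))) {
    X <- mesh$nodes[fn[i, ], , drop = FALSE]
    for (g in 1:4) {
      xi <- gps[g, 1]; et <- gps[g, 2]
      N <- 0.25 * c((1 - xi) * (1 - et), (1 + xi) * (1 - et),
                    (1 + xi) * (1 + et), (1 - xi) * (1 + et))
      dNxi <- 0.25 * c(-(1 - et), (1 - et), (1 + et), -(1 + et))
      dNet <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
      t1 <- as.numeric(crossprod(dNxi, X))
      t2 <- as.numeric(crossprod(dNet, X))
      da <- sqrt(sum(c(t1[2] * t2[3] - t1[3] * t2[2],
                       t1[3] * t2[1] - t1[1] * t2[3],
                       t1[1] * t2[2] - t1[2] * t2[1])^2))
      for (a in 1:4) {
        dof <- 3 * (fn[i, a] - 1)
        f[dof + 1:3] <- f[dof + 1:3] + N[a] * da * direction
      }
    }
  }
  f
}

## per-node tributary area of a face set (z-projection-free, true area)
tributary_areas <- function(mesh, faces) {
  fn <- face_nodes(mesh, faces)
  nn <- nrow(mesh$nodes)
  areas <- numeric(nn)
  for (i in seq_len(nrow(fn))) {
    X <- mesh$nodes[fn[i, ], , drop = FALSE]
    d1 <- X[3, ] - X[1, ]; d2 <- X[4, ] - X[2, ]
    a <- 0.5 * sqrt(sum(c(d1[2] * d2[3] - d1[3] * d2[2],
                          d1[3] * d2[1] - d1[1] * d2[3],
                          d1[1] * d2[2] - d1[2] * d2[1])^2))
    areas[fn[i, ]] <- areas[fn[i, ]] + a / 4
  }
  areas
}

## Contact forces and consistent tangent against the rigid sphere at
## center + (0, 0, w). The penalty force is C1-smoothed over a small
## penetration band `delta` (quadratic ramp) to avoid active-set chatter:
## f(pen) = k pen^2 / (2 delta) for pen < delta, k (pen - delta/2) beyond.
contact_eval <- function(nodes, U, cnodes, kA, center, radius, w,
                         delta = 0.02) {
  x <- nodes[cnodes, , drop = FALSE] +
    matrix(U[as.vector(t(outer(3 * (cnodes - 1), 1:3, `+`)))],
           ncol = 3, byrow = TRUE)
  d <- sweep(x, 2, center + c(0, 0, w))
  dist <- sqrt(rowSums(d^2))
  pen <- radius - dist
  act <- which(pen > 0 & kA[cnodes] > 0)
  out <- list(f = numeric(length(U)), ti = integer(0), tj = integer(0),
              tx = numeric(0), jw_i = integer(0), jw_x = numeric(0), jww = 0,
              total = c(0, 0, 0), max_pen = 0, n_active = 0L,
              forces = NULL, normals = NULL, nodes = integer(0))
  if (!length(act)) return(out)
  ia <- cnodes[act]
  nhat <- d[act, , drop = FALSE] / dist[act]
  k <- kA[ia]
  pa <- pen[act]
  fmag <- ifelse(pa < delta, k * pa^2 / (2 * delta), k * (pa - delta / 2))
  fprime <- ifelse(pa < delta, k * pa / delta, k)
  fvec <- nhat * fmag
  dofs <- t(outer(3 * (ia - 1), 1:3, `+`))   # 3 x nact
  f <- numeric(length(U))
  f[as.vector(dofs)] <- as.vector(t(fvec))
  na <- length(act)
  ti <- tj <- integer(9 * na); tx <- numeric(9 * na)
  jw_i <- integer(3 * na); jw_x <- numeric(3 * na)
  jww <- 0
  for (a in seq_len(na)) {
    n1 <- nhat[a, ]
    Mc <- (fmag[a] / dist[act[a]]) * (diag(3) - tcrossprod(n1)) -
      fprime[a] * tcrossprod(n1)             # d f / d x (symmetric)
    dd <- dofs[, a]
    r0 <- 9 * (a - 1)
    ti[r0 + 1:9] <- rep(dd, times = 3)
    tj[r0 + 1:9] <- rep(dd, each = 3)
    tx[r0 + 1:9] <- as.vector(-Mc)           # J_uu contribution
    jw_i[3 * (a - 1) + 1:3] <- dd
    jw_x[3 * (a - 1) + 1:3] <- Mc[, 3]       # dR_u/dw = +Mc e_z
    jww <- jww - Mc[3, 3]                    # dR_w/dw
  }
  list(f = f, ti = ti, tj = tj, tx = tx, jw_i = jw_i, jw_x = jw_x, jww = jww,
       total = colSums(fvec), max_pen = max(pen[act]), n_active = na,
       forces = fvec, normals = nhat, nodes = ia)
}

sphere_gaps <- function(nodes, U, cnodes, center, radius, w) {
  x <- nodes[cnodes, , drop = FALSE] +
    matrix(U[as.vector(t(outer(3 * (cnodes - 1), 1:3, `+`)))], ncol = 3,
           byrow = TRUE)
  d <- sweep(x, 2, center + c(0, 0, w))
  sqrt(rowSums(d^2)) - radius
}

resolve_faces <- function(mesh, faces) {
  if (is.character(faces)) {
    fs <- mesh$face_sets[[faces]]
    if (is.null(fs)) stopf("no face set named '%s'", faces)
    fs
  } else faces
}

#' Assemble the linearized poroelastic system at a given state
#'
#' Backward-Euler discretization of the u-p equations, equal-order
#' interpolation plus pressure-projection stabilization, in the symmetric
#' indefinite form `[K, -Q; -Q^T, -(dt H + S)]` with Dirichlet rows handled
#' by elimination in the solver. Exported as a building block for patch
#' tests and diagnostics; [solve_protocol()] is the user-facing driver.
#'
#' @param prob an [fe_problem()]
#' @param U,P current displacement (length 3N) and pore pressure (length N)
#' @param Un,Pn previous converged step values
#' @param dt time increment (s)
#' @param f_ext external nodal force vector (length 3N)
#' @return list with sparse tangent `A` (4N x 4N), momentum residual `Ru`,
#'   (sign-flipped) mass residual `Rp`, and quadrature arrays `eps`, `sig`
#' @export
assemble <- function(prob, U, P, Un = U * 0, Pn = P * 0, dt = 1,
                     f_ext = numeric(length(U))) {
  pre <- prepare_fe(prob)
  st <- compute_stress(prob, pre, U)
  nn <- pre$nn
  fint <- fe_fint(prob$mesh$elems, pre$q$dNdx, pre$q$wdet, t(st$sig), nn)
  Ru <- fint - f_ext - as.numeric(pre$Q %*% P)
  if (!is.null(prob$springs))
    Ru <- Ru + as.numeric(spring_matrix(prob$springs, nn) %*% U)
  Rp_raw <- as.numeric(Matrix::crossprod(pre$Q, U - Un)) +
    dt * as.numeric(pre$H %*% P) + as.numeric(pre$S %*% (P - Pn))
  A <- tangent_matrix(prob, pre, st, dt)
  list(A = A, Ru = Ru, Rp = -Rp_raw, eps = st$eps, sig = st$sig, fint = fint)
}

## constant part of the tangent (matrix stiffness, coupling, flow,
## stabilization, springs) for a given time increment. `contact_nodes`
## pre-seeds the contact 3x3 blocks (structurally, with negligible values)
## so the sparsity pattern is invariant to the active set and symbolic
## factorizations can be reused. A tiny negative regularization on the
## pressure diagonal keeps the quasi-definite LDL factorization stable when
## the whole boundary is sealed (constant-pressure mode).
tangent_base <- function(prob, pre, dt, contact_nodes = integer(0)) {
  nn <- pre$nn
  b <- pre$base
  preg <- 1e-8 * max(dt * b$hx + b$sx, 1e-12)
  ti <- c(pre$k0$i, b$qi, b$qj + 3L * nn, b$hi + 3L * nn, 3L * nn + seq_len(nn))
  tj <- c(pre$k0$j, b$qj + 3L * nn, b$qi, b$hj + 3L * nn, 3L * nn + seq_len(nn))
  tx <- c(pre$k0$x, -b$qx, -b$qx, -(dt * b$hx + b$sx), rep(-preg, nn))
  if (!is.null(prob$springs)) {
    tt <- Matrix::mat2triplet(spring_matrix(prob$springs, nn))
    ti <- c(ti, tt$i); tj <- c(tj, tt$j); tx <- c(tx, tt$x)
  }
  if (length(contact_nodes)) {
    dofs <- t(outer(3L * (contact_nodes - 1L), 1:3, `+`))
    ci <- as.vector(dofs[rep(1:3, 3), ])
    cj <- as.vector(dofs[rep(1:3, each = 3), ])
    ti <- c(ti, ci); tj <- c(tj, cj); tx <- c(tx, rep(1e-300, length(ci)))
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(4L * nn, 4L * nn))
}

tangent_matrix <- function(prob, pre, st, dt, base = NULL) {
  nn <- pre$nn
  A <- base %||% tangent_base(prob, pre, dt)
  Dfib <- if (!is.null(st$fib) && !is.null(st$fib$Dfib)) st$fib$Dfib
  else if (!is.null(pre$arch)) fibril_response(pre$arch, st$eps, TRUE)$Dfib
  else NULL
  if (!is.null(Dfib) && any(Dfib != 0)) {
    kf <- fe_stiff_triplets(prob$mesh$elems, pre$q$dNdx, pre$q$wdet,
                            as.numeric(Dfib))
    A <- A + Matrix::sparseMatrix(i = kf$i, j = kf$j, x = kf$x,
                                  dims = c(4L * nn, 4L * nn))
  }
  A
}

#' Solve a poroelastic problem over a load protocol
#'
#' Steps the backward-Euler system through the protocol's time points with
#' full Newton iterations (tension-only fibrils and contact are the
#' nonlinearities). In force mode the rigid indenter carries one extra
#' unknown (its vertical position) and its control-point equilibrium
#' equation, so the axial contact reaction balances the applied axial force
#' at every converged step.
#'
#' @param prob an [fe_problem()]
#' @param protocol a `load_protocol`, or any list with `times_s` and
#'   `axial_force_N` (and optionally `stance_pct`)
#' @param measure_steps "all", "none", or indices of the steps at which
#'   quadrature strain/stress measures are extracted
#' @return object of class `fe_states`: displacement/pressure histories,
#'   indenter track, contact force resultants, convergence info and
#'   per-step [strain measure][strain_measures] arrays
#' @export
solve_protocol <- function(prob, protocol, measure_steps = "all") {
  cfg <- prob$config
  mesh <- prob$mesh
  pre <- prepare_fe(prob)
  nn <- pre$nn
  times <- protocol$times_s
  loads <- protocol$axial_force_N
  nt <- length(times)
  if (length(loads) != nt) stopf("protocol vectors must have equal length")
  mst <- if (identical(measure_steps, "all")) seq_len(nt)
  else if (identical(measure_steps, "none")) integer(0)
  else as.integer(measure_steps)

  ## Dirichlet bookkeeping: global dof indices and per-step values
  fix_dof <- integer(0); fix_val <- NULL
  for (bc in prob$fixed_u) {
    dims <- bc$dims %||% 1:3
    dd <- as.vector(t(outer(3 * (bc$nodes - 1), dims, `+`)))
    v <- bc$value %||% 0
    vm <- if (is.function(v))
      vapply(times, function(t1) rep_len(v(t1), length(dd)), numeric(length(dd)))
    else if (is.matrix(v)) {
      if (ncol(v) != nt || nrow(v) != length(dd))
        stopf("prescribed displacement matrix must be (n dofs) x (n steps)")
      v
    } else matrix(rep_len(v, length(dd)), length(dd), nt)
    fix_dof <- c(fix_dof, dd)
    fix_val <- rbind(fix_val, vm)
  }
  if (length(prob$drained_nodes)) {
    dd <- 3L * nn + prob$drained_nodes
    pv <- prob$drained_values
    fix_dof <- c(fix_dof, dd)
    fix_val <- rbind(fix_val, if (is.null(pv)) matrix(0, length(dd), nt) else pv)
  }
  if (anyDuplicated(fix_dof)) {
    keep <- !duplicated(fix_dof)
    fix_dof <- fix_dof[keep]; fix_val <- fix_val[keep, , drop = FALSE]
  }

  has_contact <- !is.null(prob$contact)
  force_mode <- has_contact && identical(prob$contact$mode %||% "force", "force")
  ndof <- 4L * nn
  free <- setdiff(seq_len(ndof), fix_dof)
  iu_free <- which(free <= 3L * nn)
  ip_free <- which(free > 3L * nn)

  f_unit <- if (!is.null(prob$traction))
    traction_forces(mesh, resolve_faces(mesh, prob$traction$faces),
                    prob$traction$direction)
  else NULL
  kA <- NULL; cnodes <- NULL
  if (has_contact) {
    faces <- resolve_faces(mesh, prob$contact$faces %||% "surface")
    kA <- tributary_areas(mesh, faces) * cfg$contact_penalty_N_mm3
    cnodes <- sort(unique(as.vector(face_nodes(mesh, faces))))
  }

  ldl_fac <- NULL    # CHOLMOD symbolic analysis, reused across iterations

  U <- numeric(3 * nn); P <- numeric(nn)
  w_touch <- if (has_contact)
    -min(sphere_gaps(mesh$nodes, U, cnodes, prob$contact$center,
                     prob$contact$radius, 0))
  else 0
  w <- if (has_contact && !force_mode) prob$contact$w[1] else w_touch

  states <- list(times = times,
                 stance_pct = protocol$stance_pct %||%
                   (times / max(times) * 100),
                 U = matrix(0, 3 * nn, nt), P = matrix(0, nn, nt),
                 w = numeric(nt), contact_force_N = matrix(0, 3, nt),
                 applied_force_N = loads, iterations = integer(nt),
                 converged = logical(nt), measures = vector("list", nt))

  ## one backward-Euler increment (indenter position fixed) solved by Newton
  ## with backtracking line search and a displacement trust region
  newton_increment <- function(U0, P0, Uini, Pini, Ft, dt, fixv, w) {
    fx <- if (!is.null(f_unit)) f_unit * (prob$traction$scale %||% 1) * Ft
    else numeric(3 * nn)
    U <- Uini; P <- Pini
    Abase <- tangent_base(prob, pre, dt, contact_nodes = cnodes)

    ## reference scales are FROZEN at the start of the increment so the
    ## line-search merit is a consistent function across iterations
    ref_f <- NULL; ref_p <- NULL
    eval_R <- function(U, P) {
      stq <- compute_stress(prob, pre, U, want_tangent = FALSE)
      fint <- fe_fint(mesh$elems, pre$q$dNdx, pre$q$wdet, t(stq$sig), nn)
      Ru <- fint - fx - as.numeric(pre$Q %*% P)
      if (!is.null(prob$springs))
        Ru <- Ru + as.numeric(spring_matrix(prob$springs, nn) %*% U)
      ce <- NULL
      if (has_contact) {
        ce <- contact_eval(mesh$nodes, U, cnodes, kA, prob$contact$center,
                           prob$contact$radius, w,
                           delta = cfg$contact_smooth_mm)
        Ru <- Ru - ce$f
      }
      QtdU <- as.numeric(Matrix::crossprod(pre$Q, U - U0))
      HP <- dt * as.numeric(pre$H %*% P)
      SdP <- as.numeric(pre$S %*% (P - P0))
      R <- c(Ru, -(QtdU + HP + SdP))
      if (is.null(ref_f)) {
        ref_f <<- max(sqrt(sum(fx^2)),
                      if (!is.null(ce)) sqrt(sum(ce$f^2)) else 0,
                      sqrt(sum(fint^2)), abs(Ft), 1e-3)
        ref_p <<- max(sqrt(sum(HP^2)), sqrt(sum(SdP^2)),
                      ref_f * dt * 1e-3, 1e-9)
      }
      nrm <- sqrt(sum((R[free][iu_free] / ref_f)^2) +
                    sum((R[free][ip_free] / ref_p)^2))
      list(stq = stq, ce = ce, R = R, ref_f = ref_f, ref_p = ref_p, norm = nrm)
    }

    cur <- eval_R(U, P)
    norm0 <- max(cur$norm, 1)
    norm_hist <- rep(cur$norm, 4)
    hist_norms <- rep(cur$norm, 5)   # nonmonotone line-search memory
    first_iter <- TRUE
    for (it in seq_len(cfg$max_iter)) {
      x <- c(U, P)
      dfix <- if (length(fix_dof)) fixv - x[fix_dof] else numeric(0)
      conv_u <- sqrt(sum(cur$R[free][iu_free]^2)) <= cfg$newton_tol * cur$ref_f
      conv_p <- sqrt(sum(cur$R[free][ip_free]^2)) <=
        max(cfg$newton_tol * cur$ref_p, 1e-12)
      if (conv_u && conv_p && !first_iter &&
          (!length(dfix) || all(abs(dfix) < 1e-14)))
        return(list(ok = TRUE, U = U, P = P, iters = it, ce = cur$ce))
      if (cur$norm > 1e3 * norm0) break   # diverged; caller bisects
      ## stall detection from the recent decay rate: give up only when the
      ## projected iterations to tolerance exceed the remaining budget
      norm_hist <- c(norm_hist, cur$norm)
      if (it >= 8) {
        rate <- (cur$norm / norm_hist[length(norm_hist) - 4])^(1 / 4)
        ## Newton on these semismooth problems crawls through the contact
        ## smoothing band and then accelerates; give up only on genuine
        ## no-progress (the caller then halves the increment)
        if (rate >= 0.995 && cur$norm > 1e-2 * norm0) break
      }
      A <- tangent_matrix(prob, pre, cur$stq, dt, base = Abase)
      if (has_contact && length(cur$ce$ti))
        A <- A + Matrix::sparseMatrix(i = cur$ce$ti, j = cur$ce$tj,
                                      x = cur$ce$tx, dims = c(ndof, ndof))
      Rfree <- cur$R[free]
      if (length(fix_dof) && any(dfix != 0))
        Rfree <- Rfree + as.numeric(A[free, fix_dof, drop = FALSE] %*% dfix)
      Afs <- Matrix::forceSymmetric(A[free, free, drop = FALSE])
      dx <- tryCatch({
        ldl_fac <<- if (is.null(ldl_fac))
          Matrix::Cholesky(Afs, LDL = TRUE, super = FALSE, perm = TRUE)
        else Matrix::update(ldl_fac, Afs)
        -as.numeric(Matrix::solve(ldl_fac, Rfree))
      }, error = function(e) NULL)
      if (is.null(dx) || !all(is.finite(dx)))
        dx <- tryCatch(
          -as.numeric(Matrix::solve(Matrix::lu(A[free, free, drop = FALSE]),
                                    Rfree)),
          error = function(e)
            stopf("linear solve failed (%s); check for unconstrained rigid-body modes",
                  conditionMessage(e)))
      du_max <- max(abs(dx[iu_free]), 0)
      if (du_max > cfg$max_du_mm) dx <- dx * (cfg$max_du_mm / du_max)
      ## backtracking line search on the scaled residual norm
      alpha <- 1
      best <- NULL
      repeat {
        xt <- x
        xt[free] <- xt[free] + alpha * dx
        if (length(fix_dof)) xt[fix_dof] <- xt[fix_dof] + dfix
        Ut <- xt[seq_len(3L * nn)]
        Pt <- xt[3L * nn + seq_len(nn)]
        trial <- eval_R(Ut, Pt)
        if (is.null(best) || trial$norm < best$trial$norm)
          best <- list(trial = trial, U = Ut, P = Pt)
        ## nonmonotone acceptance: compare against the worst recent norm so
        ## active-set rearrangements (contact, tension-only fibrils) can pass
        accept <- trial$norm <= (1 - 1e-4 * alpha) * max(hist_norms) ||
          (length(dfix) && any(abs(dfix) > 1e-14))
        if (accept || alpha <= 1 / 64) {
          if (!accept) { trial <- best$trial; Ut <- best$U; Pt <- best$P }
          U <- Ut; P <- Pt
          cur <- trial
          hist_norms <- c(hist_norms[-1], cur$norm)
          break
        }
        alpha <- alpha / 2
      }
      if (isTRUE(getOption("cartimech.trace_newton")))
        message(sprintf("    inner it %2d: alpha=%.4f norm=%.4g nact=%s",
                        it, alpha, cur$norm,
                        if (is.null(cur$ce)) "-" else cur$ce$n_active))
      first_iter <- FALSE
    }
    list(ok = FALSE, U = U, P = P, iters = cfg$max_iter, ce = cur$ce)
  }

  dw_safe <- 0.08   # adaptive safe indenter move per inner continuation chunk
  pred <- NULL      # power-law force-indentation model from the previous step

  ## advance the indenter from w_from to w_to within one time increment,
  ## walking in adaptive chunks so every Newton solve starts warm
  solve_to_w <- function(U0, P0, Uini, Pini, Ft, dt, fixv, w_from, w_to) {
    Uc <- Uini; Pc <- Pini; wc <- w_from
    iters <- 0L; last_res <- NULL
    for (chunk in 1:60) {
      remaining <- w_to - wc
      target <- wc + sign(remaining) * min(abs(remaining), dw_safe)
      res <- newton_increment(U0, P0, Uc, Pc, Ft, dt, fixv, target)
      iters <- iters + res$iters
      if (res$ok) {
        Uc <- res$U; Pc <- res$P; wc <- target; last_res <- res
        if (res$iters <= 6) dw_safe <<- min(dw_safe * 1.4, 0.3)
        if (abs(wc - w_to) < 1e-12)
          return(list(ok = TRUE, U = Uc, P = Pc, iters = iters,
                      ce = res$ce))
      } else {
        dw_safe <<- dw_safe / 2
        if (dw_safe < 4e-3)
          return(list(ok = FALSE, iters = iters))
      }
    }
    list(ok = FALSE, iters = iters)
  }

  ## force-driven indenter: bracketing secant / regula-falsi iteration on the
  ## indenter height so the axial contact reaction matches the applied force
  ## (control-point equilibrium within 0.2%)
  F_scale <- max(abs(loads), 1)
  solve_step_force <- function(U0, P0, w_start, Ft, dt, fixv) {
    ## balance tolerance: 0.3% of the step force, floored at 0.2% of the
    ## protocol peak (near-zero force levels carry no useful precision)
    bal_tol <- max(3e-3 * abs(Ft), 2e-3 * F_scale)
    k_pen0 <- sum(kA[cnodes]) / max(length(cnodes), 1)
    wk <- w_start
    ## warm start: predict the height for the new force level from the
    ## previous step's force-indentation power law
    if (!is.null(pred) && pred$F > 1 && abs(Ft) > 1 && pred$d > 1e-3) {
      d_guess <- pred$d * (abs(Ft) / pred$F)^(1 / pred$m)
      wk <- w_touch - d_guess
    }
    Uw <- U0; Pw <- P0
    w_solved <- w_start                 # height at which (Uw, Pw) is converged
    lo <- hi <- NULL                    # bracket: lo = (w, G<0), hi = (w, G>0)
    iters <- 0L
    last <- NULL
    for (ot in 1:40) {
      res <- solve_to_w(U0, P0, Uw, Pw, Ft, dt, fixv, w_solved, wk)
      iters <- iters + res$iters
      if (!res$ok) return(list(ok = FALSE, iters = iters))
      Uw <- res$U; Pw <- res$P
      w_solved <- wk
      Fz <- res$ce$total[3]
      G <- Ft + Fz                      # > 0: under-loaded, indenter too high
      if (cfg$verbose)
        message(sprintf("  balance it %d: w=%.4f Fc=%.2f target=%.2f (%d inner iters)",
                        ot, wk, -Fz, Ft, res$iters))
      if (abs(G) <= bal_tol) {
        if (Fmag_ok <- (-Fz) > 1 && (w_touch - wk) > 1e-3) {
          m_est <- if (!is.null(last) && last$F > 1 &&
                       abs(log((w_touch - wk) / last$d)) > 1e-8)
            min(max(log(-Fz / last$F) / log((w_touch - wk) / last$d), 1), 6)
          else pred$m %||% 2
          pred <<- list(F = -Fz, d = w_touch - wk, m = m_est)
        }
        return(list(ok = TRUE, U = Uw, P = Pw, w = wk, iters = iters,
                    ce = res$ce))
      }
      if (G > 0) { if (is.null(hi) || G < hi$G) hi <- list(w = wk, G = G) }
      else { if (is.null(lo) || G > lo$G) lo <- list(w = wk, G = G) }
      Fmag <- -Fz                       # current contact force magnitude
      d_now <- w_touch - wk             # indentation depth
      dw <- if (!is.null(lo) && !is.null(hi)) {
        ## regula falsi inside the bracket (G is increasing in w)
        (lo$w * hi$G - hi$w * lo$G) / (hi$G - lo$G) - wk
      } else if (!is.null(last) && last$F > 1e-3 && Fmag > 1e-3 &&
                 d_now > 1e-4 && abs(last$d - d_now) > 1e-6) {
        ## the contact force stiffens with depth; a local power law
        ## F = a d^m extrapolates far better than a linear secant
        m <- log(Fmag / last$F) / log(d_now / last$d)
        m <- min(max(m, 1), 6)
        -(d_now * (abs(Ft) / Fmag)^(1 / m) - d_now)
      } else if (Fmag < 1e-3 * max(abs(Ft), 1)) {
        ## no meaningful contact yet: walk down by a fixed geometric step
        -0.06
      } else {
        kc <- if (!is.null(res$ce) && res$ce$n_active > 0)
          2 * sum(kA[res$ce$nodes]) else 20 * k_pen0
        -sign(G) * max(abs(G) / kc, 0.004)
      }
      last <- list(w = wk, G = G, F = Fmag, d = d_now)
      if (!is.finite(dw) || dw == 0) dw <- -sign(G) * 0.01
      ## cap unbracketed walking; regula falsi is confined by the bracket
      cap <- if (is.null(lo) || is.null(hi)) min(cfg$max_dw_mm, 0.3)
      else cfg$max_dw_mm
      dw <- sign(dw) * min(abs(dw), cap)
      wk <- wk + dw
    }
    ## accept the best height found if the balance error is within 1%
    if (!is.null(last) && abs(last$G) <= 0.01 * max(abs(Ft), 1)) {
      res <- solve_to_w(U0, P0, Uw, Pw, Ft, dt, fixv, w_solved, last$w)
      if (res$ok)
        return(list(ok = TRUE, U = res$U, P = res$P, w = last$w,
                    iters = iters + res$iters, ce = res$ce))
    }
    list(ok = FALSE, iters = iters)
  }

  Un <- U; Pn <- P
  fail <- NULL
  for (st_i in seq_len(nt)) {
    dt_full <- if (st_i == 1) max(times[min(2, nt)] - times[1], 1e-6)
    else times[st_i] - times[st_i - 1]
    F_prev <- if (st_i == 1) 0 else loads[st_i - 1]
    F_target <- loads[st_i]
    fixv_prev <- if (!length(fix_dof)) numeric(0)
    else if (st_i == 1) fix_val[, 1] * 0 else fix_val[, st_i - 1]
    fixv_target <- if (length(fix_dof)) fix_val[, st_i] else numeric(0)

    frac_done <- 0
    stack <- 1
    iters_used <- 0L
    ce_last <- NULL
    while (length(stack)) {
      df <- stack[1]; stack <- stack[-1]
      frac_try <- frac_done + df
      Ft_s <- F_prev + frac_try * (F_target - F_prev)
      fixv_s <- if (length(fix_dof))
        fixv_prev + frac_try * (fixv_target - fixv_prev) else numeric(0)
      dt_s <- df * dt_full
      if (force_mode) {
        res <- solve_step_force(Un, Pn, w, Ft_s, dt_s, fixv_s)
      } else {
        w_s <- if (has_contact) {
          w_prev <- if (st_i == 1) prob$contact$w[1] else prob$contact$w[st_i - 1]
          w_prev + frac_try * (prob$contact$w[st_i] - w_prev)
        } else 0
        res <- newton_increment(Un, Pn, Un, Pn, Ft_s, dt_s, fixv_s, w_s)
        res$w <- w_s
      }
      iters_used <- iters_used + res$iters
      if (res$ok) {
        Un <- res$U; Pn <- res$P; w <- res$w %||% w
        ce_last <- res$ce
        frac_done <- frac_try
      } else if (df > 1 / 32) {
        stack <- c(df / 2, df / 2, stack)
      } else {
        fail <- list(step = st_i, time = times[st_i])
        break
      }
    }
    states$iterations[st_i] <- iters_used
    states$converged[st_i] <- is.null(fail)
    if (!is.null(fail)) {
      warning(sprintf("step %d (t = %.3g s) did not converge; returning partial history",
                      st_i, times[st_i]), call. = FALSE)
      states$failure <- fail
      break
    }
    states$U[, st_i] <- Un
    states$P[, st_i] <- Pn
    states$w[st_i] <- w
    if (has_contact && !is.null(ce_last)) {
      states$contact_force_N[, st_i] <- ce_last$total
      th <- mesh$fields$thickness
      if (!is.null(th) && ce_last$max_pen > 0.1 * min(th))
        warning("contact penetration exceeds 10% of minimum thickness; consider a higher penalty",
                call. = FALSE)
    }
    if (st_i %in% mst)
      states$measures[[st_i]] <- qp_measures(prob, pre, Un, Pn)
    if (cfg$verbose)
      message(sprintf("step %3d t=%.3g F=%.1f N: %d iterations, w=%.4g, Fc=%.1f N",
                      st_i, times[st_i], loads[st_i], iters_used, w,
                      if (has_contact && !is.null(ce_last)) -ce_last$total[3] else NA))
  }
  states$qp_coords <- t(pre$q$xq)
  states$mesh <- mesh
  structure(states, class = "fe_states")
}

## per-quadrature-point derived measures for one converged displacement state
qp_measures <- function(prob, pre, U, P) {
  g <- fe_gradu(prob$mesh$elems, pre$q$dNdx, U)
  El <- hencky_voigt(g)
  pr <- eig3_sym(El)
  stq <- compute_stress(prob, pre, U, want_tangent = FALSE)
  p_qp <- as.numeric(fe_interp_qp(prob$mesh$elems, pre$q$Nshape,
                                  matrix(P, ncol = 1)))
  sig_tot <- stq$sig
  sig_tot[, 1:3] <- sig_tot[, 1:3] - p_qp
  s1 <- eig3_sym(sig_tot)[, 1]
  fib <- if (!is.null(pre$arch)) {
    ## finite-strain fibril stretch along the primary direction
    m9 <- matrix(g, nrow = 9)
    f <- m9; f[c(1, 5, 9), ] <- f[c(1, 5, 9), ] + 1
    m <- pre$arch$primary
    fm1 <- f[1, ] * m[, 1] + f[4, ] * m[, 2] + f[7, ] * m[, 3]
    fm2 <- f[2, ] * m[, 1] + f[5, ] * m[, 2] + f[8, ] * m[, 3]
    fm3 <- f[3, ] * m[, 1] + f[6, ] * m[, 2] + f[9, ] * m[, 3]
    sqrt(fm1^2 + fm2^2 + fm3^2) - 1
  } else rep(0, nrow(El))
  cbind(e1 = pr[, 1], e2 = pr[, 2], e3 = pr[, 3],
        shear = pr[, 1] - pr[, 3],
        axial = El[, 3], lateral = El[, 1],
        fibril = fib, sig1 = s1, p = p_qp)
}

#' Strain measures of a (logarithmic) strain state
#'
#' Principal logarithmic strains sorted descending, maximum engineering
#' shear (largest minus smallest principal), axial and lateral components,
#' and the fibril strain if supplied.
#'
#' @param E strain tensor(s) in Voigt order (xx, yy, zz, xy, yz, xz) with
#'   tensor (not engineering) shear components; a length-6 vector or a
#'   matrix with one state per row
#' @param axial_axis,lateral_axis coordinate indices of the loading axis and
#'   the reported in-plane axis
#' @param fibril_strain optional fibril strain(s) passed through
#' @return matrix with columns `e1,e2,e3,shear,axial,lateral,fibril`
#' @export
strain_measures <- function(E, axial_axis = 3, lateral_axis = 1,
                            fibril_strain = NULL) {
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  if (ncol(E) != 6) stopf("E must have 6 Voigt components")
  pr <- eig3_sym(E)
  cbind(e1 = pr[, 1], e2 = pr[, 2], e3 = pr[, 3],
        shear = pr[, 1] - pr[, 3],
        axial = E[, axial_axis], lateral = E[, lateral_axis],
        fibril = if (is.null(fibril_strain)) rep(NA_real_, nrow(E))
        else rep_len(fibril_strain, nrow(E)))
}

#' @export
print.fe_states <- function(x, ...) {
  cat(sprintf("<fe_states> %d steps, %d nodes, peak |u| = %.3g mm, peak applied force %.1f N\n",
              length(x$times), nrow(x$U) / 3, max(abs(x$U)),
              max(x$applied_force_N)))
  if (!is.null(x$failure))
    cat(sprintf("  NOT fully converged: failed at step %d\n", x$failure$step))
  invisible(x)
}

#' @export
summary.fe_states <- function(object, ...) {
  steps_with <- which(!vapply(object$measures, is.null, logical(1)))
  peak <- if (length(steps_with)) {
    m <- do.call(rbind, object$measures[steps_with])
    c(min_principal = min(m[, "e3"]), max_principal = max(m[, "e1"]),
      max_shear = max(m[, "shear"]), max_fibril = max(m[, "fibril"]),
      max_sig1_MPa = max(m[, "sig1"]))
  } else NULL
  out <- list(n_steps = length(object$times),
              converged = all(object$converged[seq_along(object$times)]),
              peak_measures = peak,
              max_contact_force_N = max(abs(object$contact_force_N[3, ])))
  class(out) <- "summary.fe_states"
  out
}

#' @export
print.summary.fe_states <- function(x, ...) {
  cat(sprintf("Poroelastic solve: %d steps, %s\n", x$n_steps,
              if (x$converged) "all converged" else "NOT fully converged"))
  if (!is.null(x$peak_measures)) {
    cat("Peak measures over stored steps:\n")
    print(round(x$peak_measures, 5))
  }
  invisible(x)
}
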