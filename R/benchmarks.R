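## Poroelastic verification benchmark: one-dimensional confined-compression
## consolidation of a laterally confined column loaded by a ramp-hold
## surface pressure, drained at the loaded face. The closed-form series
## solution serves as the independent oracle for the u-p solver.

#' Closed-form ramp-hold consolidation solution
#'
#' Settlement of the loaded surface and pore pressure at a given depth for a
#' single-drained poroelastic column under a surface pressure ramped
#' linearly to `sigma0` over `t_ramp` and then held. Series solution of the
#' one-dimensional consolidation equation with consolidation coefficient
#' `cv = k * M` (`M` the drained constrained modulus, `k` the permeability).
#'
#' @param t times (s)
#' @param sigma0 held surface pressure (MPa)
#' @param L column height = drainage path (mm)
#' @param M drained constrained modulus (MPa)
#' @param cv consolidation coefficient (mm^2/s)
#' @param t_ramp ramp duration (s)
#' @param x_obs observation depth below the drained surface (mm) for the
#'   pore pressure
#' @param n_terms number of series terms
#' @return data frame with `t`, `settlement_mm`, `pressure_MPa`
#' @export
consolidation_series <- function(t, sigma0, L, M, cv, t_ramp,
                                 x_obs = L / 2, n_terms = 200) {
  m <- 0:(n_terms - 1)
  lam <- (2 * m + 1)^2 * pi^2 * cv / (4 * L^2)
  Bm <- 8 / (pi^2 * (2 * m + 1)^2)
  Am <- 4 / (pi * (2 * m + 1)) * sin((2 * m + 1) * pi * x_obs / (2 * L))
  C <- sigma0 * L / M
  settle <- pressure <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= t_ramp) {
      settle[i] <- C / t_ramp * (ti - sum(Bm * (1 - exp(-lam * ti)) / lam))
      pressure[i] <- sigma0 / t_ramp * sum(Am * (1 - exp(-lam * ti)) / lam)
    } else {
      gm <- (exp(pmin(lam * t_ramp, 700)) - 1) / (lam * t_ramp)
      ## guard overflow: for large lam*t_ramp the mode is fully decayed anyway
      term <- ifelse(lam * ti > 700, 0, gm * exp(-lam * ti))
      settle[i] <- C * (1 - sum(Bm * term))
      pressure[i] <- sigma0 * sum(Am * term)
    }
  }
  data.frame(t = t, settlement_mm = settle, pressure_MPa = pressure)
}

#' Build the confined-compression column problem
#'
#' A single column of hex elements, laterally confined, fixed at the base,
#' loaded by a downward surface pressure on the drained top face.
#'
#' @param n_elem number of elements through the height
#' @param L column height (mm)
#' @param a cross-section edge length (mm)
#' @param params material ([frpe_params()]; set the fibril moduli to zero to
#'   match the linear closed form)
#' @param config a [solver_config()]
#' @return list with the `fe_problem`, cross-section area, and node indices
#'   of the loaded surface and the mid-height plane
#' @export
confined_compression_problem <- function(n_elem = 20, L = 1, a = 0.25,
                                         params = frpe_params(
                                           matrix_E_MPa = 1.0, matrix_nu = 0.3,
                                           permeability_mm4_per_Ns = 1e-2,
                                           fibril_E0_MPa = 0, fibril_Eeps_MPa = 0),
                                         config = solver_config()) {
  zs <- seq(0, L, length.out = n_elem + 1)
  xy <- c(0, a)
  nodes <- as.matrix(expand.grid(x = xy, y = xy, z = zs))[, c("x", "y", "z")]
  nid <- function(i, j, k) (k - 1L) * 4L + (j - 1L) * 2L + i
  elems <- t(vapply(seq_len(n_elem), function(k) {
    c(nid(1L, 1L, k), nid(2L, 1L, k), nid(2L, 2L, k), nid(1L, 2L, k),
      nid(1L, 1L, k + 1L), nid(2L, 1L, k + 1L), nid(2L, 2L, k + 1L),
      nid(1L, 2L, k + 1L))
  }, integer(8)))
  top <- which(abs(nodes[, 3] - L) < 1e-12)
  bottom <- which(abs(nodes[, 3]) < 1e-12)
  mid <- which(abs(nodes[, 3] - L / 2) < 1e-9)
  mesh <- volume_mesh(nodes, elems,
                      node_sets = list(top = top, bottom = bottom),
                      face_sets = list(top = cbind(n_elem, 2L),
                                       bottom = cbind(1L, 1L)))
  prob <- fe_problem(
    mesh, materials = list("1" = params),
    fixed_u = list(list(nodes = seq_len(nrow(nodes)), dims = 1:2, value = 0),
                   list(nodes = bottom, dims = 3, value = 0)),
    drained_nodes = top,
    traction = list(faces = "top", direction = c(0, 0, -1), scale = 1 / a^2),
    config = config)
  list(prob = prob, area = a^2, top = top, mid = mid, L = L)
}

#' Run the confined-compression consolidation benchmark
#'
#' Solves the ramp-hold consolidation problem and reports relative L2
#' errors of the surface settlement and mid-height pore pressure against
#' the closed-form series over the hold phase.
#'
#' @param n_elem elements through the height
#' @param sigma0 held surface pressure (MPa)
#' @param t_ramp ramp duration (s)
#' @param t_end end of the hold (s)
#' @param n_ramp,n_hold time steps in each phase
#' @inheritParams confined_compression_problem
#' @return list with the state history, oracle table, and the two relative
#'   L2 errors
#' @export
consolidation_benchmark <- function(n_elem = 20, sigma0 = 0.1,
                                    t_ramp = 10, t_end = 160,
                                    n_ramp = 20, n_hold = 60,
                                    params = frpe_params(
                                      matrix_E_MPa = 1.0, matrix_nu = 0.3,
                                      permeability_mm4_per_Ns = 1e-2,
                                      fibril_E0_MPa = 0, fibril_Eeps_MPa = 0),
                                    config = solver_config()) {
  setup <- confined_compression_problem(n_elem = n_elem, params = params,
                                        config = config)
  lc <- lame_constants(params)
  M <- lc$lambda + 2 * lc$mu
  cv <- params$permeability_mm4_per_Ns * M
  times <- c(seq(0, t_ramp, length.out = n_ramp + 1)[-1],
             t_ramp + (t_end - t_ramp) *
               (seq(0, 1, length.out = n_hold + 1)[-1])^1.5)
  force <- sigma0 * setup$area * pmin(times / t_ramp, 1)
  states <- solve_protocol(setup$prob,
                           list(times_s = times, axial_force_N = force),
                           measure_steps = "none")
  settle <- -colMeans(states$U[3 * (setup$top - 1) + 3, , drop = FALSE])
  pmid <- colMeans(states$P[setup$mid, , drop = FALSE])
  oracle <- consolidation_series(times, sigma0, setup$L, M, cv, t_ramp,
                                 x_obs = setup$L / 2)
  hold <- times > t_ramp
  rel_l2 <- function(x, y) sqrt(sum((x - y)^2) / sum(y^2))
  list(states = states, oracle = oracle, times = times,
       settlement_mm = settle, pressure_MPa = pmid,
       err_settlement = rel_l2(settle[hold], oracle$settlement_mm[hold]),
       err_pressure = rel_l2(pmid[hold], oracle$pressure_MPa[hold]))
}
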