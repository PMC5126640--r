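## Parametric defects: carving into the layered cartilage mesh, intact
## surface reconstruction over a defect, relocation at constant normalized
## penetration depth, and defect-wall drainage boundary conditions.
##
## Footprints live in a 2-D tangent-plane chart at the defect center;
## relocation transports the chart (and the footprint polygon, unchanged) to
## the target center. Carving is realized by node-column morphing: surface
## vertices inside the footprint are pushed to the defect floor along the
## local normal and the column is re-graded, which keeps the mesh conformal
## at the rim. Per-vertex footprint coverage (sub-sampled area fractions)
## gives smoothed walls one cell wide and conserves the removed volume.

## orthonormal tangent basis at a surface point (chart axes)
chart_basis <- function(comp, center) {
  n <- as.numeric(surface_normal_at(comp, center[1], center[2]))
  a <- c(1, 0, 0)
  e1 <- a - n * sum(a * n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  p0 <- c(center, surface_height_at(comp, center[1], center[2]))
  list(origin = p0, n = n, e1 = e1, e2 = e2)
}

## chart coordinates of surface points (rows of xyz)
chart_coords <- function(basis, xyz) {
  d <- sweep(matrix(xyz, ncol = 3), 2, basis$origin)
  cbind(d %*% basis$e1, d %*% basis$e2)
}

## vectorized ray-casting point-in-polygon test
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## fraction of each vertex's tributary cell inside the polygon (chart coords)
footprint_coverage <- function(uv, poly, cell, n_sub = 4L) {
  offs <- (seq_len(n_sub) - 0.5) / n_sub - 0.5
  cov <- numeric(nrow(uv))
  for (ox in offs) for (oy in offs) {
    pts <- cbind(uv[, 1] + ox * cell, uv[, 2] + oy * cell)
    cov <- cov + points_in_polygon(pts, poly)
  }
  cov / n_sub^2
}

#' Normalized penetration depth of points below the intact surface
#'
#' Distance below the analytic intact surface along the local surface
#' normal, divided by the local cartilage thickness; clamped to \[0, 1\]
#' (clamping is reported via an attribute).
#'
#' @param points numeric vector (one point) or matrix of xyz coordinates (mm)
#' @param comp the [make_compartment()] result holding the intact surface
#'   and thickness profile
#' @return numeric vector of penetrations in \[0, 1\]
#' @export
normalized_penetration <- function(points, comp) {
  pts <- matrix(points, ncol = 3)
  out <- numeric(nrow(pts))
  n_clamped <- 0L
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    xy <- p[1:2]
    for (it in 1:8) {                      # foot-point projection iteration
      n <- as.numeric(surface_normal_at(comp, xy[1], xy[2]))
      ps <- c(xy, surface_height_at(comp, xy[1], xy[2]))
      s <- sum((p - ps) * n)
      proj <- p - s * n
      if (sum((proj[1:2] - xy)^2) < 1e-20) break
      xy <- proj[1:2]
    }
    th <- thickness_at(comp, xy[1], xy[2])
    pen <- -s / th                         # s < 0 below the surface
    if (pen < -1e-6 || pen > 1 + 1e-6) {
      if (pen < -0.02 || pen > 1.02)
        stopf("point %d lies outside the cartilage slab (penetration %.3f)",
              k, pen)
      n_clamped <- n_clamped + 1L
    }
    out[k] <- min(1, max(0, pen))
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Carve a parametric defect into a compartment mesh
#'
#' Removes material under the footprint down to `depth_fraction` times the
#' local thickness by morphing the node columns of the layered mesh: the
#' surface vertex of a column inside the footprint moves to the defect
#' floor and the layers below are re-graded, so the mesh stays conformal at
#' the rim. Per-vertex footprint coverage smooths the walls over one cell.
#'
#' @param comp a [make_compartment()] result
#' @param spec a [make_defect()] specification
#' @return object of class `defect_geometry`: the carved `volume_mesh`, the
#'   defect/rim node sets, the inner-wall face set, per-defect-node
#'   normalized penetrations, projected footprint area, and removed volume
#' @export
carve_defect <- function(comp, spec) {
  mesh <- comp$mesh
  g <- attr(mesh, "grid")
  if (is.null(g)) stopf("carving requires a generated (layered grid) compartment mesh")
  basis <- chart_basis(comp, spec$center)
  surf <- mesh$node_sets$surface
  uv <- chart_coords(basis, mesh$nodes[surf, , drop = FALSE])
  cell <- mean(diff(g$xs))
  ## footprint must stay inside the meshed patch (with one cell margin)
  rng <- apply(spec$footprint, 2, range)
  if (spec$center[1] + rng[1, 1] < min(g$xs) + cell ||
      spec$center[1] + rng[2, 1] > max(g$xs) - cell ||
      spec$center[2] + rng[1, 2] < min(g$ys) + cell ||
      spec$center[2] + rng[2, 2] > max(g$ys) - cell)
    stopf("defect footprint '%s' extends off the meshed surface patch", spec$label)

  cov <- footprint_coverage(uv, spec$footprint, cell)
  ## full-thickness defects are carved to 99.5% so the remaining column
  ## keeps positive element volumes; the full-thickness marker is on the spec
  frac <- pmin(spec$depth_fraction, 0.995) * cov
  if (max(cov) < 1 - 1e-9)
    warning("footprint is barely resolved by the mesh: no fully covered vertex",
            call. = FALSE)

  ## morph node columns: new normalized depth d' = frac + d (1 - frac)
  nc <- g$ncol_grid; nz <- g$nz
  xy <- mesh$nodes[surf, 1:2, drop = FALSE]
  zs <- surface_height_at(comp, xy[, 1], xy[, 2])
  th <- thickness_at(comp, xy[, 1], xy[, 2])
  nrm <- surface_normal_at(comp, xy[, 1], xy[, 2])
  nodes <- mesh$nodes
  depth <- mesh$fields$depth
  for (k in 0:nz) {
    idx <- k * nc + seq_len(nc)
    d0 <- k / nz
    dnew <- frac + d0 * (1 - frac)
    nodes[idx, ] <- cbind(xy, zs) - nrm * (dnew * th)
    depth[idx] <- dnew
  }
  carved <- mesh
  carved$nodes <- nodes
  carved$fields$depth <- depth

  defect_surf_nodes <- surf[cov > 0]
  ## rim: uncarved surface vertices adjacent (grid 8-neighborhood) to carved ones
  carved_mask <- matrix(cov > 0, g$nx + 1, g$ny + 1)
  rim_mask <- matrix(FALSE, g$nx + 1, g$ny + 1)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(g$nx + 1, g$nx + 1 + di)
    ti <- max(1, 1 - di):min(g$nx + 1, g$nx + 1 - di)
    sj <- max(1, 1 + dj):min(g$ny + 1, g$ny + 1 + dj)
    tj <- max(1, 1 - dj):min(g$ny + 1, g$ny + 1 - dj)
    rim_mask[ti, tj] <- rim_mask[ti, tj] | carved_mask[si, sj]
  }
  rim_nodes <- surf[as.vector(rim_mask) & cov == 0]

  ## inner-wall faces: articular-side faces of top-layer elements with at
  ## least one carved vertex (floor and smoothed wall belong to this set)
  sf <- mesh$face_sets$surface
  carved_set <- rep(FALSE, nrow(mesh$nodes))
  carved_set[defect_surf_nodes] <- TRUE
  fn <- face_nodes(mesh, sf)
  wall <- sf[rowSums(matrix(carved_set[fn], ncol = 4)) > 0, , drop = FALSE]

  removed <- mesh_volume(mesh) - mesh_volume(carved)
  structure(list(mesh = carved, spec = spec,
                 defect_nodes = defect_surf_nodes,
                 rim_nodes = rim_nodes,
                 inner_wall_faces = wall,
                 penetration = frac[cov > 0],
                 coverage = cov,
                 projected_area_mm2 = polygon_area(spec$footprint),
                 removed_volume_mm3 = removed,
                 compartment_spec = comp$spec),
            class = "defect_geometry")
}

#' @export
print.defect_geometry <- function(x, ...) {
  cat(sprintf("<defect_geometry> '%s': %d defect nodes, %d rim nodes, removed %.3f mm^3, max penetration %.3f\n",
              x$spec$label, length(x$defect_nodes), length(x$rim_nodes),
              x$removed_volume_mm3, max(x$penetration)))
  invisible(x)
}

#' Relocate a defect at constant normalized penetration depth
#'
#' Transports the footprint polygon in its tangent-plane chart to the
#' target center and re-carves: each relocated node sits at the projected
#' surface point minus its normalized penetration fraction times the local
#' thickness along the local inward normal. The normalized depth profile
#' and the projected footprint area are therefore preserved while the
#' absolute defect depth follows the local thickness.
#'
#' @param comp a [make_compartment()] result
#' @param spec the defect to relocate (a [make_defect()] spec)
#' @param target length-2 target center in surface coordinates (mm)
#' @return list with the relocated `spec` and carved `geometry`
#' @export
relocate_defect <- function(comp, spec, target) {
  new_spec <- spec
  new_spec$center <- as.numeric(target)
  geometry <- carve_defect(comp, new_spec)
  list(spec = new_spec, geometry = geometry)
}

#' Reconstruct the intact surface over a defect
#'
#' Discrete biharmonic (clamped thin-plate) hole fill on the structured
#' surface grid: heights inside the hole are solved from the bilaplacian
#' equation with two rings of known values outside the hole prescribing
#' position and slope continuity at the rim.
#'
#' @param surface a `surface_mesh` over a structured grid (the compartment's
#'   `intact_surface` layout) with heights to be repaired in place
#' @param hole_vertices vertex indices whose heights are unknown (the
#'   defect); an empty set returns the surface unchanged
#' @param grid_dims c(nx + 1, ny + 1) vertex grid dimensions; taken from the
#'   `grid` attribute when present
#' @return the surface with filled vertex heights
#' @export
fill_defect_surface <- function(surface, hole_vertices, grid_dims = NULL) {
  if (!length(hole_vertices)) return(surface)
  if (is.null(grid_dims)) {
    g <- attr(surface, "grid")
    if (is.null(g)) stopf("grid_dims required for a surface without grid attribute")
    grid_dims <- c(g$nx + 1L, g$ny + 1L)
  }
  nx1 <- grid_dims[1]; ny1 <- grid_dims[2]
  if (nrow(surface$nodes) != nx1 * ny1) stopf("grid dimensions do not match surface")
  hole <- rep(FALSE, nx1 * ny1)
  hole[hole_vertices] <- TRUE
  hm <- matrix(hole, nx1, ny1)
  ij <- which(hm, arr.ind = TRUE)
  if (any(ij[, 1] <= 2 | ij[, 1] >= nx1 - 1 | ij[, 2] <= 2 | ij[, 2] >= ny1 - 1))
    stopf("hole touches the patch boundary; rim must be a closed interior loop")
  idx <- function(i, j) (j - 1L) * nx1 + i
  ## 13-point discrete bilaplacian stencil
  st <- rbind(c(0, 0, 20), c(1, 0, -8), c(-1, 0, -8), c(0, 1, -8), c(0, -1, -8),
              c(1, 1, 2), c(1, -1, 2), c(-1, 1, 2), c(-1, -1, 2),
              c(2, 0, 1), c(-2, 0, 1), c(0, 2, 1), c(0, -2, 1))
  un <- which(hole)
  row_of <- integer(nx1 * ny1); row_of[un] <- seq_along(un)
  ti <- tj <- integer(0); tx <- numeric(0)
  rhs <- numeric(length(un))
  z <- surface$nodes[, 3]
  for (r in seq_along(un)) {
    i <- (un[r] - 1L) %% nx1 + 1L
    j <- (un[r] - 1L) %/% nx1 + 1L
    for (q in seq_len(nrow(st))) {
      ii <- i + st[q, 1]; jj <- j + st[q, 2]
      k <- idx(ii, jj)
      if (hole[k]) {
        ti <- c(ti, r); tj <- c(tj, row_of[k]); tx <- c(tx, st[q, 3])
      } else {
        rhs[r] <- rhs[r] - st[q, 3] * z[k]
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(length(un), length(un)))
  zfill <- as.numeric(Matrix::solve(A, rhs))
  out <- surface
  out$nodes[un, 3] <- zfill
  out
}

#' Defect-wall drainage boundary conditions
#'
#' Free fluid flow is allowed only through the inner defect surfaces: the
#' drained set is exactly the carved inner-wall face set, every other
#' external face is sealed (no flux). For an intact model the drained set
#' is empty.
#'
#' @param geometry a [carve_defect()] result, or a plain `volume_mesh` for
#'   the intact case
#' @param sealed_defect if `TRUE`, returns the sealed-defect variant (the
#'   drained set is emptied; nothing else changes)
#' @return list with `drained_faces`, `sealed_faces` (disjoint, jointly
#'   covering the boundary) and `drained_nodes` for the pressure Dirichlet
#' @export
defect_drainage_bcs <- function(geometry, sealed_defect = FALSE) {
  if (inherits(geometry, "volume_mesh")) {
    bf <- boundary_faces(geometry)
    return(list(drained_faces = bf[0, , drop = FALSE], sealed_faces = bf,
                drained_nodes = integer(0)))
  }
  mesh <- geometry$mesh
  bf <- boundary_faces(mesh)
  key <- function(f) paste(f[, 1], f[, 2], sep = ":")
  wall <- geometry$inner_wall_faces
  if (sealed_defect) wall <- wall[0, , drop = FALSE]
  in_wall <- key(bf) %in% key(wall)
  drained <- bf[in_wall, , drop = FALSE]
  sealed <- bf[!in_wall, , drop = FALSE]
  if (length(intersect(key(drained), key(sealed))))
    stopf("drained and sealed face sets overlap")
  drained_nodes <- if (nrow(drained))
    sort(unique(as.vector(face_nodes(mesh, drained)))) else integer(0)
  list(drained_faces = drained, sealed_faces = sealed,
       drained_nodes = drained_nodes)
}

#' Export a defect specification as JSON
#' @param spec a `defect_spec`
#' @param path output file
#' @export
write_defect_json <- function(spec, path) {
  jsonlite::write_json(
    list(shape = spec$shape, area_mm2 = spec$area_mm2,
         depth_fraction = spec$depth_fraction, center = spec$center,
         label = spec$label, units = "mm",
         footprint = unname(apply(spec$footprint, 1, function(r) r,
                                  simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
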