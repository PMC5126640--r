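## Volume/surface mesh containers and geometric utilities.
##
## Node indexing is 1-based in memory (R convention); all on-disk formats
## (legacy VTK, STL) use the formats' own 0-based connectivity.

## local faces of a hex8 (VTK node ordering), outward-oriented quads
HEX_FACES <- rbind(
  zmin = c(1, 4, 3, 2),
  zmax = c(5, 6, 7, 8),
  ymin = c(1, 2, 6, 5),
  xmax = c(2, 3, 7, 6),
  ymax = c(3, 4, 8, 7),
  xmin = c(4, 1, 5, 8)
)

#' Volume mesh container
#'
#' Nodes in millimetres plus hex8 (and optionally tet4) connectivity, named
#' node/face/element sets, and a per-element material id. Face sets are stored
#' as (element, local face) pairs.
#'
#' @param nodes numeric N x 3 matrix of coordinates (mm)
#' @param elems integer E x 8 hex connectivity (VTK ordering, 1-based)
#' @param material integer per-element material id
#' @param node_sets,face_sets,elem_sets named lists of sets
#' @param fields named list of per-node scalar/vector fields
#' @param elem_type "hex8" or "tet4" (tet4 meshes are carried for imaging
#'   quadrature only; the poroelastic solver operates on hex8)
#' @return an object of class `volume_mesh`
#' @export
volume_mesh <- function(nodes, elems, material = rep(1L, nrow(elems)),
                        node_sets = list(), face_sets = list(),
                        elem_sets = list(), fields = list(),
                        elem_type = "hex8") {
  nodes <- as.matrix(nodes)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3) stopf("nodes must be N x 3")
  npe <- if (elem_type == "hex8") 8L else 4L
  if (ncol(elems) != npe) stopf("elems must be E x %d for %s", npe, elem_type)
  if (max(elems) > nrow(nodes) || min(elems) < 1L)
    stopf("element connectivity references missing nodes")
  if (anyDuplicated(names(node_sets)) || anyDuplicated(names(face_sets)))
    stopf("set names must be unique")
  structure(list(nodes = nodes, elems = elems, material = as.integer(material),
                 node_sets = node_sets, face_sets = face_sets,
                 elem_sets = elem_sets, fields = fields,
                 elem_type = elem_type, units = "mm"),
            class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("<volume_mesh> %d nodes, %d %s elements (units: %s)\n",
              nrow(x$nodes), nrow(x$elems), x$elem_type, x$units))
  if (length(x$node_sets)) cat(" node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$face_sets)) cat(" face sets:", paste(names(x$face_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Surface mesh (triangles)
#' @param nodes N x 3 coordinates (mm)
#' @param tris T x 3 triangle connectivity (1-based)
#' @param fields named list of per-vertex fields
#' @return an object of class `surface_mesh`
#' @export
surface_mesh <- function(nodes, tris, fields = list()) {
  storage.mode(tris) <- "integer"
  structure(list(nodes = as.matrix(nodes), tris = tris, fields = fields,
                 units = "mm"),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$nodes), nrow(x$tris)))
  invisible(x)
}

## face node indices for a face-set matrix (elem, localface)
face_nodes <- function(mesh, faces) {
  t(vapply(seq_len(nrow(faces)), function(i) {
    mesh$elems[faces[i, 1], HEX_FACES[faces[i, 2], ]]
  }, integer(4)))
}

## all boundary faces of a hex mesh as (elem, localface) pairs
boundary_faces <- function(mesh) {
  E <- nrow(mesh$elems)
  all_faces <- do.call(rbind, lapply(1:6, function(lf) {
    cbind(seq_len(E), lf)
  }))
  keys <- vapply(seq_len(nrow(all_faces)), function(i) {
    nd <- sort(mesh$elems[all_faces[i, 1], HEX_FACES[all_faces[i, 2], ]])
    paste(nd, collapse = "-")
  }, character(1))
  tab <- table(keys)
  all_faces[keys %in% names(tab)[tab == 1L], , drop = FALSE]
}

## per-element volumes via the quadrature kernel
element_volumes <- function(mesh) {
  q <- fe_quadrature(mesh$nodes, mesh$elems)
  if (q$min_detJ <= 0) stopf("mesh has non-positive Jacobians")
  rowSums(matrix(q$wdet, ncol = 8, byrow = TRUE))
}

#' Total mesh volume (mm^3)
#' @param mesh a `volume_mesh`
#' @export
mesh_volume <- function(mesh) sum(element_volumes(mesh))

## minimum scaled Jacobian over element corners (quality metric in [−1, 1])
min_scaled_jacobian <- function(mesh) {
  el <- mesh$elems; nd <- mesh$nodes
  ## corner a: edges to its three neighbours in the hex graph
  nb <- rbind(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
              c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  worst <- Inf
  for (a in 1:8) {
    p0 <- nd[el[, a], , drop = FALSE]
    e1 <- nd[el[, nb[a, 1]], , drop = FALSE] - p0
    e2 <- nd[el[, nb[a, 2]], , drop = FALSE] - p0
    e3 <- nd[el[, nb[a, 3]], , drop = FALSE] - p0
    det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
      e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
      e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    ## corner parity: odd corners have left-handed edge triples
    sgn <- if (a %in% c(1, 3, 6, 8)) 1 else 1
    sj <- det / (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)) * sqrt(rowSums(e3^2)))
    worst <- min(worst, sgn * sj)
  }
  worst
}

## --- point location (inverse trilinear map) ---------------------------------

hex_shape <- function(xi) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  N <- 0.125 * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3])
  dN <- cbind(0.125 * s[, 1] * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3]),
              0.125 * s[, 2] * (1 + s[, 1] * xi[1]) * (1 + s[, 3] * xi[3]),
              0.125 * s[, 3] * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]))
  list(N = N, dN = dN)
}

## locate points in a hex mesh; returns element index and local coordinates.
## tol_out: allowed excursion outside [-1,1] in local coordinates.
locate_points <- function(mesh, pts, tol_out = 1e-6, n_candidates = 12L) {
  pts <- matrix(pts, ncol = 3)
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 7], ]) / 2
  elem_out <- integer(nrow(pts))
  xi_out <- matrix(NA_real_, nrow(pts), 3)
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 + (cent[, 3] - p[3])^2
    cand <- order(d2)[seq_len(min(n_candidates, nrow(cent)))]
    best <- NULL; best_ex <- Inf
    for (e in cand) {
      X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
      xi <- c(0, 0, 0)
      for (it in 1:30) {
        sh <- hex_shape(xi)
        r <- as.numeric(crossprod(sh$N, X)) - p
        if (sqrt(sum(r^2)) < 1e-12) break
        J <- t(crossprod(sh$dN, X))  # J[i,j] = dx_i/dxi_j
        xi <- xi - tryCatch(solve(t(J), r), error = function(e2) r * 0)
        xi <- pmin(2, pmax(-2, xi))
      }
      ex <- max(abs(xi)) - 1
      if (ex < best_ex) { best_ex <- ex; best <- list(e = e, xi = xi) }
      if (ex <= tol_out) break
    }
    if (best_ex > tol_out)
      stopf("point %d (%.3f, %.3f, %.3f) lies outside the mesh", k, p[1], p[2], p[3])
    elem_out[k] <- best$e
    xi_out[k, ] <- best$xi
  }
  list(elem = elem_out, xi = xi_out)
}

## evaluate nodal fields (N x m) at located points
interp_at <- function(mesh, loc, vals) {
  vals <- as.matrix(vals)
  out <- matrix(0, length(loc$elem), ncol(vals))
  for (k in seq_along(loc$elem)) {
    sh <- hex_shape(loc$xi[k, ])
    out[k, ] <- as.numeric(crossprod(sh$N, vals[mesh$elems[loc$elem[k], ], , drop = FALSE]))
  }
  out
}

## --- writers (plain-text formats) -------------------------------------------

#' Write a volume mesh as legacy ASCII VTK
#'
#' Named per-node fields are emitted as POINT_DATA arrays, per-element vectors
#' of length E as CELL_DATA arrays.
#'
#' @param mesh a `volume_mesh`
#' @param path output file path (.vtk)
#' @param cell_data named list of per-element arrays
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cartimech mesh (units %s)", mesh$units),
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(format(mesh$nodes, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
  npe <- ncol(mesh$elems)
  writeLines(sprintf("CELLS %d %d", e, e * (npe + 1)), con)
  writeLines(apply(cbind(npe, mesh$elems - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  ctype <- if (mesh$elem_type == "hex8") 12L else 10L
  writeLines(as.character(rep(ctype, e)), con)
  if (length(mesh$fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(mesh$fields)) {
      f <- mesh$fields[[nm]]
      if (is.matrix(f) && ncol(f) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(format(f, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(f), digits = 10, trim = TRUE), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", e), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 10, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a triangulated surface as ASCII STL
#' @param surf a `surface_mesh`
#' @param path output file path (.stl)
#' @param name solid name embedded in the file
#' @export
write_stl <- function(surf, path, name = "cartimech") {
  v1 <- surf$nodes[surf$tris[, 1], , drop = FALSE]
  v2 <- surf$nodes[surf$tris[, 2], , drop = FALSE]
  v3 <- surf$nodes[surf$tris[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- pmax(sqrt(rowSums(nrm^2)), 1e-30)
  nrm <- nrm / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(surf$tris))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (v in list(v1[i, ], v2[i, ], v3[i, ]))
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
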