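#' Triangle mesh in millimetres
#'
#' The basic unit of geometry: a watertight triangle surface given as an
#' `n x 3` vertex matrix (mm) and an `m x 3` matrix of 1-based vertex
#' indices. Both the implant "environment" components and the mobile-bearing
#' "robot" are `tri_mesh` objects.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name label carried through printing and STL export.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d faces", x$name,
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0L) {
    b <- mesh_bounds(x)
    cat(sprintf(", bounds [%.2f %.2f %.2f]..[%.2f %.2f %.2f] mm",
                b[1, 1], b[1, 2], b[1, 3], b[2, 1], b[2, 2], b[2, 3]))
  }
  cat("\n")
  invisible(x)
}

#' Axis-aligned bounds of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return 2 x 3 matrix; first row the minimum corner, second the maximum.
#' @export
mesh_bounds <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedra about the origin; positive for
#' consistently outward-wound closed surfaces.
#' @param mesh a [tri_mesh()].
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(det3) / 6
}

#' Volume centroid of a closed mesh (mm)
#'
#' @param mesh a [tri_mesh()].
#' @return length-3 numeric vector. This is the "centre of mass" whose entry
#'   into the goal region defines a dislocation.
#' @export
mesh_centroid <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  v <- det3 / 6
  vol <- sum(v)
  if (abs(vol) < 1e-12) stop("mesh has (near) zero volume")
  colSums((v / 4) * (a + b + c)) / vol
}

# directed edge table, one row per half-edge
mesh_half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1], f[, 2], f[, 3]), to = c(f[, 2], f[, 3], f[, 1]))
}

#' Count boundary edges of a mesh
#'
#' A half-edge is a boundary edge when no opposite half-edge exists. A closed
#' (watertight, consistently wound) surface has zero boundary edges.
#' @param mesh a [tri_mesh()].
#' @export
mesh_boundary_edges <- function(mesh) {
  he <- mesh_half_edges(mesh)
  key <- paste(he[, 1], he[, 2])
  opp <- paste(he[, 2], he[, 1])
  sum(!(key %in% opp))
}

#' Is a mesh watertight?
#'
#' Requires zero boundary edges and every undirected edge shared by exactly
#' one pair of oppositely wound faces (a 2-manifold closed surface, possibly
#' with several closed components).
#' @param mesh a [tri_mesh()].
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  he <- mesh_half_edges(mesh)
  key <- paste(he[, 1], he[, 2])
  opp <- paste(he[, 2], he[, 1])
  if (any(duplicated(key))) return(FALSE)      # non-manifold fan
  all(key %in% opp)
}

#' Edge lengths of a mesh (mm)
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector, one entry per unique undirected edge.
#' @export
mesh_edge_lengths <- function(mesh) {
  he <- mesh_half_edges(mesh)
  und <- unique(cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2])))
  sqrt(rowSums((mesh$vertices[und[, 1], , drop = FALSE] -
                  mesh$vertices[und[, 2], , drop = FALSE])^2))
}

# smallest triangle area, used to reject degenerate faces from generators
mesh_min_face_area <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  min(sqrt(cx^2 + cy^2 + cz^2) / 2)
}

#' Concatenate meshes into one surface
#'
#' Each input keeps its own closed component; indices are offset. Used to
#' assemble the tibial component (plateau + dome + wall) into a single mesh.
#' @param meshes list of [tri_mesh()] objects.
#' @param name label for the result.
#' @export
mesh_concat <- function(meshes, name = "mesh") {
  vs <- lapply(meshes, `[[`, "vertices")
  fs <- lapply(meshes, `[[`, "faces")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  f <- do.call(rbind, Map(function(fm, o) fm + o, fs, off[-length(off)]))
  tri_mesh(do.call(rbind, vs), f, name = name)
}

#' Rigidly transform a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param pose a [pose()] applied to every vertex.
#' @export
mesh_transform <- function(mesh, pose) {
  mesh$vertices <- transform_points(pose, mesh$vertices)
  mesh
}

#' Translate a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param t length-3 translation (mm).
#' @export
mesh_translate <- function(mesh, t) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(t), "+")
  mesh
}

# flip winding so enclosed volume is positive
mesh_orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}
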