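#' Procedural cylinder mesh
#'
#' Generates a triangle mesh of a right circular cylinder along +z with its
#' base at the origin, the procedural analogue of running a circle of radius
#' `radius` with `n_segments` vertices along the axis. With caps the mesh is
#' a watertight solid (Euler characteristic 2); the lateral surface carries
#' smooth (radial) interpolated vertex normals, the cap centres axial ones,
#' which avoids the faceting artefacts of flat-shaded cylinders.
#'
#' @param radius,height cylinder dimensions in m.
#' @param n_segments number of vertices on the circumference (>= 3).
#' @param with_caps close the solid with top and bottom fans.
#' @return An object of class `mesh`: `vertices` (n x 3), `triangles`
#'   (m x 3, 1-based, outward counter-clockwise), `normals` (n x 3
#'   per-vertex).
#' @export
build_cylinder_mesh <- function(radius, height, n_segments = 64L,
                                with_caps = TRUE) {
  stopifnot(radius > 0, height > 0, n_segments >= 3)
  n <- as.integer(n_segments)
  a <- 2 * pi * (seq_len(n) - 1) / n
  ca <- cos(a); sa <- sin(a)
  vb <- cbind(radius * ca, radius * sa, 0)
  vt <- cbind(radius * ca, radius * sa, height)
  verts <- rbind(vb, vt)
  nrm <- rbind(cbind(ca, sa, 0), cbind(ca, sa, 0))
  i <- seq_len(n)
  j <- c(seq_len(n - 1) + 1L, 1L)            # next index around the ring
  # outward-facing lateral quads split into two triangles
  tris <- rbind(cbind(i, j, n + i),
                cbind(j, n + j, n + i))
  if (with_caps) {
    cb <- nrow(verts) + 1L                    # bottom centre
    ct <- nrow(verts) + 2L                    # top centre
    verts <- rbind(verts, c(0, 0, 0), c(0, 0, height))
    nrm <- rbind(nrm, c(0, 0, -1), c(0, 0, 1))
    tris <- rbind(tris,
                  cbind(j, i, cb),            # bottom, normal -z
                  cbind(n + i, n + j, ct))    # top, normal +z
  }
  structure(list(vertices = unname(verts), triangles = unname(tris),
                 normals = unname(nrm)),
            class = "mesh")
}

#' @export
print.mesh <- function(x, ...) {
  cat(sprintf("<mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Total triangle area of a mesh
#' @param mesh a `mesh`.
#' @return Summed triangle area in m^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Watertightness and consistency checks for a triangle mesh
#'
#' A closed orientable solid must have every edge shared by exactly two
#' triangles with opposite winding, no degenerate (zero-area) triangles, and
#' Euler characteristic `V - E + F = 2` for a genus-0 solid.
#'
#' @param mesh a `mesh`.
#' @return A list with `watertight`, `euler`, `min_triangle_area`.
#' @export
mesh_check <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  directed <- paste(edges[, 1], edges[, 2])
  # opposite winding: each directed edge must appear exactly once
  watertight <- all(cnt == 2) && !any(duplicated(directed))
  n_edges <- length(cnt)
  euler <- nrow(v) - n_edges + nrow(tr)
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  areas <- sqrt(cx^2 + cy^2 + cz^2) / 2
  list(watertight = watertight, euler = euler,
       min_triangle_area = min(areas))
}

#' Export a mesh as Wavefront OBJ or ASCII PLY
#'
#' @param mesh a `mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# pbrsim mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %.9g %.9g %.9g", mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3]), con)
  tr <- mesh$triangles
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     tr[, 1], tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                     mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]), con)
  tr <- mesh$triangles - 1L
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}
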