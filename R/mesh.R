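#' Triangle mesh in millimetre coordinates
#'
#' Container for a watertight triangle surface mesh. Vertices are physical
#' coordinates in mm; faces are 1-based vertex-index triples, consistently
#' oriented with outward normals. Meshes produced by the package pipeline
#' additionally carry their exact rectilinear-solid representation (see
#' [rect_solid()]), which the Boolean engine exploits for exact set
#' operations; meshes read from arbitrary STL files do not.
#'
#' @param vertices numeric matrix, n x 3, mm.
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @param provenance free-text label recording how the mesh was produced.
#' @param rect optional [rect_solid()] this mesh is the boundary of.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, provenance = "user", rect = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces,
         provenance = provenance, rect = rect),
    class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces [%s]\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  if (nrow(x$faces) > 0L) {
    bb <- mesh_bbox(x)
    cat(sprintf("  bbox  : [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    cat(sprintf("  volume: %.4f mm^3\n", mesh_volume(x)))
  } else {
    cat("  (empty mesh)\n")
  }
  invisible(x)
}

#' Is a mesh empty (no faces)?
#' @param mesh a [tri_mesh()].
#' @return logical.
#' @export
is_empty_mesh <- function(mesh) nrow(mesh$faces) == 0L

#' Axis-aligned bounding box of a mesh
#' @param mesh a [tri_mesh()].
#' @return 2 x 3 matrix, rows = (min, max), columns = x, y, z (mm).
#' @export
mesh_bbox <- function(mesh) {
  if (is_empty_mesh(mesh)) stop("empty mesh has no bounding box", call. = FALSE)
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume: one sixth of the sum of scalar triple products
#' of the face vertices. Positive for consistently outward-oriented meshes.
#'
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1L], , drop = FALSE]
  b <- v[mesh$faces[, 2L], , drop = FALSE]
  c_ <- v[mesh$faces[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
    a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
    a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det3) / 6
}

#' Check that a mesh bounds a solid (closed, consistently oriented)
#'
#' A surface encloses a well-defined volume when its boundary operator
#' vanishes: every directed edge (a, b) is balanced by an equal number of
#' opposite edges (b, a). This is the correct closedness criterion for
#' voxel-derived surfaces, where four faces may legitimately meet along one
#' undirected edge (two solid cells touching diagonally).
#'
#' @param mesh a [tri_mesh()].
#' @return logical; `TRUE` also for the empty mesh.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(TRUE)
  from <- c(f[, 1L], f[, 2L], f[, 3L])
  to <- c(f[, 2L], f[, 3L], f[, 1L])
  nv <- nrow(mesh$vertices)
  key_fwd <- (from - 1) * nv + to
  key_rev <- (to - 1) * nv + from
  tf <- table(key_fwd)
  tr <- table(key_rev)
  if (length(tf) != length(tr)) return(FALSE)
  tf <- tf[order(as.numeric(names(tf)))]
  tr <- tr[order(as.numeric(names(tr)))]
  identical(names(tf), names(tr)) && all(tf == tr)
}

stop_not_watertight <- function(mesh, what = "mesh") {
  if (!is_watertight(mesh))
    stop(sprintf("%s is not watertight (unbalanced boundary edges)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Translate a mesh
#' @param mesh a [tri_mesh()].
#' @param offset numeric length-3 translation in mm.
#' @return translated `tri_mesh`; an exact rectilinear representation, when
#'   present, is translated with it.
#' @export
translate_mesh <- function(mesh, offset) {
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3L)
  mesh$vertices <- sweep(mesh$vertices, 2L, offset, "+")
  if (!is.null(mesh$rect)) {
    mesh$rect$breaks <- lapply(1:3, function(a) mesh$rect$breaks[[a]] + offset[a])
  }
  mesh
}

#' Axis-aligned box mesh
#'
#' Convenience constructor for an axis-aligned cuboid; carries its exact
#' rectilinear representation so Booleans on boxes are exact.
#'
#' @param lower,upper numeric length-3 opposite corners in mm.
#' @return a `tri_mesh` (12 triangles).
#' @export
box_mesh <- function(lower = c(0, 0, 0), upper = c(1, 1, 1)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(upper <= lower)) stop("upper must exceed lower on all axes", call. = FALSE)
  rs <- rect_solid(list(c(lower[1], upper[1]),
                        c(lower[2], upper[2]),
                        c(lower[3], upper[3])),
                   array(TRUE, dim = c(1L, 1L, 1L)))
  rect_boundary_mesh(rs, provenance = "box")
}
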