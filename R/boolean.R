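#' Mesh Boolean operations
#'
#' Set operations on watertight meshes. When every operand carries its
#' exact rectilinear-solid representation (true for all meshes the
#' pipeline produces: thresholded HU classes, lattice cubes, boxes, and
#' previous Boolean results), the operation is performed exactly on the
#' merged breakpoint grid and the result is again exact. Otherwise the
#' operands are voxel-remeshed at a configurable resolution; such results
#' are flagged `"voxel-remeshed"` in their provenance and are approximate
#' to the voxel size.
#'
#' An empty intersection returns an explicit empty mesh
#' ([is_empty_mesh()] is `TRUE`).
#'
#' @param a,b watertight [tri_mesh()] objects.
#' @param meshes list of watertight [tri_mesh()] objects.
#' @param engine `"auto"` (exact when possible), `"exact"` (error if an
#'   operand has no rectilinear representation), or `"voxel"`.
#' @param voxel_spacing voxel size in mm for the voxel engine (default:
#'   1/128 of the largest bounding-box extent).
#' @return a watertight `tri_mesh`.
#' @name mesh_boolean
NULL

prepare_rects <- function(meshes, engine, voxel_spacing) {
  for (i in seq_along(meshes)) stop_not_watertight(meshes[[i]],
                                                   sprintf("operand %d", i))
  have_rect <- vapply(meshes, function(m) !is.null(m$rect), TRUE)
  if (engine == "exact" && !all(have_rect))
    stop("exact engine requires rectilinear operands", call. = FALSE)
  if (engine == "auto" && all(have_rect)) {
    return(list(rects = lapply(meshes, `[[`, "rect"), exact = TRUE))
  }
  # voxel-remesh fallback
  bbs <- lapply(meshes, mesh_bbox)
  ext <- max(vapply(bbs, function(b) max(b[2L, ] - b[1L, ]), 0))
  if (is.null(voxel_spacing)) voxel_spacing <- ext / 128
  rects <- lapply(meshes, function(m) {
    if (!is.null(m$rect)) return(m$rect)
    occ <- voxelize_occupancy(m, voxel_spacing, supersample = 2L)
    rect_from_mask(occ$data >= 0.5, occ$spacing, occ$origin)
  })
  list(rects = rects, exact = FALSE)
}

boolean_op <- function(meshes, op, engine, voxel_spacing) {
  pr <- prepare_rects(meshes, engine, voxel_spacing)
  rs <- rect_op_multi(pr$rects, op)
  prov <- sprintf("boolean-%s:%s", op,
                  if (pr$exact) "exact-rectilinear" else "voxel-remeshed")
  rect_boundary_mesh(rs, provenance = prov)
}

#' @rdname mesh_boolean
#' @export
boolean_intersection <- function(a, b, engine = c("auto", "exact", "voxel"),
                                 voxel_spacing = NULL) {
  engine <- match.arg(engine)
  boolean_op(list(a, b), "and", engine, voxel_spacing)
}

#' @rdname mesh_boolean
#' @export
boolean_union <- function(meshes, engine = c("auto", "exact", "voxel"),
                          voxel_spacing = NULL) {
  engine <- match.arg(engine)
  if (inherits(meshes, "tri_mesh")) meshes <- list(meshes)
  stopifnot(length(meshes) >= 1L)
  if (length(meshes) == 1L) return(meshes[[1L]])
  boolean_op(meshes, "or", engine, voxel_spacing)
}

#' @rdname mesh_boolean
#' @export
boolean_difference <- function(a, b, engine = c("auto", "exact", "voxel"),
                               voxel_spacing = NULL) {
  engine <- match.arg(engine)
  boolean_op(list(a, b), "diff", engine, voxel_spacing)
}
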