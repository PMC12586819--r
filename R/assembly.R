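#' Assembly plan for a part-solid nodule phantom
#'
#' Pairs each ground-glass class mesh with the lattice design that will
#' realise its radiodensity, alongside the solid core mesh that is printed
#' fully dense. [assemble_partsolid_nodule()] executes the plan.
#'
#' @param core_mesh watertight [tri_mesh()] of the solid core (printed
#'   gap-free), or `NULL` for a plan without a core.
#' @param bands named list; each element a list with `mesh` (the class
#'   [tri_mesh()]), `spec` (its [lattice_spec()]), and optionally
#'   `lattice` (a pre-built lattice [tri_mesh()]; it must fully cover the
#'   band mesh's bounding box, otherwise assembly fails).
#' @return an object of class `assembly_plan`.
#' @export
assembly_plan <- function(core_mesh, bands = list()) {
  if (is.null(core_mesh) && length(bands) == 0L)
    stop("plan needs a core or at least one band", call. = FALSE)
  if (!is.null(core_mesh)) stop_not_watertight(core_mesh, "core mesh")
  if (length(bands) && is.null(names(bands)))
    names(bands) <- paste0("band", seq_along(bands))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!inherits(b$spec, "lattice_spec"))
      stop(sprintf("band %s: spec is not a lattice_spec", nm), call. = FALSE)
    if (!is.null(b$mesh)) stop_not_watertight(b$mesh, sprintf("band %s", nm))
  }
  structure(list(core = core_mesh, bands = bands), class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("assembly_plan: %s core, %d band(s)\n",
              if (is.null(x$core)) "no" else "solid", length(x$bands)))
  for (nm in names(x$bands)) {
    b <- x$bands[[nm]]
    cat(sprintf("  %s: %s (fill %.4f)\n", nm, format(b$spec),
                fill_fraction(b$spec)))
  }
  invisible(x)
}

#' Assemble a printable multi-density nodule mesh
#'
#' Executes the Boolean pipeline: each ground-glass band mesh is
#' intersected with a lattice cube of its assigned design (built to cover
#' the band's bounding box plus a margin), the intersections are unioned
#' with the fully dense core, and a single watertight mesh is returned.
#' Bands whose class mesh is missing or empty are skipped with a message.
#' The manifest (attribute `"manifest"`) reports per-band and total
#' material volumes plus an estimated resin cost.
#'
#' @param plan an [assembly_plan()].
#' @param lattice_margin margin in mm by which each lattice cube exceeds
#'   its band's bounding box.
#' @param price_per_ml resin price per millilitre for the cost estimate.
#' @return a watertight [tri_mesh()] with attribute `"manifest"`.
#' @export
assemble_partsolid_nodule <- function(plan, lattice_margin = 1,
                                      price_per_ml = NULL) {
  stopifnot(inherits(plan, "assembly_plan"))
  if (is.null(price_per_ml))
    price_per_ml <- nodulefab_config()$resin_price_per_ml
  parts <- list()
  manifest <- list(bands = list())
  for (nm in names(plan$bands)) {
    b <- plan$bands[[nm]]
    if (is.null(b$mesh) || is_empty_mesh(b$mesh)) {
      message(sprintf("band %s: class absent, skipped", nm))
      next
    }
    bb <- mesh_bbox(b$mesh)
    if (!is.null(b$lattice)) {
      # user-supplied lattice cube for this band
      if (is.null(b$lattice$rect))
        stop(sprintf("band %s: supplied lattice lacks a rectilinear %s",
                     nm, "representation"), call. = FALSE)
      lat <- b$lattice$rect
    } else {
      side <- max(bb[2L, ] - bb[1L, ]) + 2 * lattice_margin
      p_mm <- b$spec$p_um / 1000
      if (side < 2 * p_mm) side <- 2 * p_mm
      lat_origin <- bb[1L, ] - lattice_margin
      lat <- tryCatch(
        lattice_rect(b$spec, side, origin = lat_origin),
        error = function(e) stop(sprintf("band %s: %s", nm,
                                         conditionMessage(e)),
                                 call. = FALSE))
    }
    if (is.null(b$mesh$rect))
      stop(sprintf(
        "band %s: mesh lacks a rectilinear representation; intersect it with ",
        nm), "boolean_intersection(engine = 'voxel') first", call. = FALSE)
    # coverage precondition: the lattice cube must contain the band bbox
    lat_bb <- vapply(lat$breaks, range, numeric(2L))
    if (any(lat_bb[1L, ] > bb[1L, ] + 1e-9) ||
        any(lat_bb[2L, ] < bb[2L, ] - 1e-9))
      stop(sprintf("band %s: lattice cube does not cover the band mesh", nm),
           call. = FALSE)
    inter <- rect_op(b$mesh$rect, lat, "and")
    band_vol <- rect_volume(b$mesh$rect)
    inter_vol <- rect_volume(inter)
    manifest$bands[[nm]] <- list(
      spec = format(b$spec),
      t_um = b$spec$t_um, g_um = b$spec$g_um,
      fill_fraction = fill_fraction(b$spec),
      band_volume_mm3 = band_vol,
      material_volume_mm3 = inter_vol)
    parts[[length(parts) + 1L]] <- inter
  }
  if (!is.null(plan$core)) {
    if (is.null(plan$core$rect))
      stop("core mesh lacks a rectilinear representation", call. = FALSE)
    parts[[length(parts) + 1L]] <- plan$core$rect
    manifest$core_volume_mm3 <- rect_volume(plan$core$rect)
  } else {
    manifest$core_volume_mm3 <- 0
  }
  if (!length(parts)) stop("nothing to assemble", call. = FALSE)
  assembled <- if (length(parts) == 1L) parts[[1L]] else
    rect_op_multi(parts, "or")
  mesh <- rect_boundary_mesh(assembled, provenance = "assembled-nodule")
  total <- rect_volume(assembled)
  manifest$total_material_mm3 <- total
  manifest$total_material_ml <- total / 1000
  manifest$estimated_cost <- total / 1000 * price_per_ml
  attr(mesh, "manifest") <- manifest
  mesh
}

#' Assembly manifest of an assembled mesh
#' @param mesh result of [assemble_partsolid_nodule()].
#' @return the manifest list (band volumes in mm^3, totals, cost).
#' @export
assembly_manifest <- function(mesh) attr(mesh, "manifest")
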