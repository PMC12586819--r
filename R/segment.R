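#' HU class specification
#'
#' One radiodensity band of the part-solid nodule model. The default bands
#' (see [default_hu_classes()]) tile `(-750, Inf)`: a solid core above
#' 0 HU and three ground-glass shells down to -750 HU, the lowest HU
#' observed in the patient nodules the phantom workflow targets; voxels
#' below -750 HU are background.
#'
#' @param name band label.
#' @param lower,upper HU bounds (`upper = Inf` allowed).
#' @param lower_open,upper_open whether each bound is exclusive.
#' @return an object of class `hu_class`.
#' @export
hu_class <- function(name, lower, upper, lower_open = TRUE,
                     upper_open = FALSE) {
  if (!is.finite(lower)) stop("lower bound must be finite", call. = FALSE)
  if (lower >= upper) stop("lower must be below upper", call. = FALSE)
  structure(list(name = as.character(name), lower = lower, upper = upper,
                 lower_open = isTRUE(lower_open),
                 upper_open = isTRUE(upper_open)),
            class = "hu_class")
}

#' Default nodule HU bands
#'
#' core: HU > 0; gg1: (-300, 0]; gg2: (-500, -300]; gg3: \[-750, -500\].
#' Closures make 0 and -750 assignable while keeping the bands disjoint.
#' Values live in the package configuration file, not in code.
#'
#' @return list of four [hu_class()] objects named core, gg1, gg2, gg3.
#' @export
default_hu_classes <- function() {
  cfg <- nodulefab_config()
  lapply(cfg$hu_classes, function(cl)
    hu_class(cl$name, cl$lower,
             if (is.null(cl$upper)) Inf else cl$upper,
             lower_open = cl$lower_open, upper_open = cl$upper_open))
}

in_class <- function(cl, hu) {
  lo <- if (cl$lower_open) hu > cl$lower else hu >= cl$lower
  hi <- if (cl$upper_open) hu < cl$upper else hu <= cl$upper
  lo & hi
}

classes_overlap <- function(classes) {
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i >= j) next
      a <- classes[[i]]; b <- classes[[j]]
      # closed-interval overlap with open-bound adjustment
      lo <- max(a$lower, b$lower); hi <- min(a$upper, b$upper)
      if (lo < hi) return(TRUE)
      if (lo == hi) {
        a_has <- in_class(a, lo); b_has <- in_class(b, lo)
        if (a_has && b_has) return(TRUE)
      }
    }
  }
  FALSE
}

#' Label volume container
#' @param labels integer 3-D array (0 = background, 1..K = classes).
#' @param spacing,origin as in [hu_volume()].
#' @param class_names character vector naming labels 1..K.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         class_names = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be 3-D", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (min(labels) < 0L)
    stop("labels must be non-negative", call. = FALSE)
  structure(list(labels = labels, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L),
                 class_names = class_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(factor(x$labels, levels = 0:length(x$class_names),
                      labels = c("background", x$class_names)))
  print(tab)
  invisible(x)
}

#' Threshold an HU volume into radiodensity classes
#'
#' Assigns each voxel the unique class whose HU interval contains it;
#' voxels matching no class (e.g. below -750 HU with the default bands) or
#' outside the mask are background (0).
#'
#' @param vol an [hu_volume()].
#' @param classes list of non-overlapping [hu_class()] objects.
#' @param mask optional logical array of the volume's shape.
#' @return a [label_volume()] with labels in class order.
#' @export
threshold_classes <- function(vol, classes = default_hu_classes(),
                              mask = NULL) {
  if (classes_overlap(classes))
    stop("class specifications overlap", call. = FALSE)
  if (!is.null(mask) && !identical(dim(mask), dim(vol$data)))
    stop("mask shape does not match volume", call. = FALSE)
  lab <- array(0L, dim = dim(vol$data))
  for (i in seq_along(classes)) {
    sel <- in_class(classes[[i]], vol$data)
    lab[sel] <- i
  }
  if (!is.null(mask)) lab[!mask] <- 0L
  label_volume(lab, vol$spacing, vol$origin,
               class_names = vapply(classes, `[[`, "", "name"))
}

#' Extract the surface mesh of one class
#'
#' Converts the binary mask of one label into a closed surface mesh by
#' exact voxel-boundary extraction: each voxel owns the axis-aligned cube
#' around its centre, and the mesh bounds the union of the class's voxel
#' cubes, so the enclosed volume equals voxel count x voxel volume exactly.
#'
#' @param labels a [label_volume()].
#' @param class class label: integer id or class name.
#' @return a [tri_mesh()] in mm coordinates (spacing and origin applied).
#' @export
class_mesh <- function(labels, class) {
  id <- class
  if (is.character(class)) {
    id <- match(class, labels$class_names)
    if (is.na(id)) stop("unknown class name: ", class, call. = FALSE)
  }
  mask <- labels$labels == id
  if (!any(mask))
    stop(sprintf("class %s is empty in this volume", as.character(class)),
         call. = FALSE)
  name <- if (!is.null(labels$class_names)) labels$class_names[id] else id
  rs <- rect_from_mask(mask, labels$spacing, labels$origin)
  rect_boundary_mesh(rs, provenance = sprintf("class:%s", name))
}

#' Mean and standard deviation of HU in a spherical or disc ROI
#'
#' Gathers voxels whose centres lie within `radius` of `center`. The
#' default ROI is a 3-D sphere; `mode = "disc"` confines it to a slab of
#' the given thickness around the centre's z, mirroring a per-slice
#' circular ROI. The SD is the population standard deviation over the ROI
#' voxels.
#'
#' @param vol an [hu_volume()].
#' @param center length-3 physical coordinates in mm.
#' @param radius ROI radius in mm.
#' @param mode `"sphere"` or `"disc"`.
#' @param thickness slab thickness in mm for disc mode (default: one voxel).
#' @return list with `mean`, `sd` (HU) and `n` (voxel count), class
#'   `roi_stats`.
#' @export
measure_roi_hu <- function(vol, center, radius, mode = c("sphere", "disc"),
                           thickness = NULL) {
  mode <- match.arg(mode)
  center <- rep_len(as.numeric(center), 3L)
  stopifnot(radius > 0)
  d <- dim(vol$data)
  cx <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1] - center[1]
  cy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2] - center[2]
  cz <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3] - center[3]
  # limit to the bounding sub-box before forming the distance field
  ix <- which(abs(cx) <= radius)
  iy <- which(abs(cy) <= radius)
  if (mode == "disc") {
    if (is.null(thickness)) thickness <- vol$spacing[3]
    iz <- which(abs(cz) <= thickness / 2)
  } else {
    iz <- which(abs(cz) <= radius)
  }
  if (!length(ix) || !length(iy) || !length(iz))
    stop("ROI does not intersect the volume", call. = FALSE)
  r2 <- outer(outer(cx[ix]^2, cy[iy]^2, "+"),
              if (mode == "disc") rep(0, length(iz)) else cz[iz]^2, "+")
  sel <- r2 <= radius^2
  vals <- vol$data[ix, iy, iz, drop = FALSE][sel]
  if (!length(vals)) stop("ROI contains no voxel centres", call. = FALSE)
  m <- mean(vals)
  structure(list(mean = m,
                 sd = sqrt(mean((vals - m)^2)),
                 n = length(vals)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI: mean %.1f HU, sd %.1f HU (n = %d voxels)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}
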