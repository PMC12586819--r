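#' HU volume container
#'
#' A 3-D array of Hounsfield units with physical voxel spacing and origin.
#' The origin is the physical position (mm) of the centre of voxel
#' `(1, 1, 1)`; voxel `(i, j, k)` is centred on `origin + (index - 1) *
#' spacing` and owns the cube of side `spacing` around its centre.
#'
#' @param data numeric 3-D array of HU values.
#' @param spacing numeric length-3 voxel size in mm (strictly positive).
#' @param origin numeric length-3, mm.
#' @param clamp clamp HU into the 12-bit CT range \[-1024, 3071\]? Keeps
#'   sentinel values out of downstream statistics.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(data, spacing, origin = c(0, 0, 0), clamp = TRUE) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on all axes", call. = FALSE)
  if (any(!is.finite(data))) stop("HU data must be finite", call. = FALSE)
  if (clamp) data <- pmin(pmax(data, -1024), 3071)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hu_volume: %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$data), max(x$data),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Apply the CT rescale transform
#'
#' Maps stored pixel values to HU via `HU = stored * slope + intercept`,
#' the standard CT calibration applied on load.
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale slope and intercept.
#' @return HU values.
#' @export
hu_rescale <- function(stored, slope = 1, intercept = 0) {
  stored * slope + intercept
}

#' Load an HU volume from NIfTI
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`), applies the stored scaling to
#' obtain calibrated HU, clamps to the 12-bit CT range, and optionally
#' crops to a region of interest given in voxel indices.
#'
#' @param path NIfTI file path.
#' @param roi optional crop: list with `lo` and `hi`, each length-3 1-based
#'   voxel indices, both inclusive.
#' @return an [hu_volume()]; cropping shifts the origin so physical
#'   coordinates are preserved.
#' @export
read_hu_volume <- function(path, roi = NULL) {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) stop("expected a 3-D volume", call. = FALSE)
  pd <- RNifti::pixdim(img)
  spacing <- rep_len(as.numeric(pd), 3L)
  vol <- hu_volume(data, spacing = spacing, origin = c(0, 0, 0))
  if (!is.null(roi)) vol <- crop_volume(vol, roi$lo, roi$hi)
  vol
}

#' Write an HU or label volume to NIfTI
#' @param vol an [hu_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- if (inherits(vol, "label_volume")) vol$labels else vol$data
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop a volume to a voxel-index box
#' @param vol an [hu_volume()].
#' @param lo,hi length-3 1-based voxel indices, inclusive.
#' @return cropped [hu_volume()] with shifted origin.
#' @export
crop_volume <- function(vol, lo, hi) {
  lo <- as.integer(rep_len(lo, 3L)); hi <- as.integer(rep_len(hi, 3L))
  d <- dim(vol$data)
  if (any(lo < 1L) || any(hi > d) || any(hi < lo))
    stop("crop region outside volume bounds", call. = FALSE)
  data <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  hu_volume(data, vol$spacing,
            origin = vol$origin + (lo - 1L) * vol$spacing, clamp = FALSE)
}

# 1-D linear interpolation weight matrix from input voxel centres to output
# voxel centres (replicate clamping at the edges); trilinear resampling is
# the separable application of three of these.
interp_matrix <- function(n_in, sp_in, n_out, sp_out) {
  # both grids share the same physical extent origin (extent convention:
  # the volume spans [c1 - sp/2, cn + sp/2])
  centers_out <- (seq_len(n_out) - 0.5) * sp_out  # from extent min
  f <- centers_out / sp_in + 0.5                  # fractional input index
  f <- pmin(pmax(f, 1), n_in)
  i0 <- pmin(floor(f), n_in - 1L); i0[n_in == 1] <- 1
  w <- f - i0
  W <- matrix(0, n_out, n_in)
  if (n_in == 1L) { W[, 1L] <- 1; return(W) }
  W[cbind(seq_len(n_out), i0)] <- 1 - w
  W[cbind(seq_len(n_out), i0 + 1L)] <- w
  W
}

apply_axis <- function(arr, W, axis) {
  # multiply along `axis` by W (n_out x n_in)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- W %*% matrix(a, nrow = d[1L])
  out <- array(m, dim = c(nrow(W), d[2L], d[3L]))
  aperm(out, order(perm))
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto an isotropic grid covering the same
#' physical extent; the output has `ceiling(extent / target)` voxels per
#' axis. Intensity (HU) volumes are interpolated trilinearly; use
#' [resample_labels()] for categorical volumes.
#'
#' @param vol an [hu_volume()].
#' @param target_spacing isotropic voxel size in mm (default 0.1).
#' @return resampled [hu_volume()].
#' @export
resample_isotropic <- function(vol, target_spacing = 0.1) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be a single positive number", call. = FALSE)
  d <- dim(vol$data)
  extent <- d * vol$spacing
  n_out <- as.integer(ceiling(extent / target_spacing - 1e-9))
  out <- vol$data
  for (ax in 1:3) {
    W <- interp_matrix(d[ax], vol$spacing[ax], n_out[ax], target_spacing)
    out <- apply_axis(out, W, ax)
  }
  # extent minimum is preserved; first output centre sits half a voxel in
  ext_min <- vol$origin - vol$spacing / 2
  hu_volume(out, spacing = rep(target_spacing, 3L),
            origin = ext_min + target_spacing / 2, clamp = FALSE)
}

#' Nearest-neighbour resampling for label volumes
#' @param labels a [label_volume()].
#' @param target_spacing isotropic voxel size in mm.
#' @return resampled [label_volume()].
#' @export
resample_labels <- function(labels, target_spacing = 0.1) {
  d <- dim(labels$labels)
  extent <- d * labels$spacing
  n_out <- as.integer(ceiling(extent / target_spacing - 1e-9))
  idx <- lapply(1:3, function(ax) {
    centers_out <- (seq_len(n_out[ax]) - 0.5) * target_spacing
    i <- round(centers_out / labels$spacing[ax] + 0.5)
    pmin(pmax(i, 1L), d[ax])
  })
  out <- labels$labels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  ext_min <- labels$origin - labels$spacing / 2
  label_volume(out, spacing = rep(target_spacing, 3L),
               origin = ext_min + target_spacing / 2,
               class_names = labels$class_names)
}
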