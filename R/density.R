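#' Partial-volume density model
#'
#' A CT voxel's HU is the volume-weighted average of the attenuation of
#' the materials it contains, and HU is affine in attenuation, so a
#' lattice with material fill fraction `f` images at
#' `HU(f) = f * hu_material + (1 - f) * hu_air`, with air fixed at
#' -1000 HU. `hu_material` is the effective HU of the fully dense cured
#' resin (configurable; fit it from calibration scans with
#' [fit_material_hu()]).
#'
#' @param hu_material effective HU of the dense print material.
#' @param hu_air HU of air, fixed at -1000 by the CT scale.
#' @return an object of class `pv_model`.
#' @export
partial_volume_model <- function(hu_material = NULL, hu_air = -1000) {
  if (is.null(hu_material)) hu_material <- nodulefab_config()$hu_material
  if (!is.finite(hu_material) || hu_material <= hu_air)
    stop("hu_material must exceed hu_air", call. = FALSE)
  structure(list(hu_material = hu_material, hu_air = hu_air),
            class = "pv_model")
}

#' @export
print.pv_model <- function(x, ...) {
  cat(sprintf("partial-volume model: HU(f) = %g + f * %g\n",
              x$hu_air, x$hu_material - x$hu_air))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted from %d calibration records, residual SD %.2f HU\n",
                x$fit$n, x$fit$sigma))
  }
  invisible(x)
}

#' @export
coef.pv_model <- function(object, ...) {
  c(hu_air = object$hu_air, hu_material = object$hu_material)
}

#' Predict HU from fill fraction
#'
#' @param model a [partial_volume_model()].
#' @param f fill fraction(s) in \[0, 1\].
#' @return predicted HU.
#' @export
predict_hu <- function(model, f) {
  stopifnot(inherits(model, "pv_model"))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("fill fraction must lie in [0, 1]", call. = FALSE)
  f * model$hu_material + (1 - f) * model$hu_air
}

#' @export
predict.pv_model <- function(object, f, ...) predict_hu(object, f)

#' @export
residuals.pv_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model was not fitted", call. = FALSE)
  object$fit$residuals
}

#' Fit the effective material HU from calibration measurements
#'
#' Least-squares fit of `hu_material` in
#' `mean_hu = -1000 + f * (hu_material + 1000)` over measured lattice
#' cubes, where `f` is each design's closed-form fill fraction. The model
#' is deliberately the ideal mixing law: systematic deviations of printed
#' cubes (trapped uncured resin at small voids, air gaps) surface in the
#' residuals rather than being absorbed into the model.
#'
#' @param records data frame with columns `t_um`, `g_um`, `mean_hu`
#'   (additional acquisition columns such as `kv`, `ctdi_mgy`,
#'   `algorithm`, `kernel`, `sd_hu` are carried through untouched).
#' @param spot_um printer spot size for design validation.
#' @param hu_air fixed air HU.
#' @return a [partial_volume_model()] with a `fit` element (residuals,
#'   residual SD, record count).
#' @export
fit_material_hu <- function(records, spot_um = 85, hu_air = -1000) {
  req <- c("t_um", "g_um", "mean_hu")
  if (!all(req %in% names(records)))
    stop("records need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(records) < 2L)
    stop("need at least two calibration records", call. = FALSE)
  f <- vapply(seq_len(nrow(records)), function(i)
    fill_fraction(lattice_spec(records$t_um[i], records$g_um[i], spot_um)),
    0)
  if (length(unique(round(f, 12))) < 2L)
    stop("calibration records share a single fill fraction; ",
         "hu_material is not identifiable", call. = FALSE)
  y <- records$mean_hu - hu_air
  slope <- sum(f * y) / sum(f * f)
  hu_material <- slope + hu_air
  res <- records$mean_hu - (hu_air + f * slope)
  m <- partial_volume_model(hu_material = hu_material, hu_air = hu_air)
  m$fit <- list(residuals = res,
                sigma = if (length(res) > 1L) stats::sd(res) else 0,
                n = nrow(records), fill = f)
  m
}

#' Read a calibration measurement table
#'
#' CSV schema: `t_um,g_um,kv,ctdi_mgy,algorithm,kernel,mean_hu,sd_hu`,
#' one row per design x acquisition/reconstruction condition.
#'
#' @param path CSV path.
#' @return data frame of calibration records.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("t_um", "g_um", "kv", "ctdi_mgy", "algorithm", "kernel",
           "mean_hu", "sd_hu")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("calibration CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$sd_hu < 0)) stop("sd_hu must be non-negative", call. = FALSE)
  df
}

#' Default lattice-visibility rules
#'
#' Above a void-size threshold the periodic print pattern becomes
#' discernible on CT and inflates ROI standard deviations, so such designs
#' are excluded from selection. Thresholds per beam thickness (and the
#' reconstruction kernels they were observed on) live in the package
#' configuration; the 510 µm threshold is interpolated between the two
#' observed anchors.
#'
#' @return data frame with columns `t_um`, `g_min_visible_um`,
#'   `kernel_scope`.
#' @export
default_visibility_rules <- function() {
  cfg <- nodulefab_config()
  do.call(rbind, lapply(cfg$visibility_rules, function(r)
    data.frame(t_um = as.numeric(r$t_um),
               g_min_visible_um = as.numeric(r$g_min_visible_um),
               kernel_scope = as.character(r$kernel_scope))))
}

#' Default band-to-design anchors
#'
#' The published part-solid nodule design assigns one lattice per HU band:
#' (-750, -500) -> t 340 / g 1020, (-500, -300) -> t 510 / g 850,
#' (-300, 0) -> t 680 / g 680. These assignments derive from measured HU
#' of printed cubes, which deviates from ideal partial-volume mixing
#' (trapped resin at small voids raises the apparent density), so they are
#' shipped as configuration anchors rather than recomputed from the ideal
#' model.
#'
#' @return data frame with columns `band`, `lower_hu`, `upper_hu`, `t_um`,
#'   `g_um`.
#' @export
default_band_anchors <- function() {
  cfg <- nodulefab_config()
  do.call(rbind, lapply(cfg$band_anchors, function(a)
    data.frame(band = a$band, lower_hu = as.numeric(a$lower_hu),
               upper_hu = as.numeric(a$upper_hu),
               t_um = as.numeric(a$t_um), g_um = as.numeric(a$g_um))))
}

rule_excludes <- function(rules, t_um, g_um) {
  if (is.null(rules) || nrow(rules) == 0L) return(FALSE)
  any(rules$t_um == t_um & g_um >= rules$g_min_visible_um)
}

#' Select a lattice design for a target HU range
#'
#' Returns the design whose calibrated or predicted HU best represents the
#' target band. When the band anchor table covers the requested range
#' (the default configuration anchors the three ground-glass bands of the
#' part-solid nodule design), the anchored design is returned. Otherwise
#' the design whose model-predicted HU lies nearest the target-range
#' midpoint is chosen among designs not excluded by the visibility rules,
#' with ties broken toward thicker beams (coarser beams print more
#' reliably).
#'
#' @param target length-2 numeric HU range (order irrelevant).
#' @param grid a [design_grid()].
#' @param model a [partial_volume_model()] for the fallback prediction.
#' @param rules visibility-rule data frame (see
#'   [default_visibility_rules()]); `NULL` disables exclusion.
#' @param anchors band anchor table (see [default_band_anchors()]);
#'   `NULL` forces model-based selection.
#' @return the selected [lattice_spec()].
#' @export
select_lattice <- function(target, grid = design_grid(),
                           model = partial_volume_model(),
                           rules = default_visibility_rules(),
                           anchors = default_band_anchors()) {
  stopifnot(length(target) == 2L, all(is.finite(target)))
  target <- sort(as.numeric(target))
  specs <- grid_specs(grid)
  if (length(specs) == 0L) stop("design grid is empty", call. = FALSE)
  if (!is.null(anchors) && nrow(anchors)) {
    hit <- which(abs(anchors$lower_hu - target[1L]) < 1e-6 &
                   abs(anchors$upper_hu - target[2L]) < 1e-6)
    if (length(hit)) {
      a <- anchors[hit[1L], ]
      in_grid <- vapply(specs, function(s)
        s$t_um == a$t_um && s$g_um == a$g_um, TRUE)
      if (any(in_grid) && !rule_excludes(rules, a$t_um, a$g_um))
        return(specs[[which(in_grid)[1L]]])
    }
  }
  feasible <- specs[!vapply(specs, function(s)
    rule_excludes(rules, s$t_um, s$g_um), TRUE)]
  if (!length(feasible))
    stop("no feasible design: all grid entries excluded by visibility rules",
         call. = FALSE)
  mid <- mean(target)
  pred <- vapply(feasible, function(s) predict_hu(model, fill_fraction(s)), 0)
  d <- abs(pred - mid)
  best <- which(d < min(d) + 1e-9)
  if (length(best) > 1L) {
    tvals <- vapply(feasible[best], `[[`, 0, "t_um")
    best <- best[which.max(tvals)]
  }
  feasible[[best[1L]]]
}

#' Occupancy (material fraction) volume of a mesh
#'
#' Computes the per-voxel material volume fraction of a watertight mesh.
#' Meshes that carry their exact rectilinear-solid representation (all
#' meshes the pipeline produces) are integrated exactly against the voxel
#' grid (`method = "exact"`). For general meshes, and always under
#' `method = "sampling"`, the fraction is estimated by supersampled
#' ray-parity classification: each voxel is probed on a `supersample^2`
#' grid of ray columns (jittered off any axis-aligned mesh plane), and
#' along each ray the inside intervals are integrated against the voxel
#' extents exactly, so the axial direction contributes no sampling error.
#' The sampling estimator is independent of the exact path, which makes
#' it usable as a volume oracle against closed-form expectations.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param spacing voxel size in mm.
#' @param supersample in-plane sub-samples per axis per voxel for the
#'   sampling path (>= 4 recommended).
#' @param method `"auto"` (exact when available), `"exact"`, or
#'   `"sampling"`.
#' @return an object of class `occ_volume`: list of `data` (fractions in
#'   \[0, 1\]), `spacing`, `origin` (centre of voxel (1,1,1), mm).
#' @export
voxelize_occupancy <- function(mesh, spacing, supersample = 4L,
                               method = c("auto", "exact", "sampling")) {
  method <- match.arg(method)
  stopifnot(spacing > 0, supersample >= 1L)
  stop_not_watertight(mesh)
  bb <- mesh_bbox(mesh)
  n <- pmax(1L, as.integer(ceiling((bb[2L, ] - bb[1L, ]) / spacing - 1e-9)))
  if (method == "exact" && is.null(mesh$rect))
    stop("mesh has no exact rectilinear representation", call. = FALSE)
  if (method != "sampling" && !is.null(mesh$rect))
    return(rect_voxelize(mesh$rect, spacing, bb, n))
  s <- as.integer(supersample)
  h <- spacing / s
  # low-discrepancy intra-cell offsets: keep each column inside its
  # sub-cell but break any commensurability between the column grid and
  # axis-aligned mesh planes (otherwise periodic geometry aliases)
  golden <- c(0.6180339887498949, 0.7548776662466927)
  cs <- lapply(1:2, function(a) {
    j <- seq_len(n[a] * s)
    off <- (j * golden[a]) %% 1 - 0.5
    bb[1L, a] + (j - 0.5) * h + off * h * 0.999
  })
  zb <- bb[1L, 3L] + (0:n[3L]) * spacing
  occ <- ray_parity_occupancy(mesh$vertices, mesh$faces,
                              cs[[1L]], cs[[2L]], zb, s, s)
  dim(occ) <- n
  structure(list(data = occ, spacing = rep(spacing, 3L),
                 origin = bb[1L, ] + spacing / 2),
            class = "occ_volume")
}

# Exact per-voxel occupancy of a rectilinear solid: separable 1-D overlap
# matrices between voxel intervals and solid cells, contracted against
# the occupancy array.
rect_voxelize <- function(rs, spacing, bb, n) {
  overlap_matrix <- function(vox_breaks, cell_breaks) {
    nv <- length(vox_breaks) - 1L
    nc <- length(cell_breaks) - 1L
    W <- matrix(0, nv, nc)
    for (i in seq_len(nv)) {
      lo <- pmax(vox_breaks[i], cell_breaks[-length(cell_breaks)])
      hi <- pmin(vox_breaks[i + 1L], cell_breaks[-1L])
      W[i, ] <- pmax(hi - lo, 0)
    }
    W
  }
  arr <- array(as.numeric(rs$occ), dim = dim(rs$occ))
  for (ax in 1:3) {
    vb <- bb[1L, ax] + (0:n[ax]) * spacing
    W <- overlap_matrix(vb, rs$breaks[[ax]])
    arr <- apply_axis(arr, W, ax)
  }
  arr <- pmin(pmax(arr / spacing^3, 0), 1)
  structure(list(data = arr, spacing = rep(spacing, 3L),
                 origin = bb[1L, ] + spacing / 2),
            class = "occ_volume")
}

#' @export
print.occ_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "occ_volume: %d x %d x %d voxels @ %.3g mm, mean occupancy %.4f\n",
    d[1], d[2], d[3], x$spacing[1], mean(x$data)))
  invisible(x)
}

# Separable Gaussian smoothing with edge-renormalised kernels.
gauss_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(arr)[ax]
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    arr <- apply_axis(arr, K, ax)
  }
  arr
}

#' Virtual-CT simulation of an occupancy volume
#'
#' Desk-scale stand-in for a CT acquisition of a printed object: converts
#' material occupancy to HU through the partial-volume model, applies an
#' isotropic Gaussian point-spread function, and adds i.i.d. Gaussian
#' noise. No beam hardening, scatter, or reconstruction-kernel modelling.
#'
#' @param occ an `occ_volume` from [voxelize_occupancy()].
#' @param model a [partial_volume_model()].
#' @param psf_sigma Gaussian PSF sigma in mm (0 disables blurring).
#' @param noise_sd noise standard deviation in HU (0 disables noise).
#' @param seed RNG seed for the noise (required when `noise_sd > 0`).
#' @return an [hu_volume()] on the occupancy grid.
#' @export
simulate_ct <- function(occ, model = partial_volume_model(),
                        psf_sigma = 0.6, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(occ, "occ_volume"), psf_sigma >= 0, noise_sd >= 0)
  hu <- model$hu_air + occ$data * (model$hu_material - model$hu_air)
  if (psf_sigma > 0) hu <- gauss_smooth(hu, psf_sigma / occ$spacing)
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required when noise_sd > 0", call. = FALSE)
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = noise_sd)
  }
  hu_volume(array(hu, dim = dim(occ$data)), occ$spacing, occ$origin,
            clamp = FALSE)
}

#' Lattice visibility score on a CT-like volume
#'
#' Quantifies whether the periodic print pattern is discernible: the score
#' is the ROI coefficient of spatial variation (SD divided by the mean
#' contrast above air) plus the mean over axes of the normalised spectral
#' amplitude at the lattice frequency `1/p`. A constant volume scores 0;
#' an unblurred lattice rendering scores far above 1 because its
#' occupancy alternates between air and material at exactly that
#' frequency.
#'
#' @param vol an [hu_volume()] (typically from [simulate_ct()]).
#' @param spec the [lattice_spec()] whose period sets the probe frequency.
#' @param roi optional crop (list `lo`, `hi` of voxel indices, inclusive)
#'   restricting the analysis; must span at least three lattice periods
#'   per axis.
#' @param threshold visibility threshold on the score (default from
#'   configuration).
#' @return list with `score`, `visible`, and the two components `cv` and
#'   `spectral`.
#' @export
lattice_visibility_score <- function(vol, spec, roi = NULL,
                                     threshold = NULL) {
  if (is.null(threshold)) threshold <- nodulefab_config()$visibility_threshold
  x <- if (is.null(roi)) vol$data else
    vol$data[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3],
             drop = FALSE]
  p_mm <- spec$p_um / 1000
  ext <- dim(x) * vol$spacing
  if (any(ext < 3 * p_mm))
    stop("ROI must span at least three lattice periods per axis",
         call. = FALSE)
  contrast <- max(mean(x) + 1000, 1)
  cv <- stats::sd(as.vector(x)) / contrast
  spec_amp <- vapply(1:3, function(ax) {
    prof <- apply(x, ax, mean)
    n <- length(prof)
    cyc <- ext[ax] / p_mm                 # lattice cycles across the ROI
    bin <- max(2L, min(n, round(cyc) + 1L))
    a <- Mod(stats::fft(prof - mean(prof)))
    2 * a[bin] / (n * contrast)
  }, 0)
  score <- cv + mean(spec_amp)
  list(score = score, visible = score >= threshold,
       cv = cv, spectral = mean(spec_amp))
}
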