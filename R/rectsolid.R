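#' Rectilinear solid
#'
#' Exact representation of an axis-aligned cell complex: three ascending
#' breakpoint vectors define a (generally non-uniform) rectilinear grid, and
#' a logical array marks which cells are material. All meshes the pipeline
#' produces (thresholded HU classes, beam lattices, Boolean results) are
#' boundaries of such solids, which makes volumes and Boolean set operations
#' exact: two rectilinear solids are merged onto the union of their
#' breakpoints, where every cell lies entirely inside or outside each
#' operand.
#'
#' @param breaks list of three strictly increasing numeric vectors (mm).
#' @param occ logical array with `dim = lengths(breaks) - 1`.
#' @return an object of class `rect_solid`.
#' @export
rect_solid <- function(breaks, occ) {
  stopifnot(is.list(breaks), length(breaks) == 3L)
  breaks <- lapply(breaks, as.numeric)
  for (b in breaks) {
    if (length(b) < 2L || any(diff(b) <= 0))
      stop("breaks must be strictly increasing with >= 2 entries", call. = FALSE)
  }
  occ <- array(as.logical(occ), dim = dim(occ))
  if (!identical(dim(occ), as.integer(lengths(breaks) - 1L)))
    stop("occupancy dimensions do not match breaks", call. = FALSE)
  structure(list(breaks = breaks, occ = occ), class = "rect_solid")
}

#' @export
print.rect_solid <- function(x, ...) {
  cat(sprintf("rect_solid: %d x %d x %d cells, %d material, volume %.4f mm^3\n",
              dim(x$occ)[1], dim(x$occ)[2], dim(x$occ)[3],
              sum(x$occ), rect_volume(x)))
  invisible(x)
}

#' Exact material volume of a rectilinear solid
#' @param rs a [rect_solid()].
#' @return volume in mm^3.
#' @export
rect_volume <- function(rs) {
  dx <- diff(rs$breaks[[1L]])
  dy <- diff(rs$breaks[[2L]])
  dz <- diff(rs$breaks[[3L]])
  dxy <- outer(dx, dy)
  v <- 0
  for (k in seq_along(dz)) v <- v + dz[k] * sum(dxy[rs$occ[, , k]])
  v
}

# Material membership of physical points (cell lookup; boundary points
# belong to the cell on their + side, points beyond the grid are outside).
rect_point_in <- function(rs, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  idx <- lapply(1:3, function(a) findInterval(pts[, a], rs$breaks[[a]]))
  nd <- dim(rs$occ)
  ok <- idx[[1L]] >= 1L & idx[[1L]] <= nd[1L] &
    idx[[2L]] >= 1L & idx[[2L]] <= nd[2L] &
    idx[[3L]] >= 1L & idx[[3L]] <= nd[3L]
  out <- logical(nrow(pts))
  if (any(ok))
    out[ok] <- rs$occ[cbind(idx[[1L]][ok], idx[[2L]][ok], idx[[3L]][ok])]
  out
}

# Collapse breakpoints closer than tol (absorbs floating-point near-dupes
# when merging grids from different origins).
dedupe_breaks <- function(b, tol) {
  b <- sort(b)
  keep <- c(TRUE, diff(b) > tol)
  b[keep]
}

# Boolean combination of rectilinear solids on their merged breakpoint grid.
# op: "and", "or", "diff" (a minus b).
rect_op <- function(a, b, op = c("and", "or", "diff")) {
  op <- match.arg(op)
  rect_op_multi(list(a, b), op)
}

# n-ary version; for "diff" the first solid minus the union of the rest.
rect_op_multi <- function(solids, op = c("and", "or", "diff")) {
  op <- match.arg(op)
  stopifnot(length(solids) >= 1L)
  if (length(solids) == 1L) return(solids[[1L]])
  scale <- max(unlist(lapply(solids, function(s) lapply(s$breaks, range))))
  tol <- max(1e-9, abs(scale) * 1e-12)
  breaks <- vector("list", 3L)
  for (ax in 1:3) {
    all_b <- unlist(lapply(solids, function(s) s$breaks[[ax]]))
    rng <- switch(op,
      and = c(max(vapply(solids, function(s) min(s$breaks[[ax]]), 0)),
              min(vapply(solids, function(s) max(s$breaks[[ax]]), 0))),
      c(min(all_b), max(all_b)))
    if (op == "and" && rng[2L] - rng[1L] <= tol) {
      # disjoint supports: empty result on a token cell
      return(rect_solid(lapply(1:3, function(i) c(0, tol * 2 + 1e-6)),
                        array(FALSE, dim = c(1L, 1L, 1L))))
    }
    b <- dedupe_breaks(c(all_b, rng), tol)
    breaks[[ax]] <- b[b >= rng[1L] - tol & b <= rng[2L] + tol]
  }
  mids <- lapply(breaks, function(b) (b[-1L] + b[-length(b)]) / 2)
  nd <- lengths(mids)
  # per-operand membership evaluated separably per axis where possible is
  # not valid in general, so classify the full cell-centre grid per operand
  pts_x <- rep(mids[[1L]], times = nd[2L] * nd[3L])
  pts_y <- rep(rep(mids[[2L]], each = nd[1L]), times = nd[3L])
  pts_z <- rep(mids[[3L]], each = nd[1L] * nd[2L])
  pts <- cbind(pts_x, pts_y, pts_z)
  memb <- lapply(solids, rect_point_in, pts = pts)
  acc <- memb[[1L]]
  for (i in seq_along(memb)[-1L]) {
    acc <- switch(op,
      and = acc & memb[[i]],
      or = acc | memb[[i]],
      diff = acc & !memb[[i]])
  }
  rect_solid(breaks, array(acc, dim = nd))
}

#' Rectilinear solid from a voxel mask
#'
#' Voxel `(i, j, k)` is treated as the axis-aligned cell centred on
#' `origin + (index - 1) * spacing` with side lengths `spacing`, so the
#' solid's volume is exactly the voxel count times the voxel volume.
#'
#' @param mask logical 3-D array.
#' @param spacing numeric length-3 voxel size in mm.
#' @param origin physical position of voxel (1,1,1) centre in mm.
#' @return a [rect_solid()].
#' @export
rect_from_mask <- function(mask, spacing, origin = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  nd <- dim(mask)
  breaks <- lapply(1:3, function(a)
    origin[a] - spacing[a] / 2 + spacing[a] * (0:nd[a]))
  rect_solid(breaks, mask)
}

#' Boundary surface mesh of a rectilinear solid
#'
#' Emits one outward-oriented quad (two triangles) per grid face separating
#' a material cell from a non-material cell or from the outside. The mesh is
#' closed by construction and its divergence-theorem volume equals
#' [rect_volume()] exactly.
#'
#' @param rs a [rect_solid()].
#' @param provenance provenance label for the resulting [tri_mesh()].
#' @return a `tri_mesh` carrying `rs` as its exact representation.
#' @export
rect_boundary_mesh <- function(rs, provenance = "rectilinear-boundary") {
  nd <- dim(rs$occ)
  xb <- rs$breaks[[1L]]; yb <- rs$breaks[[2L]]; zb <- rs$breaks[[3L]]
  nvx <- nd[1L] + 1L; nvy <- nd[2L] + 1L; nvz <- nd[3L] + 1L
  vid <- function(i, j, k) i + nvx * ((j - 1L) + nvy * (k - 1L))

  tris <- vector("list", 6L)
  pad <- function(occ, axis) {
    # pad with FALSE on both ends of `axis`
    nd2 <- dim(occ); nd2[axis] <- nd2[axis] + 2L
    out <- array(FALSE, dim = nd2)
    idx <- lapply(seq_len(3L), function(a) seq_len(dim(occ)[a]))
    idx[[axis]] <- idx[[axis]] + 1L
    out[idx[[1L]], idx[[2L]], idx[[3L]]] <- occ
    out
  }
  ti <- 1L
  for (axis in 1:3) {
    p <- pad(rs$occ, axis)
    n_ax <- nd[axis]
    left_idx <- lapply(1:3, function(a) seq_len(if (a == axis) n_ax + 1L else nd[a]))
    right_idx <- left_idx
    left_idx[[axis]] <- left_idx[[axis]]        # cells 0..n (padded index 1..n+1)
    right_idx[[axis]] <- right_idx[[axis]] + 1L # cells 1..n+1 (padded 2..n+2)
    L <- p[left_idx[[1L]], left_idx[[2L]], left_idx[[3L]], drop = FALSE]
    R <- p[right_idx[[1L]], right_idx[[2L]], right_idx[[3L]], drop = FALSE]
    plus <- which(L & !R, arr.ind = TRUE)   # outward normal +axis at break index[axis]
    minus <- which(!L & R, arr.ind = TRUE)  # outward normal -axis
    for (sgn in c(1L, -1L)) {
      w <- if (sgn == 1L) plus else minus
      if (nrow(w) == 0L) { ti <- ti + 1L; next }
      i <- w[, 1L]; j <- w[, 2L]; k <- w[, 3L]
      # face lies at break position along `axis`; spans one cell on the others
      if (axis == 1L) {
        A <- vid(i, j, k);      B <- vid(i, j + 1L, k)
        C <- vid(i, j + 1L, k + 1L); D <- vid(i, j, k + 1L)
      } else if (axis == 2L) {
        A <- vid(i, j, k);      B <- vid(i, j, k + 1L)
        C <- vid(i + 1L, j, k + 1L); D <- vid(i + 1L, j, k)
      } else {
        A <- vid(i, j, k);      B <- vid(i + 1L, j, k)
        C <- vid(i + 1L, j + 1L, k); D <- vid(i, j + 1L, k)
      }
      tris[[ti]] <- if (sgn == 1L)
        rbind(cbind(A, B, C), cbind(A, C, D))
      else
        rbind(cbind(A, C, B), cbind(A, D, C))
      ti <- ti + 1L
    }
  }
  fmat <- do.call(rbind, tris[!vapply(tris, is.null, TRUE)])
  if (is.null(fmat) || nrow(fmat) == 0L) {
    return(tri_mesh(matrix(numeric(0), ncol = 3L),
                    matrix(integer(0), ncol = 3L),
                    provenance = provenance, rect = rs))
  }
  used <- sort(unique(as.vector(fmat)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  fmat2 <- matrix(remap[fmat], ncol = 3L)
  u0 <- used - 1L
  gi <- u0 %% nvx + 1L
  gj <- (u0 %/% nvx) %% nvy + 1L
  gk <- u0 %/% (nvx * nvy) + 1L
  verts <- cbind(xb[gi], yb[gj], zb[gk])
  tri_mesh(verts, fmat2, provenance = provenance, rect = rs)
}
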