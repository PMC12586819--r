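#' Beam-lattice specification
#'
#' A cubic beam lattice is three orthogonal families of square-section
#' beams (section `t x t` µm) laid on a common grid of period
#' `p = t + g` µm, where `g` is the void side length. Printed in a single
#' dense resin, the lattice's material fill fraction sets the apparent CT
#' density through the partial-volume effect. All lengths must be integer
#' multiples of the printer spot size (85 µm by default): the printer
#' cannot realise finer lateral features.
#'
#' @param t_um beam (material) thickness in µm; positive multiple of
#'   `spot_um`.
#' @param g_um void side length in µm; non-negative multiple of `spot_um`
#'   (0 gives a solid cube).
#' @param spot_um printer spot size in µm.
#' @return an object of class `lattice_spec` with fields `t_um`, `g_um`,
#'   `spot_um`, `p_um` (period).
#' @export
lattice_spec <- function(t_um, g_um, spot_um = 85) {
  check_spot_multiple(c(t = t_um, g = g_um), spot_um)
  if (t_um <= 0) stop("beam thickness must be positive", call. = FALSE)
  if (g_um < 0) stop("void side length must be non-negative", call. = FALSE)
  structure(list(t_um = t_um, g_um = g_um, spot_um = spot_um,
                 p_um = t_um + g_um),
            class = "lattice_spec")
}

check_spot_multiple <- function(x, spot_um) {
  r <- x / spot_um
  bad <- abs(r - round(r)) > 1e-9
  if (any(bad))
    stop(sprintf("not a multiple of the %g um spot size: %s",
                 spot_um,
                 paste(sprintf("%s=%g", names(x)[bad], x[bad]),
                       collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "lattice_spec: t = %g um, g = %g um (period %g um, fill %.4f)\n",
    x$t_um, x$g_um, x$p_um, fill_fraction(x)))
  invisible(x)
}

#' @export
format.lattice_spec <- function(x, ...) sprintf("t%g_g%g", x$t_um, x$g_um)

#' Material fill fraction of a beam lattice
#'
#' For beam-width ratio `r = t / (t + g)`, the union of the three
#' orthogonal beam families occupies `f = 3 r^2 - 2 r^3` of the unit cell
#' (inclusion-exclusion: a point is material when at least two of its
#' three axis coordinates fall in beam phase). `g = 0` gives a solid cube
#' (`f = 1`).
#'
#' @param spec a [lattice_spec()].
#' @return fill fraction in (0, 1].
#' @export
fill_fraction <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  r <- spec$t_um / spec$p_um
  3 * r^2 - 2 * r^3
}

#' Calibration design grid
#'
#' Cartesian product of beam thicknesses and void side lengths in
#' deterministic order (thickness-major, voids ascending). The defaults
#' are read from the package configuration and enumerate the 18 cubic
#' calibration samples of the phantom workflow.
#'
#' @param thicknesses_um beam thicknesses in µm.
#' @param voids_um void side lengths in µm.
#' @param spot_um printer spot size in µm.
#' @return an object of class `design_grid`: a data frame with columns
#'   `t_um`, `g_um`, `p_um`, `fill`, plus the spec list as attribute
#'   `"specs"`.
#' @export
design_grid <- function(thicknesses_um = NULL, voids_um = NULL,
                        spot_um = NULL) {
  cfg <- nodulefab_config()
  if (is.null(thicknesses_um)) thicknesses_um <- cfg$thicknesses_um
  if (is.null(voids_um)) voids_um <- cfg$voids_um
  if (is.null(spot_um)) spot_um <- cfg$spot_um
  check_spot_multiple(stats::setNames(thicknesses_um,
                                      paste0("t", thicknesses_um)), spot_um)
  check_spot_multiple(stats::setNames(voids_um,
                                      paste0("g", voids_um)), spot_um)
  if (anyDuplicated(thicknesses_um) || anyDuplicated(voids_um))
    stop("duplicate design entries", call. = FALSE)
  voids_um <- sort(voids_um)
  specs <- list()
  for (t in thicknesses_um)
    for (g in voids_um)
      specs[[length(specs) + 1L]] <- lattice_spec(t, g, spot_um)
  df <- data.frame(
    t_um = vapply(specs, `[[`, 0, "t_um"),
    g_um = vapply(specs, `[[`, 0, "g_um"),
    p_um = vapply(specs, `[[`, 0, "p_um"),
    fill = vapply(specs, fill_fraction, 0))
  structure(df, specs = specs, class = c("design_grid", "data.frame"))
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("design_grid: %d lattice specifications\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Specs of a design grid as a list
#' @param grid a [design_grid()].
#' @return list of [lattice_spec()].
#' @export
grid_specs <- function(grid) attr(grid, "specs")

# 1-D beam interval set on [0, side] for phase `phi`: beams occupy
# [phi + k p, phi + k p + t] (mm). Returns matrix of (start, end).
beam_intervals <- function(t, p, side, phi) {
  k_lo <- floor((-phi - t) / p) - 1
  k_hi <- ceiling((side - phi) / p) + 1
  starts <- phi + (k_lo:k_hi) * p
  ends <- starts + t
  s <- pmax(starts, 0); e <- pmin(ends, side)
  keep <- e > s + 1e-12
  cbind(s[keep], e[keep])
}

beam_measure <- function(t, p, side, phi) {
  iv <- beam_intervals(t, p, side, phi)
  if (nrow(iv) == 0L) 0 else sum(iv[, 2L] - iv[, 1L])
}

# Phase that makes the clipped 1-D beam fraction equal t/p exactly, so the
# trimmed cube preserves the nominal fill fraction (the in-beam measure is
# continuous and periodic in the phase with mean r * side, so a root
# always exists).
solve_beam_phase <- function(t, p, side) {
  target <- side * t / p
  f <- function(phi) beam_measure(t, p, side, phi) - target
  phis <- seq(0, p, length.out = 257L)
  vals <- vapply(phis, f, 0)
  if (all(abs(vals) < 1e-9)) return(0)
  s <- which(vals[-length(vals)] * vals[-1L] <= 0)[1L]
  if (is.na(s)) return(phis[which.min(abs(vals))])
  stats::uniroot(f, c(phis[s], phis[s + 1L]), tol = 1e-12)$root
}

#' Build the watertight mesh of a beam-lattice cube
#'
#' Generates the union of three orthogonal square-section beam families
#' trimmed to a cube of the given side. Trimming clips beams at the cube
#' boundary so the outer faces are closed (printable), and the beam phase
#' is chosen so that the clipped per-axis material fraction equals
#' `t / p` exactly, making the enclosed volume equal
#' `fill_fraction(spec) * side^3` up to floating-point error. The lattice
#' is an exact rectilinear solid, so the mesh is watertight by
#' construction.
#'
#' @param spec a [lattice_spec()].
#' @param side_mm cube side in mm; must be at least two lattice periods.
#' @param origin mm position of the cube's minimum corner.
#' @return a [tri_mesh()] carrying its exact rectilinear representation.
#' @export
build_lattice_mesh <- function(spec, side_mm = 10, origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "lattice_spec"))
  rs <- lattice_rect(spec, side_mm, origin)
  rect_boundary_mesh(rs, provenance = sprintf("lattice:%s",
                                              format(spec)))
}

# Rectilinear-solid representation of a lattice cube.
lattice_rect <- function(spec, side_mm, origin = c(0, 0, 0)) {
  origin <- rep_len(as.numeric(origin), 3L)
  t <- spec$t_um / 1000; p <- spec$p_um / 1000
  if (spec$g_um == 0) {
    rs <- rect_solid(lapply(origin, function(o) c(o, o + side_mm)),
                     array(TRUE, dim = c(1L, 1L, 1L)))
    return(rs)
  }
  if (side_mm < 2 * p)
    stop(sprintf("cube side %.3f mm is below two lattice periods (%.3f mm)",
                 side_mm, 2 * p), call. = FALSE)
  phi <- solve_beam_phase(t, p, side_mm)
  iv <- beam_intervals(t, p, side_mm, phi)
  brk <- sort(unique(c(0, side_mm, as.vector(iv))))
  brk <- brk[c(TRUE, diff(brk) > 1e-12)]
  mids <- (brk[-1L] + brk[-length(brk)]) / 2
  in_beam <- vapply(mids, function(m) any(m >= iv[, 1L] & m <= iv[, 2L]),
                    TRUE)
  n <- length(mids)
  bx <- array(in_beam, dim = c(n, n, n))
  by <- aperm(bx, c(2L, 1L, 3L))
  bz <- aperm(bx, c(3L, 2L, 1L))
  occ <- (bx & by) | (bx & bz) | (by & bz)
  rect_solid(lapply(origin, function(o) brk + o), occ)
}
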