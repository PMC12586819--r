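#' Write a mesh to STL
#'
#' Binary (default) or ASCII stereolithography export. STL itself carries no
#' units; all geometry in this package is in mm, which is what slicers
#' assume. Binary output is byte-deterministic for identical input meshes.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param mode `"binary"` or `"ascii"`.
#' @param name solid name recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii"),
                      name = "nodulefab") {
  mode <- match.arg(mode)
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  n <- nrow(f)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("nodulefab binary STL:", name)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    if (n > 0L) {
      # 12 floats per facet, then a zero attribute byte count
      block <- rbind(t(nrm), t(a), t(b), t(c_))
      dat <- as.vector(block)
      raw_f <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
      raw_m <- matrix(raw_f, nrow = 48L)
      attr_bytes <- matrix(as.raw(0L), nrow = 2L, ncol = n)
      writeBin(as.vector(rbind(raw_m, attr_bytes)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    if (n > 0L) {
      txt <- sprintf(
        paste0("facet normal %.9e %.9e %.9e\n outer loop\n",
               "  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n",
               "  vertex %.9e %.9e %.9e\n endloop\nendfacet"),
        nrm[, 1L], nrm[, 2L], nrm[, 3L],
        a[, 1L], a[, 2L], a[, 3L],
        b[, 1L], b[, 2L], b[, 3L],
        c_[, 1L], c_[, 2L], c_[, 3L])
      writeLines(txt, con)
    }
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' Read a mesh from STL
#'
#' Reads binary or ASCII STL (auto-detected) and reconstructs shared
#' topology by welding exactly coincident vertices. Coordinates in binary
#' files are IEEE float32, so a write/read round trip preserves geometry to
#' float32 precision.
#'
#' @param path STL file path.
#' @return a [tri_mesh()] (provenance `"stl:<path>"`; no exact rectilinear
#'   representation, so Booleans on it use the voxel-remesh engine).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("cannot read STL: ", path, call. = FALSE)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84L, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84L) {
    n <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (n >= 0 && sz == 84 + 50 * as.numeric(n)) is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    n <- readBin(con, "integer", size = 4L, endian = "little")
    if (n == 0L) return(tri_mesh(matrix(numeric(0), ncol = 3L),
                                 matrix(integer(0), ncol = 3L),
                                 provenance = paste0("stl:", path)))
    body <- readBin(con, "raw", n = 50L * n)
    if (length(body) < 50L * n)
      stop(sprintf("malformed binary STL %s: truncated at byte %d",
                   path, 84L + length(body)), call. = FALSE)
    bm <- matrix(body, nrow = 50L)
    floats <- readBin(as.vector(bm[1:48, , drop = FALSE]), "numeric",
                      n = 12L * n, size = 4L, endian = "little")
    fm <- matrix(floats, nrow = 12L)
    tri <- rbind(t(fm[4:6, , drop = FALSE]),
                 t(fm[7:9, , drop = FALSE]),
                 t(fm[10:12, , drop = FALSE]))
    ord <- as.vector(t(matrix(seq_len(3L * n), nrow = n)))
    tri <- tri[ord, , drop = FALSE]  # interleave to v1,v2,v3 per facet
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop(sprintf("malformed ASCII STL %s: %d vertex lines (byte offset n/a)",
                   path, length(vlines)), call. = FALSE)
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(p)
      as.numeric(p[2:4]))
    tri <- do.call(rbind, nums)
    if (anyNA(tri)) stop("malformed ASCII STL: non-numeric vertex", call. = FALSE)
  }
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "|")
  uid <- match(key, key)
  uniq <- !duplicated(key)
  verts <- tri[uniq, , drop = FALSE]
  remap <- match(key[uniq], key)
  idx <- match(uid, remap)
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces, provenance = paste0("stl:", path))
}
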