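#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected). STL stores each triangle with
#' its own three vertex records, so shared vertices are welded on import.
#'
#' @param path STL file path.
#' @param weld_tol weld tolerance in mm (default 1e-6).
#' @return a [tri_surface()].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("malformed STL (file too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(84, size))
  is_binary <- FALSE
  if (size >= 84) {
    n_tri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(n_tri) && n_tri >= 0 && size == 84 + 50 * as.numeric(n_tri))
      is_binary <- TRUE
  }
  if (is_binary) {
    n_tri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (n_tri == 0L) stop("empty mesh in ", path)
    rec <- readBin(con, "raw", n = 50 * n_tri)
    # 50-byte records: 12 float32 then uint16 attribute
    idx <- rep(seq(0L, 50L * (n_tri - 1L), by = 50L), each = 48L) +
      rep(1:48, times = n_tri)
    vals <- readBin(rec[idx], "double", size = 4, n = 12L * n_tri,
                    endian = "little")
    m <- matrix(vals, ncol = 12L, byrow = TRUE)
    verts <- rbind_interleave(m[, 4:6, drop = FALSE],
                              m[, 7:9, drop = FALSE],
                              m[, 10:12, drop = FALSE])
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L)
      stop(sprintf("malformed STL %s: no vertex records (byte offset 0)", path))
    if (length(vl) %% 3L != 0L)
      stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    verts <- do.call(rbind, nums)
    if (any(!is.finite(verts))) stop("malformed ASCII STL vertex line in ", path)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  tri_surface(verts, faces, weld = TRUE, weld_tol = weld_tol)
}

# interleave rows of three equally sized matrices: a1,b1,c1,a2,b2,c2,...
rbind_interleave <- function(a, b, c) {
  n <- nrow(a)
  out <- matrix(0, nrow = 3L * n, ncol = 3L)
  out[seq(1L, 3L * n, by = 3L), ] <- a
  out[seq(2L, 3L * n, by = 3L), ] <- b
  out[seq(3L, 3L * n, by = 3L), ] <- c
  out
}

#' Write an STL file
#'
#' @param s a [tri_surface()].
#' @param path output path.
#' @param format "binary" (default) or "ascii".
#' @param name solid name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(s, path, format = c("binary", "ascii"),
                      name = "kneemorph") {
  format <- match.arg(format)
  p1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  p2 <- s$vertices[s$faces[, 2], , drop = FALSE]
  p3 <- s$vertices[s$faces[, 3], , drop = FALSE]
  nrm <- face_normals(s)
  n <- nrow(s$faces)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", name))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    block <- matrix(0, nrow = n, ncol = 12L)
    block[, 1:3] <- nrm; block[, 4:6] <- p1; block[, 7:9] <- p2
    block[, 10:12] <- p3
    floats <- writeBin(as.numeric(t(block)), raw(), size = 4,
                       endian = "little")
    fm <- matrix(floats, ncol = 48L, byrow = TRUE)
    rec <- cbind(fm, matrix(as.raw(0), nrow = n, ncol = 2L))
    writeBin(as.raw(t(rec)), con)
  } else {
    fmt <- function(v) sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    lines <- c(paste("solid", name),
               as.vector(rbind(paste("  facet normal", fmt(nrm)),
                               "    outer loop",
                               paste("      vertex", fmt(p1)),
                               paste("      vertex", fmt(p2)),
                               paste("      vertex", fmt(p3)),
                               "    endloop",
                               "  endfacet")),
               paste("endsolid", name))
    writeLines(lines, path)
  }
  invisible(path)
}
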