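#' Per-element scalar field on a triangulated surface
#'
#' Holds one scalar per face (wall thickness in mm, or Gaussian curvature in
#' mm^-2) plus a validity flag for faces where the analysis failed (e.g. no
#' opposite surface found for a thickness ray).
#'
#' @param surface the [tri_surface()] the values belong to.
#' @param values numeric vector, one value per face.
#' @param analysis_kind "wall" or "curvature".
#' @param valid logical vector, one flag per face.
#' @return an object of class `element_field`.
#' @export
element_field <- function(surface, values, analysis_kind = c("wall", "curvature"),
                          valid = rep(TRUE, length(values))) {
  analysis_kind <- match.arg(analysis_kind)
  if (length(values) != nrow(surface$faces))
    stop("value count must equal face count")
  if (length(valid) != length(values))
    stop("validity flag count must equal value count")
  if (analysis_kind == "wall" && any(values[valid] <= 0, na.rm = TRUE))
    stop("thickness values must be positive where valid")
  structure(list(surface = surface, values = as.numeric(values),
                 analysis_kind = analysis_kind, valid = as.logical(valid)),
            class = "element_field")
}

#' @export
print.element_field <- function(x, ...) {
  cat(sprintf("<element_field [%s]: %d elements, %d valid>\n",
              x$analysis_kind, length(x$values), sum(x$valid)))
  invisible(x)
}

#' Write a per-element field as an element text file
#'
#' One whitespace-delimited line per valid element: the nine coordinates of
#' the triangle's three vertices (mm) followed by the analysis value.
#' @param field an [element_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_element_field <- function(field, path) {
  s <- field$surface
  sel <- which(field$valid)
  p1 <- s$vertices[s$faces[sel, 1], , drop = FALSE]
  p2 <- s$vertices[s$faces[sel, 2], , drop = FALSE]
  p3 <- s$vertices[s$faces[sel, 3], , drop = FALSE]
  m <- cbind(p1, p2, p3, field$values[sel])
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an element text file into an element field
#'
#' Parses the ten-numbers-per-line element dialect (three vertex coordinate
#' triples plus the analysis value) and rebuilds a standalone surface whose
#' faces are the listed elements.
#' @param path input path.
#' @param analysis_kind "wall" or "curvature".
#' @return an [element_field()] with `NE` = number of lines.
#' @export
read_element_field <- function(path, analysis_kind = c("wall", "curvature")) {
  analysis_kind <- match.arg(analysis_kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty element file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 10L))
    stop(sprintf("malformed line %d in %s: expected 10 numbers, got %d",
                 which(nt != 10L)[1], path, nt[nt != 10L][1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 10L,
              byrow = TRUE)
  if (any(!is.finite(m)))
    stop(sprintf("malformed line %d in %s: non-numeric token",
                 which(rowSums(!is.finite(m)) > 0)[1], path))
  n <- nrow(m)
  verts <- rbind_interleave(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
                            m[, 7:9, drop = FALSE])
  faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  s <- tri_surface(verts, faces, weld = TRUE, drop_degenerate = FALSE)
  element_field(s, m[, 10], analysis_kind = analysis_kind)
}
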