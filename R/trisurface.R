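#' Triangulated surface in millimetres
#'
#' A `tri_surface` is a list with a numeric `vertices` matrix (n x 3, mm) and
#' an integer `faces` matrix (m x 3) of 1-based vertex indices. All geometry
#' in the package (areas in mm^2, volumes in mm^3, thickness in mm) is
#' computed from this representation.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param weld if `TRUE`, duplicate vertices within `weld_tol` are merged.
#' @param weld_tol welding tolerance in mm.
#' @param drop_degenerate drop faces with area below `area_epsilon`.
#' @param area_epsilon degeneracy threshold in mm^2.
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, weld = FALSE, weld_tol = 1e-6,
                        drop_degenerate = TRUE, area_epsilon = 1e-10) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (weld) {
    w <- weld_vertices(vertices, faces, tol = weld_tol)
    vertices <- w$vertices
    faces <- w$faces
  }
  s <- structure(list(vertices = vertices, faces = faces),
                 class = "tri_surface")
  if (drop_degenerate) {
    a <- face_areas(s)
    bad <- a <= area_epsilon
    if (any(bad)) {
      s$faces <- s$faces[!bad, , drop = FALSE]
      attr(s, "dropped_degenerate") <- sum(bad)
      if (nrow(s$faces) == 0L) stop("all faces degenerate")
    }
  }
  s
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface: %d vertices, %d faces, %s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_closed(x)) "closed" else "open"))
  invisible(x)
}

#' Merge duplicate vertices
#'
#' STL files repeat every vertex per triangle; welding rebuilds shared
#' connectivity by snapping coordinates to a grid of size `tol`.
#' @param vertices,faces as in [tri_surface()].
#' @param tol weld tolerance (mm).
#' @return list with deduplicated `vertices` and re-indexed `faces`.
#' @export
weld_vertices <- function(vertices, faces, tol = 1e-6) {
  rx <- round(vertices[, 1] / tol)
  ry <- round(vertices[, 2] / tol)
  rz <- round(vertices[, 3] / tol)
  o <- order(rx, ry, rz)
  n <- length(o)
  new_grp <- c(TRUE, rx[o][-1] != rx[o][-n] | ry[o][-1] != ry[o][-n] |
                 rz[o][-1] != rz[o][-n])
  grp <- cumsum(new_grp)
  id <- integer(n)
  id[o] <- grp
  list(vertices = vertices[o[new_grp], , drop = FALSE],
       faces = matrix(id[faces], ncol = 3L))
}

face_corner <- function(s, k) s$vertices[s$faces[, k], , drop = FALSE]

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas (mm^2)
#' @param s a `tri_surface`.
#' @return numeric vector, one area per face.
#' @export
face_areas <- function(s) {
  p1 <- face_corner(s, 1L); p2 <- face_corner(s, 2L); p3 <- face_corner(s, 3L)
  cr <- cross3(p2 - p1, p3 - p1)
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-face unit normals
#' @param s a `tri_surface`.
#' @return m x 3 matrix of unit normals (right-hand rule on vertex order).
#' @export
face_normals <- function(s) {
  p1 <- face_corner(s, 1L); p2 <- face_corner(s, 2L); p3 <- face_corner(s, 3L)
  cr <- cross3(p2 - p1, p3 - p1)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' Per-face centroids
#' @param s a `tri_surface`.
#' @return m x 3 matrix of triangle centroids (mm).
#' @export
face_centroids <- function(s) {
  (face_corner(s, 1L) + face_corner(s, 2L) + face_corner(s, 3L)) / 3
}

#' Total surface area
#' @param s a `tri_surface`.
#' @return area in mm^2 (sum of per-face areas).
#' @export
surface_area <- function(s) sum(face_areas(s))

# Directed edge table: one row per half-edge (from, to, face); `list` not
# data.frame to keep large meshes cheap.
half_edges <- function(s) {
  f <- s$faces
  list(from = c(f[, 1], f[, 2], f[, 3]),
       to   = c(f[, 2], f[, 3], f[, 1]),
       face = rep.int(seq_len(nrow(f)), 3L))
}

# numeric undirected edge key (exact while vertex ids < 2^26)
edge_key <- function(a, b) pmin(a, b) * 67108864 + pmax(a, b)

# multiplicity of each undirected edge, named by key
edge_counts <- function(s) {
  he <- half_edges(s)
  k <- sort(edge_key(he$from, he$to))
  r <- rle(k)
  stats::setNames(r$lengths, format(r$values, scientific = FALSE))
}

# keys of edges used by exactly `times` faces
edge_keys_with_count <- function(he, times = 1L) {
  k <- edge_key(he$from, he$to)
  r <- rle(sort(k))
  r$values[r$lengths == times]
}

#' Is the surface closed (watertight and consistently oriented)?
#'
#' Closed means every undirected edge is shared by exactly two faces and the
#' two incident half-edges run in opposite directions.
#' @param s a `tri_surface`.
#' @return logical scalar.
#' @export
is_closed <- function(s) {
  he <- half_edges(s)
  k <- sort(edge_key(he$from, he$to))
  r <- rle(k)
  if (any(r$lengths != 2L)) return(FALSE)
  # orientation: each directed edge must appear exactly once
  dk <- he$from * 67108864 + he$to
  !any(duplicated(dk))
}

#' Euler characteristic V - E + F
#' @param s a `tri_surface`.
#' @return integer; 2 for a topological sphere, 2 - 2g for genus g.
#' @export
euler_characteristic <- function(s) {
  v <- length(unique(as.vector(s$faces)))
  e <- length(edge_counts(s))
  f <- nrow(s$faces)
  v - e + f
}

#' Enclosed volume of a closed surface
#'
#' Divergence-theorem volume (sum of signed tetrahedra against the origin);
#' positive for consistently outward-oriented surfaces.
#' @param s a closed `tri_surface`.
#' @param signed if `TRUE`, return the signed value instead of rejecting
#'   inward orientation.
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(s, signed = FALSE) {
  if (!is_closed(s))
    stop("enclosed_volume requires a closed, consistently oriented surface")
  p1 <- face_corner(s, 1L); p2 <- face_corner(s, 2L); p3 <- face_corner(s, 3L)
  v <- sum(rowSums(p1 * cross3(p2, p3))) / 6
  if (!signed && v < 0)
    stop("surface is oriented inward (negative volume); flip face winding")
  v
}

#' Reverse face orientation
#' @param s a `tri_surface`.
#' @return the surface with all face windings flipped.
#' @export
flip_orientation <- function(s) {
  s$faces <- s$faces[, c(1L, 3L, 2L), drop = FALSE]
  s
}

#' Boundary loops of an open surface
#'
#' Boundary edges (used by exactly one face) are chained into closed cycles.
#' The loop with the largest projected (Newell) area is classified `outer`,
#' all others `interior`; on a closed surface the result is empty.
#'
#' @param s a `tri_surface`, manifold except at the boundary.
#' @return list of loops; each has `vertices` (ordered indices), `length_mm`,
#'   and `classification` ("outer" or "interior").
#' @export
boundary_loops <- function(s) {
  he <- half_edges(s)
  k <- edge_key(he$from, he$to)
  r <- rle(sort(k))
  if (any(r$lengths > 2L)) {
    bad <- r$values[r$lengths > 2L]
    stop(sprintf("non-manifold edges (>2 incident faces): %s",
                 paste(utils::head(format(bad), 5L), collapse = ", ")))
  }
  sel <- k %in% r$values[r$lengths == 1L]
  bnd <- list(from = he$from[sel], to = he$to[sel])
  if (length(bnd$from) == 0L) return(list())
  # For a consistently wound mesh each boundary vertex has one outgoing
  # boundary half-edge; follow successors until the cycle closes.
  succ <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(bnd$from)) {
    key <- as.character(bnd$from[i])
    if (!is.null(succ[[key]]))
      stop("boundary is not manifold: vertex with two outgoing boundary edges")
    succ[[key]] <- bnd$to[i]
  }
  visited <- new.env(hash = TRUE, parent = emptyenv())
  loops <- list()
  for (start in bnd$from) {
    if (!is.null(visited[[as.character(start)]])) next
    cyc <- integer(0)
    v <- start
    repeat {
      cyc <- c(cyc, v)
      visited[[as.character(v)]] <- TRUE
      v <- succ[[as.character(v)]]
      if (is.null(v)) stop("boundary chain broken: open boundary path")
      if (v == start) break
    }
    loops[[length(loops) + 1L]] <- cyc
  }
  # Newell-area classification: the largest loop bounds the outer rim.
  areas <- vapply(loops, function(idx) {
    p <- s$vertices[idx, , drop = FALSE]
    q <- p[c(seq_len(nrow(p))[-1], 1L), , drop = FALSE]
    nv <- colSums(cross3(p, q)) / 2
    sqrt(sum(nv^2))
  }, numeric(1))
  lens <- vapply(loops, function(idx) {
    p <- s$vertices[idx, , drop = FALSE]
    q <- p[c(seq_len(nrow(p))[-1], 1L), , drop = FALSE]
    sum(sqrt(rowSums((q - p)^2)))
  }, numeric(1))
  outer <- which.max(areas)
  lapply(seq_along(loops), function(i) {
    list(vertices = loops[[i]], length_mm = lens[i],
         classification = if (i == outer) "outer" else "interior")
  })
}

#' Faces adjacent to each face across an edge or vertex
#'
#' @param s a `tri_surface`.
#' @param by "edge" for edge-sharing neighbours, "vertex" for any face
#'   sharing a vertex.
#' @return list of integer vectors, one per face.
#' @export
face_neighbors <- function(s, by = c("vertex", "edge")) {
  by <- match.arg(by)
  f <- s$faces
  m <- nrow(f)
  if (by == "vertex") {
    vert2face <- split(rep.int(seq_len(m), 3L), as.vector(f))
    lapply(seq_len(m), function(i) {
      setdiff(unique(unlist(vert2face[as.character(f[i, ])], use.names = FALSE)), i)
    })
  } else {
    he <- half_edges(s)
    k <- edge_key(he$from, he$to)
    o <- order(k)
    ks <- k[o]; fs <- he$face[o]
    # consecutive equal keys are edge-sharing face pairs
    same <- which(ks[-1] == ks[-length(ks)])
    p1 <- fs[same]; p2 <- fs[same + 1L]
    nb <- vector("list", m)
    pairs <- split(c(p2, p1), c(p1, p2))
    nb[as.integer(names(pairs))] <- pairs
    nb
  }
}

#' Mesh validation report
#'
#' Counts of degenerate faces, non-manifold edges, boundary edges and
#' boundary loops, serializable to JSON.
#' @param s a `tri_surface`.
#' @param area_epsilon degeneracy threshold (mm^2).
#' @return list report.
#' @export
validate_surface <- function(s, area_epsilon = 1e-10) {
  tab <- edge_counts(s)
  nonman <- sum(tab > 2L)
  nbnd <- sum(tab == 1L)
  loops <- if (nonman == 0L && nbnd > 0L) length(boundary_loops(s)) else 0L
  list(n_vertices = nrow(s$vertices),
       n_faces = nrow(s$faces),
       n_degenerate_faces = sum(face_areas(s) <= area_epsilon),
       n_nonmanifold_edges = nonman,
       n_boundary_edges = nbnd,
       n_boundary_loops = loops,
       closed = is_closed(s),
       euler_characteristic = euler_characteristic(s))
}
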