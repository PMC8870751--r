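# Fixtures built in code: primitive meshes with analytic area/volume and
# a brute-force ray-casting oracle independent of the package's search path.

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward-wound
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = 1
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = 1
  tri_surface(v, f)
}

# planar rectangular grid in the z = 0 plane (open disk-like patch)
flat_grid_mesh <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  tri_surface(v, f)
}

# flat grid with faces removed where centroids fall inside given ellipses;
# holes are (cx, cy, a, b) rows
flat_grid_with_holes <- function(holes, nx = 40, ny = 40, spacing = 0.5) {
  s <- flat_grid_mesh(nx, ny, spacing)
  cent <- face_centroids(s)
  removed <- rep(FALSE, nrow(s$faces))
  for (k in seq_len(nrow(holes))) {
    q <- ((cent[, 1] - holes[k, 1]) / holes[k, 3])^2 +
      ((cent[, 2] - holes[k, 2]) / holes[k, 4])^2
    removed <- removed | q <= 1
  }
  tri_surface(s$vertices, s$faces[!removed, , drop = FALSE])
}

# two parallel unit squares z = 0 and z = gap, both wound so normals face
# outward (away from the slab interior)
parallel_plates <- function(gap = 2) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, gap), c(1, 0, gap), c(1, 1, gap), c(0, 1, gap))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),      # bottom, normal -z
             c(5, 6, 7), c(5, 7, 8))      # top, normal +z
  tri_surface(v, f)
}

# closed box slab [0,L]x[0,L]x[0,t]: cube mesh scaled anisotropically
box_slab <- function(L = 10, t = 3.5) {
  s <- unit_cube_mesh()
  s$vertices <- sweep(s$vertices, 2, c(L, L, t), "*")
  s
}

# O(F) reference ray caster: plain scalar loop over every triangle,
# written independently of the package's accelerated path
brute_force_first_hit <- function(s, origin, direction, excluded = integer(0),
                                  eps = 1e-9) {
  direction <- direction / sqrt(sum(direction^2))
  best_t <- Inf
  best_f <- NA_integer_
  for (i in seq_len(nrow(s$faces))) {
    if (i %in% excluded) next
    a <- s$vertices[s$faces[i, 1], ]
    b <- s$vertices[s$faces[i, 2], ]
    c_ <- s$vertices[s$faces[i, 3], ]
    e1 <- b - a; e2 <- c_ - a
    p <- c(direction[2] * e2[3] - direction[3] * e2[2],
           direction[3] * e2[1] - direction[1] * e2[3],
           direction[1] * e2[2] - direction[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) <= 1e-14) next
    tv <- origin - a
    u <- sum(tv * p) / det
    if (u < 0 || u > 1) next
    q <- c(tv[2] * e1[3] - tv[3] * e1[2],
           tv[3] * e1[1] - tv[1] * e1[3],
           tv[1] * e1[2] - tv[2] * e1[1])
    vv <- sum(direction * q) / det
    if (vv < 0 || u + vv > 1) next
    tt <- sum(e2 * q) / det
    if (tt > eps && tt < best_t) {
      best_t <- tt
      best_f <- i
    }
  }
  if (!is.finite(best_t)) return(NULL)
  list(face = best_f, distance = best_t)
}
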