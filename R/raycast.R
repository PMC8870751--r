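# Ray-triangle intersection (Moller-Trumbore), vectorized over triangles.

# Precompute per-triangle origin and edge vectors once per surface.
precompute_tris <- function(s) {
  v0 <- s$vertices[s$faces[, 1], , drop = FALSE]
  list(v0 = v0,
       e1 = s$vertices[s$faces[, 2], , drop = FALSE] - v0,
       e2 = s$vertices[s$faces[, 3], , drop = FALSE] - v0)
}

# Distances from ray(s) to triangles; Inf where no intersection.
# `tris` is precompute_tris() output, optionally subset by `idx`.
# `origin`/`direction` may be length-3 vectors (one ray against all listed
# triangles) or n x 3 matrices paired row-wise with `idx`.
ray_tri_distances <- function(origin, direction, tris, idx = NULL,
                              ray_epsilon = 1e-9) {
  v0 <- tris$v0; e1 <- tris$e1; e2 <- tris$e2
  if (!is.null(idx)) {
    v0 <- v0[idx, , drop = FALSE]
    e1 <- e1[idx, , drop = FALSE]
    e2 <- e2[idx, , drop = FALSE]
  }
  if (is.matrix(direction)) {
    d1 <- direction[, 1]; d2 <- direction[, 2]; d3 <- direction[, 3]
  } else {
    d1 <- direction[1]; d2 <- direction[2]; d3 <- direction[3]
  }
  # pvec = direction x e2
  p1 <- d2 * e2[, 3] - d3 * e2[, 2]
  p2 <- d3 * e2[, 1] - d1 * e2[, 3]
  p3 <- d1 * e2[, 2] - d2 * e2[, 1]
  det <- e1[, 1] * p1 + e1[, 2] * p2 + e1[, 3] * p3
  if (is.matrix(origin)) {
    t1 <- origin[, 1] - v0[, 1]; t2 <- origin[, 2] - v0[, 2]
    t3 <- origin[, 3] - v0[, 3]
  } else {
    t1 <- origin[1] - v0[, 1]; t2 <- origin[2] - v0[, 2]
    t3 <- origin[3] - v0[, 3]
  }
  u <- (t1 * p1 + t2 * p2 + t3 * p3) / det
  # qvec = tvec x e1
  q1 <- t2 * e1[, 3] - t3 * e1[, 2]
  q2 <- t3 * e1[, 1] - t1 * e1[, 3]
  q3 <- t1 * e1[, 2] - t2 * e1[, 1]
  v <- (d1 * q1 + d2 * q2 + d3 * q3) / det
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
  ok <- is.finite(tt) & abs(det) > 1e-14 & u >= 0 & v >= 0 & (u + v) <= 1 &
    tt > ray_epsilon
  tt[!ok] <- Inf
  tt
}

#' First ray-surface intersection
#'
#' Casts a ray from `origin` along `direction` and returns the nearest
#' triangle hit beyond `ray_epsilon`, testing every face (brute force).
#' Faces listed in `excluded_faces` are ignored, which lets a caller cast
#' from a face centroid without hitting the face itself.
#'
#' @param s a [tri_surface()].
#' @param origin numeric length-3 ray origin (mm).
#' @param direction numeric length-3 direction (need not be unit length).
#' @param excluded_faces integer face indices to skip.
#' @param max_dist ignore hits beyond this distance (mm).
#' @param ray_epsilon minimum hit distance (mm).
#' @return list with `face` and `distance`, or `NULL` when nothing is hit.
#' @export
ray_first_hit <- function(s, origin, direction, excluded_faces = integer(0),
                          max_dist = Inf, ray_epsilon = 1e-9) {
  if (sum(direction^2) == 0) stop("direction must be nonzero")
  direction <- direction / sqrt(sum(direction^2))
  tris <- precompute_tris(s)
  tt <- ray_tri_distances(origin, direction, tris, ray_epsilon = ray_epsilon)
  if (length(excluded_faces)) tt[excluded_faces] <- Inf
  tt[tt > max_dist] <- Inf
  i <- which.min(tt)
  if (!is.finite(tt[i])) return(NULL)
  list(face = i, distance = tt[i])
}

# --- uniform-grid spatial bin over face centroids -------------------------

build_face_grid <- function(centroids, cell) {
  lo <- apply(centroids, 2, min) - 1e-9
  ext <- apply(centroids, 2, max) - lo
  # keep the bin table a manageable size
  while (prod(floor(ext / cell) + 1) > 4e6) cell <- cell * 2
  ci <- floor(sweep(centroids, 2, lo) / cell)
  dims <- apply(ci, 2, max) + 1L
  key <- 1L + ci[, 1] + dims[1] * (ci[, 2] + dims[2] * ci[, 3])
  bins <- vector("list", prod(dims))
  tab <- split(seq_len(nrow(centroids)), key)
  bins[as.integer(names(tab))] <- tab
  list(lo = lo, cell = cell, dims = dims, bins = bins)
}

# Face indices whose centroid cell intersects the ball B(center, radius).
grid_gather <- function(grid, center, radius) {
  lo <- floor((center - radius - grid$lo) / grid$cell)
  hi <- floor((center + radius - grid$lo) / grid$cell)
  lo <- pmax(lo, 0); hi <- pmin(hi, grid$dims - 1L)
  if (any(hi < lo)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  keys <- 1L + as.vector(outer(outer(xs, grid$dims[1] * ys, "+"),
                               grid$dims[1] * grid$dims[2] * zs, "+"))
  unlist(grid$bins[keys], use.names = FALSE)
}
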