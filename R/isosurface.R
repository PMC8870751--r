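# Iso-surface extraction from a voxel mask by marching tetrahedra.
#
# Each grid cube is split into six tetrahedra sharing the main diagonal;
# within a tetrahedron the iso-surface of a linearly interpolated field is
# one or two triangles, enumerated by the inside/outside pattern of its four
# corners. The binary mask is first smoothed with a small box filter so the
# 0.5-level set approximates the voxel-boundary surface without staircase
# area inflation.

box_smooth3 <- function(a, reps = 1L) {
  d <- dim(a)
  for (r in seq_len(reps)) {
    out <- array(0, d)
    cnt <- array(0, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
      ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
      zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
      out[xs - dx, ys - dy, zs - dz] <- out[xs - dx, ys - dy, zs - dz] +
        a[xs, ys, zs]
      cnt[xs - dx, ys - dy, zs - dz] <- cnt[xs - dx, ys - dy, zs - dz] + 1
    }
    a <- out / cnt
  }
  a
}

# the six tetrahedra of a cube, as corner ids 0..7 (bit order x, y, z),
# every tet containing the 0-6 main diagonal
tet6 <- rbind(c(0L, 1L, 2L, 6L), c(0L, 2L, 3L, 6L), c(0L, 3L, 7L, 6L),
              c(0L, 7L, 4L, 6L), c(0L, 4L, 5L, 6L), c(0L, 5L, 1L, 6L))

#' Iso-surface of a voxel mask
#'
#' Extracts the 0.5-level surface of a (smoothed) binary mask by marching
#' tetrahedra, with voxel centers at `(index - 1) * spacing`.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing, scalar or length-3 (mm).
#' @param smooth number of 3x3x3 box-smoothing passes applied to the binary
#'   field before extraction (0 = raw staircase surface).
#' @return list with `area` (mm^2) and `surface` (a [tri_surface()];
#'   triangle winding is not globally oriented).
#' @export
mask_isosurface <- function(mask, spacing = 0.5, smooth = 2L) {
  if (!any(mask)) stop("empty mask")
  spacing <- rep(spacing, length.out = 3L)
  # crop to the mask bounding box (plus margin) so large mostly-empty grids
  # cost nothing; vertex coordinates are shifted back afterwards
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 2L, 1L)
  hi <- pmin(apply(w, 2, max) + 2L, dim(mask))
  offset <- (lo - 1L) * spacing
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d0 <- dim(mask)
  # pad so surfaces at the volume border are closed (logged via attribute)
  padded <- any(mask[1, , ], mask[d0[1], , ], mask[, 1, ], mask[, d0[2], ],
                mask[, , 1], mask[, , d0[3]])
  f <- array(0, d0 + 2L)
  f[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <- as.numeric(mask)
  iso <- 0.5
  # tiny masks can be smoothed entirely below the iso level; back off
  raw <- f
  while (smooth > 0) {
    f <- box_smooth3(raw, smooth)
    if (max(f) >= iso) break
    smooth <- smooth - 1L
  }
  if (smooth == 0L) f <- raw
  d <- dim(f)

  nx <- d[1]; ny <- d[2]; nz <- d[3]
  corner_off <- function(cid) {
    bx <- bitwAnd(cid, 1L); by <- bitwAnd(bitwShiftR(cid, 1L), 1L)
    bz <- bitwShiftR(cid, 2L)
    bx + nx * by + nx * ny * bz
  }
  # cubes whose value range crosses iso
  base_idx <- which(array(TRUE, d - 1L))
  bi <- arrayInd(base_idx, d - 1L)
  base <- bi[, 1] + nx * (bi[, 2] - 1L) + nx * ny * (bi[, 3] - 1L)
  fmin <- fmax <- f[base]
  for (cid in 1:7) {
    fc <- f[base + corner_off(cid)]
    fmin <- pmin(fmin, fc); fmax <- pmax(fmax, fc)
  }
  base <- base[fmin < iso & fmax >= iso]
  if (length(base) == 0L) stop("no iso-surface found")

  # grid coordinates of a linear index (voxel centers of the padded grid,
  # shifted so the original grid starts at 0)
  coord <- function(lin) {
    ai <- arrayInd(lin, d)
    cbind((ai[, 1] - 2L) * spacing[1], (ai[, 2] - 2L) * spacing[2],
          (ai[, 3] - 2L) * spacing[3])
  }
  interp <- function(la, lb) {
    fa <- f[la]; fb <- f[lb]
    tt <- (iso - fa) / (fb - fa)
    coord(la) + tt * (coord(lb) - coord(la))
  }

  tri_list <- list()
  emit <- function(p1, p2, p3) {
    tri_list[[length(tri_list) + 1L]] <<- cbind(p1, p2, p3)
  }
  for (t in seq_len(nrow(tet6))) {
    lin <- vapply(tet6[t, ], function(cid) base + corner_off(cid),
                  numeric(length(base)))
    lin <- matrix(lin, ncol = 4L)
    inside <- matrix(f[lin] >= iso, ncol = 4L)
    cnt <- rowSums(inside)
    # one corner separated: single triangle
    for (k in 1:4) {
      sel <- which((cnt == 1L & inside[, k]) | (cnt == 3L & !inside[, k]))
      if (!length(sel)) next
      oth <- setdiff(1:4, k)
      a <- lin[sel, k]
      emit(interp(a, lin[sel, oth[1]]), interp(a, lin[sel, oth[2]]),
           interp(a, lin[sel, oth[3]]))
    }
    # two-two split: quad as two triangles
    pairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
                   c(3L, 4L))
    for (pr in seq_len(nrow(pairs))) {
      i <- pairs[pr, 1]; j <- pairs[pr, 2]
      sel <- which(cnt == 2L & inside[, i] & inside[, j])
      if (!length(sel)) next
      kl <- setdiff(1:4, c(i, j))
      v1 <- interp(lin[sel, i], lin[sel, kl[1]])
      v2 <- interp(lin[sel, i], lin[sel, kl[2]])
      v3 <- interp(lin[sel, j], lin[sel, kl[2]])
      v4 <- interp(lin[sel, j], lin[sel, kl[1]])
      emit(v1, v2, v3)
      emit(v1, v3, v4)
    }
  }
  tri <- do.call(rbind, tri_list)     # each row: 9 numbers (3 points)
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  n <- nrow(tri)
  faces <- cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n)
  verts <- sweep(verts, 2, -offset)
  s <- tri_surface(verts, faces, weld = TRUE, weld_tol = 1e-9,
                   drop_degenerate = TRUE)
  attr(s, "padded") <- padded
  list(area = surface_area(s), surface = s)
}
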