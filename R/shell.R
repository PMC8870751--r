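# Synthetic cartilage compartment generator.
#
# A compartment is modelled as a spherical-cap shell: an outer cap of radius
# `base_radius`, an inner cap offset inward by the local thickness, joined at
# the rim. Through-holes are punched as elliptical tunnels (defined in
# geodesic normal coordinates on the cap, semi-axes in mm) and thinning
# patches locally reduce the wall thickness. The analytic geometry (cap area
# 2*pi*R^2*(1-cos(theta)), curvature 1/R^2, hole area pi*a*b, radial offset
# thickness) provides exact oracles for every downstream measurement.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; used as an analytic fixture
#' (area 4*pi*r^2, curvature 1/r^2).
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @return a closed [tri_surface()] oriented outward.
#' @export
icosphere <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    n <- nrow(v)
    a <- f[, 1]; b <- f[, 2]; c_ <- f[, 3]
    mab <- (v[a, ] + v[b, ]) / 2
    mbc <- (v[b, ] + v[c_, ]) / 2
    mca <- (v[c_, ] + v[a, ]) / 2
    i1 <- n + seq_len(nrow(f))
    i2 <- i1 + nrow(f)
    i3 <- i2 + nrow(f)
    v <- rbind(v, mab, mbc, mca)
    f <- rbind(cbind(a, i1, i3), cbind(i1, b, i2),
               cbind(i3, i2, c_), cbind(i1, i2, i3))
    w <- weld_vertices(v, f, tol = 1e-9)
    v <- w$vertices; f <- w$faces
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  tri_surface(v, f)
}

# Orthonormal tangent frame at a unit direction c0.
tangent_frame <- function(c0) {
  ref <- if (abs(c0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * c0) * c0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
          c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

sph_dir <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Geodesic normal coordinates (mm) of unit directions `d` (matrix) around
# unit center c0, in frame (e1, e2), on a sphere of radius R.
geodesic_uv <- function(d, c0, frame, R) {
  ca <- pmin(pmax(d %*% c0, -1), 1)
  alpha <- acos(as.vector(ca))
  w <- d - outer(as.vector(ca), c0)
  wn <- sqrt(rowSums(w^2))
  wn[wn == 0] <- 1
  u <- R * alpha * (w %*% frame$e1) / wn
  v <- R * alpha * (w %*% frame$e2) / wn
  cbind(as.vector(u), as.vector(v))
}

# Inverse: map geodesic coordinates (mm) back to a unit direction.
geodesic_point <- function(uv, c0, frame, R) {
  ang <- sqrt(rowSums(uv^2)) / R
  tdir <- outer(uv[, 1] / pmax(ang * R, 1e-300), frame$e1) +
    outer(uv[, 2] / pmax(ang * R, 1e-300), frame$e2)
  d <- outer(cos(ang), c0) + sin(ang) * tdir
  d / sqrt(rowSums(d^2))
}

# Signed ellipse membership in rotated geodesic coordinates: <= 1 is inside.
ellipse_q <- function(uv, hole) {
  ang <- if (is.null(hole$angle)) 0 else hole$angle
  u <- cos(ang) * uv[, 1] + sin(ang) * uv[, 2]
  v <- -sin(ang) * uv[, 1] + cos(ang) * uv[, 2]
  (u / hole$a)^2 + (v / hole$b)^2
}

validate_defects <- function(holes, patches, base_radius, cap_angle, h) {
  feats <- c(lapply(holes, function(x) list(center = x$center,
                                            r = max(x$a, x$b), kind = "hole")),
             lapply(patches, function(x) list(center = x$center,
                                              r = x$radius, kind = "patch")))
  if (length(feats) == 0) return(invisible(TRUE))
  dirs <- do.call(rbind, lapply(feats, function(x)
    sph_dir(x$center[1], x$center[2])))
  rr <- vapply(feats, `[[`, numeric(1), "r")
  # features must stay inside the cap with a 2-cell margin
  rim_margin <- base_radius * cap_angle -
    (base_radius * vapply(feats, function(x) x$center[1], numeric(1)) + rr)
  if (any(rim_margin < 2 * h))
    stop("hole/patch extends past the cap rim (or within 2 cells of it)")
  if (length(feats) > 1) {
    for (i in seq_len(length(feats) - 1)) {
      for (j in (i + 1):length(feats)) {
        gd <- base_radius * acos(pmin(pmax(sum(dirs[i, ] * dirs[j, ]), -1), 1))
        need <- rr[i] + rr[j] +
          if (feats[[i]]$kind == "hole" && feats[[j]]$kind == "hole") 2 * h else 0
        if (gd < need)
          stop(sprintf("overlapping holes/patches (features %d and %d)", i, j))
      }
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic cartilage compartment shell
#'
#' Builds a closed spherical-cap shell (outer cap + inner cap + rim and
#' tunnel walls) together with the open outer-surface patch and ground
#' truth. Holes are realized both topologically (as tunnels through the
#' closed shell, raising its genus) and as interior boundary loops of the
#' open patch; hole-rim vertices are snapped exactly onto the defining
#' ellipse so the recorded analytic area pi*a*b is exact.
#'
#' @param base_radius outer cap radius R (mm).
#' @param nominal_thickness wall thickness t (mm), > 0.
#' @param cap_angle polar half-angle of the cap (radians).
#' @param thinning_patches list of patches, each
#'   `list(center = c(theta, phi), radius, depth)` (mm); thickness inside a
#'   patch is `nominal_thickness - depth`.
#' @param holes list of elliptical through-holes, each
#'   `list(center = c(theta, phi), a, b, angle)` with semi-axes in mm.
#' @param refinement number of polar rings; `NULL` picks the number giving
#'   `target_edge` spacing.
#' @param target_edge target mesh edge length (mm) when `refinement` is NULL.
#' @param roughness_amp amplitude (mm, sd) of a smooth random radial
#'   perturbation of the outer surface; 0 disables it.
#' @param roughness_wavelength spatial wavelength (mm) of the perturbation.
#' @param seed integer seed for the roughness field.
#' @return list with elements `closed` (watertight [tri_surface()]),
#'   `outer_patch` (open [tri_surface()]), and `ground_truth` (nominal
#'   thickness per outer-patch face, hole table with exact areas, analytic
#'   outer area/volume/curvature).
#' @export
generate_shell <- function(base_radius = 40, nominal_thickness = 2,
                           cap_angle = pi / 2, thinning_patches = list(),
                           holes = list(), refinement = NULL,
                           target_edge = 2, roughness_amp = 0,
                           roughness_wavelength = 8, seed = 1) {
  stopifnot(nominal_thickness > 0, base_radius > nominal_thickness,
            cap_angle > 0, cap_angle < 2.8)
  R <- base_radius
  if (is.null(refinement)) refinement <- max(8L, ceiling(R * cap_angle / target_edge))
  n <- as.integer(refinement)
  h <- R * cap_angle / n
  if (length(holes)) {
    bmin <- min(vapply(holes, function(x) min(x$a, x$b), numeric(1)))
    if (h > bmin / 1.5) {
      need <- ceiling(R * cap_angle / (bmin / 1.5))
      stop(sprintf(
        "refinement %d too low to resolve smallest hole (semi-axis %.2f mm); minimum refinement is %d",
        n, bmin, need))
    }
  }
  for (p in thinning_patches)
    if (p$depth >= nominal_thickness)
      stop("thinning patch depth must be smaller than the nominal thickness")
  validate_defects(holes, thinning_patches, R, cap_angle, h)
  m <- max(8L, ceiling(2 * pi * R * sin(min(cap_angle, pi / 2)) / h))

  # vertex grid: apex (index 1) + n rings of m vertices
  theta <- rep(seq_len(n) * cap_angle / n, each = m)
  phi <- rep(2 * pi * (seq_len(m) - 1) / m, times = n)
  dirs <- rbind(c(0, 0, 1), sph_dir(theta, phi))
  vid <- function(i, j) 1L + (i - 1L) * m + (j - 1L) %% m + 1L  # ring i>=1

  j <- seq_len(m)
  fan <- cbind(1L, vid(1L, j), vid(1L, j + 1L))
  quads <- NULL
  if (n > 1) {
    grid_i <- rep(seq_len(n - 1L), each = m)
    grid_j <- rep(j, times = n - 1L)
    a <- vid(grid_i, grid_j); b <- vid(grid_i, grid_j + 1L)
    cc <- vid(grid_i + 1L, grid_j); dd <- vid(grid_i + 1L, grid_j + 1L)
    quads <- rbind(cbind(a, cc, dd), cbind(a, dd, b))
  }
  faces <- rbind(fan, quads)

  # hole membership per face (centroid test in geodesic coordinates)
  ek_num <- function(f) {
    a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
    pmin(a, b) * 67108864 + pmax(a, b)
  }
  cents_dir <- (dirs[faces[, 1], ] + dirs[faces[, 2], ] + dirs[faces[, 3], ]) / 3
  cents_dir <- cents_dir / sqrt(rowSums(cents_dir^2))
  removed <- rep(FALSE, nrow(faces))
  hole_frames <- list()
  for (k in seq_along(holes)) {
    hk <- holes[[k]]
    c0 <- as.vector(sph_dir(hk$center[1], hk$center[2]))
    fr <- tangent_frame(c0)
    hole_frames[[k]] <- list(c0 = c0, frame = fr)
    q <- ellipse_q(geodesic_uv(cents_dir, c0, fr, R), hk)
    inside <- q <= 1
    if (!any(inside))
      stop(sprintf("refinement %d too low to resolve hole %d; increase refinement", n, k))
    removed <- removed | inside
  }
  kept <- faces[!removed, , drop = FALSE]

  # snap hole-boundary vertices exactly onto their ellipse
  if (length(holes)) {
    kept_e <- ek_num(kept)
    rem_e <- ek_num(faces[removed, , drop = FALSE])
    shared <- intersect(unique(kept_e), unique(rem_e))
    bverts <- unique(c(shared %/% 67108864, shared %% 67108864))
    # only vertices still used by kept faces
    bverts <- intersect(bverts, unique(as.vector(kept)))
    if (length(bverts)) {
      bdir <- dirs[bverts, , drop = FALSE]
      # each boundary vertex belongs to the hole whose ellipse quotient is
      # smallest (robust when elongated holes crowd together)
      dmat <- vapply(seq_along(holes), function(k)
        ellipse_q(geodesic_uv(bdir, hole_frames[[k]]$c0,
                              hole_frames[[k]]$frame, R), holes[[k]]),
        numeric(length(bverts)))
      dmat <- matrix(dmat, nrow = length(bverts))
      owner <- max.col(-dmat)
      for (k in seq_along(holes)) {
        sel <- owner == k
        if (!any(sel)) next
        hf <- hole_frames[[k]]; hk <- holes[[k]]
        uv <- geodesic_uv(bdir[sel, , drop = FALSE], hf$c0, hf$frame, R)
        lam <- 1 / sqrt(ellipse_q(uv, hk))
        dirs[bverts[sel], ] <- geodesic_point(uv * lam, hf$c0, hf$frame, R)
      }
    }
  }

  # per-vertex thickness (patches carve the inner surface outward)
  tvert <- rep(nominal_thickness, nrow(dirs))
  for (p in thinning_patches) {
    c0 <- as.vector(sph_dir(p$center[1], p$center[2]))
    fr <- tangent_frame(c0)
    uv <- geodesic_uv(dirs, c0, fr, R)
    tvert[rowSums(uv^2) <= p$radius^2] <- nominal_thickness - p$depth
  }

  r_out <- rep(R, nrow(dirs))
  if (roughness_amp > 0) {
    r_out <- r_out + roughness_field(dirs * R, roughness_amp,
                                     roughness_wavelength, seed)
  }
  outer_v <- dirs * r_out
  inner_v <- dirs * (R - tvert)

  # prune unused grid vertices from the outer patch
  used <- sort(unique(as.vector(kept)))
  remap <- integer(nrow(dirs)); remap[used] <- seq_along(used)
  patch_faces <- matrix(remap[kept], ncol = 3L)
  outer_patch <- tri_surface(outer_v[used, , drop = FALSE], patch_faces,
                             drop_degenerate = FALSE)

  # closed shell: outer kept + flipped inner copy + walls on every boundary
  # half-edge (rim and hole tunnels alike)
  nu <- length(used)
  closed_v <- rbind(outer_v[used, , drop = FALSE], inner_v[used, , drop = FALSE])
  inner_faces <- patch_faces[, c(1L, 3L, 2L), drop = FALSE] + nu
  heb <- half_edges(outer_patch)
  ky <- edge_key(heb$from, heb$to)
  bsel <- ky %in% edge_keys_with_count(heb, 1L)
  bfrom <- heb$from[bsel]; bto <- heb$to[bsel]
  walls <- rbind(cbind(bto, bfrom, bfrom + nu),
                 cbind(bto, bfrom + nu, bto + nu))
  closed <- tri_surface(closed_v, rbind(patch_faces, inner_faces, walls),
                        drop_degenerate = FALSE)

  # ground truth
  kept_cent <- cents_dir[!removed, , drop = FALSE]
  gt_thick <- rep(nominal_thickness, nrow(kept))
  for (p in thinning_patches) {
    c0 <- as.vector(sph_dir(p$center[1], p$center[2]))
    fr <- tangent_frame(c0)
    uv <- geodesic_uv(kept_cent, c0, fr, R)
    gt_thick[rowSums(uv^2) <= p$radius^2] <- nominal_thickness - p$depth
  }
  hole_tab <- if (length(holes)) {
    data.frame(hole = seq_along(holes),
               a = vapply(holes, function(x) max(x$a, x$b), numeric(1)),
               b = vapply(holes, function(x) min(x$a, x$b), numeric(1)),
               area = vapply(holes, function(x) pi * x$a * x$b, numeric(1)))
  } else {
    data.frame(hole = integer(0), a = numeric(0), b = numeric(0),
               area = numeric(0))
  }
  cap_area <- 2 * pi * R^2 * (1 - cos(cap_angle))
  shell_volume <- (2 * pi / 3) * (R^3 - (R - nominal_thickness)^3) *
    (1 - cos(cap_angle))
  list(closed = closed,
       outer_patch = outer_patch,
       ground_truth = list(
         thickness = gt_thick,
         n_holes = length(holes),
         holes = hole_tab,
         outer_area = cap_area - sum(hole_tab$area),
         shell_volume = shell_volume,
         curvature = 1 / R^2,
         base_radius = R,
         cap_angle = cap_angle,
         nominal_thickness = nominal_thickness))
}

# Smooth pseudo-random radial field: superposed plane-wave cosines,
# standardized to sd `amp`. Deterministic for a given seed.
roughness_field <- function(points, amp, wavelength, seed) {
  withr::with_seed(as.integer(seed), {
    k <- 8L
    g <- matrix(stats::rnorm(3L * k), ncol = 3L)
    g <- g / sqrt(rowSums(g^2)) * (2 * pi / wavelength)
    ph <- stats::runif(k, 0, 2 * pi)
    f <- rowSums(cos(points %*% t(g) + matrix(ph, nrow(points), k, byrow = TRUE)))
    f <- f - mean(f)
    s <- stats::sd(f)
    if (s == 0) return(rep(0, nrow(points)))
    amp * f / s
  })
}
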