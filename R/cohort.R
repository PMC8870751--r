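# Synthetic cohort generation: group archetypes carrying the degenerative /
# traumatic / control compartment statistics, per-subject realization as
# meshes and voxel volumes, and cohort assembly with a ground-truth manifest.

#' Group archetype
#'
#' Statistical description of one subject group: per-compartment density,
#' volume and surface moments, thinning-patch load, hole model and surface
#' roughness. Positive quantities are drawn from moment-matched lognormals,
#' densities from Gaussians.
#'
#' @param group_label "D", "T" or "C".
#' @param bone_bmd,patella_volume,patella_surface,cartilage moment tables
#'   (see [default_archetypes()] for the shipped defaults).
#' @param thinning_patch_rate fraction of cartilage surface with reduced
#'   thickness.
#' @param patch_depth_range depth as a fraction of local thickness (range).
#' @param roughness_amp radial surface roughness amplitude (mm, sd).
#' @param hole_subject_prob probability that a subject has any holes.
#' @param hole_profiles matrix of per-compartment hole counts (columns
#'   Fem/Lat/Med/Pat), one row sampled per affected subject; `NULL` for no
#'   holes (control).
#' @param hole_area_meanlog,hole_area_sdlog,hole_area_range lognormal hole
#'   area model (mm^2), truncated to the range.
#' @return object of class `group_archetype`.
#' @export
group_archetype <- function(group_label, bone_bmd, patella_volume,
                            patella_surface, cartilage,
                            thinning_patch_rate = 0,
                            patch_depth_range = c(0.3, 0.6),
                            roughness_amp = 0.05,
                            hole_subject_prob = 0,
                            hole_profiles = NULL,
                            hole_area_meanlog = log(12),
                            hole_area_sdlog = 1,
                            hole_area_range = c(7, 150)) {
  stopifnot(group_label %in% c("D", "T", "C"))
  patella_volume <- stats::setNames(as.numeric(patella_volume),
                                    c("mean", "sd"))
  patella_surface <- stats::setNames(as.numeric(patella_surface),
                                     c("mean", "sd"))
  sds <- c(bone_bmd$sd, patella_volume["sd"], patella_surface["sd"],
           unlist(lapply(cartilage, function(x)
             c(x$dens[2], x$vol[2], x$surf[2]))))
  if (any(sds < 0)) stop("all archetype sds must be >= 0")
  if (group_label == "C" &&
      (hole_subject_prob > 0 || !is.null(hole_profiles)))
    stop("control archetype must have zero hole mass")
  structure(list(group_label = group_label, bone_bmd = bone_bmd,
                 patella_volume = patella_volume,
                 patella_surface = patella_surface, cartilage = cartilage,
                 thinning_patch_rate = thinning_patch_rate,
                 patch_depth_range = patch_depth_range,
                 roughness_amp = roughness_amp,
                 hole_subject_prob = hole_subject_prob,
                 hole_profiles = hole_profiles,
                 hole_area_meanlog = hole_area_meanlog,
                 hole_area_sdlog = hole_area_sdlog,
                 hole_area_range = hole_area_range),
            class = "group_archetype")
}

cart_comps <- c("FemCart", "TibCartLat", "TibCartMed", "PatCart")
cart_short <- c(FemCart = "Fem", TibCartLat = "Lat", TibCartMed = "Med",
                PatCart = "Pat")
cap_angles <- c(FemCart = 1.7, TibCartLat = 1.0, TibCartMed = 1.0,
                PatCart = 1.1)

#' Default group archetypes
#'
#' Compartment moments for the degenerative (D), traumatic (T) and control
#' (C) groups: bone BMD in g/cm^3, cartilage radiodensity in HU, volumes in
#' mm^3 and surfaces in mm^2, with holes essentially confined to the
#' degenerative group. Hole-count profiles follow the per-patient hole
#' bookkeeping table shipped in `extdata`.
#' @return named list of three [group_archetype()]s.
#' @export
default_archetypes <- function() {
  cart <- function(fd, fv, fs, ld, lv, ls, md, mv, ms, pd, pv, ps) {
    list(FemCart = list(dens = fd, vol = fv, surf = fs),
         TibCartLat = list(dens = ld, vol = lv, surf = ls),
         TibCartMed = list(dens = md, vol = mv, surf = ms),
         PatCart = list(dens = pd, vol = pv, surf = ps))
  }
  d_profiles <- rbind(c(3, 1, 7, 0), c(2, 0, 0, 0), c(1, 0, 1, 0),
                      c(1, 0, 0, 1), c(1, 0, 0, 3), c(4, 0, 0, 0),
                      c(1, 0, 0, 0), c(1, 0, 0, 0))
  colnames(d_profiles) <- c("FemCart", "TibCartLat", "TibCartMed", "PatCart")
  t_profiles <- matrix(c(5, 0, 0, 2), nrow = 1,
                       dimnames = list(NULL, colnames(d_profiles)))
  list(
    D = group_archetype("D",
      bone_bmd = data.frame(compartment = c("Femur", "Tibia", "Patella"),
                            mean = c(1.25, 1.28, 1.34),
                            sd = c(0.03, 0.02, 0.05)),
      patella_volume = c(mean = 20368.41, sd = 4486.86),
      patella_surface = c(mean = 4867.88, sd = 1614.10),
      cartilage = cart(c(88.55, 5.74), c(20265.18, 6856.78),
                       c(14737.79, 2866.13),
                       c(88.45, 8.30), c(2075.11, 1515.56),
                       c(1809.96, 922.87),
                       c(104.20, 19.94), c(1526.14, 1226.54),
                       c(1702.80, 997.76),
                       c(78.98, 17.53), c(3241.89, 1164.37),
                       c(2546.89, 469.92)),
      thinning_patch_rate = 0.15, roughness_amp = 0.12,
      hole_subject_prob = 8 / 24, hole_profiles = d_profiles),
    T = group_archetype("T",
      bone_bmd = data.frame(compartment = c("Femur", "Tibia", "Patella"),
                            mean = c(1.29, 1.32, 1.41),
                            sd = c(0.03, 0.03, 0.04)),
      patella_volume = c(mean = 17747.93, sd = 4389.93),
      patella_surface = c(mean = 5648.82, sd = 3180.33),
      cartilage = cart(c(88.64, 12.34), c(13429.59, 2725.04),
                       c(12270.98, 1378.72),
                       c(91.78, 19.85), c(1110.60, 409.59),
                       c(1299.96, 437.06),
                       c(101.32, 16.70), c(981.93, 610.23),
                       c(1233.47, 469.07),
                       c(79.19, 18.27), c(2778.97, 656.93),
                       c(2443.72, 480.52)),
      thinning_patch_rate = 0.08, roughness_amp = 0.06,
      hole_subject_prob = 1 / 15, hole_profiles = t_profiles),
    C = group_archetype("C",
      bone_bmd = data.frame(compartment = c("Femur", "Tibia", "Patella"),
                            mean = c(1.27, 1.30, 1.41),
                            sd = c(0.03, 0.03, 0.05)),
      patella_volume = c(mean = 19375.79, sd = 5009.31),
      patella_surface = c(mean = 4105.83, sd = 725.54),
      cartilage = cart(c(94.06, 7.45), c(11764.49, 4479.56),
                       c(11968.50, 2663.58),
                       c(91.76, 3.10), c(757.59, 380.87),
                       c(1082.64, 371.60),
                       c(104.93, 7.65), c(555.76, 368.51),
                       c(949.80, 400.35),
                       c(95.10, 16.47), c(2866.61, 715.97),
                       c(2517.28, 409.93)),
      thinning_patch_rate = 0.02, roughness_amp = 0.03))
}

#' Write / read archetypes as JSON
#'
#' Serializes a list of [group_archetype()]s (as produced by
#' [default_archetypes()]) to a JSON configuration file and back.
#' @param archetypes named list of archetypes.
#' @param path JSON file path.
#' @return `path` invisibly / the archetype list.
#' @export
archetypes_to_json <- function(archetypes, path) {
  jsonlite::write_json(lapply(archetypes, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname archetypes_to_json
#' @export
archetypes_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(a) {
    hp <- a$hole_profiles
    if (length(hp) == 0L) hp <- NULL
    if (!is.null(hp)) {
      if (is.null(dim(hp))) hp <- matrix(hp, nrow = 1)
      hp <- as.matrix(hp)
      colnames(hp) <- c("FemCart", "TibCartLat", "TibCartMed", "PatCart")
    }
    group_archetype(a$group_label,
                    bone_bmd = as.data.frame(a$bone_bmd),
                    patella_volume = unlist(a$patella_volume),
                    patella_surface = unlist(a$patella_surface),
                    cartilage = lapply(a$cartilage, function(m)
                      lapply(m, unlist)),
                    thinning_patch_rate = a$thinning_patch_rate,
                    patch_depth_range = unlist(a$patch_depth_range),
                    roughness_amp = a$roughness_amp,
                    hole_subject_prob = a$hole_subject_prob,
                    hole_profiles = hp,
                    hole_area_meanlog = a$hole_area_meanlog,
                    hole_area_sdlog = a$hole_area_sdlog,
                    hole_area_range = unlist(a$hole_area_range))
  })
}

# moment-matched lognormal transform of standard-normal draws z
lnorm_from_z <- function(z, mean, sd) {
  if (sd <= 0) return(rep(mean, length(z)))
  s2 <- log(1 + (sd / mean)^2)
  exp(log(mean) - s2 / 2 + sqrt(s2) * z)
}

# place non-overlapping defects (holes then patches) on a cap by rejection
place_defects <- function(R, cap_angle, hole_ab, patch_radii, margin) {
  placed <- list()
  ok_pos <- function(theta, phi, r) {
    d <- as.vector(sph_dir(theta, phi))
    if (R * theta + r + 2.5 * margin > R * cap_angle) return(FALSE)
    for (p in placed) {
      gd <- R * acos(pmin(pmax(sum(d * p$dir), -1), 1))
      if (gd < r + p$r + 3 * margin) return(FALSE)
    }
    TRUE
  }
  put <- function(r) {
    for (try in 1:200) {
      theta <- sqrt(stats::runif(1)) * 0.8 * cap_angle
      phi <- stats::runif(1, 0, 2 * pi)
      if (ok_pos(theta, phi, r)) {
        placed[[length(placed) + 1L]] <<-
          list(center = c(theta, phi), r = r,
               dir = as.vector(sph_dir(theta, phi)))
        return(length(placed))
      }
    }
    NA_integer_
  }
  holes <- list()
  if (nrow(hole_ab)) {
    for (i in seq_len(nrow(hole_ab))) {
      j <- put(hole_ab$a[i])
      if (!is.na(j))
        holes[[length(holes) + 1L]] <- list(center = placed[[j]]$center,
                                            a = hole_ab$a[i], b = hole_ab$b[i],
                                            angle = stats::runif(1, 0, pi))
    }
  }
  patches <- list()
  for (r in patch_radii) {
    j <- put(r)
    if (!is.na(j))
      patches[[length(patches) + 1L]] <- list(center = placed[[j]]$center,
                                              radius = r)
  }
  list(holes = holes, patches = patches)
}

#' Generate one synthetic subject
#'
#' Draws compartment parameters from the archetype's moments, then (on
#' request) realizes the four cartilage shells as meshes and paints the
#' labeled HU voxel volume.
#'
#' @param archetype a [group_archetype()].
#' @param seed integer seed; all randomness for this subject derives from it.
#' @param subject_id identifier string.
#' @param realize character subset of `c("mesh", "voxel")`; parameter draws
#'   and ground truth are always produced.
#' @param spacing voxel spacing (mm).
#' @param hu_noise_sd additive Gaussian HU noise sd.
#' @param target_edge cartilage mesh edge length (mm); refined locally when
#'   a hole would be unresolvable at this resolution.
#' @param calibration a [calibrate_bmd()] object used to paint bone HU from
#'   drawn BMD.
#' @return a `synthetic_subject` list: `params` (drawn values), `meshes`
#'   (per cartilage compartment, from [generate_shell()]), `volume`
#'   (a [labeled_volume()]) and `ground_truth`.
#' @export
generate_subject <- function(archetype, seed, subject_id = "S1",
                             realize = c("mesh", "voxel"), spacing = 0.5,
                             hu_noise_sd = 10, target_edge = 2.5,
                             calibration = calibrate_bmd(
                               data.frame(hu = c(0, 1000),
                                          density = c(1.0, 1.8)))) {
  ar <- archetype
  params <- withr::with_seed(as.integer(seed), {
    bone <- ar$bone_bmd
    bone$bmd <- stats::rnorm(nrow(bone), bone$mean, bone$sd)
    zv <- stats::rnorm(1)
    zs <- 0.5 * zv + sqrt(1 - 0.25) * stats::rnorm(1)
    pat_vol <- lnorm_from_z(zv, ar$patella_volume["mean"],
                            ar$patella_volume["sd"])
    pat_surf <- lnorm_from_z(zs, ar$patella_surface["mean"],
                             ar$patella_surface["sd"])
    carts <- list()
    for (cc in cart_comps) {
      m <- ar$cartilage[[cc]]
      zv <- stats::rnorm(1)
      zs <- 0.8 * zv + sqrt(1 - 0.64) * stats::rnorm(1)
      vol <- lnorm_from_z(zv, m$vol[1], m$vol[2])
      surf <- lnorm_from_z(zs, m$surf[1], m$surf[2])
      dens <- min(max(stats::rnorm(1, m$dens[1], m$dens[2]), 0), 300)
      cap <- cap_angles[[cc]]
      R <- sqrt(surf / (2 * pi * (1 - cos(cap))))
      inner3 <- R^3 - 3 * vol / (2 * pi * (1 - cos(cap)))
      t <- if (inner3 <= 0) 0.6 * R else R - inner3^(1 / 3)
      t <- min(max(t, 0.15), 0.6 * R)
      vol_real <- (2 * pi / 3) * (R^3 - (R - t)^3) * (1 - cos(cap))
      carts[[cc]] <- list(dens = dens, vol = vol_real, surf = surf,
                          thickness = t, R = R, cap_angle = cap)
    }
    # holes
    hole_counts <- stats::setNames(rep(0L, 4L), cart_comps)
    if (ar$hole_subject_prob > 0 && stats::runif(1) < ar$hole_subject_prob) {
      prof <- ar$hole_profiles[sample(nrow(ar$hole_profiles), 1L), ]
      hole_counts[colnames(ar$hole_profiles)] <- as.integer(prof)
    }
    for (cc in cart_comps) {
      k <- hole_counts[[cc]]
      p <- carts[[cc]]
      hole_ab <- if (k > 0) {
        area <- pmin(pmax(stats::rlnorm(k, ar$hole_area_meanlog,
                                        ar$hole_area_sdlog),
                          ar$hole_area_range[1]), ar$hole_area_range[2])
        q <- stats::runif(k, 1, 2)
        # semi-minor axis floored at mesh-resolvable size, exact area kept
        b <- pmax(sqrt(area / (pi * q)), 1.4)
        data.frame(a = area / (pi * b), b = b)
      } else data.frame(a = numeric(0), b = numeric(0))
      # thinning patches up to the archetype's area rate
      target <- ar$thinning_patch_rate * p$surf
      radii <- numeric(0)
      while (sum(pi * radii^2) < target && length(radii) < 12L) {
        radii <- c(radii, min(stats::runif(1, 4, 8),
                              0.3 * p$R * p$cap_angle))
      }
      h_eff <- min(target_edge,
                   if (nrow(hole_ab)) min(hole_ab$b) / 1.6 else Inf)
      def <- place_defects(p$R, p$cap_angle, hole_ab, radii, margin = h_eff)
      depth <- vapply(def$patches, function(pp)
        stats::runif(1, ar$patch_depth_range[1], ar$patch_depth_range[2]) *
          p$thickness, numeric(1))
      carts[[cc]]$holes <- def$holes
      carts[[cc]]$patches <- Map(function(pp, dd) {
        pp$depth <- dd; pp
      }, def$patches, as.list(depth))
      carts[[cc]]$target_edge <- h_eff
    }
    list(bone = bone, patella_volume = unname(pat_vol),
         patella_surface = unname(pat_surf), cartilage = carts)
  })

  meshes <- NULL
  if ("mesh" %in% realize) {
    meshes <- list()
    for (cc in cart_comps) {
      p <- params$cartilage[[cc]]
      meshes[[cc]] <- generate_shell(
        base_radius = p$R, nominal_thickness = p$thickness,
        cap_angle = p$cap_angle, thinning_patches = p$patches,
        holes = p$holes, target_edge = p$target_edge,
        roughness_amp = ar$roughness_amp,
        seed = (as.integer(seed) + match(cc, cart_comps)) %% 2147483647L)
    }
  }
  volume <- if ("voxel" %in% realize) {
    paint_subject_volume(params, seed = seed, spacing = spacing,
                         hu_noise_sd = hu_noise_sd,
                         calibration = calibration)
  } else NULL

  gt_holes <- lapply(params$cartilage, function(p) {
    if (length(p$holes) == 0L)
      return(data.frame(a = numeric(0), b = numeric(0), area = numeric(0)))
    data.frame(a = vapply(p$holes, function(h) max(h$a, h$b), numeric(1)),
               b = vapply(p$holes, function(h) min(h$a, h$b), numeric(1)),
               area = vapply(p$holes, function(h) pi * h$a * h$b, numeric(1)))
  })
  structure(list(subject_id = subject_id, group = ar$group_label,
                 params = params, meshes = meshes, volume = volume,
                 ground_truth = list(
                   holes = gt_holes,
                   n_holes = vapply(gt_holes, nrow, integer(1)),
                   densities = vapply(params$cartilage, function(p) p$dens,
                                      numeric(1)),
                   volumes = vapply(params$cartilage, function(p) p$vol,
                                    numeric(1)),
                   surfaces = vapply(params$cartilage, function(p) p$surf,
                                     numeric(1)),
                   thicknesses = vapply(params$cartilage,
                                        function(p) p$thickness, numeric(1)))),
            class = "synthetic_subject")
}

# Paint the labeled HU volume: compartments in disjoint sub-boxes along z.
paint_subject_volume <- function(params, seed, spacing, hu_noise_sd,
                                 calibration, background_hu = 40) {
  vv <- spacing^3
  specs <- list()
  add_spec <- function(name, kind, mm_extent, hu_mean, n_target = NULL,
                       axes = NULL) {
    specs[[name]] <<- list(kind = kind, mm = mm_extent, hu = hu_mean,
                           n = n_target, axes = axes)
  }
  bone <- params$bone
  hu_of <- function(bmd) invert_bmd(calibration, bmd)
  add_spec("FemurBone", "slab", c(30, 30, 16), hu_of(bone$bmd[1]))
  add_spec("TibiaBone", "slab", c(30, 30, 16), hu_of(bone$bmd[2]))
  # patella: oblate spheroid matching drawn volume and surface
  pv <- params$patella_volume; ps <- params$patella_surface
  sphereS <- (36 * pi)^(1 / 3) * pv^(2 / 3)
  rho <- if (ps <= sphereS * 1.001) 1 else {
    ob_s <- function(rho) {
      a <- (3 * pv / (4 * pi * rho))^(1 / 3)
      c_ <- rho * a
      e <- sqrt(max(1 - rho^2, 1e-12))
      2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e)) - ps
    }
    stats::uniroot(ob_s, c(0.02, 0.999))$root
  }
  pa <- (3 * pv / (4 * pi * rho))^(1 / 3)
  add_spec("PatellaBone", "ellipsoid", 2 * c(pa, pa, rho * pa) + 4,
           hu_of(bone$bmd[3]), n_target = round(pv / vv),
           axes = c(pa, pa, rho * pa))
  for (cc in cart_comps) {
    p <- params$cartilage[[cc]]
    n <- round(p$vol / vv)
    r <- (3 * p$vol / (4 * pi))^(1 / 3)
    add_spec(cc, "ball", 2 * c(r, r, r) + 4, p$dens, n_target = n)
  }
  # layout sub-boxes along z
  gap <- 3L
  dims_vox <- lapply(specs, function(s) pmax(ceiling(s$mm / spacing), 3L) + 2L)
  nx <- max(vapply(dims_vox, `[`, numeric(1), 1)) + 2L
  ny <- max(vapply(dims_vox, `[`, numeric(1), 2)) + 2L
  nz <- sum(vapply(dims_vox, `[`, numeric(1), 3)) + gap * (length(specs) + 1L)
  hu <- array(background_hu, c(nx, ny, nz))
  labels <- array(0L, c(nx, ny, nz))
  z0 <- gap
  for (li in seq_along(specs)) {
    nm <- names(specs)[li]
    s <- specs[[nm]]
    dv <- dims_vox[[nm]]
    cx <- round((nx + 1) / 2); cy <- round((ny + 1) / 2)
    cz <- z0 + (dv[3] + 1) / 2
    xs <- seq_len(nx); ys <- seq_len(ny); zs <- (z0 + 1):(z0 + dv[3])
    if (s$kind == "slab") {
      hx <- floor(s$mm[1] / spacing / 2); hy <- floor(s$mm[2] / spacing / 2)
      hz <- floor(s$mm[3] / spacing / 2)
      labels[(cx - hx):(cx + hx), (cy - hy):(cy + hy),
             round(cz - hz):round(cz + hz)] <- li
    } else {
      ax <- if (s$kind == "ball") rep((3 * (s$n * vv) / (4 * pi))^(1 / 3), 3)
            else s$axes
      dx2 <- ((xs - cx) * spacing / ax[1])^2
      dy2 <- ((ys - cy) * spacing / ax[2])^2
      dz2 <- ((zs - cz) * spacing / ax[3])^2
      q <- outer(outer(dx2, dy2, "+"), dz2, "+")
      # exact voxel count: take the n voxels with smallest quadratic form
      ord <- order(q)[seq_len(min(s$n, length(q)))]
      sub <- array(0L, dim(q))
      sub[ord] <- li
      labels[, , zs] <- sub
    }
    z0 <- z0 + dv[3] + gap
  }
  hu[labels > 0L] <- vapply(specs, `[[`, numeric(1), "hu")[labels[labels > 0L]]
  noise_seed <- (as.integer(seed) + 104729L) %% 2147483647L
  hu <- hu + withr::with_seed(noise_seed,
                              array(stats::rnorm(length(hu), 0, hu_noise_sd),
                                    dim(hu)))
  labeled_volume(hu, spacing = spacing, labels = labels,
                 mask_names = names(specs))
}

#' Generate a synthetic cohort
#'
#' Default sizes 24 degenerative, 15 traumatic, 8 control. Reproducible for
#' a fixed seed; emits a ground-truth manifest.
#'
#' @param n_d,n_t,n_c group sizes.
#' @param seed integer master seed.
#' @param archetypes list of [group_archetype()]s (default
#'   [default_archetypes()]).
#' @param realize what to realize per subject (see [generate_subject()]).
#' @param callback optional `function(subject)` invoked per subject; when
#'   given, heavy per-subject data (meshes, volume) are not retained and the
#'   callback's return values are collected instead.
#' @param ... passed to [generate_subject()].
#' @return list with `manifest` (data.frame) and `subjects` (list of
#'   subjects, or of callback results).
#' @export
generate_cohort <- function(n_d = 24, n_t = 15, n_c = 8, seed = 1,
                            archetypes = default_archetypes(),
                            realize = c("mesh", "voxel"), callback = NULL,
                            ...) {
  stopifnot(n_d >= 0, n_t >= 0, n_c >= 0)
  groups <- c(rep("D", n_d), rep("T", n_t), rep("C", n_c))
  subjects <- list()
  rows <- list()
  for (i in seq_along(groups)) {
    sid <- sprintf("S%03d", i)
    sseed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483647L
    subj <- generate_subject(archetypes[[groups[i]]], seed = sseed,
                             subject_id = sid, realize = realize, ...)
    gt <- subj$ground_truth
    row <- data.frame(subject_id = sid, group = groups[i], seed = sseed)
    for (cc in cart_comps) {
      sh <- cart_short[[cc]]
      row[[paste0("dens_", sh)]] <- gt$densities[[cc]]
      row[[paste0("vol_", sh)]] <- gt$volumes[[cc]]
      row[[paste0("surf_", sh)]] <- gt$surfaces[[cc]]
      row[[paste0("thick_", sh)]] <- gt$thicknesses[[cc]]
      row[[paste0("holes_", sh)]] <- gt$n_holes[[cc]]
      row[[paste0("holearea_", sh)]] <- sum(gt$holes[[cc]]$area)
    }
    row$patella_volume <- subj$params$patella_volume
    row$patella_surface <- subj$params$patella_surface
    for (b in seq_len(nrow(subj$params$bone)))
      row[[paste0("bmd_", subj$params$bone$compartment[b])]] <-
        subj$params$bone$bmd[b]
    rows[[i]] <- row
    subjects[[i]] <- if (is.null(callback)) subj else callback(subj)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0))
  list(manifest = manifest, subjects = subjects)
}
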