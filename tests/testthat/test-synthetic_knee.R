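test_that("uniform shell has exact offset geometry and ground truth", {
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2, target_edge = 2, seed = 1)
  expect_true(is_closed(sh$closed))
  expect_equal(euler_characteristic(sh$closed), 2L)
  expect_true(all(sh$ground_truth$thickness == 2))
  expect_equal(sh$ground_truth$n_holes, 0L)
  expect_lt(abs(surface_area(sh$outer_patch) /
                  sh$ground_truth$outer_area - 1), 0.01)
  expect_lt(abs(enclosed_volume(sh$closed) /
                  sh$ground_truth$shell_volume - 1), 0.01)
})

test_that("a hole with semi-axes 2.523 mm records the 20 mm^2 grade boundary", {
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2,
                       holes = list(list(center = c(0.7, 1), a = 2.523,
                                         b = 2.523)),
                       target_edge = 1.5, seed = 1)
  expect_equal(sh$ground_truth$holes$area, pi * 2.523^2)
  expect_equal(sh$ground_truth$holes$area, 20, tolerance = 1e-3)
  expect_equal(grade_from_area(sh$ground_truth$holes$area), 1L)
})

test_that("thinning patches produce a bimodal thickness field with the right mass", {
  rp <- 8
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2,
                       thinning_patches = list(list(center = c(0.8, 2),
                                                    radius = rp, depth = 1)),
                       target_edge = 1, seed = 2)
  gt <- sh$ground_truth$thickness
  expect_setequal(unique(gt), c(1, 2))
  areas <- face_areas(sh$outer_patch)
  frac <- sum(areas[gt == 1]) / sum(areas)
  frac_true <- 2 * pi * 40^2 * (1 - cos(rp / 40)) /
    (2 * pi * 40^2 * (1 - cos(pi / 2)))
  expect_lt(abs(frac / frac_true - 1), 0.15)
})

test_that("shell topology encodes the hole count (Euler and boundary loops)", {
  for (g in 0:3) {
    holes <- lapply(seq_len(g), function(k)
      list(center = c(0.35 + 0.28 * k, 1.9 * k), a = 2.5, b = 2))
    sh <- generate_shell(base_radius = 35, nominal_thickness = 2,
                         cap_angle = 1.8, holes = holes,
                         target_edge = 1.2, seed = g + 1)
    expect_true(is_closed(sh$closed))
    expect_equal(euler_characteristic(sh$closed), 2L - 2L * g)
    loops <- boundary_loops(sh$outer_patch)
    ninterior <- sum(vapply(loops, function(l) l$classification, "") ==
                       "interior")
    expect_equal(ninterior, g)
  }
})

test_that("defect validation rejects overlap and under-refinement", {
  expect_error(generate_shell(
    base_radius = 40, nominal_thickness = 2, cap_angle = pi / 2,
    holes = list(list(center = c(0.5, 1), a = 3, b = 3),
                 list(center = c(0.5, 1.05), a = 3, b = 3)),
    target_edge = 1, seed = 1), "overlap")
  expect_error(generate_shell(
    base_radius = 40, nominal_thickness = 2, cap_angle = pi / 2,
    holes = list(list(center = c(0.5, 1), a = 1, b = 1)),
    refinement = 15, seed = 1), "minimum refinement")
  expect_error(generate_shell(
    base_radius = 40, nominal_thickness = 2, cap_angle = pi / 2,
    thinning_patches = list(list(center = c(0.5, 1), radius = 5, depth = 3)),
    seed = 1), "depth")
})

test_that("control archetype yields zero holes for any seed", {
  ar <- default_archetypes()
  for (seed in c(2, 33, 444)) {
    s <- generate_subject(ar$C, seed = seed, realize = character(0))
    expect_true(all(s$ground_truth$n_holes == 0))
  }
})

test_that("cohort structure, determinism and empty edge case", {
  coh <- generate_cohort(3, 2, 1, seed = 5, realize = character(0))
  expect_equal(nrow(coh$manifest), 6L)
  expect_equal(as.vector(table(coh$manifest$group)[c("D", "T", "C")]),
               c(3L, 2L, 1L))
  coh2 <- generate_cohort(3, 2, 1, seed = 5, realize = character(0))
  expect_identical(coh$manifest, coh2$manifest)
  coh3 <- generate_cohort(3, 2, 1, seed = 6, realize = character(0))
  expect_false(identical(coh$manifest, coh3$manifest))

  empty <- generate_cohort(0, 0, 0, seed = 1, realize = character(0))
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("archetypes round-trip through JSON and reproduce draws", {
  ar <- default_archetypes()
  tmp <- withr::local_tempfile(fileext = ".json")
  archetypes_to_json(ar, tmp)
  back <- archetypes_from_json(tmp)
  expect_equal(names(back), c("D", "T", "C"))
  s1 <- generate_subject(ar$D, seed = 77, realize = character(0))
  s2 <- generate_subject(back$D, seed = 77, realize = character(0))
  expect_equal(s1$ground_truth$volumes, s2$ground_truth$volumes)
  expect_equal(s1$ground_truth$n_holes, s2$ground_truth$n_holes)
  # control invariant survives the round trip
  expect_error(group_archetype("C", back$C$bone_bmd, back$C$patella_volume,
                               back$C$patella_surface, back$C$cartilage,
                               hole_subject_prob = 0.5),
               "zero hole mass")
})

test_that("drawn cohort moments converge to the archetype moments", {
  # n = 1000 subjects from the degenerative archetype: the sample mean of
  # the femoral cartilage volume must sit within 3 standard errors
  ar <- default_archetypes()
  coh <- generate_cohort(1000, 0, 0, seed = 11, realize = character(0))
  m <- coh$manifest
  mu <- 20265.18; sdv <- 6856.78
  expect_lt(abs(mean(m$vol_Fem) - mu), 3 * sdv / sqrt(1000))
  # same for a density (Gaussian path) and the patella surface (lognormal)
  expect_lt(abs(mean(m$dens_Fem) - 88.55), 3 * 5.74 / sqrt(1000))
  expect_lt(abs(mean(m$patella_surface) - 4867.88), 3 * 1614.10 / sqrt(1000))
})

test_that("degenerate archetype (all sds zero) yields identical draws", {
  ar <- default_archetypes()$C
  ar$bone_bmd$sd <- rep(0, 3)
  ar$patella_volume["sd"] <- 0
  ar$patella_surface["sd"] <- 0
  for (cc in names(ar$cartilage)) {
    ar$cartilage[[cc]]$dens[2] <- 0
    ar$cartilage[[cc]]$vol[2] <- 0
    ar$cartilage[[cc]]$surf[2] <- 0
  }
  ar$thinning_patch_rate <- 0
  s1 <- generate_subject(ar, seed = 1, realize = character(0))
  s2 <- generate_subject(ar, seed = 999, realize = character(0))
  expect_equal(s1$ground_truth$densities, s2$ground_truth$densities)
  expect_equal(s1$ground_truth$volumes, s2$ground_truth$volumes)
  expect_equal(s1$ground_truth$surfaces, s2$ground_truth$surfaces)
})

test_that("labeled volumes are disjoint and realize drawn volumes", {
  ar <- default_archetypes()
  s <- generate_subject(ar$T, seed = 21, realize = "voxel", spacing = 0.5)
  vol <- s$volume
  expect_s3_class(vol, "labeled_volume")
  expect_equal(length(vol$mask_names), 7L)
  vv <- prod(vol$spacing)
  for (cc in c("FemCart", "TibCartLat", "TibCartMed", "PatCart")) {
    st <- mask_density_stats(vol, cc)
    expect_lt(abs(st$volume_mm3 / s$ground_truth$volumes[[cc]] - 1), 0.01)
    expect_lt(abs(st$mean_hu - s$ground_truth$densities[[cc]]),
              4 * 10 / sqrt(st$n_voxels) + 0.5)
  }
})
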