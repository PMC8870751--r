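test_that("wall thickness recovers the uniform-shell offset", {
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2, target_edge = 2, seed = 1)
  n_outer <- nrow(sh$outer_patch$faces)
  wt <- wall_thickness(sh$closed, faces = seq_len(n_outer))
  v <- wt$values[seq_len(n_outer)][wt$valid[seq_len(n_outer)]]
  expect_gte(mean(v >= 1.9 & v <= 2.1), 0.99)
})

test_that("wall thickness on a slab is the exact plate separation", {
  slab <- box_slab(L = 10, t = 3.5)
  # subdivide top/bottom faces for interior sampling: use a generated fine
  # slab instead, built from two offset flat grids joined by the generator
  # contract here: measure the coarse slab's two z-faces directly
  wt <- wall_thickness(slab)
  cents <- face_centroids(slab)
  zfaces <- which(abs(face_normals(slab)[, 3]) > 0.99)
  expect_true(all(abs(wt$values[zfaces] - 3.5) < 1e-9))
})

test_that("thickness field reflects thinning patches", {
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2,
                       thinning_patches = list(list(center = c(0.8, 2),
                                                    radius = 6, depth = 1)),
                       target_edge = 1.5, seed = 2)
  n_outer <- nrow(sh$outer_patch$faces)
  wt <- wall_thickness(sh$closed, faces = seq_len(n_outer))
  gt <- sh$ground_truth$thickness
  v <- wt$values[seq_len(n_outer)]
  agree <- abs(v - gt) < 0.15
  expect_gte(mean(agree, na.rm = TRUE), 0.98)
  expect_lt(abs(mean(v[gt == 1], na.rm = TRUE) - 1), 0.1)
  expect_lt(abs(mean(v[gt == 2], na.rm = TRUE) - 2), 0.1)
})

test_that("thickness is rigid-motion invariant and scales with the mesh", {
  sh <- generate_shell(base_radius = 15, nominal_thickness = 1.5,
                       cap_angle = 1.0, target_edge = 2, seed = 5)
  n_outer <- nrow(sh$outer_patch$faces)
  sel <- seq_len(min(n_outer, 300))
  wt0 <- wall_thickness(sh$closed, faces = sel)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- sh$closed
  moved$vertices <- moved$vertices %*% rot +
    matrix(c(3, 4, 5), nrow(moved$vertices), 3, byrow = TRUE)
  wt1 <- wall_thickness(moved, faces = sel)
  expect_equal(wt0$values[sel], wt1$values[sel], tolerance = 1e-6)
  scaled <- sh$closed
  scaled$vertices <- scaled$vertices * 2.5
  wt2 <- wall_thickness(scaled, faces = sel)
  expect_equal(wt2$values[sel], 2.5 * wt0$values[sel], tolerance = 1e-6)
})

test_that("wall thickness rejects open surfaces", {
  expect_error(wall_thickness(flat_grid_mesh(5, 5)), "open patches")
})

test_that("angle-deficit curvature matches the analytic sphere", {
  s <- icosphere(10, 3)
  gc_ <- gaussian_curvature(s)
  expect_true(all(gc_$valid))
  expect_lt(max(abs(gc_$values / 0.01 - 1)), 0.06)
  expect_lt(abs(mean(gc_$values) / 0.01 - 1), 0.01)
})

test_that("planar interior curvature is zero and boundaries are flagged", {
  g <- flat_grid_mesh(12, 12)
  gc_ <- gaussian_curvature(g)
  interior <- gc_$valid
  expect_true(any(interior))
  expect_true(all(abs(gc_$values[interior]) < 1e-9))
  # faces whose vertices all lie on the rim have no valid vertex value
  expect_true(any(!gc_$valid))
})

test_that("total angle deficit equals 2 pi chi on closed meshes (Gauss-Bonnet)", {
  fixtures <- list(
    unit_cube_mesh(),
    icosphere(5, 2),
    generate_shell(base_radius = 30, nominal_thickness = 2, cap_angle = 1.5,
                   holes = list(list(center = c(0.6, 1), a = 3, b = 2),
                                list(center = c(0.6, 4), a = 2, b = 2)),
                   target_edge = 1.2, seed = 7)$closed)
  for (s in fixtures) {
    ad <- angle_deficits(s)
    total <- sum(ad$deficit, na.rm = TRUE)
    chi <- euler_characteristic(s)
    expect_lt(abs(total - 2 * pi * chi) / (2 * pi * max(abs(chi), 1)), 1e-8)
  }
})

test_that("hole detection fits circles and ellipses to their true areas", {
  sh <- generate_shell(base_radius = 40, nominal_thickness = 2,
                       cap_angle = pi / 2,
                       holes = list(list(center = c(0.7, 1), a = 3, b = 3),
                                    list(center = c(0.5, 3.5), a = 4, b = 2)),
                       target_edge = 1.2, seed = 2)
  hd <- detect_holes(sh$outer_patch)
  expect_equal(nrow(hd), 2L)
  hd <- hd[order(hd$area), ]
  expect_lt(abs(hd$area[1] / (pi * 4 * 2) - 1), 0.05)   # 25.13 mm^2
  expect_lt(abs(hd$area[2] / (pi * 9) - 1), 0.05)       # 28.27 mm^2
  expect_lt(abs(hd$a[1] / 4 - 1), 0.05)
  expect_lt(abs(hd$b[1] / 2 - 1), 0.05)
})

test_that("hole-count recovery is exact for 0..5 holes with accurate areas", {
  for (g in 0:5) {
    holes <- lapply(seq_len(g), function(k)
      list(center = c(0.3 + 0.22 * k, 1.1 * k), a = 2.6, b = 2.1))
    sh <- generate_shell(base_radius = 38, nominal_thickness = 2,
                         cap_angle = 1.9, holes = holes,
                         target_edge = 1, seed = 30 + g)
    hd <- detect_holes(sh$outer_patch)
    expect_equal(nrow(hd), g)
    if (g > 0) {
      big <- hd$n_vertices >= 30
      expect_true(all(abs(hd$area[big] / (pi * 2.6 * 2.1) - 1) < 0.10))
    }
  }
})

test_that("closed input yields no hole records, open patch without holes empty", {
  expect_message(hd <- detect_holes(unit_cube_mesh()), "genus")
  expect_equal(nrow(hd), 0L)
  expect_equal(nrow(detect_holes(flat_grid_mesh(6, 6))), 0L)
})

test_that("compartment grading follows the inclusive 20 mm^2 rule", {
  expect_equal(grade_from_area(186.83), 2L)   # largest femoral total
  expect_equal(grade_from_area(1.18), 1L)     # small lateral tibial total
  expect_equal(grade_from_area(20), 1L)       # boundary inclusive
  expect_equal(grade_from_area(20 + 1e-9), 2L)
  expect_equal(grade_from_area(0, n_holes = 0L), 0L)

  none <- grade_compartment(detect_holes(flat_grid_mesh(5, 5)))
  expect_equal(none$grade, 0L)
  expect_equal(none$total_area, 0)
})

test_that("reference hole table reproduces the printed bookkeeping", {
  tab <- hole_reference_table()
  expect_equal(nrow(tab), 9L)
  expect_equal(sum(tab$group == "D"), 8L)
  expect_equal(sum(tab$group == "T"), 1L)
  grades <- vapply(seq_len(nrow(tab)), function(i)
    grade_from_area(tab$fem_area[i], tab$fem_count[i]), integer(1))
  expect_equal(grades[tab$patient == 2], 2L)   # 186.83 mm^2
  lat1 <- grade_from_area(tab$lat_area[tab$patient == 1],
                          tab$lat_count[tab$patient == 1])
  expect_equal(lat1, 1L)                        # 1.18 mm^2
})
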