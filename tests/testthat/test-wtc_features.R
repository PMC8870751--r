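# two-triangle surface with prescribed areas 0.5 and 1.0
two_tri_surface <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 0, 0), c(7, 0, 0), c(5, 1, 0))
  tri_surface(v, rbind(c(1, 2, 3), c(4, 5, 6)))
}

test_that("area normalization multiplies values by element areas", {
  s <- two_tri_surface()
  f <- element_field(s, c(2, 3), analysis_kind = "wall")
  nf <- normalize_by_area(f)
  expect_equal(nf$values, c(1, 3))
  expect_equal(nf$ne, 2L)
  # invalid elements are excluded from NE
  f2 <- element_field(s, c(2, 3), analysis_kind = "wall",
                      valid = c(TRUE, FALSE))
  expect_equal(normalize_by_area(f2)$ne, 1L)
  f3 <- element_field(s, c(2, 3), analysis_kind = "wall",
                      valid = c(FALSE, FALSE))
  expect_error(normalize_by_area(f3), "no valid")
})

test_that("uniform-area meshes leave scale-free statistics unchanged", {
  g <- flat_grid_mesh(10, 10)       # all faces area 0.5
  withr::with_seed(3, x <- runif(nrow(g$faces)))
  f <- element_field(g, x, analysis_kind = "wall")
  nf <- normalize_by_area(f)
  expect_equal(nf$values, 0.5 * x)
  for (a in c(0, 0.5, 1, 2))
    expect_equal(w_percent(nf, a), w_percent(x, a))
})

test_that("normalized sum matches an independent accumulation", {
  sh <- generate_shell(base_radius = 20, nominal_thickness = 2,
                       cap_angle = 1.2, target_edge = 2.5, seed = 8)
  s <- sh$outer_patch
  withr::with_seed(4, x <- rlnorm(nrow(s$faces)))
  nf <- normalize_by_area(element_field(s, x, analysis_kind = "wall"))
  # element-by-element oracle: areas from Heron's formula in a plain loop
  tot <- 0
  for (i in seq_len(nrow(s$faces))) {
    p <- s$vertices[s$faces[i, ], ]
    ab <- sqrt(sum((p[2, ] - p[1, ])^2))
    bc <- sqrt(sum((p[3, ] - p[2, ])^2))
    ca <- sqrt(sum((p[1, ] - p[3, ])^2))
    sp <- (ab + bc + ca) / 2
    tot <- tot + sqrt(sp * (sp - ab) * (sp - bc) * (sp - ca)) * x[i]
  }
  expect_equal(sum(nf$values), tot, tolerance = 1e-9)
})

test_that("summary parameters match hand arithmetic and a two-pass oracle", {
  expect_equal(summary_params(c(1, 1, 1, 1)),
               list(mean = 1, std = 0, var = 0, rms = 1))
  sp <- summary_params(c(0, 2))
  expect_equal(sp$mean, 1)
  expect_equal(sp$var, 2)
  expect_equal(sp$std, sqrt(2))
  expect_equal(sp$rms, sqrt(2))
  expect_error(summary_params(c(1)), "NE >= 2")

  withr::with_seed(9, y <- rnorm(1e4, 5, 3))
  sp <- summary_params(y)
  # streaming two-pass oracle
  m <- sum(y) / length(y)
  v <- sum((y - m)^2) / (length(y) - 1)
  expect_equal(sp$mean, m, tolerance = 1e-10)
  expect_equal(sp$var, v, tolerance = 1e-10)
  expect_equal(sp$rms, sqrt(sum(y^2) / length(y)), tolerance = 1e-10)
  # RMS^2 = mean^2 + VAR * (n-1)/n
  n <- length(y)
  expect_equal(sp$rms^2, sp$mean^2 + sp$var * (n - 1) / n, tolerance = 1e-10)
})

test_that("tail fractions match brute-force counts and handle degeneracy", {
  expect_equal(w_percent(c(5, 5, 5, 5), 1), 0)
  expect_equal(c_percent(c(5, 5, 5, 5), 1), 0)
  # worked example: mean 2, sd sqrt(20); threshold below zero -> fraction 0
  y <- c(0, 0, 0, 0, 10)
  expect_equal(w_percent(y, 0.5), 0)
  expect_equal(mean(y < mean(y) - 0.5 * sd(y)), 0)

  withr::with_seed(12, y <- rlnorm(1e4, 0, 1))
  for (a in c(0, 0.5, 1, 2, 5)) {
    expect_equal(w_percent(y, a), mean(y < mean(y) - a * sd(y)))
    expect_equal(c_percent(y, a), mean(y > mean(y) + a * sd(y)))
  }
  # partition at the strict inequality for alpha = 0
  expect_equal(w_percent(y, 0) + mean(y >= mean(y)), 1)
  # symmetric data: mirrored fractions agree at alpha = 0
  ys <- c(y, -y)
  expect_equal(w_percent(ys, 0.3), c_percent(ys, 0.3))
})

test_that("tail fractions are scale invariant, monotone in alpha, in [0,1]", {
  sh <- generate_shell(base_radius = 20, nominal_thickness = 2,
                       cap_angle = 1.2, target_edge = 2.5, seed = 13)
  s <- sh$outer_patch
  withr::with_seed(14, x <- rgamma(nrow(s$faces), 2, 1))
  nf <- normalize_by_area(element_field(s, x, analysis_kind = "wall"))
  scaled <- nf
  scaled$values <- nf$values * 37.5   # uniform area rescale scales Y, mu, sigma
  grid <- seq(0, 3, by = 0.25)
  wp <- vapply(grid, function(a) w_percent(nf, a), numeric(1))
  cp <- vapply(grid, function(a) c_percent(nf, a), numeric(1))
  expect_equal(wp, vapply(grid, function(a) w_percent(scaled, a), numeric(1)))
  expect_equal(cp, vapply(grid, function(a) c_percent(scaled, a), numeric(1)))
  expect_true(all(diff(wp) <= 0))
  expect_true(all(diff(cp) <= 0))
  expect_true(all(wp >= 0 & wp <= 1 & cp >= 0 & cp <= 1))
})

test_that("alpha selection maximizes group separation deterministically", {
  # construct two groups separated only at moderate alpha: group 1 has a
  # heavy lower tail; group 2 is clean
  withr::with_seed(15, {
    make_nf <- function(contaminated) {
      y <- rnorm(400, 10, 1)
      if (contaminated) y[1:40] <- rnorm(40, 6.5, 0.3)
      structure(list(values = y, ne = length(y), analysis_kind = "wall"),
                class = "normalized_field")
    }
    fields <- c(lapply(1:8, function(i) make_nf(TRUE)),
                lapply(1:8, function(i) make_nf(FALSE)))
    labels <- rep(c("D", "C"), each = 8)
    sel <- select_alpha(fields, labels, grid = seq(0, 3, 0.5), kind = "wall")
    # exhaustive check over the grid
    hs <- vapply(seq(0, 3, 0.5), function(a) {
      p <- vapply(fields, w_percent, numeric(1), alpha = a)
      kruskal_wallis(split(p, labels))$H
    }, numeric(1))
    expect_equal(sel$alpha, seq(0, 3, 0.5)[which.max(hs)])
    expect_equal(sel$H, max(hs))
    # singleton grid returns its only candidate
    expect_equal(select_alpha(fields, labels, grid = 0.5,
                              kind = "wall")$alpha, 0.5)
  })
  # all-identical fields warn and return the smallest alpha
  const <- lapply(1:6, function(i)
    structure(list(values = rep(1, 10), ne = 10, analysis_kind = "wall"),
              class = "normalized_field"))
  expect_warning(
    res <- select_alpha(const, rep(c("D", "C"), 3), grid = c(0.5, 1)),
    "no alpha")
  expect_equal(res$alpha, 0.5)
})

test_that("default STD weights carry the published configuration", {
  al <- default_alphas()
  expect_equal(al$wall[["Fem"]], 0.5)
  expect_equal(al$wall[["Pat"]], 0.5)
  expect_equal(al$wall[["Med"]], 0.5)
  expect_equal(al$wall[["Lat"]], 0.3)
  expect_true(all(al$curvature == 5))
})

test_that("the assembled block has 48 named parameters with constant alphas", {
  withr::with_seed(16, {
    mk <- function(kind) {
      sh <- flat_grid_mesh(6, 6)
      normalize_by_area(element_field(sh, rlnorm(nrow(sh$faces)),
                                      analysis_kind = kind))
    }
    analyses <- list()
    for (comp in c("Fem", "Pat", "Lat", "Med")) {
      analyses[[paste0(comp, ".wall")]] <- mk("wall")
      analyses[[paste0(comp, ".curvature")]] <- mk("curvature")
    }
  })
  blk <- assemble_wtc_block(analyses)
  expect_length(blk, 48L)
  expect_true(all(c("FemWallBelowSTDWeight", "PatWallVar", "LatWallMean",
                    "FemWallRMS", "FemCurvAboveSTDWeight") %in% names(blk)))
  expect_equal(unname(blk["FemWallSTDWeight"]), 0.5)
  expect_equal(unname(blk["LatWallSTDWeight"]), 0.3)
  expect_equal(unname(blk["MedCurvSTDWeight"]), 5)
  expect_error(assemble_wtc_block(analyses[-1]), "missing analyses")
})
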