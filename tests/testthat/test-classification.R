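# build a small labelled feature table for classifier checks
make_blob_table <- function(n_per_class = 30, n_features = 6, sep = 4,
                            seed = 1) {
  withr::with_seed(seed, {
    k <- 3
    x <- do.call(rbind, lapply(seq_len(k), function(c_) {
      matrix(rnorm(n_per_class * n_features, mean = sep * c_), n_per_class)
    }))
    colnames(x) <- paste0("f", seq_len(n_features))
    list(table = as.data.frame(x),
         labels = factor(rep(c("D", "T", "C"), each = n_per_class),
                         levels = c("D", "T", "C")))
  })
}

test_that("feature selections have the documented column sets", {
  fb <- feature_blocks()
  tab <- as.data.frame(matrix(rnorm(5 * 72), nrow = 5))
  names(tab) <- c(fb$bone, fb$cartilage, fb$wtc)
  expect_equal(names(build_selection(tab, "Bone")),
               c("FemurDENS", "FemurSTD", "TibiaDENS", "TibiaSTD",
                 "PatellaDENS", "PatellaSTD", "PatellaVOL", "PatellaSURF"))
  expect_equal(ncol(build_selection(tab, "Cartilage")), 16L)
  expect_equal(ncol(build_selection(tab, "B-C")), 24L)
  # 48 raw minus the 8 constant STD-weight columns
  wtc <- build_selection(tab, "WT-C")
  expect_equal(ncol(wtc), 40L)
  expect_false(any(grepl("(?<!Below|Above)STDWeight$", names(wtc),
                         perl = TRUE)))
  expect_true("FemWallBelowSTDWeight" %in% names(wtc))
  expect_equal(ncol(build_selection(tab, "TOT")), 64L)
  # configured unstable features are removed from WT-C and TOT
  expect_equal(ncol(build_selection(tab, "WT-C",
                                    unstable = c("FemWallVar", "PatCurvRMS"))),
               38L)
  expect_error(build_selection(tab, "Everything"), "unknown selection")
  # hole columns are never selected
  tab$HoleCountFem <- 1
  expect_false(any(grepl("Hole", names(build_selection(tab, "TOT")))))
})

test_that("unstable-feature screening flags high-CV columns", {
  fb <- feature_blocks()
  tab <- as.data.frame(matrix(abs(rnorm(40 * 72)) + 5, nrow = 40))
  names(tab) <- c(fb$bone, fb$cartilage, fb$wtc)
  tab$FemWallVar <- c(rep(0.001, 39), 1000)   # sample CV ~ 6.2
  uns <- unstable_wtc_features(tab, cv_threshold = 5)
  expect_true("FemWallVar" %in% uns)
  expect_false("FemurDENS" %in% uns)   # only WT-C columns are screened
})

test_that("a single perfectly informative feature is learned exactly by DT", {
  labs <- factor(rep(c("D", "T", "C"), each = 10), levels = c("D", "T", "C"))
  tab <- data.frame(x = as.integer(labs))
  rep_ <- crossval_classify(tab, labs, algorithm = "DT", k = 5, seed = 1)
  expect_equal(rep_$accuracy, 100)
})

test_that("well-separated classes reach high accuracy for all learners", {
  d <- make_blob_table(sep = 5, seed = 2)
  for (alg in c("RF", "DT", "GB")) {
    rep_ <- crossval_classify(d$table, d$labels, algorithm = alg, k = 5,
                              seed = 3)
    expect_gte(rep_$accuracy, 95)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  # 150 subjects keep the single-draw chance sd near 3.9%, so 20 draws sit
  # inside the binomial band around 33%
  d <- make_blob_table(n_per_class = 50, sep = 5, seed = 4)
  accs <- vapply(1:20, function(s) {
    labs <- withr::with_seed(1000 + s, sample(d$labels))
    crossval_classify(d$table, labs, algorithm = "RF", k = 5,
                      seed = s)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 20 & accs <= 47))
})

test_that("reports are self-consistent and deterministic", {
  d <- make_blob_table(n_per_class = 15, sep = 1.5, seed = 6)
  r1 <- crossval_classify(d$table, d$labels, algorithm = "RF", k = 5,
                          seed = 11)
  r2 <- crossval_classify(d$table, d$labels, algorithm = "RF", k = 5,
                          seed = 11)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(r1$accuracy, 100 * sum(diag(r1$confusion)) / sum(r1$confusion))
  # row sums equal per-class counts
  expect_equal(as.vector(rowSums(r1$confusion)),
               as.vector(table(d$labels)))
  # per-class sensitivity recomputed from the stored confusion matrix
  for (c_ in levels(d$labels)) {
    expect_equal(r1$sensitivity[[c_]],
                 100 * r1$confusion[c_, c_] / sum(r1$confusion[c_, ]))
  }
})

test_that("degenerative sensitivity dominates control sensitivity on the default cohort", {
  # unbalanced groups (24/15/8) drawn from the default archetypes: the
  # degenerative class is both largest and most distinct, so its
  # sensitivity should beat the control class for RF in most fold seeds
  coh <- generate_cohort(24, 15, 8, seed = 7, realize = character(0))
  x <- build_selection(parameter_features(coh$manifest), "B-C")
  labs <- factor(coh$manifest$group, levels = c("D", "T", "C"))
  wins <- 0L
  for (s in 1:20) {
    r <- suppressWarnings(crossval_classify(x, labs, algorithm = "RF",
                                            k = 5, seed = s))
    if (r$sensitivity[["D"]] > r$sensitivity[["C"]]) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("random-forest importance is normalized, ranked and informative", {
  withr::with_seed(8, {
    n <- 120
    tab <- as.data.frame(matrix(rnorm(n * 10), n))
    names(tab) <- paste0("f", 1:10)
    labs <- factor(rep(c("D", "T", "C"), each = n / 3))
    tab$f1 <- as.integer(labs) + rnorm(n, 0, 0.3)   # informative
  })
  top_first <- vapply(1:20, function(s) {
    rf <- withr::with_seed(s, randomForest::randomForest(
      x = tab, y = labs, ntree = 100))
    imp <- feature_importance(rf)
    expect_equal(sum(imp$importance_pct), 100, tolerance = 1e-9)
    imp$feature[1] == "f1"
  }, logical(1))
  expect_gte(sum(top_first), 18L)
})

test_that("duplicated columns share importance", {
  withr::with_seed(9, {
    n <- 150
    tab <- data.frame(sig = rep(1:3, each = n / 3) + rnorm(n, 0, 0.4),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    labs <- factor(rep(c("D", "T", "C"), each = n / 3))
    rf1 <- randomForest::randomForest(x = tab, y = labs, ntree = 300)
    imp1 <- feature_importance(rf1)
    tab2 <- cbind(tab, sig_copy = tab$sig)
    rf2 <- randomForest::randomForest(x = tab2, y = labs, ntree = 300)
    imp2 <- feature_importance(rf2)
  })
  single <- imp1$importance_pct[imp1$feature == "sig"]
  pair <- sum(imp2$importance_pct[imp2$feature %in% c("sig", "sig_copy")])
  expect_lt(abs(pair - single) / single, 0.30)
})
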