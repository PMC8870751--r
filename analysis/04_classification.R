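#!/usr/bin/env Rscript
# Tree-ensemble classification of subject group (D/T/C) from the feature
# table: five feature selections (Bone, Cartilage, B-C, WT-C, TOT) times
# three learners (decision tree, random forest, gradient boosting), each
# evaluated by stratified 5-fold cross-validation, plus random-forest
# feature importance. Hole features are excluded throughout.
#
# Usage: Rscript analysis/04_classification.R [--seed N] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(kneemorph)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 42L),
  make_option("--out", type = "character", default = "results/run")
)))

ff <- file.path(opts$out, "features.csv")
if (!file.exists(ff))
  stop("run analysis/02_extract_features.R first (missing ", ff, ")")
feats <- read.csv(ff, check.names = FALSE)
cfg <- default_config(seed = opts$seed)

unstable <- unstable_wtc_features(feats, cfg$cv_threshold)
cat(sprintf("WT-C features excluded as unstable (CV > %.1f): %d\n",
            cfg$cv_threshold, length(unstable)))

labels <- factor(feats$group, levels = c("D", "T", "C"))
rows <- list()
for (sel in cfg$selections) {
  x <- build_selection(feats, sel, unstable = unstable)
  for (alg in cfg$algorithms) {
    r <- suppressWarnings(
      crossval_classify(x, labels, algorithm = alg, k = cfg$k_folds,
                        seed = cfg$seed, hyper = cfg$hyper, selection = sel))
    rows[[paste(sel, alg)]] <-
      data.frame(selection = sel, algorithm = alg, n_features = ncol(x),
                 accuracy = r$accuracy,
                 sens_D = r$sensitivity[["D"]], spec_D = r$specificity[["D"]],
                 sens_T = r$sensitivity[["T"]], spec_T = r$specificity[["T"]],
                 sens_C = r$sensitivity[["C"]], spec_C = r$specificity[["C"]])
    if (alg == "RF" && sel %in% c("B-C", "TOT"))
      write.csv(r$importance,
                file.path(opts$out, sprintf("importance_%s_RF.csv",
                                            gsub("-", "", sel))),
                row.names = FALSE)
  }
}
metrics <- do.call(rbind, rows)
write.csv(metrics, file.path(opts$out, "classification_metrics.csv"),
          row.names = FALSE)
print(metrics, digits = 3, row.names = FALSE)

best <- metrics[which.max(metrics$accuracy), ]
cat(sprintf("\nbest accuracy: %.1f%% (%s / %s)\n", best$accuracy,
            best$selection, best$algorithm))
cat(sprintf("written: %s\n", file.path(opts$out,
                                       "classification_metrics.csv")))
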