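#!/usr/bin/env Rscript
# Nonparametric group comparison over every extracted feature: Shapiro-Wilk
# normality screen per group, Kruskal-Wallis omnibus, and Dunn's post hoc
# on the pairs (C-D, D-T, T-C) wherever the omnibus is significant at 0.05.
#
# Usage: Rscript analysis/03_group_statistics.R [--out DIR]
#        (reads DIR/features.csv written by 02_extract_features.R)

suppressPackageStartupMessages({
  library(optparse)
  library(kneemorph)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "results/run")
)))

ff <- file.path(opts$out, "features.csv")
if (!file.exists(ff))
  stop("run analysis/02_extract_features.R first (missing ", ff, ")")
feats <- read.csv(ff)

fb <- feature_blocks()
cols <- intersect(c(fb$bone, fb$cartilage, fb$wtc), names(feats))
cols <- cols[vapply(feats[cols], function(v) sd(v) > 0, logical(1))]
stats_tab <- compare_groups(feats[, cols], feats$group)
write.csv(stats_tab, file.path(opts$out, "group_stats.csv"),
          row.names = FALSE)

nsig <- sum(stats_tab$significant)
cat(sprintf("%d of %d features significant at the 0.05 omnibus level\n",
            nsig, nrow(stats_tab)))
sig <- stats_tab[stats_tab$significant,
                 c("feature", "kw_H", "kw_p", "dunn_p_C-D", "dunn_p_D-T",
                   "dunn_p_T-C")]
if (nrow(sig)) print(sig[order(sig$kw_p), ], digits = 3, row.names = FALSE)
normal_frac <- mean(stats_tab$shapiro_p_D > 0.05, na.rm = TRUE)
cat(sprintf("fraction of features looking normal in D (Shapiro p > 0.05): %.2f\n",
            normal_frac))
cat(sprintf("written: %s\n", file.path(opts$out, "group_stats.csv")))
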