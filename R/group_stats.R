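# Nonparametric group comparison battery: Shapiro-Wilk normality screen,
# Kruskal-Wallis omnibus, Dunn's pairwise post hoc on joint ranks.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston implementation.
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`; for zero-variance input `W`/`p` are `NA`
#'   with `computable = FALSE`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("Shapiro-Wilk requires n >= 3")
  if (length(values) > 5000L) stop("Shapiro-Wilk requires n <= 5000")
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, computable = FALSE))
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p = t$p.value, computable = TRUE)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom (delegated to the base implementation).
#' @param groups list of numeric vectors, one per group (>= 2 groups).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 1L)) stop("each group needs at least 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  t <- stats::kruskal.test(x, g)
  list(H = unname(t$statistic), p = t$p.value, df = unname(t$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each requested pair (i, j), the z statistic on joint ranks
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with the tie term
#' `T = sum(t^3 - t) / (12 (N - 1))`, and a two-sided normal p-value.
#' Unadjusted by default; Holm adjustment across the reported pairs by flag.
#'
#' @param groups named list of numeric vectors.
#' @param pairs list of character pairs to compare; defaults to all pairs
#'   in the order (C-D, D-T, T-C) when those names are present, otherwise
#'   all combinations.
#' @param adjust "none" (default) or "holm".
#' @return data.frame with columns `pair`, `z`, `p`.
#' @export
dunn_posthoc <- function(groups, pairs = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(pairs)) {
    pairs <- if (all(c("C", "D", "T") %in% names(groups)))
      list(c("C", "D"), c("D", "T"), c("T", "C"))
    else
      utils::combn(names(groups), 2L, simplify = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, gl, mean)
  n <- tapply(r, gl, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  res <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    data.frame(pair = paste(i, j, sep = "-"), z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, res)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Group-comparison battery over a feature table
#'
#' For every feature column: per-group Shapiro-Wilk, Kruskal-Wallis
#' omnibus, and (when the omnibus is significant at `alpha`) Dunn's post
#' hoc on the pairs (C-D, D-T, T-C).
#'
#' @param features data.frame of numeric feature columns.
#' @param group group label per row (factor with levels D/T/C or similar).
#' @param alpha significance level (default 0.05).
#' @param posthoc_only_if_significant run Dunn only when the omnibus
#'   p < alpha (default TRUE).
#' @param adjust p adjustment for Dunn ("none" or "holm").
#' @return data.frame, one row per feature, with Shapiro W/p per group,
#'   `kw_H`, `kw_p`, `significant`, and z/p per pair (NA when not run).
#' @export
compare_groups <- function(features, group, alpha = 0.05,
                           posthoc_only_if_significant = TRUE,
                           adjust = "none") {
  group <- as.factor(group)
  lv <- levels(droplevels(group))
  pair_names <- if (all(c("C", "D", "T") %in% lv))
    c("C-D", "D-T", "T-C")
  else
    vapply(utils::combn(lv, 2L, simplify = FALSE), paste, "", collapse = "-")
  rows <- lapply(names(features), function(fn) {
    v <- features[[fn]]
    gs <- split(v, group)
    sw <- lapply(gs, function(g)
      if (length(g[is.finite(g)]) >= 3L) shapiro_wilk(g)
      else list(W = NA_real_, p = NA_real_))
    kw <- kruskal_wallis(gs)
    row <- data.frame(feature = fn, kw_H = kw$H, kw_p = kw$p,
                      significant = kw$p < alpha)
    for (g in names(gs)) {
      row[[paste0("shapiro_W_", g)]] <- sw[[g]]$W
      row[[paste0("shapiro_p_", g)]] <- sw[[g]]$p
    }
    for (pn in pair_names) {
      row[[paste0("dunn_z_", pn)]] <- NA_real_
      row[[paste0("dunn_p_", pn)]] <- NA_real_
    }
    if (!posthoc_only_if_significant || isTRUE(kw$p < alpha)) {
      dn <- dunn_posthoc(gs, adjust = adjust)
      for (i in seq_len(nrow(dn))) {
        row[[paste0("dunn_z_", dn$pair[i])]] <- dn$z[i]
        row[[paste0("dunn_p_", dn$pair[i])]] <- dn$p[i]
      }
    }
    row
  })
  do.call(rbind, rows)
}
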