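# Area-normalized per-element statistics for the wall-thickness and
# curvature analyses: each element value is weighted by its triangle area
# (Y_i = A_i * X_i) so that large elements count for more, and summary
# parameters plus tail fractions are computed on the normalized set.

#' Area-normalize an element field
#'
#' Multiplies each valid element value by its triangle area: thickness
#' becomes mm^3 per element, curvature dimensionless. Invalid elements are
#' dropped, so the normalized set has NE = number of valid elements.
#'
#' @param field an [element_field()].
#' @return object of class `normalized_field` with `values` (Y_i), `ne`,
#'   `analysis_kind`.
#' @export
normalize_by_area <- function(field) {
  a <- face_areas(field$surface)
  sel <- field$valid & is.finite(field$values)
  if (!any(sel)) stop("no valid elements to normalize")
  structure(list(values = a[sel] * field$values[sel],
                 ne = sum(sel),
                 analysis_kind = field$analysis_kind),
            class = "normalized_field")
}

#' @export
print.normalized_field <- function(x, ...) {
  cat(sprintf("<normalized_field [%s]: NE = %d>\n", x$analysis_kind, x$ne))
  invisible(x)
}

as_norm_values <- function(nf) {
  if (inherits(nf, "normalized_field")) nf$values else as.numeric(nf)
}

#' Summary parameters of a normalized set
#'
#' Mean, STD, VAR (n-1 denominator) and RMS of the normalized values.
#' @param nf a `normalized_field` (or bare numeric vector).
#' @return list with `mean`, `std`, `var`, `rms`.
#' @export
summary_params <- function(nf) {
  y <- as_norm_values(nf)
  if (length(y) < 2L) stop("need at least 2 elements (NE >= 2)")
  v <- stats::var(y)
  list(mean = mean(y), std = sqrt(v), var = v,
       rms = sqrt(mean(y^2)))
}

#' Fraction of elements below mean - alpha * STD
#'
#' The wall-thickness tail fraction: the proportion of normalized element
#' values strictly below `mu - alpha * sigma`, with `mu` and `sigma`
#' computed from the same normalized set unless supplied (cohort-pooled
#' moments can be passed via `mu`/`sigma`).
#'
#' @param nf a `normalized_field` or numeric vector.
#' @param alpha nonnegative STD weight.
#' @param mu,sigma optional externally pooled moments.
#' @return fraction in [0, 1]; 0 when sigma is 0.
#' @export
w_percent <- function(nf, alpha, mu = NULL, sigma = NULL) {
  y <- as_norm_values(nf)
  if (length(y) < 2L) stop("need NE >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(mu)) mu <- mean(y)
  if (is.null(sigma)) sigma <- stats::sd(y)
  if (sigma == 0) return(0)
  mean(y < mu - alpha * sigma)
}

#' Fraction of elements above mean + alpha * STD
#'
#' The curvature tail fraction, mirror of [w_percent()]: proportion of
#' normalized values strictly above `mu + alpha * sigma`.
#' @inheritParams w_percent
#' @return fraction in [0, 1]; 0 when sigma is 0.
#' @export
c_percent <- function(nf, alpha, mu = NULL, sigma = NULL) {
  y <- as_norm_values(nf)
  if (length(y) < 2L) stop("need NE >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(mu)) mu <- mean(y)
  if (is.null(sigma)) sigma <- stats::sd(y)
  if (sigma == 0) return(0)
  mean(y > mu + alpha * sigma)
}

#' Select the STD weight maximizing group separation
#'
#' Guess-and-check over a candidate grid: for each alpha the per-subject
#' tail fraction is computed and the Kruskal-Wallis H statistic across
#' groups measured; the alpha with the largest H wins, ties broken toward
#' the smallest alpha.
#'
#' @param fields list of `normalized_field`s (one per subject) for one
#'   (compartment, analysis) pair.
#' @param labels group label per subject (factor or character).
#' @param grid candidate alpha values.
#' @param kind "wall" (below-threshold fraction) or "curvature"
#'   (above-threshold fraction).
#' @return list with `alpha`, `H` and the full `trace` (alpha, H).
#' @export
select_alpha <- function(fields, labels, grid = seq(0, 3, by = 0.1),
                         kind = c("wall", "curvature")) {
  kind <- match.arg(kind)
  if (length(grid) == 0L) stop("alpha grid is empty")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 groups")
  grid <- sort(grid)
  pfun <- if (kind == "wall") w_percent else c_percent
  hs <- vapply(grid, function(a) {
    p <- vapply(fields, pfun, numeric(1), alpha = a)
    if (length(unique(p)) == 1L) return(0)
    kruskal_wallis(split(p, labels))$H
  }, numeric(1))
  if (all(hs == 0))
    warning("no alpha in the grid separates the groups; returning smallest")
  best <- which.max(hs)   # which.max returns the first (smallest alpha) tie
  list(alpha = grid[best], H = hs[best],
       trace = data.frame(alpha = grid, H = hs))
}

wtc_compartments <- c("Fem", "Pat", "Lat", "Med")

#' Default STD weights
#'
#' Wall weight 0.5 for femoral, patellar and medial tibial cartilage and
#' 0.3 for the lateral tibial cartilage; curvature weight 5 for all.
#' @return list with `wall` and `curvature` named vectors.
#' @export
default_alphas <- function() {
  list(wall = c(Fem = 0.5, Pat = 0.5, Lat = 0.3, Med = 0.5),
       curvature = c(Fem = 5, Pat = 5, Lat = 5, Med = 5))
}

#' Assemble the 48-parameter per-subject feature block
#'
#' Six values per analysis (Mean, STD, Var, RMS, tail fraction, STD weight)
#' for each of the eight analyses (4 cartilage compartments x wall/curvature)
#' gives 48 named parameters per subject.
#'
#' @param analyses named list of `normalized_field`s with names
#'   `<Comp>.<wall|curvature>` for Comp in Fem, Pat, Lat, Med.
#' @param alphas STD weights as in [default_alphas()].
#' @return named numeric vector of length 48, columns
#'   `<Comp><Wall|Curv><Mean|STD|Var|RMS|BelowSTDWeight|AboveSTDWeight|STDWeight>`.
#' @export
assemble_wtc_block <- function(analyses, alphas = default_alphas()) {
  need <- as.vector(outer(wtc_compartments, c("wall", "curvature"),
                          paste, sep = "."))
  missing <- setdiff(need, names(analyses))
  if (length(missing))
    stop("missing analyses: ", paste(missing, collapse = ", "))
  out <- numeric(0)
  for (comp in wtc_compartments) {
    for (an in c("wall", "curvature")) {
      nf <- analyses[[paste(comp, an, sep = ".")]]
      sp <- summary_params(nf)
      tag <- if (an == "wall") "Wall" else "Curv"
      alpha <- alphas[[an]][[comp]]
      pct <- if (an == "wall") w_percent(nf, alpha) else c_percent(nf, alpha)
      ptag <- if (an == "wall") "BelowSTDWeight" else "AboveSTDWeight"
      vals <- c(sp$mean, sp$std, sp$var, sp$rms, pct, alpha)
      names(vals) <- paste0(comp, tag,
                            c("Mean", "STD", "Var", "RMS", ptag, "STDWeight"))
      out <- c(out, vals)
    }
  }
  stopifnot(length(out) == 48L)
  out
}
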