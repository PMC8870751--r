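# Tree-ensemble classification of the morphometric feature table:
# feature-selection groups, stratified k-fold cross-validation with DT/RF/GB,
# pooled out-of-fold confusion matrix, per-class metrics, RF importance.

#' Canonical feature-block column names
#' @return list with `bone` (8), `cartilage` (16) and `wtc` (48) names.
#' @export
feature_blocks <- function() {
  cart_comps <- c("FemCart", "TibCartLat", "TibCartMed", "PatCart")
  wtc <- character(0)
  for (comp in wtc_compartments) {
    wtc <- c(wtc,
             paste0(comp, "Wall", c("Mean", "STD", "Var", "RMS",
                                    "BelowSTDWeight", "STDWeight")),
             paste0(comp, "Curv", c("Mean", "STD", "Var", "RMS",
                                    "AboveSTDWeight", "STDWeight")))
  }
  list(bone = c("FemurDENS", "FemurSTD", "TibiaDENS", "TibiaSTD",
                "PatellaDENS", "PatellaSTD", "PatellaVOL", "PatellaSURF"),
       cartilage = as.vector(t(outer(cart_comps, c("DENS", "STD", "VOL", "SURF"),
                                     paste0))),
       wtc = wtc)
}

#' Build a named feature selection
#'
#' Selections: `Bone` (8 columns), `Cartilage` (16), `B-C` (24), `WT-C`
#' (the 48-parameter block minus the 8 constant STD-weight columns minus
#' any configured unstable features) and `TOT` (B-C plus WT-C).
#' Hole-related columns are never included.
#'
#' @param table data.frame containing the feature blocks.
#' @param name one of "Bone", "Cartilage", "B-C", "WT-C", "TOT".
#' @param unstable feature names excluded from WT-C (see
#'   [unstable_wtc_features()]).
#' @return data.frame with the selected columns, in block order.
#' @export
build_selection <- function(table, name, unstable = character(0)) {
  fb <- feature_blocks()
  alpha_cols <- grep("STDWeight$", fb$wtc, value = TRUE)
  alpha_cols <- alpha_cols[!grepl("BelowSTDWeight$|AboveSTDWeight$", alpha_cols)]
  wtc_cols <- setdiff(fb$wtc, c(alpha_cols, unstable))
  cols <- switch(name,
    "Bone" = fb$bone,
    "Cartilage" = fb$cartilage,
    "B-C" = c(fb$bone, fb$cartilage),
    "WT-C" = wtc_cols,
    "TOT" = c(fb$bone, fb$cartilage, wtc_cols),
    stop("unknown selection: ", name,
         " (expected Bone, Cartilage, B-C, WT-C or TOT)"))
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  table[, cols, drop = FALSE]
}

#' Flag unstable WT-C features
#'
#' Features whose cross-subject coefficient of variation (sd/|mean|)
#' exceeds `cv_threshold` are flagged for exclusion from the WT-C
#' selection; constant STD-weight columns are never flagged (they are
#' removed separately).
#' @param table feature data.frame.
#' @param cv_threshold coefficient-of-variation cutoff (default 5).
#' @return character vector of feature names.
#' @export
unstable_wtc_features <- function(table, cv_threshold = 5) {
  fb <- feature_blocks()
  cand <- intersect(fb$wtc, names(table))
  cand <- cand[!grepl("STDWeight$", cand) |
                 grepl("BelowSTDWeight$|AboveSTDWeight$", cand)]
  cv <- vapply(cand, function(cn) {
    v <- table[[cn]]
    m <- mean(v)
    if (m == 0) return(Inf)
    stats::sd(v) / abs(m)
  }, numeric(1))
  names(cv)[cv > cv_threshold]
}

stratified_folds <- function(y, k, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Default learner hyperparameters
#' @return list of per-algorithm settings.
#' @export
default_hyperparameters <- function() {
  list(RF = list(ntree = 100),
       GB = list(nrounds = 100, eta = 0.1, max_depth = 3),
       DT = list(cp = 0, minsplit = 2, minbucket = 1))
}

fit_predict <- function(algorithm, x_train, y_train, x_test, hyper, seed) {
  y_train <- droplevels(y_train)
  lv <- levels(y_train)
  withr::with_seed(as.integer(seed), {
    if (algorithm == "RF") {
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = hyper$RF$ntree)
      as.character(stats::predict(fit, x_test))
    } else if (algorithm == "DT") {
      df <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = hyper$DT$cp, minsplit = hyper$DT$minsplit,
                            minbucket = hyper$DT$minbucket, xval = 0))
      as.character(stats::predict(fit, data.frame(x_test, check.names = FALSE),
                                  type = "class"))
    } else if (algorithm == "GB") {
      yt <- as.integer(y_train) - 1L
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train), label = yt)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = length(lv),
                      eta = hyper$GB$eta,
                      max_depth = hyper$GB$max_depth,
                      nthread = 1),
        data = dtrain, nrounds = hyper$GB$nrounds, verbose = 0)
      lv[stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x_test))) + 1L]
    } else stop("unknown algorithm: ", algorithm)
  })
}

#' Cross-validated classification report
#'
#' Stratified k-fold cross-validation; out-of-fold predictions are pooled
#' into a single confusion matrix from which overall accuracy and one-vs-rest
#' per-class sensitivity/specificity are computed (all in percent).
#' Deterministic for a fixed seed.
#'
#' @param table feature data.frame (numeric columns only).
#' @param labels class label per row (D/T/C or any factor).
#' @param algorithm "DT", "RF" or "GB".
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds and learners.
#' @param hyper hyperparameters, see [default_hyperparameters()].
#' @param selection optional selection name recorded in the report.
#' @return object of class `classification_report`: `algorithm`,
#'   `selection`, `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (rows = truth), `folds`, `seed`, and `importance` (RF only, percent
#'   summing to 100).
#' @export
crossval_classify <- function(table, labels, algorithm = c("RF", "DT", "GB"),
                              k = 5, seed = 42,
                              hyper = default_hyperparameters(),
                              selection = NA_character_) {
  algorithm <- match.arg(algorithm)
  labels <- factor(labels)
  lv <- levels(labels)
  stopifnot(nrow(table) == length(labels), k >= 2)
  fold <- stratified_folds(labels, k, seed)
  pred <- character(length(labels))
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    ytr <- labels[!test]
    if (nlevels(droplevels(ytr)) < nlevels(labels))
      warning(sprintf("fold %d: class absent from training data", f))
    pred[test] <- fit_predict(algorithm, table[!test, , drop = FALSE], ytr,
                              table[test, , drop = FALSE], hyper,
                              seed = seed + f)
  }
  pred <- factor(pred, levels = lv)
  conf <- table(truth = labels, predicted = pred)
  acc <- 100 * sum(diag(conf)) / sum(conf)
  sens <- spec <- stats::setNames(numeric(length(lv)), lv)
  for (c_ in lv) {
    tp <- conf[c_, c_]
    fn <- sum(conf[c_, ]) - tp
    fp <- sum(conf[, c_]) - tp
    tn <- sum(conf) - tp - fn - fp
    sens[c_] <- 100 * tp / (tp + fn)
    spec[c_] <- 100 * tn / (tn + fp)
  }
  imp <- NULL
  if (algorithm == "RF") {
    rf <- withr::with_seed(as.integer(seed),
      randomForest::randomForest(x = table, y = labels,
                                 ntree = hyper$RF$ntree,
                                 importance = FALSE))
    imp <- feature_importance(rf)
  }
  structure(list(algorithm = algorithm, selection = selection,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 confusion = conf, folds = fold, seed = seed,
                 importance = imp),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<%s%s: accuracy %.1f%%>\n", x$algorithm,
              if (is.na(x$selection)) "" else paste0(" on ", x$selection),
              x$accuracy))
  invisible(x)
}

#' Ranked random-forest feature importance
#'
#' Mean decrease in Gini impurity, normalized to percentages summing to
#' 100 and ranked in decreasing order.
#' @param rf a fitted `randomForest` model.
#' @return data.frame with `rank`, `feature`, `importance_pct`.
#' @export
feature_importance <- function(rf) {
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  pct <- 100 * imp / sum(imp)
  o <- order(pct, decreasing = TRUE)
  data.frame(rank = seq_along(o), feature = names(pct)[o],
             importance_pct = unname(pct[o]))
}
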