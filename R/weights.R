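## Breast-muscle weight prediction: candidate table assembly, recursive
## feature elimination with linear-SVR ranking, the final epsilon-insensitive
## linear SVR (C = 10, epsilon = 0.3), k-fold cross-validation and
## mask-to-grams prediction.
##
## Features are z-scored (fit on training rows only); the target stays in
## grams so epsilon retains its physical meaning.

#' SVR configuration
#'
#' Linear-kernel epsilon-insensitive support vector regression with the
#' published hyperparameters: penalty C = 10, epsilon = 0.3 (grams); all
#' remaining parameters at \pkg{e1071} defaults.
#'
#' @param cost penalty parameter C.
#' @param epsilon epsilon-tube half-width in target units (grams).
#' @return object of class `svr_config`.
#' @export
svr_config <- function(cost = 10, epsilon = 0.3) {
  stopifnot(cost > 0, epsilon >= 0)
  structure(list(kernel = "linear", cost = cost, epsilon = epsilon),
            class = "svr_config")
}

#' Assemble the predictor table
#'
#' Joins a shape-feature table (from [features_table()]) with a manifest of
#' live weights and measured breast-muscle weights on `sample_id`, yielding
#' the 16 candidate columns (live_weight plus the 15 shape descriptors) and
#' the target.
#'
#' @param features data frame with `sample_id` and the 15 descriptor columns.
#' @param manifest data frame with `sample_id`, `live_weight_g`,
#'   `breast_muscle_weight_g`.
#' @return data frame with `sample_id`, `live_weight`, the 15 descriptors
#'   and `breast_muscle_weight`.
#' @export
predictor_table <- function(features, manifest) {
  tab <- merge(features, manifest[, c("sample_id", "live_weight_g",
                                      "breast_muscle_weight_g")],
               by = "sample_id")
  names(tab)[names(tab) == "live_weight_g"] <- "live_weight"
  names(tab)[names(tab) == "breast_muscle_weight_g"] <- "breast_muscle_weight"
  if (anyNA(tab)) stop("predictor table contains missing values")
  if (any(tab$breast_muscle_weight <= 0)) stop("targets must be positive")
  tab[, c("sample_id", "live_weight", shape_feature_names(),
          "breast_muscle_weight")]
}

#' Candidate feature names (live weight + 15 shape descriptors)
#' @return character(16).
#' @export
candidate_features <- function() c("live_weight", shape_feature_names())

scale_fit <- function(x) {
  list(center = colMeans(x), scale = apply(x, 2, stats::sd))
}

scale_apply <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)
}

svr_fit_raw <- function(x, y, cfg) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "linear",
             cost = cfg$cost, epsilon = cfg$epsilon, scale = FALSE)
}

svr_weights <- function(fit) {
  drop(crossprod(fit$coefs, fit$SV))
}

#' Fit the breast-muscle weight model
#'
#' Standardizes the selected features on the supplied rows and fits the
#' linear-kernel epsilon-insensitive SVR. The returned object carries the
#' scaler, the selected-feature list and the fitted SVR, and supports
#' `print`, `summary`, `coef` and `predict`.
#'
#' @param table predictor table from [predictor_table()] (or any data frame
#'   with the feature columns and the target).
#' @param features character vector of feature names to use.
#' @param svr a [svr_config()].
#' @param target target column name.
#' @return object of class `weight_model`.
#' @export
fit_weight_model <- function(table, features = candidate_features(),
                             svr = svr_config(),
                             target = "breast_muscle_weight") {
  stopifnot(nrow(table) >= 2, all(features %in% names(table)),
            target %in% names(table))
  x <- as.matrix(table[, features, drop = FALSE])
  y <- table[[target]]
  sc <- scale_fit(x)
  if (any(sc$scale == 0)) {
    stop("zero-variance feature(s): ",
         paste(features[sc$scale == 0], collapse = ", "))
  }
  fit <- svr_fit_raw(scale_apply(x, sc), y, svr)
  structure(list(selected_features = features, scaler = sc, svr = fit,
                 config = svr, target = target, n = nrow(table)),
            class = "weight_model")
}

#' @export
predict.weight_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$selected_features, drop = FALSE])
  as.numeric(stats::predict(object$svr, scale_apply(x, object$scaler)))
}

#' @export
coef.weight_model <- function(object, ...) {
  w <- svr_weights(object$svr)
  names(w) <- object$selected_features
  c(`(intercept)` = -object$svr$rho, w)
}

#' @export
print.weight_model <- function(x, ...) {
  cat("Breast-muscle weight model (linear SVR, C =", x$config$cost,
      ", epsilon =", x$config$epsilon, "g)\n")
  cat("  fitted on", x$n, "animals\n")
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.weight_model <- function(object, ...) {
  print(object)
  cat("  standardized coefficients:\n")
  w <- coef(object)
  print(round(w, 4))
  invisible(object)
}

make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, k <= n)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validation of the weight model
#'
#' Seeded shuffle into k folds; for each fold the scaler and SVR are refit on
#' the training rows only (no leakage) and evaluated on the held-out rows
#' with [regression_metrics()].
#'
#' @inheritParams fit_weight_model
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return list with `folds` (data frame of per-fold r2/rmse/mae/mre),
#'   `mean` (their arithmetic means) and `assignments`.
#' @export
cross_validate_weight <- function(table, features = candidate_features(),
                                  svr = svr_config(), k = 5, seed = 1,
                                  target = "breast_muscle_weight") {
  n <- nrow(table)
  if (k > n) stop("k exceeds number of rows")
  fold <- make_folds(n, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    m <- fit_weight_model(tr, features, svr, target)
    pred <- predict(m, te)
    met <- regression_metrics(te[[target]], pred)
    data.frame(fold = f, r2 = met$r2, rmse = met$rmse, mae = met$mae,
               mre = met$mre)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = as.list(colMeans(folds[, c("r2", "rmse", "mae", "mre")])),
       assignments = fold)
}

#' Recursive feature elimination with linear-SVR ranking
#'
#' Starting from all candidates, repeatedly fits the linear SVR on the
#' standardized features and removes the feature with the smallest absolute
#' coefficient (ties broken towards the later column), producing a full
#' elimination order and the nested subsets of every size. Each subset size
#' in `sizes` is scored by `k`-fold cross-validated mean R-squared; the
#' subset with the highest score is selected (ties towards fewer features).
#' Constant columns are dropped with a warning before ranking.
#'
#' @inheritParams cross_validate_weight
#' @param sizes subset sizes to evaluate (default 1..#candidates).
#' @return list of class `rfe_result` with `selected` (character vector),
#'   `scores` (data frame size/cv_r2/features), `elimination_order` (first
#'   eliminated first).
#' @export
rfe_select <- function(table, features = candidate_features(),
                       svr = svr_config(), sizes = NULL, k = 5, seed = 1,
                       target = "breast_muscle_weight") {
  stopifnot(nrow(table) >= 2 * k)
  x <- as.matrix(table[, features, drop = FALSE])
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(features[const], collapse = ", "))
    features <- features[!const]
  }
  sizes <- sizes %||% seq_along(features)
  stopifnot(all(sizes >= 1), all(sizes <= length(features)))

  ## full-data elimination order by smallest |standardized SVR coefficient|
  current <- features
  order_out <- character()
  y <- table[[target]]
  while (length(current) > 1) {
    xs <- scale(as.matrix(table[, current, drop = FALSE]))
    w <- abs(svr_weights(svr_fit_raw(xs, y, svr)))
    drop_i <- max(which(w == min(w)))      # tie-break: later column first
    order_out <- c(order_out, current[drop_i])
    current <- current[-drop_i]
  }
  order_out <- c(order_out, current)       # survivor, eliminated last

  ## nested subset of size s = the s last-eliminated features
  subset_of <- function(s) order_out[(length(order_out) - s + 1):length(order_out)]
  scores <- data.frame(size = sizes, cv_r2 = NA_real_,
                       features = NA_character_)
  for (i in seq_along(sizes)) {
    sub <- subset_of(sizes[i])
    cv <- cross_validate_weight(table, sub, svr, k, seed, target)
    scores$cv_r2[i] <- cv$mean$r2
    scores$features[i] <- paste(sub, collapse = ",")
  }
  best <- scores[order(-scores$cv_r2, scores$size), ][1, ]
  structure(list(selected = subset_of(best$size), scores = scores,
                 elimination_order = order_out),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  best <- x$scores[which.max(x$scores$cv_r2), ]
  cat("RFE over", max(x$scores$size), "candidates:",
      length(x$selected), "features selected (CV R2 =",
      round(best$cv_r2, 4), ")\n")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Predict breast-muscle weight from a mask and live weight
#'
#' Runs the full tail of the pipeline: shape-feature extraction from the
#' binary mask, assembly with live weight, scaling and SVR prediction.
#'
#' @param mask binary (0/1) matrix (a predicted or ground-truth pectoral
#'   muscle mask).
#' @param live_weight live weight in grams (required when the model selected
#'   it).
#' @param model a fitted [fit_weight_model()] object.
#' @return predicted breast-muscle weight in grams (scalar).
#' @export
predict_weight <- function(mask, live_weight = NULL, model) {
  stopifnot(inherits(model, "weight_model"))
  feats <- as.list(extract_features(mask))
  if ("live_weight" %in% model$selected_features) {
    if (is.null(live_weight)) stop("live weight required by this model")
    feats$live_weight <- live_weight
  }
  row <- as.data.frame(feats)
  predict(model, row)
}
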