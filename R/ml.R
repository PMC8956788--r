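#' Build the model feature matrix from classified CPI results
#'
#' Features are surface area, conservation score, relative rarity, and
#' one-hot country indicators (deterministic column order: sorted country
#' names). The label is the priority class, with "high" the class of
#' interest.
#'
#' @param results Classified CPI results ([classify_priority()]).
#' @return Tibble with columns `area_km2`, `cwt`, `rrw`, one
#'   `country_<name>` indicator per country, and `priority_class`
#'   (factor low < high).
#' @export
build_features <- function(results) {
  if (nrow(results) < 2) {
    stop("cpirank analysis error: need at least 2 units to build features",
         call. = FALSE)
  }
  if (!"priority_class" %in% names(results)) {
    stop("cpirank analysis error: run classify_priority() first", call. = FALSE)
  }
  countries <- sort(unique(results$country))
  out <- tibble::tibble(area_km2 = results$area_km2,
                        cwt = as.numeric(results$cwt),
                        rrw = results$rrw)
  for (cc in countries) {
    col <- paste0("country_", gsub("[^[:alnum:]]+", "_", cc))
    out[[col]] <- as.integer(results$country == cc)
  }
  out$priority_class <- factor(as.character(results$priority_class),
                               levels = c("low", "high"))
  out
}

#' Stratified train/test split
#'
#' Randomly partitions the feature matrix into training and testing sets,
#' stratified by priority class so both sets preserve the (often
#' imbalanced) class ratio.
#'
#' @param features Output of [build_features()].
#' @param train_fraction Fraction of rows used for training, default 0.7.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with `train` and `test` tibbles.
#' @export
split_data <- function(features, train_fraction = 0.7, seed = 1L) {
  cls <- features$priority_class
  tab <- table(cls)
  if (any(tab < 2)) {
    stop("cpirank analysis error: class '", names(tab)[tab < 2][1],
         "' has fewer than 2 rows; more data needed for a stratified split",
         call. = FALSE)
  }
  set.seed(seed)
  train_idx <- unlist(lapply(levels(cls), function(lv) {
    idx <- which(cls == lv)
    n_train <- max(1, round(train_fraction * length(idx)))
    n_train <- min(n_train, length(idx) - 1)  # keep both classes in test
    sample(idx, n_train)
  }))
  list(train = features[sort(train_idx), , drop = FALSE],
       test = features[setdiff(seq_len(nrow(features)), train_idx), ,
                       drop = FALSE])
}

feature_cols <- function(features) {
  setdiff(names(features), "priority_class")
}

#' Fit a random forest priority classifier
#'
#' Tunes the number of features tried per split (mtry) by successive
#' multiplication/division with `tune_step_factor`, accepting steps while
#' the out-of-bag error improves by at least the `improve` fraction, then
#' fits a forest with permutation (mean decrease in accuracy) and Gini
#' importances.
#'
#' @param train Training tibble from [split_data()].
#' @param ntree Number of trees, default 500.
#' @param tune_step_factor Step factor for mtry tuning, default 2.
#' @param improve Minimum relative out-of-bag improvement to accept a tuning
#'   step, default 0.05.
#' @param seed Integer seed.
#' @return A `cpi_model` object (type "rf") with an `importance` tibble
#'   (`feature`, `mean_decrease_accuracy`, `mean_decrease_gini`).
#' @export
fit_random_forest <- function(train, ntree = 500, tune_step_factor = 2,
                              improve = 0.05, seed = 1L) {
  cols <- feature_cols(train)
  x <- as.data.frame(train[, cols, drop = FALSE])
  y <- droplevels(train$priority_class)
  set.seed(seed)
  mtry <- tryCatch({
    tuned <- randomForest::tuneRF(x, y, stepFactor = tune_step_factor,
                                  improve = improve, ntreeTry = ntree,
                                  trace = FALSE, plot = FALSE)
    tuned[which.min(tuned[, "OOBError"]), "mtry"]
  }, error = function(e) max(1, floor(sqrt(length(cols)))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(fit)
  importance <- tibble::tibble(
    feature = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  ) |> dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy))
  structure(list(type = "rf", fit = fit, features = cols,
                 importance = importance, seed = seed),
            class = "cpi_model")
}

#' Fit a gradient-boosted tree priority classifier
#'
#' Boosted trees with a two-class soft-probability objective and
#' multiclass log-loss as the evaluation metric; per-feature gain
#' importances are normalised to sum to 1.
#'
#' @param train Training tibble from [split_data()].
#' @param nrounds Boosting rounds, default 100.
#' @param max_depth Tree depth, default 6.
#' @param eta Learning rate, default 0.3.
#' @param seed Integer seed.
#' @return A `cpi_model` object (type "gbt") with an `importance` tibble
#'   (`feature`, `gain`), gains summing to 1.
#' @export
fit_gradient_boosting <- function(train, nrounds = 100, max_depth = 6,
                                  eta = 0.3, seed = 1L) {
  cols <- feature_cols(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  y <- as.integer(train$priority_class == "high")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  fit <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 2,
                  eval_metric = "mlogloss", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0,
    evals = list(train = dtrain)
  )
  imp_raw <- xgboost::xgb.importance(model = fit)
  importance <- tibble::tibble(feature = cols) |>
    dplyr::left_join(
      tibble::tibble(feature = imp_raw$Feature, gain = imp_raw$Gain),
      by = "feature"
    ) |>
    dplyr::mutate(gain = dplyr::coalesce(.data$gain, 0)) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  structure(list(type = "gbt", fit = fit, features = cols,
                 importance = importance, seed = seed),
            class = "cpi_model")
}

#' Predicted probability of the high-priority class
#'
#' @param model A `cpi_model`.
#' @param newdata Feature tibble (extra columns ignored).
#' @return Numeric vector of P(high) per row.
#' @export
predict_high_prob <- function(model, newdata) {
  x <- newdata[, model$features, drop = FALSE]
  if (model$type == "rf") {
    pr <- stats::predict(model$fit, as.data.frame(x), type = "prob")
    if ("high" %in% colnames(pr)) unname(pr[, "high"]) else rep(0, nrow(x))
  } else {
    pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x)))
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = 2, byrow = TRUE)
    pr[, 2]  # columns: class 0 (low), 1 (high)
  }
}

#' @export
print.cpi_model <- function(x, ...) {
  cat("cpirank priority model (", x$type, "), ",
      length(x$features), " features\n", sep = "")
  print(x$importance, n = 5)
  invisible(x)
}

#' Classification metrics on a test set
#'
#' Confusion-matrix metrics with "high" as the positive class: accuracy,
#' recall (sensitivity), specificity, precision, and F1 (the harmonic mean
#' of precision and recall). If the test set contains a single class, the
#' undefined metrics are returned as `NA` with a warning.
#'
#' @param model A `cpi_model`.
#' @param test Test tibble from [split_data()].
#' @param cutoff Probability cutoff for calling "high", default 0.5.
#' @return List: `model_name`, `n_test`, `confusion` (2x2 table),
#'   `accuracy`, `recall`, `specificity`, `precision`, `f1`.
#' @export
evaluate_model <- function(model, test, cutoff = 0.5) {
  if (nrow(test) == 0) {
    stop("cpirank analysis error: empty test set", call. = FALSE)
  }
  truth <- factor(as.character(test$priority_class), levels = c("low", "high"))
  prob <- predict_high_prob(model, test)
  pred <- factor(ifelse(prob > cutoff, "high", "low"),
                 levels = c("low", "high"))
  cm <- table(truth = truth, pred = pred)
  tp <- cm["high", "high"]; fn <- cm["high", "low"]
  tn <- cm["low", "low"]; fp <- cm["low", "high"]
  if (sum(cm["high", ]) == 0 || sum(cm["low", ]) == 0) {
    warning("cpirank: test set contains a single class; ",
            "some metrics are undefined (NA)", call. = FALSE)
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(model_name = model$type,
       n_test = nrow(test),
       confusion = cm,
       accuracy = (tp + tn) / sum(cm),
       recall = recall,
       specificity = safe_div(tn, tn + fp),
       precision = precision,
       f1 = f1)
}

#' Partial dependence of the high-priority probability on one feature
#'
#' For each grid value, clamps the feature to that value across all rows of
#' the evaluation data and averages the model's predicted probability of
#' the high-priority class.
#'
#' @param model A `cpi_model`.
#' @param data Evaluation tibble (typically the test set).
#' @param feature Name of a numeric feature.
#' @param grid Numeric grid; defaults to 20 quantile-spaced points over the
#'   feature's observed range.
#' @return Tibble `feature`, `value`, `mean_high_prob`.
#' @export
partial_dependence <- function(model, data, feature, grid = NULL) {
  if (!feature %in% model$features) {
    stop("cpirank analysis error: unknown feature '", feature, "'",
         call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- unique(stats::quantile(data[[feature]],
                                   probs = seq(0, 1, length.out = 20),
                                   names = FALSE, type = 7))
  }
  mean_prob <- vapply(grid, function(v) {
    clamped <- data
    clamped[[feature]] <- v
    mean(predict_high_prob(model, clamped))
  }, numeric(1))
  tibble::tibble(feature = feature, value = grid, mean_high_prob = mean_prob)
}
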