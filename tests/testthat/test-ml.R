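# Feature building, splitting, the two tree ensembles, metrics, and
# partial dependence.

fake_results <- function(n, countries, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    lake = paste0("L", seq_len(n)),
    country = sample(countries, n, replace = TRUE),
    richness = sample(1:20, n, replace = TRUE),
    cwt = sample(1:60, n, replace = TRUE),
    rrw = runif(n, 0, 5),
    area_km2 = runif(n, 0.5, 100),
    cpi = runif(n, 0, 2),
    richness_density = runif(n)
  ) |> classify_priority()
}

# labels driven by area alone: small lakes are high priority
area_driven_features <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    area_km2 = runif(n, 0, 100),
    cwt = runif(n, 1, 60),
    rrw = runif(n, 0, 5),
    country_A = sample(0:1, n, replace = TRUE)
  ) |>
    dplyr::mutate(country_B = 1L - .data$country_A,
                  priority_class = factor(
                    ifelse(.data$area_km2 < 40, "high", "low"),
                    levels = c("low", "high")))
}

test_that("the feature matrix has area, cwt, rrw, and one-hot countries", {
  res <- fake_results(3, c("Uganda", "Rwanda"))
  res$country <- c("Uganda", "Rwanda", "Uganda")
  feats <- build_features(res)
  expect_equal(setdiff(names(feats), "priority_class"),
               c("area_km2", "cwt", "rrw", "country_Rwanda", "country_Uganda"))
  one_hot <- as.matrix(feats[, c("country_Rwanda", "country_Uganda")])
  expect_equal(unname(rowSums(one_hot)), rep(1, 3))

  solo <- fake_results(4, "Uganda")
  f1 <- build_features(solo)
  expect_equal(f1$country_Uganda, rep(1L, 4))

  shuffled <- res[c(3, 1, 2), ]
  expect_equal(build_features(shuffled)[c(3, 1, 2) |> order(), ],
               feats, ignore_attr = TRUE)
})

test_that("splits are stratified, sized correctly, and seed-reproducible", {
  feats <- area_driven_features(100, seed = 2)
  # force an 80/20 class ratio
  feats$priority_class <- factor(rep(c("low", "high"), c(80, 20)),
                                 levels = c("low", "high"))
  spl <- split_data(feats, train_fraction = 0.7, seed = 5)
  expect_equal(nrow(spl$train), 70)
  expect_equal(nrow(spl$test), 30)
  expect_equal(sum(spl$train$priority_class == "high"), 14)  # 20 * 0.7
  again <- split_data(feats, train_fraction = 0.7, seed = 5)
  expect_identical(spl$train, again$train)
  others <- vapply(1:10, function(s) {
    sum(split_data(feats, seed = s)$train$area_km2)
  }, numeric(1))
  expect_gt(length(unique(others)), 5)  # different seeds, different splits
})

test_that("a class with a single row cannot be split", {
  feats <- area_driven_features(10, seed = 1)
  feats$priority_class <- factor(c("high", rep("low", 9)),
                                 levels = c("low", "high"))
  expect_error(split_data(feats), "more data")
})

test_that("both models recover an area-determined label structure", {
  feats <- area_driven_features(300, seed = 10)
  spl <- split_data(feats, seed = 10)
  rf <- fit_random_forest(spl$train, seed = 10)
  gbt <- fit_gradient_boosting(spl$train, seed = 10)
  # area tops both rf importance measures and gbt gain
  expect_equal(rf$importance$feature[1], "area_km2")
  expect_equal(
    rf$importance$feature[which.max(rf$importance$mean_decrease_gini)],
    "area_km2")
  expect_equal(gbt$importance$feature[1], "area_km2")
  expect_equal(sum(gbt$importance$gain), 1)
  # a cleanly learnable single-feature rule scores high accuracy
  expect_gt(evaluate_model(rf, spl$test)$accuracy, 0.9)
  expect_gt(evaluate_model(gbt, spl$test)$accuracy, 0.9)
  # seeded refits are reproducible
  rf2 <- fit_random_forest(spl$train, seed = 10)
  expect_equal(rf$importance, rf2$importance)
  expect_equal(predict_high_prob(rf, spl$test),
               predict_high_prob(rf2, spl$test))
})

test_that("pure-noise features score near the majority-class rate", {
  set.seed(20)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    feats <- tibble::tibble(
      area_km2 = runif(120), cwt = runif(120), rrw = runif(120),
      priority_class = factor(sample(c("low", "high"), 120, TRUE,
                                     prob = c(0.7, 0.3)),
                              levels = c("low", "high"))
    )
    spl <- split_data(feats, seed = s)
    rf <- fit_random_forest(spl$train, seed = s)
    evaluate_model(rf, spl$test)$accuracy
  }, numeric(1))
  majority <- 0.7
  expect_lt(abs(mean(accs) - majority), 0.15)
})

test_that("metrics match a hand-built confusion matrix", {
  # a model that learned pred = (x < 0) perfectly, then a test set with
  # deliberate truth flips: TP=9, FN=1, TN=7, FP=1
  set.seed(3)
  train <- tibble::tibble(
    x = c(runif(100, -2, -1), runif(100, 1, 2)),
    noise = runif(200),
    priority_class = factor(rep(c("high", "low"), each = 100),
                            levels = c("low", "high"))
  )
  rf <- fit_random_forest(train, seed = 3)
  test <- tibble::tibble(
    x = c(runif(9, -2, -1), runif(1, 1, 2),    # truth high: 9 TP, 1 FN
          runif(7, 1, 2), runif(1, -2, -1)),   # truth low: 7 TN, 1 FP
    noise = runif(18),
    priority_class = factor(rep(c("high", "low"), c(10, 8)),
                            levels = c("low", "high"))
  )
  m <- evaluate_model(rf, test)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$specificity, 0.875)
  expect_equal(m$accuracy, 16 / 18)
  expect_equal(m$f1, 2 * 0.9 * 0.9 / (0.9 + 0.9))
  expect_true(all(unlist(m[c("accuracy", "recall", "specificity",
                             "precision", "f1")]) >= 0 &
                    unlist(m[c("accuracy", "recall", "specificity",
                               "precision", "f1")]) <= 1))
})

test_that("a one-class test set flags undefined metrics as NA", {
  feats <- area_driven_features(100, seed = 4)
  spl <- split_data(feats, seed = 4)
  rf <- fit_random_forest(spl$train, seed = 4)
  lows <- spl$test[spl$test$priority_class == "low", ]
  expect_warning(m <- evaluate_model(rf, lows), "single class")
  expect_true(is.na(m$recall))
})

test_that("partial dependence is flat for ignored features, decreasing in area", {
  feats <- area_driven_features(300, seed = 6)
  spl <- split_data(feats, seed = 6)
  rf <- fit_random_forest(spl$train, seed = 6)
  pd_area <- partial_dependence(rf, spl$test, "area_km2")
  # the qualitative shape: high-priority probability falls as area grows
  expect_gt(pd_area$mean_high_prob[1],
            pd_area$mean_high_prob[nrow(pd_area)])
  expect_lt(stats::cor(pd_area$value, pd_area$mean_high_prob,
                       method = "spearman"), 0)
  # a feature the labels never depended on gives a near-flat curve
  pd_noise <- partial_dependence(rf, spl$test, "rrw")
  expect_lt(diff(range(pd_noise$mean_high_prob)), 0.15)
  expect_error(partial_dependence(rf, spl$test, "nope"), "unknown feature")
})
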