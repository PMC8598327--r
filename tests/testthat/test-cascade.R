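test_that("stratified folds balance classes and reproduce under seeds", {
  y <- factor(rep(c("a", "b", "c", "d"), each = 25))
  f <- stratified_folds(y, K = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 20))
  for (cl in levels(y)) expect_true(all(table(f[y == cl]) == 5))
  expect_identical(f, stratified_folds(y, K = 5, seed = 3))
  expect_false(identical(f, stratified_folds(y, K = 5, seed = 4)))
  # 23 members over 5 folds: sizes {5,5,5,4,4} in some order
  y23 <- factor(rep("a", 23))
  f23 <- stratified_folds(y23, K = 5, seed = 1)
  expect_equal(sort(as.vector(table(f23))), c(4, 4, 5, 5, 5))
  expect_error(stratified_folds(factor(c("a", "a", "b")), K = 3, seed = 1),
               "fewer than K")
})

test_that("augment concatenates non-destructively with checked shapes", {
  X <- matrix(rnorm(20), 5, 4)
  L <- matrix(runif(10), 5, 2)
  A <- augment(X, L)
  expect_equal(dim(A), c(5, 6))
  expect_identical(A[, 1:4], X)
  expect_error(augment(X, L[1:3, ]), "row mismatch")
})

test_that("a layer produces out-of-fold probabilities and Eq.-style accuracy", {
  df <- make_separable_data(n = 150, classes = 3, seed = 1)
  schema <- fit_schema(df, label_col = "label")
  X <- encode(df, schema)
  y <- factor(df$label)
  cfg <- fast_config(seed = 2)
  folds <- stratified_folds(y, K = 3, seed = 5)
  layer <- train_layer(X, y, cfg, folds)
  P <- nlevels(y)
  expect_equal(dim(layer$oof), c(150, P * length(cfg$roster)))
  # per-learner blocks are probability vectors
  for (p in layer$oof_list) {
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  }
  # E is exactly the mean of the per-fold accuracies
  expect_equal(layer$E, mean(layer$E_i))
  expect_length(layer$E_i, 3)
  # clearly separable data is learned well out of fold
  expect_gte(layer$E, 0.95)
})

test_that("out-of-fold predictions cannot come from in-fold memorization", {
  # labels independent of features: any out-of-fold accuracy is chance-level,
  # while refit-on-all tree ensembles memorize the training set
  set.seed(9)
  df <- data.frame(x1 = rnorm(120), x2 = rnorm(120),
                   label = sample(c("a", "b"), 120, replace = TRUE),
                   stringsAsFactors = FALSE)
  schema <- fit_schema(df, label_col = "label")
  X <- encode(df, schema)
  y <- factor(df$label)
  cfg <- fast_config(seed = 3)
  layer <- train_layer(X, y, cfg, stratified_folds(y, 3, seed = 1))
  expect_lt(layer$E, 0.7)  # chance is 0.5
  refit_pred <- dsnrisk:::predict_proba(layer$learners$random_forest, X)
  refit_acc <- mean(levels(y)[max.col(refit_pred, "first")] == df$label)
  expect_gt(refit_acc, 0.85)
  expect_gt(refit_acc, layer$E + 0.15)
})

test_that("the cascade trains, stops, and predicts with coherent shapes", {
  df <- make_separable_data(n = 240, classes = 3, seed = 4)
  cfg <- fast_config(architecture = 1L, seed = 5L, max_layers = 3L)
  model <- fit_dsn(df, config = cfg, label_col = "label")
  expect_s3_class(model, "dsn")
  expect_lte(model$depth, length(model$trace))
  # the retained depth maximizes the traced accuracy
  expect_equal(model$trace[model$depth], max(model$trace))
  # Eq.-style consistency at every layer
  for (l in seq_along(model$layers)) {
    expect_equal(model$layers[[l]]$E, mean(model$layers[[l]]$E_i))
  }
  pred <- predict(model, df)
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-9))
  expect_gte(mean(as.character(pred$class) == df$label), 0.95)
})

test_that("a degenerate stopping tolerance keeps exactly one layer", {
  df <- make_separable_data(n = 150, classes = 3, seed = 6)
  cfg <- fast_config(architecture = 1L, seed = 2L, max_layers = 4L)
  cfg$tol <- Inf
  model <- fit_dsn(df, config = cfg, label_col = "label")
  expect_equal(model$depth, 1L)
  expect_equal(length(model$layers), 1L)
})

test_that("architecture 2 runs end to end on risk records", {
  df <- make_sim_data(n = 400, seed = 10)
  cfg <- fast_config(architecture = 2L, seed = 6L, K = 3L, max_layers = 2L)
  model <- fit_dsn(df, config = cfg)
  expect_false(is.null(model$scanners))
  expect_length(model$scanners, 3L)  # one scanner per fold
  pred <- predict(model, df[1:20, ])
  expect_equal(length(pred$class), 20)
  expect_true(all(pred$area %in% c("safe", "warning", "danger")))
  # area is a pure function of level
  expect_equal(pred$area, risk_area(as.character(pred$class)))
})

test_that("training is bit-reproducible under the master seed", {
  df <- make_sim_data(n = 300, seed = 11)
  cfg <- fast_config(architecture = 1L, seed = 42L)
  m1 <- fit_dsn(df, config = cfg)
  m2 <- fit_dsn(df, config = cfg)
  new <- make_sim_data(n = 80, seed = 12)
  p1 <- predict(m1, new); p2 <- predict(m2, new)
  expect_identical(p1$prob, p2$prob)
  expect_identical(p1$class, p2$class)
})

test_that("fit preconditions are enforced", {
  df <- make_separable_data(n = 60, classes = 1, seed = 2)
  expect_error(fit_dsn(df, config = fast_config(), label_col = "label"),
               "at least 2 classes")
  df3 <- make_separable_data(n = 9, classes = 3, seed = 2)
  expect_error(fit_dsn(df3, config = fast_config(K = 5L), label_col = "label"),
               "at least 2K")
  expect_error(fit_dsn(make_sim_data(n = 100)[, 1:5],
                       config = fast_config()), "no labels")
})

test_that("model archives round-trip and refuse foreign versions", {
  df <- make_separable_data(n = 120, classes = 2, seed = 8)
  cfg <- fast_config(architecture = 1L, seed = 9L, max_layers = 1L)
  model <- fit_dsn(df, config = cfg, label_col = "label")
  path <- tempfile(fileext = ".rds")
  save_dsn(model, path)
  back <- load_dsn(path)
  expect_identical(predict(back, df)$prob, predict(model, df)$prob)
  # tampered version field is rejected
  bad <- model; bad$version <- 99L
  saveRDS(bad, path)
  expect_error(load_dsn(path), "format version")
  saveRDS(list(), path)
  expect_error(load_dsn(path), "not a dsn model")
})

test_that("derived seeds stay within 32-bit range and spread", {
  s <- vapply(0:500, function(i) derive_seed(1234L, i), 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_gt(length(unique(s)), 490)
})
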