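test_that("easy_ensemble subsets are balanced and cover every negative", {
  tt <- toy_training(n_pos = 25, n_neg = 112)
  cfg <- train_config("logistic", "easy_ensemble", seed = 3)
  model <- suppressWarnings(train_model(tt$x, tt$y, cfg))
  n_pos <- sum(tt$y == 1)
  n_neg <- sum(tt$y == 0)
  expect_length(model$members, ceiling(n_neg / n_pos))  # ceil(112/25) = 5
  for (neg in model$member_negatives) {
    expect_length(neg, n_pos)                   # each subset padded to N_pos
    expect_length(unique(neg), n_pos)           # no duplicates within member
    expect_true(all(tt$y[neg] == 0))
  }
  all_negs <- names(tt$y)[tt$y == 0]
  expect_setequal(unlist(model$member_negatives), all_negs)  # full coverage
})

test_that("training and scoring are deterministic given the seed", {
  tt <- toy_training()
  cfg <- train_config(seed = 42)
  m1 <- train_model(tt$x, tt$y, cfg)
  m2 <- train_model(tt$x, tt$y, cfg)
  expect_identical(model_negatives_sorted(m1), model_negatives_sorted(m2))
  expect_equal(predict_scores(m1, tt$x), predict_scores(m2, tt$x))
  m3 <- train_model(tt$x, tt$y, train_config(seed = 43))
  expect_false(identical(model_negatives_sorted(m1),
                         model_negatives_sorted(m3)))
})

test_that("scores are probabilities and detect the planted signal", {
  tt <- toy_training(seed = 7)
  model <- easy_ensemble_fit(tt$x, tt$y, train_config(seed = 7))
  s <- predict_scores(model, tt$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(auroc(s, tt$y), 0.9)  # in-sample on a strong 2-feature signal
})

test_that("prevalence learner is feature-blind with AUPRC = prevalence", {
  tt <- toy_training(n_pos = 20, n_neg = 80)
  cfg <- train_config("prevalence", "raw", seed = 1)
  model <- train_model(tt$x, tt$y, cfg)
  s <- predict_scores(model, tt$x)
  expect_equal(unname(s), rep(0.2, 100))
  expect_equal(auprc(s, tt$y), 0.2)  # constant scores: AP = prevalence
  expect_equal(auroc(s, tt$y), 0.5)
})

test_that("SMOTE synthesizes convex combinations of positives", {
  set.seed(2)
  x_pos <- matrix(runif(20, 5, 6), 10, 2)
  syn <- lncforge:::smote_positives(x_pos, n_new = 50, seed = 9)
  expect_equal(dim(syn), c(50, 2))
  # interpolations stay inside the per-column bounding box of the positives
  expect_true(all(syn[, 1] >= min(x_pos[, 1]) & syn[, 1] <= max(x_pos[, 1])))
  expect_true(all(syn[, 2] >= min(x_pos[, 2]) & syn[, 2] <= max(x_pos[, 2])))
  # smote training balances the classes
  tt <- toy_training(n_pos = 15, n_neg = 60)
  model <- suppressWarnings(train_model(
    tt$x, tt$y, train_config("logistic", "oversample_smote", seed = 4)))
  expect_length(model$members, 1L)
})

test_that("every imbalance strategy trains and predicts", {
  tt <- toy_training(n_pos = 20, n_neg = 61, seed = 5)
  for (strat in c("raw", "class_weight", "undersample_random",
                  "oversample_random", "oversample_smote", "easy_ensemble")) {
    cfg <- train_config("logistic", strat, seed = 5)
    model <- suppressWarnings(train_model(tt$x, tt$y, cfg))
    s <- predict_scores(model, tt$x)
    expect_length(s, 81)
    expect_true(all(is.finite(s) & s >= 0 & s <= 1), info = strat)
  }
})

test_that("alternative base learners train and beat chance on easy data", {
  tt <- toy_training(n_pos = 25, n_neg = 50, seed = 11, shift = 2)
  for (learner in c("naive_bayes", "knn", "svm_rbf", "random_forest")) {
    cfg <- train_config(learner, "raw", seed = 11)
    model <- train_model(tt$x, tt$y, cfg)
    s <- predict_scores(model, tt$x)
    expect_gt(auroc(s, tt$y), 0.8, label = learner)
  }
})

test_that("train_config validates inputs", {
  expect_error(train_config("boosting"), "arg")
  expect_error(train_config(imbalance_strategy = "bogus"), "arg")
  expect_error(train_config(n_folds = 1))
  cfg <- train_config(hyperparams = list(n_estimators = 7))
  expect_equal(cfg$hyperparams$n_estimators, 7)
  expect_equal(cfg$hyperparams$num_leaves, 45)  # defaults preserved
})

test_that("train_model rejects degenerate inputs", {
  tt <- toy_training(n_pos = 10, n_neg = 5)
  expect_error(train_model(tt$x, tt$y, train_config("logistic")),
               "majority")
  y1 <- setNames(rep(1, 10), rownames(tt$x)[1:10])
  expect_error(train_model(tt$x[1:10, ], y1, train_config()), "both classes")
})

test_that("predict_scores reports feature mismatches by name", {
  tt <- toy_training()
  model <- train_model(tt$x, tt$y,
                       train_config("prevalence", "raw", seed = 1))
  bad <- tt$x
  colnames(bad)[1] <- "other"
  expect_error(predict_scores(model, bad), "missing \\[f1\\]")
  expect_error(predict_scores(model, bad), "extra \\[other\\]")
})

test_that("hold_out_split is stratified and exact", {
  tt <- toy_training(n_pos = 60, n_neg = 240)
  sp <- hold_out_split(tt$x, tt$y, test_fraction = 1 / 3, seed = 2)
  expect_equal(sum(sp$test$labels == 1), 20)
  expect_equal(sum(sp$test$labels == 0), 80)
  expect_length(intersect(rownames(sp$train$features),
                          rownames(sp$test$features)), 0)
  expect_setequal(c(rownames(sp$train$features), rownames(sp$test$features)),
                  rownames(tt$x))
})

test_that("cross_validate covers every gene once and is reproducible", {
  tt <- toy_training(n_pos = 25, n_neg = 75)
  cfg <- train_config("logistic", "class_weight", seed = 6, n_folds = 5)
  cv1 <- suppressWarnings(cross_validate(tt$x, tt$y, cfg))
  cv2 <- suppressWarnings(cross_validate(tt$x, tt$y, cfg))
  expect_equal(cv1$folds, cv2$folds)
  fa <- cv1$fold_assignment
  expect_setequal(names(fa), rownames(tt$x))
  expect_equal(sort(unique(fa)), 1:5)
  # stratification: each fold gets 5 positives
  expect_true(all(tapply(tt$y[names(fa)], fa, sum) == 5))
  expect_equal(cv1$mean_auprc, mean(cv1$folds$auprc))
})

test_that("cross_validate refuses folds without positives", {
  tt <- toy_training(n_pos = 3, n_neg = 50)
  expect_error(cross_validate(tt$x, tt$y, train_config(n_folds = 5)),
               "no positives")
})

test_that("strategy_leaderboard sorts by mean AUPRC descending", {
  tt <- toy_training(n_pos = 20, n_neg = 60, seed = 8)
  lb <- suppressWarnings(strategy_leaderboard(tt$x, tt$y, list(
    train_config("prevalence", "raw", seed = 8),
    train_config("logistic", "class_weight", seed = 8))))
  expect_equal(nrow(lb), 2)
  expect_true(!is.unsorted(rev(lb$mean_auprc)))
  expect_equal(lb$learner[1], "logistic")  # informative beats the null
  expect_error(strategy_leaderboard(tt$x, tt$y, list(train_config())))
})

test_that("save_model/load_model round trip reproduces predictions", {
  tt <- toy_training(n_pos = 20, n_neg = 45)
  cfg <- train_config(seed = 10, hyperparams = list(n_estimators = 20))
  model <- train_model(tt$x, tt$y, cfg)
  model$threshold <- 0.625
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_equal(back$threshold, 0.625)
  expect_equal(back$feature_order, model$feature_order)
  expect_length(back$members, length(model$members))
  expect_equal(predict_scores(back, tt$x), predict_scores(model, tt$x))
})
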