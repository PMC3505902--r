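# Cost-sensitive training, bagging, prediction and cross-validation.

test_that("cost weights are rescaled to sum to n", {
  y <- factor(c(rep("substrate", 5), rep("non-substrate", 45)),
              levels = c("substrate", "non-substrate"))
  for (cost in list(cost_spec(1, 1), cost_spec(150, 3.5), cost_spec(65, 2.5))) {
    w <- qsarpipe:::.cost_weights(y, cost)
    expect_equal(sum(w), 50)
    expect_gte(w[1] / w[50], 1)
  }
  expect_error(cost_spec(0, 1), "positive")
})

test_that("unit costs without bagging reproduce the plain base learner", {
  d <- separable_data(seed = 3)
  for (learner in c("decision_tree", "random_forest", "naive_bayes",
                    "linear_svm", "knn")) {
    mod <- train_model(d$X, d$y, learner = learner, cost = cost_spec(1, 1),
                       seed = 7)
    expect_length(mod$fits, 1)
    p1 <- predict(mod, d$X)
    # reference: identical fit path with equal weights is deterministic
    mod2 <- train_model(d$X, d$y, learner = learner, cost = cost_spec(1, 1),
                        seed = 7)
    expect_identical(p1, predict(mod2, d$X), label = learner)
  }
  # with equal weights no resampling happens: naive Bayes equals e1071 direct
  direct <- e1071::naiveBayes(as.data.frame(d$X), d$y)
  pd <- factor(as.character(predict(direct, as.data.frame(d$X))),
               levels = c("substrate", "non-substrate"))
  mod <- train_model(d$X, d$y, learner = "naive_bayes", cost = cost_spec(1, 1))
  expect_identical(predict(mod, d$X), pd)
})

test_that("an overwhelming false-negative cost forces all-substrate predictions", {
  d <- separable_data(n_sub = 8, n_non = 80, gap = 0.3, seed = 5)
  for (learner in c("decision_tree", "linear_svm")) {
    mod <- train_model(d$X, d$y, learner = learner, cost = cost_spec(1e6, 1),
                       seed = 2)
    pred <- predict(mod, d$X)
    m <- classification_metrics(confusion(d$y, pred))
    expect_equal(m$sensitivity, 1, label = learner)
  }
})

test_that("separable data give a perfect training confusion matrix", {
  d <- separable_data(seed = 11)
  for (learner in c("decision_tree", "random_forest", "linear_svm", "knn")) {
    mod <- train_model(d$X, d$y, learner = learner, seed = 4)
    m <- classification_metrics(confusion(d$y, predict(mod, d$X)))
    expect_equal(m$g_mean, 1, label = learner)
  }
})

test_that("models predict only from their selected features and catch misuse", {
  d <- separable_data(seed = 2)
  mod <- train_model(d$X, d$y, features = c("sig1", "sig2"),
                     learner = "decision_tree")
  expect_error(predict(mod, d$X[, "noise1", drop = FALSE]), "sig1")
  expect_error(train_model(d$X, d$y, features = "nope", learner = "knn"), "nope")
  expect_error(train_model(d$X, factor(rep("substrate", nrow(d$X)),
                                       levels = c("substrate", "non-substrate")),
                           learner = "knn"), "single class")
  expect_length(predict(mod, d$X[0, , drop = FALSE]), 0)
})

test_that("serialized models reload with identical predictions", {
  d <- separable_data(seed = 6)
  for (learner in c("random_forest", "naive_bayes")) {
    mod <- train_model(d$X, d$y, learner = learner,
                       cost = cost_spec(65, 2.5), bagging = 5, seed = 9)
    path <- tempfile(fileext = ".rds")
    saveRDS(mod, path)
    back <- readRDS(path)
    expect_identical(predict(mod, d$X), predict(back, d$X), label = learner)
  }
})

test_that("a single-replicate bagged model votes exactly like its one fit", {
  d <- separable_data(seed = 13)
  mod <- train_model(d$X, d$y, learner = "decision_tree",
                     cost = cost_spec(10, 1), bagging = 1, seed = 3)
  expect_length(mod$fits, 1)
  single <- qsarpipe:::.predict_base(mod$fits[[1]], "decision_tree",
                                     d$X[, mod$features, drop = FALSE])
  expect_identical(predict(mod, d$X), single)
})

test_that("bagged majority votes break ties toward the substrate class", {
  fits <- list("a", "b")   # two dummy fits
  votes <- matrix(c("substrate", "non-substrate"), 1, 2)
  pred <- apply(votes, 1, function(v) {
    if (sum(v == "substrate") * 2 >= length(v)) "substrate" else "non-substrate"
  })
  expect_equal(pred, "substrate")
})

test_that("stratified folds balance classes and pooled counts are conserved", {
  d <- separable_data(n_sub = 13, n_non = 47, seed = 21)
  fold <- qsarpipe:::stratified_folds(d$y, 5, seed = 2)
  expect_equal(range(table(fold)), c(12, 12))
  per_fold_sub <- table(fold[d$y == "substrate"])
  expect_lte(diff(range(per_fold_sub)), 1)
  m <- cross_validate(d$X, d$y, learner = "decision_tree", k = 5, seed = 3)
  cm <- m$confusion
  expect_equal(cm$tp + cm$fn, 13)            # pooled TP+FN = substrates
  expect_equal(cm$tn + cm$fp, 47)
  expect_error(cross_validate(d$X, d$y, learner = "knn", k = 20, seed = 1),
               "fewer members")
  # a cleanly separable problem cross-validates perfectly
  wide <- separable_data(n_sub = 20, n_non = 40, gap = 6, seed = 22)
  mp <- cross_validate(wide$X, wide$y, learner = "random_forest", k = 5, seed = 4)
  expect_equal(mp$g_mean, 1)
})

test_that("cross-validation is reproducible for a fixed seed", {
  d <- separable_data(n_sub = 15, n_non = 45, gap = 1, seed = 31)
  m1 <- cross_validate(d$X, d$y, learner = "random_forest", k = 5, seed = 11)
  m2 <- cross_validate(d$X, d$y, learner = "random_forest", k = 5, seed = 11)
  expect_equal(m1$confusion, m2$confusion)
})

test_that("the cost grid search returns the G-mean winner with a full report", {
  d <- separable_data(n_sub = 10, n_non = 90, gap = 0.8, seed = 41)
  cands <- list(cost_spec(1, 1), cost_spec(100, 1))
  res <- cost_grid_search(d$X, d$y, learner = "decision_tree",
                          candidates = cands, k = 5, seed = 5)
  expect_equal(nrow(res$report), 2)
  expect_equal(sum(res$report$selected), 1)
  expect_equal(res$best_metrics$g_mean, max(res$report$g_mean))
  # strong imbalance: the cost-sensitive candidate wins on G-mean
  expect_equal(res$best$fn_cost, 100)
  single <- cost_grid_search(d$X, d$y, learner = "decision_tree",
                             candidates = list(cost_spec(2, 1)), k = 5, seed = 5)
  expect_equal(single$best$fn_cost, 2)
})
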