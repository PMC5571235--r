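# Flat single-node tree helpers for ensemble-level contracts.
flat_leaf <- function(score) {
  list(feature = NA_integer_, threshold = 0, missing_left = TRUE,
       left = NA_integer_, right = NA_integer_, value = score)
}

manual_model <- function(trees_per_class, classes, feature_names) {
  structure(list(classes = classes, feature_names = feature_names,
                 trees = trees_per_class, n_rounds = 0,
                 cfg = train_config()),
            class = "semloc_gbt")
}

test_that("routing descends thresholds and missing branches", {
  leaf <- list(score = 0.7)
  expect_equal(route(leaf, c(f1 = 123)), 0.7)
  tr <- hand_tree()
  # hand-traced scores for the 8 combinations (low/high/missing per feature)
  expect_equal(route(tr, c(f1 = 0.2, f2 = 0.1)), 0.1)
  expect_equal(route(tr, c(f1 = 0.2, f2 = 0.9)), 0.2)
  expect_equal(route(tr, c(f1 = 0.9, f2 = 0.1)), 0.3)
  expect_equal(route(tr, c(f1 = 0.9, f2 = 0.9)), 0.4)
  expect_equal(route(tr, c(f1 = NA, f2 = 0.1)), 0.1)   # missing -> left
  expect_equal(route(tr, c(f1 = NA, f2 = 0.9)), 0.2)
  expect_equal(route(tr, c(f1 = 0.2, f2 = NA)), 0.2)   # inner missing -> right
  expect_equal(route(tr, c(f1 = 0.9, f2 = NA)), 0.3)   # inner missing -> left
})

test_that("ensemble scores are sums of per-class tree scores", {
  classes <- c("A", "B")
  empty <- manual_model(list(list(), list()), classes, c("x"))
  sc <- predict_scores(empty, matrix(1, 3, 1, dimnames = list(NULL, "x")))
  expect_equal(unname(sc), matrix(0, 3, 2))
  two <- manual_model(list(list(flat_leaf(0.2), flat_leaf(0.3)),
                           list(flat_leaf(-0.1))), classes, c("x"))
  sc2 <- predict_scores(two, matrix(1, 1, 1, dimnames = list(NULL, "x")))
  expect_equal(unname(sc2[1, ]), c(0.5, -0.1))
  # summation oracle on a random stack of single-leaf trees
  set.seed(301)
  vals <- rnorm(5)
  m <- manual_model(list(lapply(vals, flat_leaf), list()), classes, "x")
  expect_equal(unname(predict_scores(m, matrix(0, 1, 1,
                                               dimnames = list(NULL,
                                                               "x")))[1, 1]),
               sum(vals))
})

test_that("softmax probabilities normalise and shift-invariantly", {
  p <- class_probabilities(rep(0, 11))
  expect_equal(p, rep(1 / 11, 11))
  p2 <- class_probabilities(c(1, 0))
  expect_equal(p2, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)))
  set.seed(302)
  for (i in 1:50) {
    s <- rnorm(sample(2:11, 1), sd = 10)
    expect_equal(sum(class_probabilities(s)), 1, tolerance = 1e-9)
    expect_equal(class_probabilities(s),
                 class_probabilities(s + runif(1, -700, 700)),
                 tolerance = 1e-9)
  }
  # overflow-safe at extreme scores
  expect_equal(sum(class_probabilities(c(1e4, 0, -1e4))), 1)
})

test_that("training separates a separable toy and drives loss down", {
  toy <- toy_classes(n_per = 20)
  cfg <- train_config(learning_rate = 0.3, max_depth = 3, gamma = 0,
                      subsample = 1, colsample = 1, max_rounds = 30,
                      seed = 5)
  fit <- gbt_fit(toy$X, toy$y, cfg)
  expect_lt(fit$train_loss[30], fit$train_loss[1])
  expect_true(all(diff(fit$train_loss[1:10]) < 0))
  expect_equal(predict(fit, toy$X, type = "class"), toy$y)
})

test_that("training loss is non-increasing at learning rate 0.025", {
  toy <- toy_classes(n_per = 15, seed = 2)
  cfg <- train_config(subsample = 1, colsample = 1, max_rounds = 40,
                      seed = 6)   # paper-style lr 0.025, depth 4, gamma 0.4
  fit <- gbt_fit(toy$X, toy$y, cfg)
  expect_true(all(diff(fit$train_loss) <= 1e-10))
})

test_that("the tuned study configuration runs to completion", {
  w <- generate_cohort(world_config(n_participants = 3, study_days = 4,
                                    seed = 12))
  ds <- cohort_dataset(w$participants, "sensor")
  cfg <- train_config(max_rounds = 200)   # depth 4, lr 0.025, g .4, l 1, a 0
  fit <- gbt_fit(ds$X, ds$y, cfg)
  expect_equal(fit$n_rounds, 200)
  pr <- predict(fit, ds$X, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
})

test_that("strong L2 regularisation collapses predictions to uniform", {
  toy <- toy_classes(n_per = 10)
  cfg <- train_config(lambda = 1e6, alpha = 0, subsample = 1, colsample = 1,
                      max_rounds = 10, seed = 7)
  fit <- gbt_fit(toy$X, toy$y, cfg)
  pr <- predict(fit, toy$X, type = "prob")
  expect_equal(unname(pr), matrix(1 / 3, nrow(pr), 3), tolerance = 1e-3)
})

test_that("features no tree splits on cannot change predictions", {
  toy <- toy_classes(n_per = 20, noise_cols = 3, seed = 3)
  cfg <- train_config(learning_rate = 0.2, max_rounds = 20, subsample = 1,
                      colsample = 0.5, gamma = 0.5, seed = 8)
  fit <- gbt_fit(toy$X, toy$y, cfg)
  used <- sort(unique(unlist(lapply(fit$trees, function(cls)
    lapply(cls, function(tr) tr$feature[!is.na(tr$feature)])))))
  unused <- setdiff(seq_len(ncol(toy$X)), used)
  # the toy's noise columns should include at least one never-split feature
  expect_gt(length(unused), 0)
  X2 <- toy$X
  X2[, unused] <- X2[, unused] + rnorm(length(X2[, unused]), 0, 100)
  expect_identical(predict(fit, toy$X, type = "score"),
                   predict(fit, X2, type = "score"))
  # and making an unused feature missing changes nothing either
  X3 <- toy$X; X3[, unused] <- NA
  expect_identical(predict(fit, toy$X, type = "score"),
                   predict(fit, X3, type = "score"))
})

test_that("missing values are routed through learned default branches", {
  # class fully determined by fa, with fa missing for a block of rows whose
  # class differs: the missing branch must learn to separate them
  set.seed(304)
  X <- matrix(c(rnorm(30, 0), rnorm(30, 5), rep(NA, 30)), ncol = 1,
              dimnames = list(NULL, "fa"))
  y <- rep(c("A", "B", "B"), each = 30)
  cfg <- train_config(learning_rate = 0.5, max_rounds = 10, subsample = 1,
                      colsample = 1, gamma = 0, seed = 9)
  fit <- gbt_fit(X, y, cfg)
  expect_equal(predict(fit, X, type = "class"), y)
})

test_that("fit rejects degenerate inputs", {
  toy <- toy_classes(n_per = 5)
  expect_error(gbt_fit(toy$X, rep("A", nrow(toy$X))),
               class = "DegenerateLabels")
  expect_error(train_config(subsample = 0), class = "ConfigError")
  expect_error(train_config(colsample = 1.5), class = "ConfigError")
})

test_that("fitting is deterministic under a fixed seed", {
  toy <- toy_classes(n_per = 12, seed = 4)
  cfg <- train_config(max_rounds = 10, seed = 11)
  f1 <- gbt_fit(toy$X, toy$y, cfg)
  f2 <- gbt_fit(toy$X, toy$y, cfg)
  expect_identical(predict(f1, toy$X, type = "score"),
                   predict(f2, toy$X, type = "score"))
})

test_that("serialised models reload with identical predictions", {
  toy <- toy_classes(n_per = 15, noise_cols = 2, seed = 5)
  toy$X[sample(length(toy$X), 30)] <- NA
  fit <- gbt_fit(toy$X, toy$y, train_config(max_rounds = 15, seed = 13))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_gbt(fit, f)
  back <- read_gbt(f)
  expect_identical(back$classes, fit$classes)
  expect_equal(predict(back, toy$X, type = "score"),
               predict(fit, toy$X, type = "score"), tolerance = 1e-12)
})

test_that("internal CV early stopping can stop before the round budget", {
  set.seed(305)
  # pure-noise labels: CV loss stops improving almost immediately
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(c("A", "B"), 200, replace = TRUE)
  cfg <- train_config(learning_rate = 0.3, max_rounds = 80, subsample = 1,
                      colsample = 1, gamma = 0, es_folds = 3,
                      es_patience = 5, seed = 14)
  fit <- gbt_fit(X, y, cfg)
  expect_lt(fit$n_rounds, 80)
  expect_length(fit$cv_curve, 80)
})

test_that("grid search prefers a sane configuration over a degenerate one", {
  toy <- toy_classes(n_per = 30, seed = 6)
  subject <- rep(sprintf("S%02d", 1:10), length.out = nrow(toy$X))
  sane <- train_config(learning_rate = 0.3, max_rounds = 15, subsample = 1,
                       colsample = 1, seed = 15)
  degenerate <- train_config(learning_rate = 0.3, max_rounds = 15,
                             lambda = 1e6, subsample = 1, colsample = 1,
                             seed = 15)
  # one-point grid returns that point
  g1 <- grid_search(toy$X, toy$y, subject, list(sane), k_folds = 3)
  expect_identical(g1$best, sane)
  g2 <- grid_search(toy$X, toy$y, subject, list(degenerate, sane),
                    k_folds = 3)
  expect_identical(g2$best, sane)
  # tuning subset selection is seeded and reproducible
  ids <- sprintf("P%03d", 1:50)
  expect_identical(tuning_subset(ids, seed = 3), tuning_subset(ids, seed = 3))
  expect_length(tuning_subset(ids, frac = 0.1, seed = 3), 5)
})

test_that("per-class AUC matches the xgboost reference within 0.03", {
  skip_if_not_installed("xgboost")
  set.seed(306)
  n <- 400
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  lin <- 1.2 * X[, 1] - X[, 2]
  y <- ifelse(lin + rnorm(n) > 0.5, "A", ifelse(lin + rnorm(n) < -0.5,
                                                "B", "C"))
  X[sample(length(X), 100)] <- NA
  tr <- sample(n, 250)
  cfg <- train_config(learning_rate = 0.1, max_depth = 4, gamma = 0,
                      lambda = 1, alpha = 0, subsample = 1, colsample = 1,
                      max_rounds = 60, seed = 16)
  fit <- gbt_fit(X[tr, ], y[tr], cfg)
  pr <- predict(fit, X[-tr, ], type = "prob")
  xgb <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3,
                  eta = 0.1, max_depth = 4, gamma = 0, lambda = 1,
                  alpha = 0, nthread = 1),
    data = xgboost::xgb.DMatrix(X[tr, ],
                                label = match(y[tr], fit$classes) - 1),
    nrounds = 60, verbose = 0)
  prx <- predict(xgb, xgboost::xgb.DMatrix(X[-tr, ]))
  expect_equal(dim(prx), c(n - 250, 3))
  for (m in seq_along(fit$classes)) {
    pos <- y[-tr] == fit$classes[m]
    if (!any(pos) || all(pos)) next
    expect_lt(abs(roc_auc(pr[, m], pos) - roc_auc(prx[, m], pos)), 0.03)
  }
})
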