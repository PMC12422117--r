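test_that("split_dataset allocates subjects at the requested fractions", {
  ids <- sprintf("P%03d", 1:100)
  labels <- rep(c(1, 0), 50)
  sp <- split_spec(0.6, 0.3, 0.1, seed = 1)
  parts <- split_dataset(ids, labels, sp)
  expect_length(parts$train, 60)
  expect_length(parts$val, 30)
  expect_length(parts$test, 10)
  expect_setequal(c(parts$train, parts$val, parts$test), ids)

  # determinism
  parts2 <- split_dataset(ids, labels, split_spec(0.6, 0.3, 0.1, seed = 1))
  expect_identical(parts, parts2)
  parts3 <- split_dataset(ids, labels, split_spec(0.6, 0.3, 0.1, seed = 2))
  expect_false(identical(parts, parts3))

  # stratification keeps the class ratio within one subject per portion
  ids45 <- sprintf("Q%02d", 1:45)
  lab45 <- rep(c(1, 0), c(20, 25))
  p45 <- split_dataset(ids45, lab45, split_spec(0.6, 0.3, 0.1, seed = 3))
  for (portion in p45) {
    npos <- sum(lab45[match(portion, ids45)] == 1)
    expected <- length(portion) * 20 / 45
    expect_lte(abs(npos - expected), 1)
  }

  expect_error(split_spec(0.5, 0.3, 0.1))
  expect_error(split_dataset(ids[1:5], labels[1:5], sp))
})

test_that("make_folds partitions subjects into balanced folds", {
  ids <- sprintf("S%03d", 1:45)
  labels <- rep(c(1, 0), c(20, 25))
  folds <- make_folds(ids, labels, k = 5, seed = 1)
  expect_equal(vapply(folds, length, integer(1)), rep(9L, 5))
  expect_setequal(unlist(folds), ids)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  expect_error(make_folds(ids[1:3], labels[1:3], k = 5))
})

test_that("scalar metrics match hand arithmetic", {
  expect_equal(mse(c(1, 0), c(1, 0)), 0)
  expect_equal(mse(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(mse(1, 0), 1)
  expect_error(mse(c(1, 0), 0.5))

  expect_equal(f1_score(c(TP = 10, FP = 0, FN = 0)), 1)
  expect_equal(f1_score(c(TP = 0, FP = 3, FN = 2)), 0)
  expect_equal(round(f1_score(c(TP = 8, FP = 2, FN = 4)), 4), 0.7273)
  expect_error(f1_score(c(TP = 0, FP = 0, FN = 0)))

  expect_equal(accuracy(c(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(accuracy(c(TP = 0, TN = 0, FP = 5, FN = 5)), 0)
  expect_equal(accuracy(c(TP = 45, TN = 45, FP = 5, FN = 5)), 0.90)
})

test_that("rank-statistic AUC equals the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))$auc, 0.75)

  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)   # rounding forces ties
    expect_equal(roc_auc(y, s)$auc, pairwise_auc(y, s), tolerance = 1e-12)
  }

  # independent library cross-check
  set.seed(7)
  y <- rbinom(60, 1, 0.5); s <- runif(60)
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-9)

  # curve endpoints
  cv <- roc_auc(y, s)$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)

  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)))
})

test_that("training is reproducible, inert at lr 0, and descends", {
  set.seed(20)
  X <- rbind(matrix(rnorm(10 * 6, 1.5), 10, 6),
             matrix(rnorm(10 * 6, -1.5), 10, 6))
  y <- rep(c(1, 0), each = 10)
  cfg <- tiny_config()

  # lr = 0 leaves the initial weights untouched and the history flat
  # (stochastic regularization off so the train-mode loss is deterministic)
  cfg_det <- tiny_config(spatial_dropout_rate = 0,
                         stochastic_depth_survival = 1)
  fit0 <- adena_train(X, y, model_config = cfg_det,
                      config = train_config(0, 5L, 4L, seed = 3))
  init <- adena_init(cfg_det, 6L, seed = 3)
  expect_identical(breathdx:::flatten_weights(fit0$model$weights),
                   breathdx:::flatten_weights(init$weights))
  expect_lt(diff(range(fit0$history$train_loss)), 1e-9)

  # identical seeds give identical histories
  fa <- adena_train(X, y, model_config = cfg,
                    config = train_config(5e-4, 10L, 4L, seed = 4))
  fb <- adena_train(X, y, model_config = cfg,
                    config = train_config(5e-4, 10L, 4L, seed = 4))
  expect_identical(fa$history, fb$history)

  # loss at the end is not above the starting loss
  f200 <- adena_train(X, y, model_config = cfg,
                      config = train_config(5e-4, 60L, 4L, seed = 5))
  expect_lte(f200$history$train_loss[60], f200$history$train_loss[1])

  expect_error(adena_train(X[0, ], numeric(0)))
})

test_that("cross-validation is subject-level and leakage-free", {
  ft <- small_features()
  cv <- cross_validate(ft, k = 4,
                       config = train_config(5e-4, 15L, 4L, seed = 6))
  expect_length(cv$reports, 4)
  expect_setequal(unlist(cv$folds), ft$subject_id)
  expect_equal(nrow(cv$predictions), nrow(ft))

  # subject-id-only features cannot beat chance under subject-level folds:
  # a 1-NN memorizer classifies training subjects perfectly yet scores at
  # chance on held-out subjects
  set.seed(8)
  n <- 200
  ids <- sprintf("L%03d", 1:n)
  labs <- rep(c(1L, 0L), n / 2)
  idfeat <- matrix(rnorm(n * 3), n, 3)   # pure per-subject noise
  folds <- make_folds(ids, labs, 5, seed = 9)
  y_all <- c(); p_all <- c()
  for (f in seq_along(folds)) {
    te <- ids %in% folds[[f]]
    pr <- class::knn(idfeat[!te, ], idfeat[te, ], factor(labs[!te]), k = 1)
    # sanity: the same memorizer is perfect on its own training subjects
    tr_pred <- class::knn(idfeat[!te, ], idfeat[!te, ], factor(labs[!te]),
                          k = 1)
    expect_equal(mean(tr_pred == factor(labs[!te])), 1)
    y_all <- c(y_all, labs[te])
    p_all <- c(p_all, as.numeric(pr == "1"))
  }
  expect_lt(abs(roc_auc(y_all, p_all)$auc - 0.5), 0.1)
})

test_that("grid search ranks configurations by mean F1", {
  ft_small <- small_features()[1:12, ]

  # a single-configuration grid wins trivially
  g1 <- grid_search(ft_small, learning_rates = 1e-3, epochs_grid = 5L,
                    batch_sizes = 4L, k = 2, seed = 1)
  expect_equal(nrow(g1$ranking), 1)
  expect_equal(g1$best$learning_rate, 1e-3)
  expect_equal(g1$best$epochs, 5L)

  # the ranking is a permutation of the Cartesian product
  g2 <- grid_search(ft_small, learning_rates = c(1e-3, 1e-2),
                    epochs_grid = c(5L, 10L), batch_sizes = 4L, k = 2,
                    seed = 1)
  expect_equal(nrow(g2$ranking), 4)
  expect_setequal(paste(g2$ranking$learning_rate, g2$ranking$epochs),
                  paste(rep(c(1e-3, 1e-2), 2), rep(c(5L, 10L), each = 2)))

  # an unstable large step ranks below the tuned step on a moderately
  # separable fixture
  p <- scale_effect(table_profile("adult", noise_frac = 0.3), 0.25)
  ch <- generate_cohort(cohort_spec(15, 15, "adult", profile = p, seed = 5))
  ft <- extract_feature_table(ch)
  g3 <- grid_search(ft, learning_rates = c(5e-4, 1e-1), epochs_grid = 15L,
                    batch_sizes = 4L, k = 3, seed = 3)
  pos <- match(c(5e-4, 1e-1), g3$ranking$learning_rate)
  expect_lt(pos[1], pos[2])
})

test_that("reference classifiers clear the sanity floor on separable data", {
  ft <- medium_features()
  tab <- reference_classifiers(ft, k = 3, seed = 2)
  expect_setequal(tab$model,
                  c("svm", "knn", "logistic", "mlp", "cart", "naive_bayes"))
  ok <- is.na(tab$error)
  expect_true(all(ok))
  expect_true(all(tab$accuracy[ok] > 0.5))

  sub <- reference_classifiers(small_features(), k = 3,
                               models = c("svm", "cart"), seed = 2)
  expect_equal(nrow(sub), 2)
})

test_that("reference classifiers sit at chance when the effect is removed", {
  p0 <- scale_effect(table_profile("adult"), 0)
  ch <- generate_cohort(cohort_spec(100, 100, "adult", profile = p0,
                                    seed = 31, n_samples = 120L))
  ft <- extract_feature_table(ch)
  tab <- reference_classifiers(ft, k = 5, seed = 4)
  ok <- is.na(tab$error)
  expect_true(all(abs(tab$auc[ok] - 0.5) < 0.1))
})
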