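# Training and evaluation harness: subject-level splitting, Adam training of
# the ADENA network, k-fold cross-validation, hyperparameter grid search,
# classification metrics, and a reference-classifier comparison.

#' Split specification
#'
#' @param train_fraction,val_fraction,test_fraction portions summing to 1.
#' @param seed integer RNG seed.
#' @param stratified keep the class ratio in every portion?
#' @return list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.6, val_fraction = 0.3,
                       test_fraction = 0.1, seed = 1L, stratified = TRUE) {
  fr <- c(train_fraction, val_fraction, test_fraction)
  assert_that(all(fr >= 0) && abs(sum(fr) - 1) <= 1e-9,
              "fractions must be nonnegative and sum to 1")
  structure(list(train_fraction = train_fraction,
                 val_fraction = val_fraction, test_fraction = test_fraction,
                 seed = as.integer(seed), stratified = stratified),
            class = "split_spec")
}

# largest-remainder apportionment of n into parts proportional to fr
apportion <- function(n, fr) {
  raw <- n * fr
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Subject-level train/validation/test split
#'
#' Randomly allocates subjects (never individual replicate records) to the
#' three portions at the specified fractions, stratified by label when
#' requested. Portions are disjoint and exhaustive.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param labels 0/1 labels aligned with `subject_ids`.
#' @param spec a [split_spec()].
#' @return list with character vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(subject_ids, labels, spec = split_spec()) {
  assert_that(inherits(spec, "split_spec"), "spec must come from split_spec()")
  assert_that(!anyDuplicated(subject_ids), "subject_ids must be unique")
  assert_that(length(subject_ids) >= 10, "need at least 10 subjects")
  fr <- c(spec$train_fraction, spec$val_fraction, spec$test_fraction)
  assign_group <- function(ids, seed) {
    sizes <- apportion(length(ids), fr)
    perm <- with_seed(seed, sample(ids))
    split(perm, rep(c("train", "val", "test"), sizes))
  }
  if (spec$stratified) {
    seeds <- derive_seeds(spec$seed, 2)
    g1 <- assign_group(subject_ids[labels == 1], seeds[1])
    g0 <- assign_group(subject_ids[labels == 0], seeds[2])
    out <- lapply(c(train = "train", val = "val", test = "test"),
                  function(p) c(g1[[p]], g0[[p]]))
  } else {
    out <- assign_group(subject_ids, spec$seed)
    out <- out[c("train", "val", "test")]
  }
  lapply(out, function(x) sort(unname(x %||% character(0))))
}

#' Stratified subject-level folds
#'
#' @param subject_ids unique subject identifiers.
#' @param labels aligned 0/1 labels.
#' @param k fold count, `2 <= k <=` number of subjects.
#' @param seed RNG seed.
#' @return list of `k` character vectors (held-out subjects per fold),
#'   pairwise disjoint with union equal to all subjects.
#' @export
make_folds <- function(subject_ids, labels, k = 5L, seed = 1L) {
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2")
  assert_that(length(subject_ids) >= k, "more folds than subjects")
  seeds <- derive_seeds(seed, 2)
  folds <- rep(list(character(0)), k)
  for (cl in c(1, 0)) {
    ids <- with_seed(seeds[cl + 1], sample(subject_ids[labels == cl]))
    fold_id <- rep(seq_len(k), length.out = length(ids))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], ids[fold_id == f])
  }
  lapply(folds, sort)
}

# ---- metrics ----

#' Mean squared error between labels and predicted probabilities
#' @param y_actual 0/1 labels.
#' @param y_predicted probabilities.
#' @return scalar `(1/N) * sum((y - p)^2)`.
#' @export
mse <- function(y_actual, y_predicted) {
  assert_that(length(y_actual) == length(y_predicted) && length(y_actual) >= 1,
              "inputs must be equal-length, nonempty")
  mean((y_actual - y_predicted)^2)
}

#' Confusion counts at a threshold
#' @param y 0/1 labels; @param p probabilities; @param threshold cut point.
#' @return named vector (TP, TN, FP, FN).
#' @export
confusion_counts <- function(y, p, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  c(TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
    FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision and recall; defined as 0 when TP = 0.
#'
#' @param confusion named vector with TP, FP, FN (TN ignored).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(confusion) {
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]; fn <- confusion[["FN"]]
  assert_that(tp + fp + fn >= 1, "confusion has no positives or predictions")
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Accuracy from confusion counts
#' @param confusion named vector with TP, TN, FP, FN.
#' @return `(TP + TN) / total`.
#' @export
accuracy <- function(confusion) {
  tot <- sum(confusion[c("TP", "TN", "FP", "FN")])
  assert_that(tot >= 1, "empty confusion")
  (confusion[["TP"]] + confusion[["TN"]]) / tot
}

#' ROC curve and AUC via the rank statistic
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half (the Mann-Whitney statistic). Curve
#' points are the TPR/FPR pairs at every distinct threshold.
#'
#' @param y_actual 0/1 labels (both classes present).
#' @param scores real-valued scores (higher = more positive).
#' @return list: `auc`, `curve` (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(y_actual, scores) {
  assert_that(length(y_actual) == length(scores),
              "label/score length mismatch")
  npos <- sum(y_actual == 1); nneg <- sum(y_actual == 0)
  assert_that(npos >= 1 && nneg >= 1, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_actual == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    fpr = c(0, vapply(th, function(t) sum(scores >= t & y_actual == 0),
                      numeric(1)) / nneg),
    tpr = c(0, vapply(th, function(t) sum(scores >= t & y_actual == 1),
                      numeric(1)) / npos))
  list(auc = unname(auc), curve = curve)
}

#' Evaluation report for one prediction set
#'
#' @param y 0/1 labels; @param p probabilities; @param threshold decision
#'   threshold for the confusion counts (AUC is threshold-free).
#' @return list of class `eval_report`: accuracy, f1, mse, auc, confusion,
#'   threshold.
#' @export
eval_report <- function(y, p, threshold = 0.5) {
  cm <- confusion_counts(y, p, threshold)
  structure(list(accuracy = accuracy(cm), f1 = f1_score(cm),
                 mse = mse(y, p),
                 auc = if (length(unique(y)) == 2) roc_auc(y, p)$auc
                       else NA_real_,
                 confusion = cm, threshold = threshold),
            class = "eval_report")
}

# ---- training ----

#' Training configuration
#'
#' @param learning_rate Adam step size (optimum 5e-4).
#' @param epochs full passes over the training set (optimum 200).
#' @param batch_size minibatch size (the tuned value is 4).
#' @param seed RNG seed covering shuffling and stochastic regularization.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 200L,
                         batch_size = 4L, seed = 1L) {
  assert_that(learning_rate >= 0, "learning_rate must be >= 0")
  assert_that(is_count(epochs) && is_count(batch_size),
              "epochs and batch_size must be positive integers")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = "adam",
                 seed = as.integer(seed)), class = "train_config")
}

#' Train an ADENA model with Adam
#'
#' Minimizes the combined focal + binary cross-entropy loss by Adam updates
#' over shuffled minibatches. With a fixed seed the whole history is
#' reproducible on one thread. Non-finite loss aborts with a diagnostic.
#'
#' @param x_train,y_train training features (matrix) and 0/1 labels.
#' @param x_val,y_val optional validation set for the per-epoch history.
#' @param model_config an [adena_config()].
#' @param config a [train_config()].
#' @return list of class `adena_fit`: `model` (trained weights),
#'   `history` (data frame epoch/train_loss/val_loss).
#' @export
adena_train <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                        model_config = adena_config(),
                        config = train_config()) {
  x_train <- as.matrix(x_train)
  assert_that(nrow(x_train) >= 1, "empty training set")
  assert_that(nrow(x_train) == length(y_train), "feature/label mismatch")
  model <- adena_init(model_config, ncol(x_train), seed = config$seed)
  gamma <- model_config$gamma
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  wvec <- flatten_weights(model$weights)
  m1 <- numeric(length(wvec)); m2 <- numeric(length(wvec))
  step <- 0L
  n <- nrow(x_train)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      Xb <- x_train[bi, , drop = FALSE]
      yb <- y_train[bi]
      fw <- nn_forward(model, Xb, train = TRUE, keep_cache = TRUE)
      p <- fw$probability
      loss <- combined_loss(yb, p, gamma)
      if (!is.finite(loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
             call. = FALSE)
      ep_loss <- ep_loss + loss * length(bi)
      if (lr > 0) {
        dlogit <- combined_loss_grad_p(yb, p, gamma) * p * (1 - p) /
          length(bi)
        gr <- nn_backward(model, fw$cache, dlogit)
        gvec <- unlist(gr[names(model$weights)], use.names = FALSE)
        step <- step + 1L
        m1 <- beta1 * m1 + (1 - beta1) * gvec
        m2 <- beta2 * m2 + (1 - beta2) * gvec^2
        mhat <- m1 / (1 - beta1^step)
        vhat <- m2 / (1 - beta2^step)
        wvec <- wvec - lr * mhat / (sqrt(vhat) + adam_eps)
        model$weights <- unflatten_weights(wvec, model$weights)
      }
    }
    val_loss <- if (!is.null(x_val) && nrow(as.matrix(x_val)) > 0) {
      pv <- nn_forward(model, as.matrix(x_val), train = FALSE)$probability
      combined_loss(y_val, pv, gamma)
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
  }
  structure(list(model = model, history = history), class = "adena_fit")
}

#' Predict probabilities from a trained fit
#' @param fit an `adena_fit` (or `adena_model`).
#' @param x feature matrix.
#' @return probability vector (eval mode, deterministic).
#' @export
adena_predict <- function(fit, x) {
  model <- if (inherits(fit, "adena_fit")) fit$model else fit
  nn_forward(model, as.matrix(x), train = FALSE)$probability
}

# Standardize + PCA fitted on the training rows only, applied to both;
# returns variance-weighted scores. Guards against train/test leakage.
prepare_fold_features <- function(feat_train, feat_test,
                                  variance_target = 0.95) {
  Xtr <- suppressWarnings(standardize(feat_train))
  ctr <- attr(Xtr, "center"); scl <- attr(Xtr, "scale")
  const <- attr(Xtr, "constant_features")
  Xte <- sweep(sweep(as.matrix(feat_test), 2, ctr), 2, scl, "/")
  if (length(const)) Xte[, const] <- 0
  pca <- fit_pca(Xtr, variance_target = variance_target)
  list(train = pca_weighted_scores(pca, Xtr),
       test = pca_weighted_scores(pca, Xte), pca = pca)
}

feature_columns <- function(features) {
  setdiff(colnames(features), c("subject_id", "label", "age_group"))
}

#' Subject-level k-fold cross-validation of ADENA
#'
#' Splits subjects into `k` stratified folds (replicates of one subject
#' never straddle folds, since the feature table holds one aggregated row
#' per subject), standardizes and fits PCA on the training folds only, and
#' trains/evaluates one model per fold.
#'
#' @param features per-subject feature table from [extract_feature_table()].
#' @param k fold count (default 5).
#' @param model_config an [adena_config()].
#' @param config a [train_config()].
#' @param variance_target PCA cumulative-variance threshold.
#' @return list: `reports` (per-fold [eval_report()]s), `summary` (data
#'   frame of per-fold metrics plus the mean row), `folds`, `predictions`
#'   (pooled held-out predictions, one row per subject).
#' @export
cross_validate <- function(features, k = 5L, model_config = adena_config(),
                           config = train_config(),
                           variance_target = 0.95) {
  assert_that(k >= 2 && k <= nrow(features), "invalid fold count")
  folds <- make_folds(features$subject_id, features$label, k,
                      seed = config$seed)
  cols <- feature_columns(features)
  reports <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- features$subject_id %in% folds[[f]]
    prep <- prepare_fold_features(features[!test_idx, cols],
                                  features[test_idx, cols], variance_target)
    fit <- adena_train(prep$train, features$label[!test_idx],
                       model_config = model_config, config = config)
    p <- adena_predict(fit, prep$test)
    reports[[f]] <- eval_report(features$label[test_idx], p)
    preds[[f]] <- data.frame(subject_id = features$subject_id[test_idx],
                             label = features$label[test_idx],
                             probability = p, fold = f,
                             stringsAsFactors = FALSE)
  }
  metr <- data.frame(fold = seq_len(k),
                     accuracy = vapply(reports, `[[`, 0, "accuracy"),
                     f1 = vapply(reports, `[[`, 0, "f1"),
                     mse = vapply(reports, `[[`, 0, "mse"),
                     auc = vapply(reports, `[[`, 0, "auc"))
  summary <- rbind(metr, data.frame(fold = NA, accuracy = mean(metr$accuracy),
                                    f1 = mean(metr$f1), mse = mean(metr$mse),
                                    auc = mean(metr$auc)))
  list(reports = reports, summary = summary, folds = folds,
       predictions = do.call(rbind, preds))
}

#' Hyperparameter grid search
#'
#' Evaluates every combination of learning rate, epoch count and batch size
#' by k-fold mean F1 (ties broken by lower mean MSE, then fewer epochs). The
#' default grids are the tested learning rates plus the 5e-4 optimum,
#' epoch counts 200/500/1000 and batch sizes 2/4.
#'
#' @param features per-subject feature table.
#' @param learning_rates,epochs_grid,batch_sizes candidate values.
#' @param k fold count.
#' @param model_config an [adena_config()].
#' @param seed RNG seed shared across combinations.
#' @return list: `ranking` (data frame, best first), `best` (winning
#'   [train_config()]).
#' @export
grid_search <- function(features,
                        learning_rates = c(5e-3, 1e-3, 1e-4, 1e-1, 1e-2,
                                           5e-4),
                        epochs_grid = c(200L, 500L, 1000L),
                        batch_sizes = c(2L, 4L), k = 5L,
                        model_config = adena_config(), seed = 1L) {
  grid <- expand.grid(learning_rate = learning_rates, epochs = epochs_grid,
                      batch_size = batch_sizes, KEEP.OUT.ATTRS = FALSE)
  assert_that(nrow(grid) >= 1, "empty grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tc <- train_config(grid$learning_rate[i], grid$epochs[i],
                       grid$batch_size[i], seed = seed)
    cv <- tryCatch(cross_validate(features, k, model_config, tc),
                   error = function(e) NULL)
    if (is.null(cv)) return(c(f1 = -Inf, mse = Inf, accuracy = NA, auc = NA))
    m <- cv$summary[is.na(cv$summary$fold), ]
    c(f1 = m$f1, mse = m$mse, accuracy = m$accuracy, auc = m$auc)
  })
  ranking <- cbind(grid, do.call(rbind, res))
  ord <- order(-ranking$f1, ranking$mse, ranking$epochs)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  best <- ranking[1, ]
  list(ranking = ranking,
       best = train_config(best$learning_rate, best$epochs, best$batch_size,
                           seed = seed))
}

#' Reference classifiers under the same k-fold protocol
#'
#' Runs standard implementations of SVM, k-nearest neighbours, logistic
#' regression, multilayer perceptron, decision tree and naive Bayes (library
#' defaults) on the same stratified subject-level folds, optionally
#' alongside ADENA. Per-model failures are recorded, not fatal.
#'
#' @param features per-subject feature table.
#' @param k fold count.
#' @param models subset of
#'   `c("svm", "knn", "logistic", "mlp", "cart", "naive_bayes")`.
#' @param include_adena also train ADENA on the same folds?
#' @param model_config,config ADENA configurations (used when
#'   `include_adena`).
#' @param seed fold seed.
#' @return data frame: model, accuracy, f1, mse, auc, error (NA when the
#'   model ran).
#' @export
reference_classifiers <- function(features, k = 5L,
                                  models = c("svm", "knn", "logistic", "mlp",
                                             "cart", "naive_bayes"),
                                  include_adena = FALSE,
                                  model_config = adena_config(),
                                  config = train_config(), seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  folds <- make_folds(features$subject_id, features$label, k, seed = seed)
  cols <- feature_columns(features)
  fit_predict <- function(name, Xtr, ytr, Xte) {
    df_tr <- data.frame(Xtr); df_tr$.y <- factor(ytr, levels = c(0, 1))
    df_te <- data.frame(Xte)
    switch(name,
      svm = {
        m <- e1071::svm(.y ~ ., df_tr, probability = TRUE)
        attr(stats::predict(m, df_te, probability = TRUE),
             "probabilities")[, "1"]
      },
      knn = {
        pr <- class::knn(Xtr, Xte, factor(ytr), k = 5, prob = TRUE)
        pw <- attr(pr, "prob")
        ifelse(pr == "1", pw, 1 - pw)
      },
      logistic = {
        m <- suppressWarnings(stats::glm(.y ~ ., df_tr, family = binomial()))
        suppressWarnings(stats::predict(m, df_te, type = "response"))
      },
      mlp = {
        m <- nnet::nnet(.y ~ ., df_tr, size = 8, maxit = 300, trace = FALSE,
                        decay = 1e-3)
        as.numeric(stats::predict(m, df_te))
      },
      cart = {
        m <- rpart::rpart(.y ~ ., df_tr, method = "class")
        stats::predict(m, df_te)[, "1"]
      },
      naive_bayes = {
        m <- e1071::naiveBayes(.y ~ ., df_tr)
        stats::predict(m, df_te, type = "raw")[, "1"]
      })
  }
  run_model <- function(name) {
    y_all <- c(); p_all <- c()
    for (f in seq_len(k)) {
      test_idx <- features$subject_id %in% folds[[f]]
      prep <- prepare_fold_features(features[!test_idx, cols],
                                    features[test_idx, cols])
      if (name == "adena") {
        fit <- adena_train(prep$train, features$label[!test_idx],
                           model_config = model_config, config = config)
        p <- adena_predict(fit, prep$test)
      } else {
        p <- with_seed(seed + f,
                       fit_predict(name, prep$train,
                                   features$label[!test_idx], prep$test))
      }
      y_all <- c(y_all, features$label[test_idx])
      p_all <- c(p_all, as.numeric(p))
    }
    rep <- eval_report(y_all, p_all)
    data.frame(model = name, accuracy = rep$accuracy, f1 = rep$f1,
               mse = rep$mse, auc = rep$auc, error = NA_character_,
               stringsAsFactors = FALSE)
  }
  all_models <- c(models, if (include_adena) "adena")
  rows <- lapply(all_models, function(nm)
    tryCatch(run_model(nm), error = function(e)
      data.frame(model = nm, accuracy = NA_real_, f1 = NA_real_,
                 mse = NA_real_, auc = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`; @param path file path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy, f1 = report$f1,
                            mse = report$mse, auc = report$auc,
                            confusion = as.list(report$confusion),
                            threshold = report$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
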