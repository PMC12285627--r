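#' @name imbalance-ensemble
#' @title Imbalance-aware ensemble training
#' @description The core classifier is an EasyEnsemble: the negative
#'   (majority) class is partitioned at random into `ceil(N_neg / N_pos)`
#'   groups, each padded to exactly `N_pos` negatives by drawing from the
#'   remaining negatives, and one base classifier is fitted per balanced
#'   subset (all positives + one negative group). The ensemble score is the
#'   mean of member probabilities, so every negative informs at least one
#'   member while each member trains on a balanced problem. Alternative
#'   imbalance strategies (raw, random/SMOTE oversampling, random
#'   undersampling, class weights) and base learners are available for model
#'   selection.
NULL

#' Training configuration
#'
#' @param base_learner one of `boosted_trees` (gradient-boosted trees via
#'   xgboost; the default and the learner used by the final model),
#'   `random_forest`, `logistic`, `naive_bayes`, `knn`, `svm_linear`,
#'   `svm_rbf`, or `prevalence` (a feature-blind baseline predicting the
#'   training prevalence, useful as a null).
#' @param imbalance_strategy one of `easy_ensemble` (default), `raw`,
#'   `oversample_random`, `oversample_smote`, `undersample_random`,
#'   `class_weight`.
#' @param hyperparams named list; for boosted trees the tuned defaults are
#'   `num_leaves = 45`, `max_depth = 10`, `n_estimators = 116`,
#'   `learning_rate = 0.1`. `knn` honours `k` (default 5).
#' @param seed master seed; all randomness (subset sampling, folds,
#'   resampling) derives from it.
#' @param n_folds folds for cross-validation (default 5).
#' @return a `TrainConfig` object.
#' @export
train_config <- function(base_learner = "boosted_trees",
                         imbalance_strategy = "easy_ensemble",
                         hyperparams = list(), seed = 1, n_folds = 5) {
  base_learner <- match.arg(base_learner,
                            c("boosted_trees", "random_forest", "logistic",
                              "naive_bayes", "knn", "svm_linear", "svm_rbf",
                              "prevalence"))
  imbalance_strategy <- match.arg(imbalance_strategy,
                                  c("easy_ensemble", "raw",
                                    "oversample_random", "oversample_smote",
                                    "undersample_random", "class_weight"))
  stopifnot(n_folds >= 2, is.numeric(seed), length(seed) == 1L)
  defaults <- if (base_learner == "boosted_trees") {
    list(num_leaves = 45, max_depth = 10, n_estimators = 116,
         learning_rate = 0.1)
  } else if (base_learner == "knn") {
    list(k = 5)
  } else {
    list()
  }
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(base_learner = base_learner,
                 imbalance_strategy = imbalance_strategy,
                 hyperparams = hp, seed = seed, n_folds = as.integer(n_folds)),
            class = "TrainConfig")
}

need_pkg <- function(pkg, learner) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop(sprintf("base learner '%s' requires the '%s' package", learner, pkg),
         call. = FALSE)
  }
}

xgb_params <- function(hp, seed) {
  list(objective = "binary:logistic", eta = hp$learning_rate,
       max_depth = hp$max_depth, max_leaves = hp$num_leaves,
       grow_policy = "lossguide", tree_method = "hist", nthread = 1,
       seed = seed)
}

fit_base_learner <- function(x, y, cfg, weights = NULL, seed = 0L) {
  hp <- cfg$hyperparams
  fit <- switch(cfg$base_learner,
    boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y,
                                     weight = if (is.null(weights)) {
                                       rep(1, length(y))
                                     } else {
                                       weights
                                     })
      xgboost::xgb.train(xgb_params(hp, seed), dtrain,
                         nrounds = hp$n_estimators, verbose = 0)
    },
    logistic = {
      df <- data.frame(x)
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial(),
                                  weights = weights))
    },
    naive_bayes = {
      need_pkg("e1071", "naive_bayes")
      e1071::naiveBayes(data.frame(x), factor(y, levels = c(0, 1)))
    },
    knn = {
      need_pkg("class", "knn")
      list(train = x, cl = factor(y, levels = c(0, 1)), k = hp$k)
    },
    svm_linear = ,
    svm_rbf = {
      need_pkg("e1071", cfg$base_learner)
      kern <- if (cfg$base_learner == "svm_linear") "linear" else "radial"
      cw <- if (is.null(weights)) NULL else {
        w <- tapply(weights, y, mean)
        setNames(as.numeric(w), names(w))
      }
      with_seed(seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = kern,
                   probability = TRUE, class.weights = cw))
    },
    random_forest = {
      need_pkg("ranger", "random_forest")
      ranger::ranger(y = factor(y, levels = c(0, 1)), x = data.frame(x),
                     probability = TRUE, seed = seed, num.threads = 1,
                     case.weights = weights)
    },
    prevalence = list(p = if (is.null(weights)) mean(y) else {
      sum(weights * y) / sum(weights)
    })
  )
  structure(list(learner = cfg$base_learner, fit = fit,
                 feature_order = colnames(x)),
            class = "BaseLearner")
}

predict_base <- function(member, x) {
  x <- x[, member$feature_order, drop = FALSE]
  switch(member$learner,
    boosted_trees = predict(member$fit, xgboost::xgb.DMatrix(x)),
    logistic = as.numeric(predict(member$fit, data.frame(x),
                                  type = "response")),
    naive_bayes = predict(member$fit, data.frame(x), type = "raw")[, "1"],
    knn = {
      pr <- class::knn(member$fit$train, x, member$fit$cl, k = member$fit$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    svm_linear = ,
    svm_rbf = {
      pred <- predict(member$fit, x, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    random_forest = predict(member$fit, data.frame(x))$predictions[, "1"],
    prevalence = rep(member$fit$p, nrow(x))
  )
}

# Synthetic minority oversampling: each synthetic positive interpolates a
# random positive towards one of its k nearest positive neighbours.
smote_positives <- function(x_pos, n_new, k = 5, seed = 0L) {
  with_seed(seed, {
    k <- min(k, nrow(x_pos) - 1L)
    if (k < 1L) {
      return(x_pos[sample(nrow(x_pos), n_new, replace = TRUE), ,
                   drop = FALSE])
    }
    d <- as.matrix(stats::dist(x_pos))
    diag(d) <- Inf
    nn <- apply(d, 1L, function(r) order(r)[seq_len(k)])
    i <- sample(nrow(x_pos), n_new, replace = TRUE)
    j <- vapply(i, function(ii) nn[sample(k, 1L), ii], 0)
    u <- runif(n_new)
    x_pos[i, , drop = FALSE] +
      u * (x_pos[j, , drop = FALSE] - x_pos[i, , drop = FALSE])
  })
}

features_matrix <- function(features) {
  if (inherits(features, "FeatureTable")) features$values else {
    as.matrix(features)
  }
}

labels_vector <- function(labels, gene_ids) {
  if (inherits(labels, "LabelSet")) {
    ids <- intersect(gene_ids, c(labels$positives, labels$negatives))
    setNames(as.numeric(ids %in% labels$positives), ids)
  } else {
    stopifnot(!is.null(names(labels)), all(labels %in% c(0, 1)))
    labels[intersect(gene_ids, names(labels))]
  }
}

# Partition negatives into ceil(N_neg/N_pos) groups and pad each group to
# exactly N_pos with draws from the other negatives.
easy_ensemble_subsets <- function(pos_ids, neg_ids, seed) {
  n_pos <- length(pos_ids)
  n_neg <- length(neg_ids)
  n_subsets <- ceiling(n_neg / n_pos)
  with_seed(seed, {
    shuffled <- sample(neg_ids)
    groups <- split(shuffled, rep_len(seq_len(n_subsets), n_neg))
    lapply(groups, function(g) {
      if (length(g) < n_pos) {
        g <- c(g, sample(setdiff(neg_ids, g), n_pos - length(g)))
      }
      g
    })
  })
}

#' Train an ensemble (or single) classifier under an imbalance strategy
#'
#' With `easy_ensemble` this fits one base classifier per balanced subset;
#' all other strategies fit a single member on the (re)sampled or weighted
#' training data.
#'
#' @param features a `FeatureTable` or numeric matrix with gene rownames.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param cfg a `TrainConfig`.
#' @return an `EnsembleModel`.
#' @export
train_model <- function(features, labels, cfg) {
  x_all <- features_matrix(features)
  y <- labels_vector(labels, rownames(x_all))
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- x_all[names(y), , drop = FALSE]
  pos_ids <- names(y)[y == 1]
  neg_ids <- names(y)[y == 0]
  seed0 <- derive_seed(cfg$seed, "train")

  members <- list()
  member_negatives <- list()
  if (cfg$imbalance_strategy == "easy_ensemble") {
    if (length(neg_ids) < length(pos_ids)) {
      stop("easy_ensemble expects negatives to be the majority class",
           call. = FALSE)
    }
    subsets <- easy_ensemble_subsets(pos_ids, neg_ids, seed0)
    for (i in seq_along(subsets)) {
      ids <- c(pos_ids, subsets[[i]])
      members[[i]] <- fit_base_learner(
        x[ids, , drop = FALSE], y[ids], cfg,
        seed = derive_seed(cfg$seed, paste0("member", i)))
      member_negatives[[i]] <- subsets[[i]]
    }
  } else {
    res <- switch(cfg$imbalance_strategy,
      raw = list(x = x, y = y, w = NULL),
      class_weight = {
        w <- ifelse(y == 1, length(y) / (2 * sum(y == 1)),
                    length(y) / (2 * sum(y == 0)))
        list(x = x, y = y, w = w)
      },
      undersample_random = with_seed(seed0, {
        keep <- c(pos_ids, sample(neg_ids, length(pos_ids)))
        list(x = x[keep, , drop = FALSE], y = y[keep], w = NULL)
      }),
      oversample_random = with_seed(seed0, {
        extra <- sample(pos_ids, length(neg_ids) - length(pos_ids),
                        replace = TRUE)
        xr <- rbind(x, x[extra, , drop = FALSE])
        list(x = xr, y = c(y, setNames(rep(1, length(extra)), extra)),
             w = NULL)
      }),
      oversample_smote = {
        n_new <- length(neg_ids) - length(pos_ids)
        syn <- smote_positives(x[pos_ids, , drop = FALSE], n_new,
                               k = cfg$hyperparams$smote_k %||% 5,
                               seed = seed0)
        rownames(syn) <- paste0("smote_", seq_len(nrow(syn)))
        list(x = rbind(x, syn),
             y = c(y, setNames(rep(1, nrow(syn)), rownames(syn))), w = NULL)
      })
    members[[1L]] <- fit_base_learner(res$x, res$y, cfg, weights = res$w,
                                      seed = derive_seed(cfg$seed, "member1"))
    member_negatives[[1L]] <- neg_ids
  }
  structure(list(members = members, member_negatives = member_negatives,
                 feature_order = colnames(x), threshold = NULL, cfg = cfg),
            class = "EnsembleModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the EasyEnsemble classifier
#'
#' Convenience wrapper for [train_model()] with the `easy_ensemble`
#' strategy: `ceil(N_neg / N_pos)` balanced subsets, each holding every
#' positive and exactly `N_pos` negatives, with the union of the members'
#' negative groups covering all training negatives.
#'
#' @inheritParams train_model
#' @return an `EnsembleModel` whose members are balanced base classifiers.
#' @export
easy_ensemble_fit <- function(features, labels, cfg = train_config()) {
  cfg$imbalance_strategy <- "easy_ensemble"
  train_model(features, labels, cfg)
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf(
    "<EnsembleModel> %d member(s), learner=%s, strategy=%s, threshold=%s\n",
    length(x$members), x$cfg$base_learner, x$cfg$imbalance_strategy,
    if (is.null(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' Predict ensemble scores
#'
#' Mean of member probabilities, in `[0, 1]`; deterministic given the model
#' and invariant to gene and member order.
#'
#' @param model an `EnsembleModel`.
#' @param features a `FeatureTable` or matrix whose columns match the
#'   model's feature order.
#' @return named numeric vector of scores.
#' @export
predict_scores <- function(model, features) {
  x <- features_matrix(features)
  missing_cols <- setdiff(model$feature_order, colnames(x))
  extra_cols <- setdiff(colnames(x), model$feature_order)
  if (length(missing_cols) || length(extra_cols)) {
    stop(sprintf("feature columns mismatch: missing [%s], extra [%s]",
                 paste(missing_cols, collapse = ", "),
                 paste(extra_cols, collapse = ", ")), call. = FALSE)
  }
  x <- x[, model$feature_order, drop = FALSE]
  probs <- matrix(vapply(model$members, predict_base, numeric(nrow(x)),
                         x = x), nrow = nrow(x))
  setNames(rowMeans(probs), rownames(x))
}
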