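#' @name model-selection
#' @title Cross-validation, hold-out splits and strategy comparison
#' @description Model selection uses stratified k-fold cross-validation with
#'   AUPRC as the primary score (the metric of choice under heavy class
#'   imbalance); resampling and ensembling happen inside each training fold
#'   only, so held-out genes never leak into member training sets.
NULL

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Stratified hold-out split
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param test_fraction fraction of each class held out (default 1/3).
#' @param seed split seed.
#' @return list with `train` and `test`, each a list of `features`
#'   (`FeatureTable`) and `labels` (named 0/1 vector).
#' @export
hold_out_split <- function(features, labels, test_fraction = 1 / 3,
                           seed = 1) {
  x <- features_matrix(features)
  y <- labels_vector(labels, rownames(x))
  stopifnot(length(unique(y)) == 2L, test_fraction > 0, test_fraction < 1)
  test_ids <- with_seed(derive_seed(seed, "holdout"), {
    unlist(lapply(c(0, 1), function(cls) {
      ids <- names(y)[y == cls]
      sample(ids, round(length(ids) * test_fraction))
    }), use.names = FALSE)
  })
  train_ids <- setdiff(names(y), test_ids)
  take <- function(ids) {
    ft <- if (inherits(features, "FeatureTable")) {
      subset_features(features, genes = ids)
    } else {
      x[ids, , drop = FALSE]
    }
    list(features = ft, labels = y[ids])
  }
  list(train = take(train_ids), test = take(test_ids))
}

#' Stratified k-fold cross-validation
#'
#' All imbalance handling (resampling, ensembling) is applied inside each
#' training fold; metrics are computed on the held-out fold only.
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param cfg a `TrainConfig` (its `n_folds` and `seed` drive the folds).
#' @return a `CVResult`: list with data.frame `folds` (`fold`, `auroc`,
#'   `auprc`), `mean_auroc`, `mean_auprc` and the named `fold_assignment`.
#' @export
cross_validate <- function(features, labels, cfg = train_config()) {
  x <- features_matrix(features)
  y <- labels_vector(labels, rownames(x))
  x <- x[names(y), , drop = FALSE]
  fold <- stratified_folds(y, cfg$n_folds, derive_seed(cfg$seed, "folds"))
  if (any(tapply(y, fold, sum) == 0)) {
    stop("a fold has no positives; use fewer folds", call. = FALSE)
  }
  res <- lapply(seq_len(cfg$n_folds), function(k) {
    tr <- fold != k
    model <- train_model(x[tr, , drop = FALSE], y[tr], cfg)
    s <- predict_scores(model, x[!tr, , drop = FALSE])
    data.frame(fold = k, auroc = auroc(s, y[!tr]), auprc = auprc(s, y[!tr]))
  })
  folds <- do.call(rbind, res)
  structure(list(folds = folds, mean_auroc = mean(folds$auroc),
                 mean_auprc = mean(folds$auprc),
                 fold_assignment = setNames(fold, names(y))),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %d folds: mean AUROC %.4f, mean AUPRC %.4f\n",
              nrow(x$folds), x$mean_auroc, x$mean_auprc))
  invisible(x)
}

#' Rank (learner, strategy) configurations by cross-validated AUPRC
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param configs list of `TrainConfig` objects (>= 2).
#' @return data.frame sorted by mean AUPRC descending (AUROC, then name
#'   break ties) with one row per configuration.
#' @export
strategy_leaderboard <- function(features, labels, configs) {
  stopifnot(length(configs) >= 2L)
  rows <- lapply(configs, function(cfg) {
    cv <- cross_validate(features, labels, cfg)
    data.frame(learner = cfg$base_learner, strategy = cfg$imbalance_strategy,
               mean_auprc = cv$mean_auprc, mean_auroc = cv$mean_auroc)
  })
  out <- do.call(rbind, rows)
  out$name <- paste(out$learner, out$strategy, sep = "+")
  out <- out[order(-out$mean_auprc, -out$mean_auroc, out$name), ]
  rownames(out) <- NULL
  out
}

#' Save an ensemble model to a directory
#'
#' Writes a JSON manifest (configuration, feature order, threshold) plus one
#' payload per member.
#'
#' @param model an `EnsembleModel`.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(learner = model$cfg$base_learner,
                   strategy = model$cfg$imbalance_strategy,
                   hyperparams = model$cfg$hyperparams,
                   seed = model$cfg$seed, n_folds = model$cfg$n_folds,
                   feature_order = model$feature_order,
                   threshold = model$threshold,
                   n_members = length(model$members),
                   member_negatives = model$member_negatives)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(model$members)) {
    m <- model$members[[i]]
    if (m$learner == "boosted_trees") {
      xgboost::xgb.save(m$fit, file.path(dir, sprintf("member_%03d.ubj", i)))
    } else {
      saveRDS(m, file.path(dir, sprintf("member_%03d.rds", i)))
    }
  }
  invisible(dir)
}

#' Load an ensemble model saved by [save_model()]
#'
#' @param dir model directory.
#' @return an `EnsembleModel`.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- train_config(manifest$learner, manifest$strategy,
                      as.list(manifest$hyperparams), manifest$seed,
                      manifest$n_folds)
  members <- lapply(seq_len(manifest$n_members), function(i) {
    ubj <- file.path(dir, sprintf("member_%03d.ubj", i))
    if (file.exists(ubj)) {
      structure(list(learner = "boosted_trees",
                     fit = xgboost::xgb.load(ubj),
                     feature_order = manifest$feature_order),
                class = "BaseLearner")
    } else {
      readRDS(file.path(dir, sprintf("member_%03d.rds", i)))
    }
  })
  structure(list(members = members,
                 member_negatives = manifest$member_negatives,
                 feature_order = manifest$feature_order,
                 threshold = manifest$threshold, cfg = cfg),
            class = "EnsembleModel")
}
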