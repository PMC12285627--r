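#' @name attribution
#' @title Shapley-value attribution, feature ranking, grouping and ablation
#' @description Per-gene additive feature attributions come from the
#'   tree-path (TreeSHAP) algorithm of the boosted-tree members. Member
#'   attributions are computed on the margin scale, rescaled linearly to the
#'   probability scale (so each member's base value plus its contributions
#'   equals its predicted probability exactly), and averaged across members;
#'   because the ensemble score is itself the mean member probability, the
#'   additivity identity `base + sum(contributions) = score` carries over to
#'   the ensemble with no approximation.
NULL

#' Per-gene SHAP attributions for an ensemble of boosted trees
#'
#' @param model an `EnsembleModel` whose members are boosted trees.
#' @param features a `FeatureTable` or matrix to explain.
#' @param background_n background size recorded with the explanation
#'   (default 100). The tree-path algorithm conditions on the cover
#'   statistics stored in the trees at training time, so no explicit
#'   background rows are drawn; values larger than the training size warn,
#'   matching the contract of background-based explainers.
#' @param seed kept for interface stability with sampling-based explainers;
#'   the computation is deterministic.
#' @return an `AttributionMatrix`: list with `gene_ids`, `feature_names`,
#'   `values` (genes x features contributions on the probability scale) and
#'   scalar `base_value` (expected ensemble output).
#' @export
shap_values <- function(model, features, background_n = 100, seed = NULL) {
  stopifnot(inherits(model, "EnsembleModel"))
  if (!all(vapply(model$members, function(m) m$learner, "") ==
             "boosted_trees")) {
    stop("attribution requires boosted-tree ensemble members", call. = FALSE)
  }
  x <- features_matrix(features)
  x <- x[, model$feature_order, drop = FALSE]
  n_train <- length(model$member_negatives[[1L]]) * 2L
  if (background_n > n_train) {
    warning(sprintf(
      "background_n=%d exceeds the member training size %d; using all",
      background_n, n_train))
  }
  p <- ncol(x)
  acc <- matrix(0, nrow(x), p, dimnames = list(rownames(x), colnames(x)))
  base_acc <- 0
  for (m in model$members) {
    contrib <- predict(m$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
    phi <- contrib[, seq_len(p), drop = FALSE]
    bias <- contrib[, p + 1L]
    margin <- bias + rowSums(phi)
    prob <- stats::plogis(margin)
    base_p <- stats::plogis(bias)
    denom <- margin - bias
    fac <- ifelse(abs(denom) < 1e-12, 0, (prob - base_p) / denom)
    acc <- acc + phi * fac
    base_acc <- base_acc + mean(base_p)
  }
  k <- length(model$members)
  structure(list(gene_ids = rownames(x), feature_names = colnames(x),
                 values = acc / k, base_value = base_acc / k),
            class = "AttributionMatrix")
}

#' @export
print.AttributionMatrix <- function(x, ...) {
  cat(sprintf("<AttributionMatrix> %d genes x %d features, base value %.4f\n",
              length(x$gene_ids), length(x$feature_names), x$base_value))
  invisible(x)
}

#' Global feature ranking by attribution magnitude
#'
#' Features sorted by the sum of absolute attributions across all genes
#' (descending; ties broken by name).
#'
#' @param attr an `AttributionMatrix`.
#' @return data.frame with `feature`, `importance`, in rank order.
#' @export
feature_importance <- function(attr) {
  stopifnot(inherits(attr, "AttributionMatrix"),
            length(attr$gene_ids) > 0L)
  imp <- colSums(abs(attr$values))
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Per-gene attribution report
#'
#' The top contributions (by magnitude, signed values retained) for one
#' gene, mirroring a per-gene contribution bar chart.
#'
#' @param attr an `AttributionMatrix`.
#' @param gene_id gene to report.
#' @param top_k number of features (default 10).
#' @return data.frame with `feature`, `contribution`, `rank`.
#' @export
gene_report <- function(attr, gene_id, top_k = 10) {
  stopifnot(gene_id %in% attr$gene_ids)
  v <- attr$values[gene_id, ]
  o <- order(-abs(v))[seq_len(min(top_k, length(v)))]
  data.frame(feature = attr$feature_names[o], contribution = as.numeric(v[o]),
             rank = seq_along(o))
}

#' Redundancy-aware feature grouping
#'
#' Features are clustered with complete linkage on the distance
#' `1 - |Pearson r|` and the dendrogram is cut at `1 - threshold_abs_r`, so
#' within every group all pairwise absolute correlations are at least the
#' threshold. Zero-variance features form singleton groups. The number of
#' groups is emergent from the cut, not fixed.
#'
#' @param features a `FeatureTable` or matrix.
#' @param threshold_abs_r minimum within-group `|r|` (default 0.1).
#' @return a `FeatureGroupPartition`: list with `groups` (named list of
#'   feature-name vectors), `linkage = "complete"` and `threshold_abs_r`.
#' @export
feature_groups <- function(features, threshold_abs_r = 0.1) {
  x <- features_matrix(features)
  sds <- apply(x, 2L, stats::sd)
  varying <- colnames(x)[sds > 0]
  constant <- setdiff(colnames(x), varying)
  groups <- list()
  if (length(varying) >= 2L) {
    r <- abs(stats::cor(x[, varying, drop = FALSE]))
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "complete")
    cl <- stats::cutree(hc, h = 1 - threshold_abs_r)
    groups <- split(names(cl), cl)
  } else if (length(varying) == 1L) {
    groups <- list(varying)
  }
  groups <- c(groups, as.list(constant))
  names(groups) <- paste0("group_", seq_along(groups))
  structure(list(groups = groups, linkage = "complete",
                 threshold_abs_r = threshold_abs_r),
            class = "FeatureGroupPartition")
}

#' Exclusion-based contribution of features or feature groups
#'
#' For each unit (single feature or feature group) the model is retrained
#' without the unit's columns on the same folds and seed as the full model;
#' the contribution is the drop in mean cross-validated AUPRC (and AUROC).
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param cfg a `TrainConfig`.
#' @param units a character vector of feature names (each its own unit), a
#'   named list of feature-name vectors, or a `FeatureGroupPartition`.
#' @return data.frame with `unit`, `delta_auprc`, `delta_auroc`, sorted by
#'   `delta_auprc` descending.
#' @export
feature_ablation <- function(features, labels, cfg, units) {
  x <- features_matrix(features)
  if (inherits(units, "FeatureGroupPartition")) units <- units$groups
  if (is.character(units)) units <- setNames(as.list(units), units)
  stopifnot(length(units) > 0L)
  if (is.null(names(units))) {
    names(units) <- vapply(units, paste, "", collapse = "+")
  }
  full <- cross_validate(x, labels, cfg)
  rows <- lapply(names(units), function(u) {
    drop_cols <- units[[u]]
    keep <- setdiff(colnames(x), drop_cols)
    if (length(keep) == 0L) {
      stop(sprintf("unit '%s' would remove every feature", u), call. = FALSE)
    }
    cv <- cross_validate(x[, keep, drop = FALSE], labels, cfg)
    data.frame(unit = u, delta_auprc = full$mean_auprc - cv$mean_auprc,
               delta_auroc = full$mean_auroc - cv$mean_auroc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_auprc), ]
  rownames(out) <- NULL
  out
}

#' Random-positive permutation null
#'
#' Builds `n_sets` fake positive sets of the true positive size, drawn from
#' the candidate pool (every gene that is not a training negative), retrains
#' and cross-validates each, and compares the observed scores against the
#' null distribution with the +1-corrected permutation p-value.
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector (the true labels).
#' @param cfg a `TrainConfig`.
#' @param n_sets number of random positive sets (default 100; must be >= 1).
#' @param pool optional candidate gene ids for fake positives; defaults to
#'   all feature-table genes except the true negatives.
#' @return list with data.frame `null` (`set`, `auprc`, `auroc`),
#'   `observed` (auprc/auroc of the true labels), `p_auprc`, `p_auroc`.
#' @export
random_positive_null <- function(features, labels, cfg, n_sets = 100,
                                 pool = NULL) {
  if (n_sets < 1L) stop("n_sets must be at least 1", call. = FALSE)
  x <- features_matrix(features)
  y <- labels_vector(labels, rownames(x))
  pos <- names(y)[y == 1]
  neg <- names(y)[y == 0]
  if (is.null(pool)) pool <- setdiff(rownames(x), neg)
  if (length(pool) < length(pos)) {
    stop("candidate pool smaller than the positive set", call. = FALSE)
  }
  obs <- cross_validate(x, y, cfg)
  rows <- lapply(seq_len(n_sets), function(i) {
    fake_pos <- with_seed(derive_seed(cfg$seed, paste0("nullset", i)),
                          sample(pool, length(pos)))
    yi <- setNames(rep(0, length(neg) + length(fake_pos)),
                   c(fake_pos, neg))
    yi[fake_pos] <- 1
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, paste0("nullfit", i))
    cv <- cross_validate(x[names(yi), , drop = FALSE], yi, cfg_i)
    data.frame(set = i, auprc = cv$mean_auprc, auroc = cv$mean_auroc)
  })
  null <- do.call(rbind, rows)
  list(null = null,
       observed = c(auprc = obs$mean_auprc, auroc = obs$mean_auroc),
       p_auprc = (1 + sum(null$auprc >= obs$mean_auprc)) / (1 + n_sets),
       p_auroc = (1 + sum(null$auroc >= obs$mean_auroc)) / (1 + n_sets))
}

#' Performance as a function of positive-set size
#'
#' For each size, positives are subsampled (all negatives kept) and the
#' model cross-validated; repeated `iters` times with independent draws.
#'
#' @param features a `FeatureTable` or matrix.
#' @param labels a `LabelSet` or named 0/1 vector.
#' @param cfg a `TrainConfig`.
#' @param sizes positive-set sizes (default 50, 80, 100, 120, 150, 180).
#' @param iters draws per size (default 10).
#' @return data.frame with `size`, `iter`, `auprc`, `auroc`.
#' @export
positive_size_curve <- function(features, labels, cfg,
                                sizes = c(50, 80, 100, 120, 150, 180),
                                iters = 10) {
  x <- features_matrix(features)
  y <- labels_vector(labels, rownames(x))
  pos <- names(y)[y == 1]
  neg <- names(y)[y == 0]
  if (max(sizes) > length(pos)) {
    stop("requested size exceeds the number of positives", call. = FALSE)
  }
  rows <- list()
  for (s in sizes) {
    for (it in seq_len(iters)) {
      sub_pos <- with_seed(
        derive_seed(cfg$seed, sprintf("size%d_iter%d", s, it)),
        sample(pos, s))
      ids <- c(sub_pos, neg)
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, sprintf("fit%d_%d", s, it))
      cv <- cross_validate(x[ids, , drop = FALSE], y[ids], cfg_i)
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, iter = it, auprc = cv$mean_auprc, auroc = cv$mean_auroc)
    }
  }
  do.call(rbind, rows)
}
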