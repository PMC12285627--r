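#' End-to-end demonstration on a synthetic cosmos
#'
#' Generates a small synthetic feature table with planted truth, evaluates
#' the default EasyEnsemble boosted-tree model by cross-validation, picks the
#' maximum-F1 decision threshold, trains the final model, scores all genes
#' and explains the predictions. Everything derives from `seed`.
#'
#' @param seed master seed (default 1).
#' @param n_genes,n_pos cosmos size (defaults 600 genes, 90 positives keep
#'   the demo fast).
#' @param quiet suppress console output (default FALSE).
#' @return (invisibly) list with `cosmos`, `cv`, `model`, `threshold`,
#'   `scores`, `attributions`, `importance`.
#' @export
run_demo <- function(seed = 1, n_genes = 600, n_pos = 90, quiet = FALSE) {
  say <- function(...) if (!quiet) cat(sprintf(...))
  cfg <- cosmos_config(n_genes = n_genes, n_pos = n_pos, seed = seed)
  cosmos <- generate_feature_table(cfg)
  say("cosmos: %d genes, %d positives, %d planted informative features\n",
      n_genes, n_pos, length(cosmos$truth$informative))

  tc <- train_config(seed = seed)
  cv <- cross_validate(cosmos$features, cosmos$labels, tc)
  say("5-fold CV: mean AUROC %.4f, mean AUPRC %.4f\n",
      cv$mean_auroc, cv$mean_auprc)

  model <- train_model(cosmos$features, cosmos$labels, tc)
  scores <- predict_scores(model, cosmos$features)
  thr <- max_f1_threshold(scores, cosmos$labels[names(scores)])
  model$threshold <- thr$threshold
  say("max-F1 threshold %.4f (F1 %.4f); %d predicted positives\n",
      thr$threshold, thr$achieved$f1, sum(scores >= thr$threshold))

  attr <- shap_values(model, cosmos$features,
                      background_n = min(100L, 2L * sum(cosmos$labels)))
  resid <- max(abs(attr$base_value + rowSums(attr$values) - scores))
  imp <- feature_importance(attr)
  say("attribution additivity residual: %.2e\n", resid)
  say("top features: %s\n", paste(utils::head(imp$feature, 5),
                                  collapse = ", "))
  invisible(list(cosmos = cosmos, cv = cv, model = model,
                 threshold = thr, scores = scores, attributions = attr,
                 importance = imp))
}
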