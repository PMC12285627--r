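# Shared fixtures and brute-force oracles used across test files.

# Pairwise-counting AUROC oracle: P(score_pos > score_neg) + 0.5 P(equal).
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Step-sum average-precision oracle: walk thresholds at unique scores
# (descending) and accumulate precision * recall increments.
oracle_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * tp / (tp + fp)
    prev_rec <- rec
  }
  ap
}

# Exhaustive max-F1 scan over unique scores, ties to the larger threshold.
oracle_max_f1 <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  best_f1 <- -Inf
  best_t <- NA_real_
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1) {
      best_f1 <- f1
      best_t <- t
    }
  }
  list(threshold = best_t, f1 = best_f1)
}

# Random score/label fixture with ties.
random_fixture <- function(n, seed, p_pos = 0.3) {
  set.seed(seed)
  list(scores = round(runif(n), 2),
       labels = rbinom(n, 1, p_pos))
}

# A tiny two-gene model universe on one chromosome (0-based half-open).
tiny_models <- function() {
  list(
    gA = lncforge:::new_gene_model(
      "gA", "alpha", "chr1", "+", 1000L, 4000L,
      list(gA.t1 = data.frame(start = c(1000L, 2500L),
                              end = c(1600L, 3200L)),
           gA.t2 = data.frame(start = c(1000L, 3400L),
                              end = c(1800L, 4000L)))),
    gB = lncforge:::new_gene_model(
      "gB", "beta", "chr1", "-", 6000L, 9000L,
      list(gB.t1 = data.frame(start = c(6000L, 8000L),
                              end = c(7000L, 9000L))))
  )
}

tiny_regions <- function(promoter_len = 1000) {
  lapply(tiny_models(), derive_regions, promoter_len = promoter_len)
}

# Canonical view of an ensemble's member negative groups for comparisons.
model_negatives_sorted <- function(model) {
  lapply(model$member_negatives, sort)
}

# Balanced-ish labeled feature matrix for learner tests.
toy_training <- function(n_pos = 30, n_neg = 120, p = 6, seed = 1,
                         shift = 1.5) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- setNames(c(rep(1, n_pos), rep(0, n_neg)), rownames(x))
  x[y == 1, 1] <- x[y == 1, 1] + shift
  x[y == 1, 2] <- x[y == 1, 2] - shift
  list(x = x, y = y)
}
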