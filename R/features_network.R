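#' @name phenotype-network-features
#' @title Phenotype and network feature operators
#' @description CRISPRi growth-screen score, small-protein content, and the
#'   three network centralities (co-expression with important cancer genes,
#'   cancer-miRNA partners, important-protein binding clusters).
NULL

#' CRISPRi phenotype score
#'
#' Per cell line the score is the mean over replicates; the feature is the
#' maximum over cell lines. Genes absent from the screen get 0 when the
#' feature table is assembled.
#'
#' @param screen_scores data.frame with `gene_id`, `cell_line`, `score`
#'   (one row per replicate).
#' @return named numeric vector over the screened genes.
#' @export
crispri_phenotype <- function(screen_scores) {
  stopifnot(all(c("gene_id", "cell_line", "score") %in% names(screen_scores)))
  per_line <- stats::aggregate(score ~ gene_id + cell_line,
                               data = screen_scores, FUN = mean)
  out <- tapply(per_line$score, per_line$gene_id, max)
  setNames(as.numeric(out), names(out))
}

#' Small-protein density and coverage
#'
#' Only small-protein intervals *fully contained* in the gene span count.
#' Density is the number of contained proteins per kb of gene length;
#' coverage is the fraction of the gene span covered by the union of the
#' contained intervals.
#'
#' @param smprot_intervals small-protein coding intervals (data.frame or
#'   GRanges).
#' @param genes gene spans or gene-model list.
#' @return matrix genes x 2 with columns `small_protein_density`,
#'   `small_protein_coverage`.
#' @export
small_protein_features <- function(smprot_intervals, genes) {
  spans <- spans_from(genes)
  gids <- S4Vectors::mcols(spans)$gene_id
  sp <- as_intervals_gr(smprot_intervals)
  dens <- numeric(length(spans))
  cov <- numeric(length(spans))
  hits <- GenomicRanges::findOverlaps(sp, spans, type = "within",
                                      ignore.strand = TRUE)
  if (length(hits)) {
    by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    for (g in names(by_gene)) {
      gi <- as.integer(g)
      contained <- sp[by_gene[[g]]]
      dens[gi] <- length(contained) / (IRanges::width(spans)[gi] / 1000)
      cov[gi] <- gr_width_sum(GenomicRanges::reduce(contained)) /
        IRanges::width(spans)[gi]
    }
  }
  out <- cbind(small_protein_density = dens, small_protein_coverage = cov)
  rownames(out) <- gids
  out
}

#' Soft threshold for a scale-free co-expression network
#'
#' Smallest integer power in `betas` for which the signed scale-free fit of
#' the connectivity distribution reaches `target_r2`; the conventional
#' fallback power 6 is used when none qualifies.
#'
#' @param expr_values numeric matrix (genes x samples) used to compute the
#'   full `|cor|^beta` adjacency.
#' @param betas candidate powers (default 1:20).
#' @param target_r2 required signed R^2 (default 0.8).
#' @param n_bins connectivity histogram bins for the fit (default 10).
#' @return list with `beta` and the per-candidate `fit` data.frame
#'   (`beta`, `r2`).
#' @export
pick_soft_threshold <- function(expr_values, betas = 1:20, target_r2 = 0.8,
                                n_bins = 10) {
  cors <- abs(stats::cor(t(expr_values)))
  diag(cors) <- 0
  fit <- vapply(betas, function(b) {
    k <- rowSums(cors^b)
    if (all(k == 0) || length(unique(k)) < 3L) return(NA_real_)
    bins <- cut(k, breaks = n_bins)
    dk <- tapply(k, bins, mean)
    pk <- as.numeric(table(bins)) / length(k)
    keep <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(keep) < 3L) return(NA_real_)
    m <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
    r2 <- summary(m)$r.squared
    -sign(stats::coef(m)[2L]) * r2
  }, numeric(1L))
  ok <- which(!is.na(fit) & fit >= target_r2)
  beta <- if (length(ok)) betas[ok[1L]] else 6L
  list(beta = beta, fit = data.frame(beta = betas, r2 = fit))
}

#' mRNA co-expression centrality
#'
#' Weighted degree of each lncRNA in the signed-free co-expression network:
#' the sum over important protein-coding genes of `|cor|^beta`, where `beta`
#' is picked by the scale-free topology criterion over the combined
#' expression matrix unless supplied.
#'
#' @param expr an `ExpressionMatrix` whose rows contain both the lncRNAs and
#'   the important protein-coding genes.
#' @param important_gene_ids ids of the important protein-coding genes.
#' @param beta optional fixed power; when `NULL` it is selected with
#'   [pick_soft_threshold()].
#' @param tumor_only use tumor samples only (default TRUE).
#' @return named numeric vector of degrees for the non-important (lncRNA)
#'   rows; attribute `beta` records the power used.
#' @export
mrna_degree <- function(expr, important_gene_ids, beta = NULL,
                        tumor_only = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (tumor_only) {
    v <- v[, expr$sample_meta$condition == "tumor", drop = FALSE]
  }
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  imp <- intersect(important_gene_ids, rownames(v))
  lnc <- setdiff(rownames(v), important_gene_ids)
  if (length(imp) == 0L) {
    return(structure(setNames(numeric(length(lnc)), lnc), beta = NA_integer_))
  }
  if (is.null(beta)) beta <- pick_soft_threshold(v)$beta
  cors <- abs(stats::cor(t(v[lnc, , drop = FALSE]),
                         t(v[imp, , drop = FALSE])))
  cors[is.na(cors)] <- 0
  structure(setNames(rowSums(cors^beta), lnc), beta = beta)
}

#' Cancer-miRNA interaction degree
#'
#' Number of unique cancer-related miRNAs predicted to interact with any of
#' a gene's transcripts.
#'
#' @param target_predictions data.frame with `transcript_id`, `mirna`.
#' @param cancer_mirnas character vector of cancer-related miRNA ids.
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @return named integer-valued vector over genes with >= 1 prediction.
#' @export
mirna_degree <- function(target_predictions, cancer_mirnas, tx2gene) {
  m <- merge(target_predictions, tx2gene, by = "transcript_id")
  m <- m[m$mirna %in% cancer_mirnas, , drop = FALSE]
  if (nrow(m) == 0L) return(setNames(numeric(0L), character(0L)))
  out <- tapply(m$mirna, m$gene_id, function(x) length(unique(x)))
  setNames(as.numeric(out), names(out))
}

#' Important-protein binding-cluster degree
#'
#' Number of distinct binding clusters, over important proteins only, that a
#' gene participates in; duplicate cluster rows count once.
#'
#' @param binding_clusters data.frame with `gene_id`, `protein`,
#'   `cluster_id`.
#' @param important_proteins character vector of important protein ids.
#' @return named numeric vector over genes with >= 1 important cluster.
#' @export
protein_degree <- function(binding_clusters, important_proteins) {
  b <- unique(binding_clusters[, c("gene_id", "protein", "cluster_id")])
  b <- b[b$protein %in% important_proteins, , drop = FALSE]
  if (nrow(b) == 0L) return(setNames(numeric(0L), character(0L)))
  out <- table(b$gene_id)
  setNames(as.numeric(out), names(out))
}
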